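cp16 <- function(M = 7L, k = 6L)
  coherence_params(M, k, probe = probe_config(n_receive = 16L))

test_that("identical traces give unit coherence and SLSC pixels equal to M", {
  chan <- coherent_channel(200, 16)
  cf <- coherence_function(chan, c(100, 1), cp16())
  expect_equal(cf$values, rep(1, 7), tolerance = 1e-12)
  off <- slsc_offline(chan, cp16())
  rt <- slsc_realtime(chan, cp16())
  interior <- 4:196
  expect_true(all(abs(off$pixels[interior, 1] - 7) < 1e-9))
  expect_true(all(abs(rt$pixels[interior, 1] - 7) < 1e-9))
})

test_that("alternating-sign channels give R(m) = (-1)^m and cancel at M = 2", {
  chan <- alternating_channel()
  cf <- coherence_function(chan, c(60, 1), cp16())
  expect_equal(cf$values, (-1)^(1:7), tolerance = 1e-12)
  off2 <- slsc_offline(chan, cp16(M = 2L))
  expect_true(all(off2$pixels[4:116, 1] == 0))   # -1 + 1, clipped at 0
})

test_that("iid noise channels have near-zero mean coherence", {
  s <- slscgcnr:::with_seed(40, matrix(rnorm(1200 * 16), 1200, 16))
  chan <- channel_from_matrix(s)
  pix <- seq(10, 1190, length.out = 220)
  R <- sapply(pix, function(n)
    coherence_function(chan, c(round(n), 1), cp16())$values)
  expect_true(all(abs(rowMeans(R)) < 0.05))
})

test_that("coherence values and SLSC pixels respect their bounds", {
  s <- slscgcnr:::with_seed(41, matrix(rnorm(600 * 16), 600, 16))
  s[, 3] <- 0.7 * s[, 2] + 0.3 * s[, 3]          # some inter-element structure
  chan <- channel_from_matrix(s)
  for (n in c(50, 300, 550)) {
    cf <- coherence_function(chan, c(n, 1), cp16())
    expect_true(all(cf$values >= -1 & cf$values <= 1))
  }
  off <- slsc_offline(chan, cp16())
  rt <- slsc_realtime(chan, cp16())
  expect_true(all(off$pixels >= 0 & off$pixels <= 7))
  expect_true(all(rt$pixels >= 0 & rt$pixels <= 7))
})

test_that("both pathways are invariant to global amplitude scaling", {
  s <- slscgcnr:::with_seed(42, matrix(rnorm(300 * 12), 300, 12))
  a <- channel_from_matrix(s)
  b <- channel_from_matrix(s * 37.5)
  prm <- cp16()
  expect_equal(slsc_offline(a, prm)$pixels, slsc_offline(b, prm)$pixels,
               tolerance = 1e-12)
  expect_equal(slsc_realtime(a, prm)$pixels, slsc_realtime(b, prm)$pixels,
               tolerance = 1e-12)
})

test_that("lag sums match direct computation and obey Cauchy-Schwarz", {
  # identical real traces: C_ij(m) = (N - m) * kernel energy of the
  # analytic signal, and C_ii = C_jj = C_ij
  chan <- coherent_channel(128, 8)
  prm <- cp16(M = 3L, k = 6L)
  ls <- lag_sums(chan, 1, prm)
  sa <- analytic_signal(chan$rf[, 1, 1])
  e <- Mod(sa)^2
  ks <- stats::filter(e, rep(1, 6), sides = 2)    # centred 6-sample sum
  n <- 60L
  for (m in 1:3) {
    expect_equal(Re(ls$C_ij[n, m]), (8 - m) * ks[n], tolerance = 1e-9)
    expect_equal(ls$C_ii[n, m], (8 - m) * ks[n], tolerance = 1e-9)
    expect_equal(ls$C_jj[n, m], (8 - m) * ks[n], tolerance = 1e-9)
  }
  # a zeroed element removes its pairs from the cross term
  s <- slscgcnr:::with_seed(43, matrix(rnorm(128 * 8), 128, 8))
  s0 <- s; s0[, 4] <- 0
  l1 <- lag_sums(channel_from_matrix(s), 1, prm)
  l0 <- lag_sums(channel_from_matrix(s0), 1, prm)
  expect_false(isTRUE(all.equal(l1$C_ij, l0$C_ij)))
  # Cauchy-Schwarz on random inputs
  for (rep in 1:100) {
    sr <- matrix(rnorm(64 * 6), 64, 6)
    lr <- lag_sums(channel_from_matrix(sr), 1, cp16(M = 2L, k = 4L))
    ok <- is.finite(lr$C_ii[, 1])
    expect_true(all(Mod(lr$C_ij[ok, ]) <=
                      sqrt(lr$C_ii[ok, ] * lr$C_jj[ok, ]) + 1e-9))
  }
})

test_that("a single live element yields zero real-time SLSC", {
  s <- matrix(0, 100, 8)
  s[, 3] <- slscgcnr:::with_seed(44, rnorm(100))
  rt <- slsc_realtime(channel_from_matrix(s), cp16(M = 3L))
  expect_true(all(rt$pixels == 0))
})

test_that("production offline SLSC matches the naive nested-loop reference", {
  s <- slscgcnr:::with_seed(45, array(rnorm(200 * 16 * 8), c(200, 16, 8)))
  chan <- channel_from_matrix(s)
  prm <- cp16()
  prod <- slsc_offline(chan, prm)$pixels
  ref <- slsc_offline_reference(chan, prm)
  expect_lt(max(abs(prod - ref)), 1e-10)
})

test_that("realtime and offline pathways agree strongly but not exactly", {
  # speckle with embedded lesions spans the full coherence range
  sim <- small_lesion_sim()
  prm <- coherence_params()
  rows <- which(sim$aligned$depth_grid > 12 & sim$aligned$depth_grid < 18)
  off <- slsc_offline(sim$aligned, prm)$pixels[rows, ]
  rt <- slsc_realtime(sim$aligned, prm)$pixels[rows, ]
  expect_gt(cor(as.vector(off), as.vector(rt)), 0.9)
  expect_false(isTRUE(all.equal(off, rt)))   # different summation orders
})

test_that("VCZ triangle profile is recovered through the coherence estimate", {
  fx <- make_coherence_fixture(vcz_profile(64), n_elements = 64L,
                               n_samples = 2000L, seed = 47)
  prm <- coherence_params()
  centers <- seq(10, 1990, by = 12)           # > 100 independent kernels
  est <- rowMeans(sapply(centers, function(n)
    coherence_function(fx, c(n, 1), prm)$values))
  expect_lt(mean(abs(est - (1 - (1:7) / 64))), 0.05)
  img <- slsc_offline(fx, prm)
  expect_equal(mean(img$pixels[4:1996, 1]), 7 - (7 * 8 / 2) / 64,
               tolerance = 0.15 / 6.5625)
})

test_that("degenerate inputs are handled per the documented conventions", {
  chan <- coherent_channel(50, 4)
  expect_error(coherence_function(chan, c(1, 1), cp16()), "kernel")
  raw <- channel_from_matrix(matrix(rnorm(100), 100, 1), aligned = FALSE)
  expect_error(slsc_offline(raw, cp16()), "aligned")
  # zero-energy pairs contribute zero rather than NaN
  s <- cbind(rnorm(60), 0, rnorm(60), rnorm(60))
  cf <- coherence_function(channel_from_matrix(s), c(30, 1),
                           cp16(M = 2L))
  expect_true(all(is.finite(cf$values)))
})
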