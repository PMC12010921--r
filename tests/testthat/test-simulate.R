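test_that("a single on-axis scatterer arrives at the geometric delay", {
  probe <- tiny_probe(n_receive = 16L, n_scanlines = 8L)
  # place the scatterer on the axis of a scan line, at the focus
  line <- 4L
  xl <- slscgcnr:::scanline_positions(probe)[line]
  zf <- 12
  field <- structure(list(x = xl, z = zf, amplitude = 1,
                          extent = list(lateral = c(-6, 6), axial = c(8, 16)),
                          lesions = list(), density = 10, seed = 1),
                     class = "scatterer_field")
  chan <- simulate_channel_data(field, probe, focus_depth = zf,
                                noise = noise_spec(Inf, -Inf), seed = 1)
  ex <- slscgcnr:::element_positions(probe)[
    slscgcnr:::receive_aperture_indices(probe, line)]
  c_mm <- probe$sound_speed * 1e3
  for (e in c(1L, 8L, 16L)) {
    d <- sqrt(zf^2 + (ex[e] - xl)^2)
    expected <- (zf + d) / c_mm * probe$sampling_frequency   # 0-based sample
    env <- Mod(analytic_signal(chan$rf[, e, line, drop = FALSE]))
    expect_lt(abs((which.max(env) - 1) - expected), 0.5)
  }
})

test_that("electronic noise is uncorrelated across elements", {
  probe <- tiny_probe(n_receive = 16L, n_scanlines = 2L)
  field <- structure(list(x = numeric(0), z = numeric(0),
                          amplitude = numeric(0),
                          extent = list(lateral = c(-6, 6), axial = c(8, 75)),
                          lesions = list(), density = 10, seed = 1),
                     class = "scatterer_field")
  chan <- simulate_channel_data(field, probe, focus_depth = 12,
                                noise = noise_spec(0, -Inf), seed = 3)
  s <- chan$rf[, , 1]
  expect_gte(nrow(s), 3900)
  cors <- cor(s)[upper.tri(diag(ncol(s)))]
  expect_true(all(abs(cors) < 0.05))
})

test_that("simulation is deterministic for fixed seeds", {
  probe <- tiny_probe(n_receive = 16L, n_scanlines = 4L)
  f <- make_phantom(probe, list(), density = 10, seed = 21,
                    axial_extent = c(9, 14))
  c1 <- simulate_channel_data(f, probe, 11, noise_spec(), seed = 22)
  c2 <- simulate_channel_data(f, probe, 11, noise_spec(), seed = 22)
  expect_identical(c1$rf, c2$rf)
  c3 <- simulate_channel_data(f, probe, 11, noise_spec(), seed = 23)
  expect_false(identical(c1$rf, c3$rf))
})

test_that("speckle envelope follows Rayleigh statistics in a uniform region", {
  env <- focal_envelope(uniform_speckle_sim(1))
  # mean/sd ratio of a Rayleigh variate is sqrt(pi/2)/sqrt(2 - pi/2)
  expect_equal(mean(env) / sd(env), 1.913, tolerance = 0.05 / 1.913)
  # equivalently, intensity is exponential; pool two independent
  # realisations (each normalised to its mean intensity) for n >= 1e4
  env2 <- focal_envelope(uniform_speckle_sim(2))
  pooled <- c(env^2 / mean(env^2), env2^2 / mean(env2^2))
  expect_gt(length(pooled), 1e4)
  expect_gt(ks.test(pooled, "pexp")$p.value, 0.01)
})

test_that("coherence decreases with lag in tissue and collapses in fluid", {
  sim <- small_lesion_sim()
  al <- sim$aligned
  prm <- coherence_params()
  focal_rows <- which(al$depth_grid > 14 & al$depth_grid < 16)
  rows <- focal_rows[seq(1, length(focal_rows), length.out = 20)]
  tissue_col <- which.min(abs(al$lines_x - 0))       # between the lesions
  fluid_col <- which.min(abs(al$lines_x - sim$fluid$center[1]))
  R_t <- rowMeans(sapply(rows, function(n)
    coherence_function(al, c(round(n), tissue_col), prm)$values))
  R_f <- rowMeans(sapply(rows, function(n)
    coherence_function(al, c(round(n), fluid_col), prm)$values))
  expect_true(all(diff(R_t) < 0))
  expect_lt(mean(R_f), 0.2)
  expect_gt(mean(R_t), mean(R_f))
})

test_that("coherence fixture reproduces a prescribed correlation profile", {
  probe <- probe_config()
  fx <- make_coherence_fixture(vcz_profile(64), n_elements = 64L,
                               n_samples = 10000L, seed = 8, probe = probe)
  s <- fx$rf[, , 1]
  emp <- cor(s)
  target <- stats::toeplitz(vcz_profile(64))
  expect_lt(max(abs(emp - target)), 0.05)
})

test_that("degenerate and invalid fixture profiles behave as specified", {
  # profile of all ones: rank-one covariance, identical element signals
  fx <- make_coherence_fixture(rep(1, 8), n_elements = 8L,
                               n_samples = 256L, seed = 4)
  s <- fx$rf[, , 1]
  expect_lt(max(abs(s - s[, 1])) / max(abs(s)), 1e-6)
  # delta profile: iid elements, near-zero estimated coherence
  fx0 <- make_coherence_fixture(c(1, rep(0, 63)), n_elements = 64L,
                                n_samples = 3000L, seed = 5)
  prm <- coherence_params()
  centers <- seq(10, 2990, by = 12)
  R <- rowMeans(sapply(centers, function(n)
    coherence_function(fx0, c(n, 1), prm)$values))
  expect_true(all(abs(R) < 0.05))
  # non-PSD profile is rejected, naming the offending eigenvalue
  expect_error(make_coherence_fixture(c(1, 0.9, -0.9), n_elements = 3L,
                                      n_samples = 64L, seed = 1),
               "eigenvalue")
})

test_that("cohort bookkeeping is correct and deterministic", {
  expect_length(make_cohort(0, 0, 0, seed = 1)$masses, 0)
  probe <- probe_config(n_scanlines = 16L)
  co <- make_cohort(2, 3, 1, probe = probe, seed = 77)
  expect_equal(nrow(co$manifest), 6)
  expect_equal(sum(co$manifest$content_class == "fluid"), 2)
  expect_equal(sum(co$manifest$content_class == "solid"), 3)
  expect_equal(sum(co$manifest$content_class == "mixed"), 1)
  co2 <- make_cohort(2, 3, 1, probe = probe, seed = 77)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$masses[[1]]$channel$rf, co2$masses[[1]]$channel$rf)
})
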