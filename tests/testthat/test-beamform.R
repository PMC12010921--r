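test_that("receive delays follow the two-way geometry", {
  probe <- probe_config()
  zg <- c(10, 20, 30)
  line <- 32L
  dt <- receive_delays(probe, zg, line)
  idx <- attr(dt, "aperture_idx")
  ex <- slscgcnr:::element_positions(probe)[idx]
  xl <- slscgcnr:::scanline_positions(probe)[line]
  d <- ex - xl
  # on-axis element: 2 z / c expressed in samples
  on_axis <- which.min(abs(d))
  expect_lt(abs(d[on_axis]), 1e-9)
  expect_equal(dt[2, on_axis],
               2 * 20e-3 / probe$sound_speed * probe$sampling_frequency,
               tolerance = 1e-12)
  # elements mirrored about the axis get equal delays
  left <- which.min(abs(d + 4.8)); right <- which.min(abs(d - 4.8))
  expect_equal(dt[, left], dt[, right], tolerance = 1e-12)
  # independent evaluation of the formula at z = 20 mm, d = 4.8 mm
  expect_equal(dt[2, right],
               (0.020 + sqrt(0.020^2 + 0.0048^2)) / 1540 * 40e6,
               tolerance = 1e-9)
  expect_error(receive_delays(probe, c(5, 4), 1), "increasing")
})

test_that("explicit delay tables shift traces as specified", {
  n <- 64L
  probe <- tiny_probe(n_receive = 2L)
  # integer-sample delay d on a unit impulse at sample p -> impulse at p - d
  p <- 30L; d <- 5L
  tr <- numeric(n); tr[p] <- 1
  chan <- channel_from_matrix(matrix(tr, n, 2), probe, aligned = FALSE)
  tab <- matrix(seq_len(n) - 1 + d, n, 2)      # absolute arrival samples
  al <- apply_delays(chan, delays = tab)
  expect_equal(which(al$rf[, 1, 1] == 1), p - d)
  # zero extra delay: identity
  al0 <- apply_delays(chan, delays = matrix(seq_len(n) - 1, n, 2))
  expect_equal(al0$rf[, 1, 1], tr)
  expect_true(al0$aligned)
  expect_error(apply_delays(al0), "already")
})

test_that("half-sample delays interpolate a sinusoid to phase accuracy", {
  n <- 512L
  fs <- 40e6; f <- 0.01 * fs
  t <- (seq_len(n) - 1) / fs
  s <- sin(2 * pi * f * t)
  probe <- tiny_probe(n_receive = 2L)
  chan <- channel_from_matrix(matrix(s, n, 2), probe, aligned = FALSE)
  al <- apply_delays(chan, delays = matrix(seq_len(n) - 1 + 0.5, n, 2))
  expected <- sin(2 * pi * f * (t + 0.5 / fs))  # phase advance pi f / fs
  interior <- 10:(n - 10)
  expect_lt(max(abs(al$rf[interior, 1, 1] - expected[interior])), 1e-3)
})

test_that("delay-and-sum is linear and detects the envelope", {
  n <- 256L; ne <- 8L
  tr <- slscgcnr:::with_seed(31, rnorm(n))
  chan <- coherent_channel(n, ne)
  # identical traces: coherent sum is N times one trace (before envelope)
  summed <- apply(chan$rf, c(1, 3), sum)
  expect_equal(summed[, 1], ne * chan$rf[, 1, 1], tolerance = 1e-12)
  # envelope of a pure tone recovers its amplitude
  fs <- 40e6; f0 <- 5e6; A <- 2.5
  tone <- A * cos(2 * pi * f0 * (seq_len(n) - 1) / fs)
  ch2 <- channel_from_matrix(matrix(tone, n, 4))
  env <- das_bmode(ch2)$pixels[, 1] / 4
  expect_equal(env[32:224], rep(A, 193), tolerance = 0.01 * A)
  # linearity: das(aX + bY) = a das(X) + b das(Y) before envelope
  X <- array(rnorm(n * 4), dim = c(n, 4, 1))
  Y <- array(rnorm(n * 4), dim = c(n, 4, 1))
  sum_of <- apply(2 * X + 3 * Y, c(1, 3), sum)
  expect_equal(sum_of, 2 * apply(X, c(1, 3), sum) + 3 * apply(Y, c(1, 3), sum),
               tolerance = 1e-12)
})

test_that("point scatterer focuses to its pixel after beamforming", {
  probe <- tiny_probe(n_receive = 16L, n_scanlines = 8L)
  line <- 5L
  xl <- slscgcnr:::scanline_positions(probe)[line]
  zf <- 12
  field <- structure(list(x = xl, z = zf, amplitude = 1,
                          extent = list(lateral = c(-6, 6), axial = c(8, 16)),
                          lesions = list(), density = 10, seed = 1),
                     class = "scatterer_field")
  chan <- simulate_channel_data(field, probe, focus_depth = zf,
                                noise = noise_spec(Inf, -Inf), seed = 1)
  bm <- das_bmode(apply_delays(chan))
  peak <- which(bm$pixels == max(bm$pixels), arr.ind = TRUE)
  expect_equal(bm$depth_grid[peak[1]], zf, tolerance = 0.1)
  expect_equal(peak[2], line, ignore_attr = TRUE)
})

test_that("display rendering log-compresses, clips, and ignores scale", {
  px <- matrix(c(1, 0.5, 1e-3, 1e-9), 2, 2)
  img <- structure(list(pixels = px, kind = "bmode_envelope",
                        depth_grid = c(1, 2), lines_x = c(0, 1),
                        dz = 1, dx = 1, probe = NULL, params = NULL),
                   class = "beamformed_image")
  disp <- render_display(img, 60)
  expect_equal(disp$pixels[1, 1], 0)
  expect_equal(disp$pixels[2, 1], -6.0206, tolerance = 1e-4)
  expect_equal(disp$pixels[1, 2], -60)       # at the clip
  expect_equal(disp$pixels[2, 2], -60)       # below the clip
  # invariant to global positive scaling
  img2 <- img; img2$pixels <- 17 * px
  expect_equal(render_display(img2, 60)$pixels, disp$pixels)
  img0 <- img; img0$pixels <- px * 0
  expect_error(render_display(img0), "all-zero")
})

test_that("screenshot quantization maps dB to 8 bits within half a step", {
  px <- matrix(10^(seq(0, -3.5, length.out = 64) ), 8, 8)
  img <- structure(list(pixels = px, kind = "bmode_envelope",
                        depth_grid = 1:8, lines_x = 1:8, dz = 1, dx = 1,
                        probe = NULL, params = NULL),
                   class = "beamformed_image")
  disp <- render_display(img, 60)
  shot <- render_screenshot(disp)
  expect_equal(shot$pixels[1, 1], 255L)                    # 0 dB
  expect_true(all(shot$pixels >= 0 & shot$pixels <= 255))
  # -dynamic_range maps to 0 and -30 dB maps to round(127.5) = 128
  mk <- function(db) {
    d <- disp; d$pixels <- matrix(db, 1, 1); render_screenshot(d)$pixels[1, 1]
  }
  expect_equal(mk(-60), 0L)
  expect_equal(mk(-30), 128L)
  # per-pixel quantization error bounded by half a grey step in dB
  back <- shot$pixels / 255 * 60 - 60
  expect_lte(max(abs(back - pmax(disp$pixels, -60))), 60 / 255 / 2)
})

test_that("screenshot intensities are double precision and order-preserving", {
  r <- structure(list(pixels = matrix(128L, 3, 3), dynamic_range = 60,
                      source_kind = "bmode_envelope", depth_grid = 1:3,
                      lines_x = 1:3, dz = 1, dx = 1),
                 class = "screenshot_raster")
  v <- screenshot_to_intensity(r)
  expect_identical(v, matrix(128, 3, 3))
  # a two-level display image keeps its ordering through the round trip
  img <- structure(list(pixels = matrix(c(1, 0.1), 2, 2), kind = "x",
                        depth_grid = 1:2, lines_x = 1:2, dz = 1, dx = 1,
                        probe = NULL, params = NULL),
                   class = "beamformed_image")
  v2 <- screenshot_to_intensity(render_screenshot(render_display(img)))
  expect_true(all(v2[1, ] > v2[2, ]))
  expect_true(all(v2 >= 0 & v2 <= 255))
})
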