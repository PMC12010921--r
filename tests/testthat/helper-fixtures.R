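# Shared fixtures: small probes, hand-built channel data, and a cache so
# expensive simulations run once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

tiny_probe <- function(n_receive = 16L, n_scanlines = 8L) {
  probe_config(n_elements_total = 32L, n_receive = n_receive,
               n_scanlines = n_scanlines)
}

# Wrap a samples x elements matrix (or 3D array) as delay-aligned
# channel data so coherence operations can run on hand-built signals.
channel_from_matrix <- function(s, probe = NULL, aligned = TRUE) {
  if (length(dim(s)) == 2) s <- array(s, dim = c(dim(s), 1L))
  if (is.null(probe))
    probe <- probe_config(n_elements_total = max(32L, dim(s)[2]),
                          n_receive = dim(s)[2],
                          n_scanlines = dim(s)[3])
  dz <- probe$sound_speed * 1e3 / (2 * probe$sampling_frequency)
  structure(list(rf = s, probe = probe, focus_depth = NULL,
                 noise = NULL, aligned = aligned, seed = 0L,
                 tissue_rms = sqrt(mean(s^2)),
                 lines_x = seq_len(dim(s)[3]) * probe$pitch,
                 aperture_idx = matrix(seq_len(dim(s)[2]), ncol = dim(s)[3],
                                       nrow = dim(s)[2]),
                 depth_grid = seq_len(dim(s)[1]) * dz,
                 field_extent = NULL, truncated = FALSE),
            class = "channel_data")
}

# Fully coherent data: one random trace replicated on every element.
coherent_channel <- function(n_samples = 200L, n_elements = 16L,
                             n_lines = 1L, seed = 1L) {
  tr <- slscgcnr:::with_seed(seed, rnorm(n_samples))
  channel_from_matrix(array(rep(tr, n_elements * n_lines),
                            dim = c(n_samples, n_elements, n_lines)))
}

# Alternating-sign data: s_{i+1} = -s_i.
alternating_channel <- function(n_samples = 120L, n_elements = 12L,
                                seed = 2L) {
  tr <- slscgcnr:::with_seed(seed, rnorm(n_samples))
  s <- outer(tr, (-1)^(seq_len(n_elements) - 1))
  channel_from_matrix(s)
}

# A small simulated phantom with one fluid and one solid lesion, shared
# across test files (one simulation, desk-scale grid).
small_lesion_sim <- function() {
  cached("small_lesion_sim", {
    probe <- probe_config(n_scanlines = 32L)
    fluid <- lesion_spec(c(-2.4, 15), c(2, 2), "fluid")
    solid <- lesion_spec(c(2.4, 15), c(2, 2), "solid_benign",
                         echogenicity_gain = 0.5)
    field <- make_phantom(probe, list(fluid, solid), density = 10,
                          seed = 301, axial_extent = c(10, 20))
    chan <- simulate_channel_data(field, probe, focus_depth = 15,
                                  noise = noise_spec(), seed = 302)
    aligned <- apply_delays(chan)
    list(probe = probe, fluid = fluid, solid = solid,
         aligned = aligned, bmode = das_bmode(aligned))
  })
}

# Uniform speckle phantom near the focus, no additive interference:
# the reference object for Rayleigh-statistics checks.
uniform_speckle_sim <- function(which = 1L) {
  seeds <- list(c(11L, 12L), c(13L, 14L))[[which]]
  cached(paste0("uniform_speckle_sim", which), {
    probe <- probe_config(n_scanlines = 32L)
    field <- make_phantom(probe, list(), density = 10, seed = seeds[1],
                          axial_extent = c(10, 20))
    chan <- simulate_channel_data(field, probe, focus_depth = 15,
                                  noise = noise_spec(Inf, -Inf),
                                  seed = seeds[2])
    aligned <- apply_delays(chan)
    list(probe = probe, aligned = aligned, bmode = das_bmode(aligned))
  })
}

# Focal-band uniform speckle envelope samples (central lines, depths
# near the transmit focus where the insonification is uniform).
focal_envelope <- function(sim) {
  zidx <- which(sim$aligned$depth_grid > 12.9 & sim$aligned$depth_grid < 17.1)
  sim$bmode$pixels[zidx, 5:28]
}

# A minimal cohort whose lesions sit well inside the field of view and
# focal zone, for fast pipeline-level tests.
small_experiment <- function() {
  cached("small_experiment", {
    cfg <- small_exp_config()
    run_experiment(cfg, cohort = small_exp_cohort(cfg))
  })
}

small_exp_config <- function(outdir = NULL) {
  experiment_config(n_fluid = 1L, n_solid = 1L, seed = 5L, outdir = outdir)
}

small_exp_cohort <- function(cfg) {
  make_cohort(cfg$n_fluid, cfg$n_solid, cfg$n_mixed, probe = cfg$probe,
              noise = cfg$noise, seed = cfg$seed,
              semi_axis_range = c(1.5, 2.2), depth_range = c(13.5, 16),
              axial_extent = c(10, 20))
}
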