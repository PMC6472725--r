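test_that("unwarped noise-free waveform is a pure sinusoid peaking at 0.25", {
  cfg <- generator_config(warp_base = 0, valley_noise_sd0 = 0)
  phi <- (0:99) / 100
  set.seed(1)
  w <- cycle_waveform(phi, inclination = 0, cfg)
  expect_equal(w, cfg$force_amplitude * sin(2 * pi * phi), tolerance = 1e-12)
  expect_equal(phi[which.max(w)], 0.25)
})

test_that("warping delays the peak and prolongs the above-mean downstroke", {
  cfg0 <- generator_config(warp_base = 0, valley_noise_sd0 = 0)
  cfgw <- generator_config(warp_base = 0.3, warp_coupling = 0,
                           valley_noise_sd0 = 0)
  phi <- (0:499) / 500
  set.seed(1); w0 <- cycle_waveform(phi, 0, cfg0)
  set.seed(1); ww <- cycle_waveform(phi, 0, cfgw)
  expect_gt(phi[which.max(ww)], 0.25)
  frac_above <- function(w) mean(w > mean(w))
  expect_gt(frac_above(ww), frac_above(w0))
})

test_that("inclination coupling acts only on non-flat terrain", {
  cfg <- generator_config(valley_noise_sd0 = 0)
  phi <- (0:99) / 100
  set.seed(2); flat <- cycle_waveform(phi, 0, cfg)
  set.seed(2); base <- cycle_waveform(phi, 0, cfg, warp_coupling = 0)
  expect_equal(flat, base, tolerance = 1e-12)
  set.seed(2); hill <- cycle_waveform(phi, 6, cfg)
  expect_false(isTRUE(all.equal(hill, flat)))
})

test_that("waveform rejects out-of-range warp and bad phase grids", {
  cfg <- generator_config()
  expect_error(cycle_waveform((0:9) / 10, 0, cfg, warp_coupling = 0.1,
                              amp_coupling = 0),
               NA)
  expect_error(cycle_waveform((0:9) / 10, 20, cfg), "out of range|below 0.5")
  expect_error(cycle_waveform(c(0, 0.5, 0.4), 0, cfg), "increasing")
  expect_error(generator_config(warp_base = 0.4, warp_coupling = 0.035),
               "monotone")
})

test_that("sessions are reproducible and restore the RNG state", {
  cfg <- generator_config(terrain = default_terrain(60), rng_seed = 9)
  set.seed(123)
  before <- .Random.seed
  s1 <- simulate_session(cfg, "NO_SHIFT", 3)
  expect_identical(.Random.seed, before)
  s2 <- simulate_session(cfg, "NO_SHIFT", 3)
  expect_identical(s1$force$values, s2$force$values)
  expect_identical(s1$hr$values, s2$hr$values)
  s3 <- simulate_session(cfg, "NO_SHIFT", 4)
  expect_false(identical(s1$force$values, s3$force$values))
})

test_that("SHIFT and NO_SHIFT traces differ exactly on inclined sectors", {
  cfg <- generator_config(terrain = default_terrain(60), rng_seed = 5)
  a <- simulate_session(cfg, "SHIFT", 1)
  b <- simulate_session(cfg, "NO_SHIFT", 1)
  sec <- cfg$terrain$sectors
  t <- sample_times(a$force)
  for (s in seq_len(nrow(sec))) {
    idx <- t >= sec$start_s[s] & t < sec$end_s[s]
    same <- identical(a$force$values[idx], b$force$values[idx])
    if (sec$incline_pct[s] == 0) expect_true(same) else expect_false(same)
  }
})

test_that("zero cadence jitter propagates to zero RevTimeCV", {
  # noise-free waveform: force noise near the crossings would itself jitter
  # the integer boundaries by a sample
  cfg <- generator_config(terrain = default_terrain(60),
                          cadence_jitter_cv = 0, valley_noise_sd0 = 0,
                          rng_seed = 2)
  ses <- simulate_session(cfg, "SHIFT", 1)
  m <- session_measures(ses$force, ses$hr, ses$terrain, run_config(),
                        subject = 1, session = "SHIFT")
  expect_true(all(m$RevTimeCV == 0))
})

test_that("session mean cadence tracks the configured cadence", {
  cfg <- generator_config(terrain = default_terrain(60),
                          cadence_jitter_cv = 5, subject_cv = 0, rng_seed = 3)
  ses <- simulate_session(cfg, "SHIFT", 1)
  seg <- detect_cycle_boundaries(ses$force, 16)
  cadence <- 60 / mean(seg$revolution_times)
  expect_lt(abs(cadence - cfg$base_cadence) / cfg$base_cadence, 0.02)
})

test_that("attractor measures respond monotonically to the warp coupling", {
  measure_at <- function(kappa) {
    cfg <- generator_config(rng_seed = 7)
    set.seed(7)
    chunks <- lapply(1:40, function(i) {
      cycle_waveform((0:49) / 50, 6, cfg, warp_coupling = kappa)
    })
    f <- force_series(unlist(chunks), 64)
    seg <- detect_cycle_boundaries(f, 16)
    cl <- embed_phase(build_sector_segment(f, seg, 100), 0.25)
    mc <- componentwise_median(cl); ml1 <- geometric_median(cl)
    c(LR = compute_LR(fit_circle_lm(cl)),
      Mc = sqrt(sum(mc^2)), ML1 = sqrt(sum(ml1^2)))
  }
  sweep <- t(sapply(c(0, 0.0117, 0.0233, 0.035), measure_at))
  for (v in c("LR", "Mc", "ML1")) {
    expect_true(all(diff(sweep[, v]) > 0),
                info = paste(v, "not increasing in coupling"))
  }
})

test_that("a study on disk is complete and checksum-stable under one seed", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- generator_config(n_subjects = 1, terrain = default_terrain(30),
                          rng_seed = 11)
  m1 <- simulate_study(cfg, modes = "SHIFT", out_dir = dir1)
  expect_equal(nrow(m1), 1L)
  expect_true(all(file.exists(file.path(dir1, c(m1$force_file, m1$hr_file,
                                                "terrain.csv",
                                                "manifest.csv")))))
  m2 <- simulate_study(cfg, modes = "SHIFT", out_dir = dir2)
  expect_equal(m1$force_md5, m2$force_md5)
  expect_equal(m1$hr_md5, m2$hr_md5)

  cfg2 <- generator_config(n_subjects = 2, terrain = default_terrain(30),
                           rng_seed = 11)
  m3 <- simulate_study(cfg2, modes = c("SHIFT", "NO_SHIFT"), out_dir = dir1)
  expect_equal(nrow(m3), 4L)  # 2 subjects x 2 sessions
})
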