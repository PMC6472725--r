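#' Default 13-sector terrain profile
#'
#' A virtual terrain of 13 contiguous sectors. Sectors 1-3 and 12-13 are
#' flat accommodation stretches; sectors 4-11 carry the inclination pattern
#' entering the analysis, spanning a downhill phase followed by uphill work.
#'
#' @param sector_duration_s Duration of every sector in seconds (default 180).
#' @param inclines_pct Percent grades of sectors 4-11
#'   (default `c(0, 2, 4, 1, -2, -4, 3, 6)`).
#' @return A [terrain_profile] with `analysis_ids = 4:11`.
#' @export
default_terrain <- function(sector_duration_s = 180,
                            inclines_pct = c(0, 2, 4, 1, -2, -4, 3, 6)) {
  stopifnot(length(inclines_pct) == 8L)
  incl <- c(0, 0, 0, inclines_pct, 0, 0)
  n <- length(incl)
  start <- (seq_len(n) - 1) * sector_duration_s
  terrain_profile(
    data.frame(sector = seq_len(n), start_s = start,
               end_s = start + sector_duration_s, incline_pct = incl),
    analysis_ids = 4:11
  )
}

#' Synthetic-study generator configuration
#'
#' Parameters of the synthetic multi-sector session generator. The force
#' waveform is a phase-warped sinusoid: warping strength
#' `beta = warp_base + warp_coupling * inclination` shifts the force peak
#' later into the downstroke and prolongs the above-mean downstroke portion
#' as the load grows; additional Gaussian variability is injected around the
#' waveform's local minimum on positive grades. Heart rate follows a
#' first-order lag toward `hr_rest + hr_gain * inclination`.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param terrain A [terrain_profile] (default [default_terrain()]).
#' @param base_cadence Mean cadence, rev/min (default 77).
#' @param cadence_jitter_cv Per-cycle period CV, percent (default 3).
#' @param force_amplitude Waveform amplitude, newtons (default 150).
#' @param warp_base Baseline warp strength beta0, dimensionless in
#'   \[0, 0.45) (default 0.08).
#' @param warp_coupling Warp increase per percent grade (default 0.035);
#'   applied in NO_SHIFT sessions, forced to 0 in SHIFT.
#' @param amp_coupling Relative amplitude increase per percent grade
#'   (default 0.05); NO_SHIFT only.
#' @param valley_noise_sd0 Baseline force noise SD, newtons (default 4).
#' @param valley_noise_sd1 Extra valley-noise SD per percent positive grade,
#'   newtons (default 1.5); NO_SHIFT only.
#' @param hr_rest Flat-terrain heart rate, bpm (default 95).
#' @param hr_gain Heart-rate rise per percent grade, bpm (default 7).
#' @param hr_shift_gain_factor Multiplier on `hr_gain` in SHIFT sessions
#'   (default 0.5): gearing absorbs part of the load but effort still rises.
#' @param hr_time_constant First-order lag time constant, seconds
#'   (default 30).
#' @param hr_noise_sd Heart-rate process noise SD, bpm (default 1.5).
#' @param subject_cv Relative between-subject SD applied to cadence,
#'   warp coupling and heart-rate gain (default 0.1).
#' @param rng_seed Global seed; per-session streams are derived from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 10L,
                             terrain = default_terrain(),
                             base_cadence = 77,
                             cadence_jitter_cv = 3,
                             force_amplitude = 150,
                             warp_base = 0.08,
                             warp_coupling = 0.035,
                             amp_coupling = 0.05,
                             valley_noise_sd0 = 4,
                             valley_noise_sd1 = 1.5,
                             hr_rest = 95,
                             hr_gain = 7,
                             hr_shift_gain_factor = 0.5,
                             hr_time_constant = 30,
                             hr_noise_sd = 1.5,
                             subject_cv = 0.1,
                             rng_seed = 1L) {
  if (base_cadence <= 0) stop("base_cadence must be positive")
  if (warp_base < 0 || warp_base >= 0.45) stop("warp_base must be in [0, 0.45)")
  max_abs_incl <- max(abs(terrain$sectors$incline_pct))
  if (warp_base + warp_coupling * max_abs_incl >= 0.5) {
    stop("warp_base + warp_coupling * max|inclination| must stay below 0.5 ",
         "(the phase warp must remain a monotone time map)")
  }
  if (any(c(cadence_jitter_cv, valley_noise_sd0, valley_noise_sd1,
            hr_noise_sd, subject_cv) < 0)) {
    stop("noise scales must be non-negative")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), terrain = terrain,
         base_cadence = base_cadence, cadence_jitter_cv = cadence_jitter_cv,
         force_amplitude = force_amplitude, warp_base = warp_base,
         warp_coupling = warp_coupling, amp_coupling = amp_coupling,
         valley_noise_sd0 = valley_noise_sd0,
         valley_noise_sd1 = valley_noise_sd1,
         hr_rest = hr_rest, hr_gain = hr_gain,
         hr_shift_gain_factor = hr_shift_gain_factor,
         hr_time_constant = hr_time_constant, hr_noise_sd = hr_noise_sd,
         subject_cv = subject_cv, rng_seed = as.integer(rng_seed)),
    class = "generator_config"
  )
}

# Monotone phase warp:
#   g(phi) = phi - beta * (sin(2 pi phi) + 0.5 (1 - cos(2 pi phi))) / (2 pi).
# The sine term delays the force peak into the second quadrant; the cosine
# term moves the mid-cycle zero crossing later, prolonging the above-mean
# downstroke. A pure sine warp keeps the waveform antisymmetric over half a
# cycle (its value distribution stays symmetric about zero), so the cosine
# term is what lets location measures of the embedded cloud respond to beta.
# g is strictly increasing for |beta| < 2/sqrt(5) ~ 0.894; the config keeps
# |beta| < 0.5.
warp_phase <- function(phi, beta) {
  phi - beta * (sin(2 * pi * phi) + 0.5 * (1 - cos(2 * pi * phi))) / (2 * pi)
}

# Phase at which the warped sinusoid attains its minimum: g(phi) = 0.75.
waveform_min_phase <- function(beta) {
  if (abs(beta) < 1e-12) return(0.75)
  stats::uniroot(function(p) warp_phase(p, beta) - 0.75,
                 lower = 0.5, upper = 1, tol = 1e-10)$root
}

#' One cycle of the synthetic tangential-force waveform
#'
#' Returns `A * sin(2 pi g(phi)) + eps(phi)` on the given phase grid, with
#' warp strength `beta = warp_base + warp_coupling * inclination` and
#' zero-mean Gaussian noise whose SD is
#' `valley_noise_sd0 + valley_noise_sd1 * max(0, inclination) * v(phi)`,
#' `v` a unit Gaussian bump centered on the waveform's minimum. Consumes
#' `length(phase_grid)` normal draws from the current RNG stream.
#'
#' @param phase_grid Strictly increasing phases in \[0, 1).
#' @param inclination Percent grade of the sector.
#' @param cfg A [generator_config].
#' @param warp_coupling,amp_coupling,valley_noise_sd1 Session-effective
#'   couplings (a SHIFT session passes 0); default from `cfg`.
#' @param amplitude Waveform amplitude (default `cfg$force_amplitude`).
#' @return Numeric vector, same length as `phase_grid`.
#' @export
cycle_waveform <- function(phase_grid, inclination, cfg,
                           warp_coupling = cfg$warp_coupling,
                           amp_coupling = cfg$amp_coupling,
                           valley_noise_sd1 = cfg$valley_noise_sd1,
                           amplitude = cfg$force_amplitude) {
  if (any(phase_grid < 0 | phase_grid >= 1) ||
      any(diff(phase_grid) <= 0)) {
    stop("phase grid must be strictly increasing in [0, 1)")
  }
  beta <- cfg$warp_base + warp_coupling * inclination
  if (abs(beta) >= 0.5) stop("warp strength out of range: |beta| must be < 0.5")
  amp <- amplitude * max(0.2, 1 + amp_coupling * inclination)
  base <- amp * sin(2 * pi * warp_phase(phase_grid, beta))
  phi_min <- waveform_min_phase(beta)
  bump <- exp(-0.5 * ((phase_grid - phi_min) / 0.06)^2)
  sd_vec <- cfg$valley_noise_sd0 +
    valley_noise_sd1 * max(0, inclination) * bump
  base + stats::rnorm(length(phase_grid), mean = 0, sd = sd_vec)
}

# Deterministic per-session seed: one global seed streams all sessions.
# The stream depends on the subject only, so SHIFT and NO_SHIFT sessions of
# one subject share cadence and noise draws and differ exactly where the
# couplings act.
session_seed <- function(rng_seed, subject_index) {
  as.integer((abs(rng_seed) * 1000L + subject_index) %% 2147483647L)
}

#' Simulate one session (force at 64 Hz, heart rate at 1 Hz)
#'
#' Per sector, pedalling cycles are generated with per-cycle period
#' `60/cadence * (1 + N(0, jitter_cv/100))` and sampled at 64 Hz; the cycle
#' waveform couples to the sector inclination in NO_SHIFT sessions
#' (warp, amplitude, valley noise) and is load-invariant in SHIFT sessions
#' (gearing absorbs the load). Heart rate follows a noisy first-order lag
#' toward the sector target. Identical arguments reproduce identical output.
#'
#' @param cfg A [generator_config].
#' @param mode `"SHIFT"` or `"NO_SHIFT"`.
#' @param subject_index 1-based subject number (<= `cfg$n_subjects`).
#' @return List with `force` ([force_series]), `hr` ([hr_series]),
#'   `terrain` ([terrain_profile]), `mode`, `subject`.
#' @export
simulate_session <- function(cfg, mode = c("NO_SHIFT", "SHIFT"),
                             subject_index = 1L) {
  mode <- match.arg(mode)
  if (subject_index < 1L || subject_index > cfg$n_subjects) {
    stop("subject_index must be in 1..n_subjects")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(session_seed(cfg$rng_seed, subject_index))

  # subject traits (drawn identically for both sessions of a subject)
  cadence_i <- cfg$base_cadence * (1 + cfg$subject_cv * stats::rnorm(1))
  kappa_i <- max(0, cfg$warp_coupling * (1 + cfg$subject_cv * stats::rnorm(1)))
  hr_gain_i <- cfg$hr_gain * (1 + cfg$subject_cv * stats::rnorm(1))
  hr_rest_i <- cfg$hr_rest + 5 * stats::rnorm(1)

  shift <- mode == "SHIFT"
  kappa_eff <- if (shift) 0 else kappa_i
  amp_eff <- if (shift) 0 else cfg$amp_coupling
  valley_eff <- if (shift) 0 else cfg$valley_noise_sd1
  hr_gain_eff <- hr_gain_i * if (shift) cfg$hr_shift_gain_factor else 1

  fs <- 64
  sectors <- cfg$terrain$sectors
  base_period <- 60 / cadence_i
  force <- vector("list", nrow(sectors))
  for (s in seq_len(nrow(sectors))) {
    incl <- sectors$incline_pct[s]
    n_target <- round((sectors$end_s[s] - sectors$start_s[s]) * fs)
    chunks <- list()
    n_have <- 0L
    while (n_have < n_target) {
      period <- base_period *
        max(0.25, 1 + stats::rnorm(1, 0, cfg$cadence_jitter_cv / 100))
      n_c <- max(4L, as.integer(round(period * fs)))
      phi <- (seq_len(n_c) - 1) / n_c
      chunks[[length(chunks) + 1L]] <-
        cycle_waveform(phi, incl, cfg,
                       warp_coupling = kappa_eff, amp_coupling = amp_eff,
                       valley_noise_sd1 = valley_eff)
      n_have <- n_have + n_c
    }
    force[[s]] <- unlist(chunks, use.names = FALSE)[seq_len(n_target)]
  }
  force_vals <- unlist(force, use.names = FALSE)

  total_s <- sum(sectors$end_s - sectors$start_s)
  incl_at <- function(t) {
    s <- findInterval(t, sectors$start_s)
    sectors$incline_pct[pmax(1L, pmin(s, nrow(sectors)))]
  }
  hr <- numeric(total_s)
  hr_state <- hr_rest_i
  for (k in seq_len(total_s)) {
    target <- hr_rest_i + hr_gain_eff * incl_at(k - 1)
    hr_state <- hr_state + (target - hr_state) / cfg$hr_time_constant +
      stats::rnorm(1, 0, cfg$hr_noise_sd)
    hr[k] <- max(40, hr_state)
  }

  list(force = force_series(force_vals, sample_rate = fs),
       hr = hr_series(hr, sample_rate = 1),
       terrain = cfg$terrain, mode = mode, subject = subject_index)
}

#' Simulate and write a full synthetic study to disk
#'
#' Writes one force CSV and one heart-rate CSV per subject x session, the
#' terrain profile, and a manifest listing every file with its MD5 checksum.
#'
#' @param cfg A [generator_config].
#' @param modes Sessions to generate (default both).
#' @param out_dir Output directory (created if absent).
#' @return The manifest data.frame, invisibly. The manifest is also written
#'   to `out_dir/manifest.csv`.
#' @export
simulate_study <- function(cfg, modes = c("SHIFT", "NO_SHIFT"), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  terrain_path <- file.path(out_dir, "terrain.csv")
  write_terrain_profile(cfg$terrain, terrain_path)
  rows <- list()
  for (mode in modes) {
    for (subj in seq_len(cfg$n_subjects)) {
      ses <- simulate_session(cfg, mode, subj)
      fpath <- file.path(out_dir, sprintf("force_s%02d_%s.csv", subj, mode))
      hpath <- file.path(out_dir, sprintf("hr_s%02d_%s.csv", subj, mode))
      utils::write.csv(data.frame(force_n = signif(ses$force$values, 8)),
                       fpath, row.names = FALSE, quote = FALSE)
      utils::write.csv(data.frame(hr_bpm = signif(ses$hr$values, 8)),
                       hpath, row.names = FALSE, quote = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subj, mode = mode,
        force_file = basename(fpath), hr_file = basename(hpath),
        force_md5 = unname(tools::md5sum(fpath)),
        hr_md5 = unname(tools::md5sum(hpath)),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
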