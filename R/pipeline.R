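#' Per-sector outcome measures for one session
#'
#' For every analysis sector of the terrain profile: slice the force trace
#' to the sector's time window, segment it into pedalling cycles at upward
#' zero crossings, time-normalize and z-score, embed with a quarter-cycle
#' delay, and compute the five outcome variables — LR (regression-circle
#' center offset), the norms of the componentwise and geometric medians,
#' the revolution-time CV, and the sector-mean heart rate.
#'
#' A sector whose force slice cannot be segmented is reported as a warning
#' and omitted from the result (the contrast stage then rejects the
#' incomplete design by name).
#'
#' @param force A [force_series] covering the session.
#' @param hr An [hr_series] covering the session.
#' @param profile A [terrain_profile] with time-based sector bounds.
#' @param config A [run_config].
#' @param subject,session Identifiers copied into the output rows.
#' @return data.frame, one row per analysis sector, columns
#'   `subject,session,sector,LR,Mc,ML1,RevTimeCV,HR,n_cycles,
#'   Mc_x,Mc_y,ML1_x,ML1_y`.
#' @export
session_measures <- function(force, hr, profile, config = run_config(),
                             subject = 1L, session = "NO_SHIFT") {
  rows <- analysis_sectors(profile)
  t_force <- sample_times(force)
  out <- list()
  for (i in seq_len(nrow(rows))) {
    sec <- rows[i, ]
    idx <- which(t_force >= sec$start_s & t_force < sec$end_s)
    row <- tryCatch({
      if (length(idx) < 2L) stop("sector window contains no force samples")
      slice <- force_series(force$values[idx],
                            sample_rate = force$sample_rate,
                            start_time = t_force[idx[1L]])
      seg <- detect_cycle_boundaries(slice, config$min_cycle_samples)
      segment <- build_sector_segment(slice, seg, config$interp_points)
      cloud <- embed_phase(segment, config$tau_fraction)
      fit <- fit_circle_lm(cloud)
      mc <- componentwise_median(cloud)
      ml1 <- geometric_median(cloud)
      data.frame(
        subject = subject, session = session, sector = sec$sector,
        LR = compute_LR(fit),
        Mc = sqrt(sum(mc^2)), ML1 = sqrt(sum(ml1^2)),
        RevTimeCV = rev_time_cv(segment$revolution_times),
        HR = sector_mean_hr(hr, sec$start_s, sec$end_s),
        n_cycles = segment$n_cycles,
        Mc_x = mc[1L], Mc_y = mc[2L], ML1_x = ml1[1L], ML1_y = ml1[2L],
        stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("sector %s skipped for subject %s (%s): %s",
                      sec$sector, subject, session, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(row)) out[[length(out) + 1L]] <- row
  }
  if (length(out) == 0L) {
    stop("no sector of this session could be processed")
  }
  do.call(rbind, out)
}

#' Measures table for a whole synthetic study, in memory
#'
#' Simulates every subject x session with [simulate_session] and runs
#' [session_measures] on each, without touching the file system.
#'
#' @param cfg A [generator_config].
#' @param config A [run_config].
#' @param modes Sessions to include (default both).
#' @return data.frame of per-sector measures for all subjects and sessions.
#' @export
study_measures <- function(cfg, config = run_config(),
                           modes = c("SHIFT", "NO_SHIFT")) {
  out <- list()
  for (mode in modes) {
    for (subj in seq_len(cfg$n_subjects)) {
      ses <- simulate_session(cfg, mode, subj)
      out[[length(out) + 1L]] <-
        session_measures(ses$force, ses$hr, ses$terrain, config,
                         subject = subj, session = mode)
    }
  }
  do.call(rbind, out)
}

#' Measures table from a simulated study on disk
#'
#' Reads the manifest written by [simulate_study] and processes every
#' session file through [session_measures].
#'
#' @param study_dir Directory containing `manifest.csv`, `terrain.csv` and
#'   the session CSVs.
#' @param config A [run_config].
#' @param analysis_ids Analysis sector ids (default 4:11).
#' @return data.frame of per-sector measures.
#' @export
study_measures_from_files <- function(study_dir, config = run_config(),
                                      analysis_ids = 4:11) {
  manifest <- utils::read.csv(file.path(study_dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  profile <- read_terrain_profile(file.path(study_dir, "terrain.csv"),
                                  analysis_ids = analysis_ids)
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    force <- read_force_series(file.path(study_dir, manifest$force_file[i]),
                               sample_rate = 64)
    hr <- read_hr_series(file.path(study_dir, manifest$hr_file[i]),
                         sample_rate = 1)
    out[[length(out) + 1L]] <-
      session_measures(force, hr, profile, config,
                       subject = manifest$subject[i],
                       session = manifest$mode[i])
  }
  do.call(rbind, out)
}
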