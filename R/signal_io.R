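#' Force series constructor
#'
#' A `force_series` holds a uniformly sampled tangential pedal-force trace
#' for one session (nominally 64 Hz, newtons).
#'
#' @param values Numeric vector of force readings, in newtons.
#' @param sample_rate Samples per second (> 0).
#' @param start_time Time offset of the first sample, seconds.
#' @return An object of class `force_series` with fields `values`,
#'   `sample_rate`, `start_time`.
#' @export
force_series <- function(values, sample_rate = 64, start_time = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("force series needs at least 2 samples")
  if (!all(is.finite(values))) stop("force values must be finite")
  if (!is.finite(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be a positive number")
  }
  structure(
    list(values = values, sample_rate = sample_rate, start_time = start_time),
    class = "force_series"
  )
}

#' Heart-rate series constructor
#'
#' @param values Numeric vector of heart rates, beats per minute (> 0).
#' @param sample_rate Samples per second (nominally 1).
#' @param start_time Time offset of the first sample, seconds.
#' @return An object of class `hr_series`.
#' @export
hr_series <- function(values, sample_rate = 1, start_time = 0) {
  values <- as.numeric(values)
  if (!all(is.finite(values)) || any(values <= 0)) {
    stop("heart-rate values must be finite and positive")
  }
  if (!is.finite(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be a positive number")
  }
  structure(
    list(values = values, sample_rate = sample_rate, start_time = start_time),
    class = "hr_series"
  )
}

#' Sample times of a series
#'
#' @param x A `force_series` or `hr_series`.
#' @return Numeric vector of sample times in seconds.
#' @export
sample_times <- function(x) {
  x$start_time + (seq_along(x$values) - 1) / x$sample_rate
}

#' Terrain profile constructor
#'
#' Ordered, contiguous terrain sectors with simulated inclination, and the
#' subset of sectors that enters the statistics (the analysis sectors).
#'
#' @param sectors data.frame with columns `sector` (integer id), `start_s`,
#'   `end_s` (seconds), `incline_pct` (percent grade).
#' @param analysis_ids Sector ids used for the contrast analysis
#'   (at least 3, since the contrast needs >= 3 distinct weights).
#' @return An object of class `terrain_profile`.
#' @export
terrain_profile <- function(sectors, analysis_ids) {
  required <- c("sector", "start_s", "end_s", "incline_pct")
  if (!all(required %in% names(sectors))) {
    stop("sectors must have columns: ", paste(required, collapse = ", "))
  }
  sectors <- sectors[order(sectors$start_s), required, drop = FALSE]
  if (any(sectors$end_s <= sectors$start_s)) {
    stop("every sector must have end_s > start_s")
  }
  if (nrow(sectors) > 1L) {
    gaps <- sectors$start_s[-1L] - sectors$end_s[-nrow(sectors)]
    if (any(abs(gaps) > 1e-9)) {
      stop("sectors must be contiguous and non-overlapping")
    }
  }
  if (anyDuplicated(sectors$sector)) stop("duplicate sector ids")
  analysis_ids <- as.integer(analysis_ids)
  if (!all(analysis_ids %in% sectors$sector)) {
    stop("analysis_ids must be a subset of sector ids")
  }
  if (length(analysis_ids) < 3L) {
    stop("need at least 3 analysis sectors for a contrast")
  }
  structure(
    list(sectors = sectors, analysis_ids = analysis_ids),
    class = "terrain_profile"
  )
}

#' Analysis-sector rows of a terrain profile, in sector-id order
#' @param profile A `terrain_profile`.
#' @return data.frame of the analysis sectors.
#' @export
analysis_sectors <- function(profile) {
  rows <- profile$sectors[match(profile$analysis_ids, profile$sectors$sector), ]
  rownames(rows) <- NULL
  rows
}

#' Run configuration
#'
#' @param interp_points Samples per time-normalized cycle (default 100).
#' @param tau_fraction Embedding delay as a fraction of one cycle
#'   (default 0.25); `tau_fraction * interp_points` must be an integer so the
#'   delay is a whole number of samples on the normalized grid.
#' @param alpha Significance level for the contrast decision (default 0.01).
#' @param min_cycle_samples Minimum raw samples per cycle accepted by the
#'   segmentation (default 16, about a 240 rpm cadence ceiling at 64 Hz).
#' @param rng_seed Integer seed for anything stochastic downstream.
#' @return A list of class `run_config`.
#' @export
run_config <- function(interp_points = 100L, tau_fraction = 0.25,
                       alpha = 0.01, min_cycle_samples = 16L,
                       rng_seed = 1L) {
  interp_points <- as.integer(interp_points)
  if (interp_points < 4L) stop("interp_points must be >= 4")
  if (!(tau_fraction > 0 && tau_fraction < 1)) {
    stop("tau_fraction must lie in (0, 1)")
  }
  tau_samples <- tau_fraction * interp_points
  if (abs(tau_samples - round(tau_samples)) > 1e-8) {
    stop("tau_fraction * interp_points must be an integer number of samples")
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  structure(
    list(interp_points = interp_points, tau_fraction = tau_fraction,
         alpha = alpha, min_cycle_samples = as.integer(min_cycle_samples),
         rng_seed = as.integer(rng_seed)),
    class = "run_config"
  )
}

# Read a delimited file with an optional single header line, auto-detected
# by a non-numeric first row. Returns a data.frame of numeric columns.
read_numeric_csv <- function(path, n_cols_expected = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- utils::read.csv(path, header = FALSE, nrows = 1,
                           stringsAsFactors = FALSE)
  has_header <- any(is.na(suppressWarnings(as.numeric(unlist(first)))))
  df <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (j in seq_along(df)) {
    num <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(num) & !is.na(df[[j]]) & nzchar(trimws(df[[j]])))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value '%s' in %s at data row %d",
                   df[[j]][bad[1L]], basename(path), bad[1L]))
    }
    if (any(is.na(num))) {
      stop(sprintf("missing value in %s at data row %d",
                   basename(path), which(is.na(num))[1L]))
    }
    df[[j]] <- num
  }
  df
}

check_uniform_times <- function(times, path) {
  dt <- diff(times)
  if (any(dt <= 0)) stop("time column must be strictly increasing in ", path)
  rel <- abs(dt - mean(dt)) / mean(dt)
  if (any(rel > 1e-6)) {
    stop("time column in ", path, " is not uniformly spaced")
  }
  invisible(mean(dt))
}

#' Read a force trace from a delimited text file
#'
#' Accepts either a single force column or `time_s,force_n`; a single header
#' line is auto-detected. A time column, if present, must be uniformly
#' spaced (relative tolerance 1e-6).
#'
#' @param path File path.
#' @param sample_rate Sampling rate in Hz (default 64).
#' @return A [force_series].
#' @export
read_force_series <- function(path, sample_rate = 64) {
  df <- read_numeric_csv(path)
  if (ncol(df) == 1L) {
    force_series(df[[1L]], sample_rate = sample_rate)
  } else if (ncol(df) == 2L) {
    check_uniform_times(df[[1L]], path)
    force_series(df[[2L]], sample_rate = sample_rate,
                 start_time = df[[1L]][1L])
  } else {
    stop("expected 1 (force) or 2 (time, force) columns in ", path)
  }
}

#' Read a heart-rate trace from a delimited text file
#'
#' Same dialect as [read_force_series]: one `hr_bpm` column or
#' `time_s,hr_bpm`.
#'
#' @param path File path.
#' @param sample_rate Sampling rate in Hz (default 1).
#' @return An [hr_series].
#' @export
read_hr_series <- function(path, sample_rate = 1) {
  df <- read_numeric_csv(path)
  if (ncol(df) == 1L) {
    hr_series(df[[1L]], sample_rate = sample_rate)
  } else if (ncol(df) == 2L) {
    check_uniform_times(df[[1L]], path)
    hr_series(df[[2L]], sample_rate = sample_rate, start_time = df[[1L]][1L])
  } else {
    stop("expected 1 (hr) or 2 (time, hr) columns in ", path)
  }
}

#' Read a terrain profile from a delimited text file
#'
#' Expects columns `sector,start_s,end_s,incline_pct`; sectors are sorted by
#' start time and validated for contiguity.
#'
#' @param path File path.
#' @param analysis_ids Sector ids to include in the statistics
#'   (default 4 through 11).
#' @return A [terrain_profile].
#' @export
read_terrain_profile <- function(path, analysis_ids = 4:11) {
  df <- read_numeric_csv(path)
  if (ncol(df) != 4L) {
    stop("expected 4 columns (sector,start_s,end_s,incline_pct) in ", path)
  }
  names(df) <- c("sector", "start_s", "end_s", "incline_pct")
  df$sector <- as.integer(df$sector)
  terrain_profile(df, analysis_ids = analysis_ids)
}

#' Write a terrain profile to CSV
#' @param profile A [terrain_profile].
#' @param path Output file path.
#' @export
write_terrain_profile <- function(profile, path) {
  utils::write.csv(profile$sectors, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read the per-sector measures table
#'
#' One row per (subject, session, sector) with the five outcome variables.
#' Values round-trip to at least 6 significant digits.
#'
#' @param rows data.frame with columns `subject,session,sector,LR,Mc,ML1,
#'   RevTimeCV,HR,n_cycles`.
#' @param path File path.
#' @return `path` invisibly (writer); the data.frame (reader).
#' @export
write_measures_table <- function(rows, path) {
  if (nrow(rows) == 0L) stop("measures table is empty")
  out <- rows
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 10))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measures_table
#' @export
read_measures_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read the contrast-analysis results table
#'
#' One row per (condition, variable) with t, one-tailed p, effect size g and
#' the prerequisite-check p-values.
#'
#' @param rows data.frame as produced by [run_contrast_table].
#' @param path File path.
#' @return `path` invisibly (writer); the data.frame (reader).
#' @export
write_contrast_table <- function(rows, path) {
  if (nrow(rows) == 0L) stop("contrast table is empty")
  out <- rows
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 10))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_contrast_table
#' @export
read_contrast_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
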