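#' Segment a force trace into pedalling cycles
#'
#' Cycle boundaries are upward zero crossings: the first sample at or above
#' zero whose predecessor is below zero. No sub-sample interpolation is
#' applied, so revolution times are exact multiples of the sample period.
#' Boundaries closer than `min_cycle_samples` to the previous surviving
#' boundary are discarded (noise-induced double crossings). Samples before
#' the first and after the last boundary do not belong to any complete cycle.
#'
#' @param series A [force_series].
#' @param min_cycle_samples Minimum raw samples per cycle (default 16).
#' @return A list of class `cycle_segmentation` with `boundaries` (sample
#'   indices, 1-based), `n_cycles`, and `revolution_times` in seconds.
#' @export
detect_cycle_boundaries <- function(series, min_cycle_samples = 16L) {
  v <- series$values
  cross <- which(v[-1L] >= 0 & v[-length(v)] < 0) + 1L
  if (length(cross) >= 2L && min_cycle_samples > 1L) {
    keep <- cross[1L]
    for (k in cross[-1L]) {
      if (k - keep[length(keep)] >= min_cycle_samples) keep <- c(keep, k)
    }
    cross <- keep
  }
  if (length(cross) < 2L) {
    stop("segmentation failed: fewer than 2 upward zero crossings")
  }
  structure(
    list(boundaries = cross,
         n_cycles = length(cross) - 1L,
         revolution_times = diff(cross) / series$sample_rate),
    class = "cycle_segmentation"
  )
}

#' Time-normalize one cycle to a fixed number of samples
#'
#' Linear interpolation of the cycle onto `interp_points` equally spaced
#' positions of the rescaled index grid \[0, 1\]. Endpoints are preserved; a
#' cycle that already has `interp_points` samples is returned unchanged.
#'
#' @param cycle_values Numeric vector, at least 2 samples.
#' @param interp_points Output length (default 100).
#' @return Numeric vector of length `interp_points`.
#' @export
normalize_cycle <- function(cycle_values, interp_points = 100L) {
  n <- length(cycle_values)
  if (n < 2L) stop("a cycle needs at least 2 samples")
  if (n == interp_points) return(as.numeric(cycle_values))
  stats::approx(x = seq(0, 1, length.out = n), y = cycle_values,
                xout = seq(0, 1, length.out = interp_points))$y
}

#' Build a sector segment: normalize, reassemble, z-score
#'
#' Each complete cycle is time-normalized to `interp_points` samples, the
#' cycles are concatenated in temporal order, and the concatenated segment
#' is z-standardized with its own arithmetic mean and sample standard
#' deviation (divisor n - 1).
#'
#' @param series The [force_series] the segmentation was derived from.
#' @param seg A `cycle_segmentation` from [detect_cycle_boundaries].
#' @param interp_points Samples per normalized cycle (default 100).
#' @return A list of class `sector_segment` with `z_values`, `n_cycles`,
#'   `samples_per_cycle`, `revolution_times`, `mean_raw`, `sd_raw`.
#' @export
build_sector_segment <- function(series, seg, interp_points = 100L) {
  if (seg$n_cycles < 1L) stop("segmentation has no complete cycle")
  b <- seg$boundaries
  cycles <- lapply(seq_len(seg$n_cycles), function(j) {
    normalize_cycle(series$values[b[j]:(b[j + 1L] - 1L)], interp_points)
  })
  x <- unlist(cycles, use.names = FALSE)
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("zero variance in reassembled segment: cannot z-score")
  }
  structure(
    list(z_values = (x - m) / s,
         n_cycles = seg$n_cycles,
         samples_per_cycle = as.integer(interp_points),
         revolution_times = seg$revolution_times,
         mean_raw = m, sd_raw = s),
    class = "sector_segment"
  )
}

#' Raw samples per pedalling cycle at a given cadence
#'
#' The sampling resolution available to the time normalization:
#' `sample_rate * 60 / cadence_rpm` raw measured values per revolution.
#'
#' @param sample_rate Sampling rate in Hz.
#' @param cadence_rpm Cadence in revolutions per minute.
#' @return Samples per cycle (real).
#' @export
samples_per_cycle <- function(sample_rate, cadence_rpm) {
  if (cadence_rpm <= 0) stop("cadence must be positive")
  sample_rate * 60 / cadence_rpm
}
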