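#' Two-dimensional delay embedding of a standardized sector segment
#'
#' Pairs the z-scored series with a copy of itself delayed by
#' `tau_fraction` of one normalized cycle: point i is
#' (z\[i\], z\[i + tau\]). The series is truncated at its end (no
#' wrap-around), so the point count is `length(z) - tau_samples`. At the
#' default quarter-cycle delay a pure sinusoid unfolds into a circular
#' limit-cycle arrangement.
#'
#' @param segment A `sector_segment` from [build_sector_segment].
#' @param tau_fraction Delay as a fraction of one cycle (default 0.25);
#'   `tau_fraction * samples_per_cycle` must be a whole number of samples.
#' @return A list of class `phase_cloud` with `points` (n x 2 matrix,
#'   columns `x` = z(t), `y` = z(t + tau)) and `tau_samples`.
#' @export
embed_phase <- function(segment, tau_fraction = 0.25) {
  spc <- segment$samples_per_cycle
  tau_real <- tau_fraction * spc
  if (abs(tau_real - round(tau_real)) > 1e-8) {
    stop("tau_fraction * samples_per_cycle must be an integer")
  }
  tau <- as.integer(round(tau_real))
  z <- segment$z_values
  n <- length(z)
  if (tau < 1L || tau >= n) {
    stop("delay must satisfy 1 <= tau_samples < length of the series")
  }
  idx <- seq_len(n - tau)
  pts <- cbind(x = z[idx], y = z[idx + tau])
  structure(list(points = pts, tau_samples = tau), class = "phase_cloud")
}

#' Export a phase point cloud as x,y CSV for visual inspection
#' @param cloud A `phase_cloud`.
#' @param path Output file path.
#' @export
write_phase_cloud <- function(cloud, path) {
  utils::write.csv(as.data.frame(cloud$points), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
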