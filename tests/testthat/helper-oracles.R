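# Fixture builders and brute-force oracles shared across test files.

# Force trace of pure sinusoidal cycles sampled at `fs` Hz.
sine_force <- function(n_samples, samples_per_cycle = 50, fs = 64,
                       amplitude = 1) {
  # sinpi is exactly zero at cycle starts, so upward crossings land on the
  # grid points the hand derivation expects
  force_series(amplitude * sinpi(2 * (seq_len(n_samples) - 1) /
                                   samples_per_cycle),
               sample_rate = fs)
}

# A sector_segment built directly from a repeated 100-sample waveform,
# bypassing segmentation/interpolation (for analytic phase-space limits).
segment_from_wave <- function(wave, n_cycles) {
  x <- rep(wave, n_cycles)
  structure(
    list(z_values = (x - mean(x)) / stats::sd(x),
         n_cycles = n_cycles,
         samples_per_cycle = length(wave),
         revolution_times = rep(length(wave) / 64, n_cycles),
         mean_raw = mean(x), sd_raw = stats::sd(x)),
    class = "sector_segment"
  )
}

circle_points <- function(center, radius, angles) {
  cbind(x = center[1] + radius * cos(angles),
        y = center[2] + radius * sin(angles))
}

# Grid-search oracle for the geometric circle fit: enumerate candidate
# centers; for a fixed center the optimal radius is the mean point distance
# (closed form), so the search is 2-D.
grid_circle_fit <- function(points, xc_range, yc_range, step) {
  xs <- seq(xc_range[1], xc_range[2], by = step)
  ys <- seq(yc_range[1], yc_range[2], by = step)
  best <- list(obj = Inf)
  for (xc in xs) {
    dx2 <- (points[, 1] - xc)^2
    for (yc in ys) {
      d <- sqrt(dx2 + (points[, 2] - yc)^2)
      r <- mean(d)
      obj <- sum((d - r)^2)
      if (obj < best$obj) best <- list(center = c(xc, yc), radius = r, obj = obj)
    }
  }
  best
}

# Staged enumeration oracle for the geometric median (sum of Euclidean
# distances): a coarse pass over the bounding box, then successively denser
# passes around the running argmin down to `step` (the objective is convex,
# so each argmin is near the true minimizer).
grid_geometric_median <- function(points, step = 2.5e-4) {
  eval_grid <- function(xs, ys) {
    g <- expand.grid(x = xs, y = ys)
    vals <- 0
    for (i in seq_len(nrow(points))) {
      vals <- vals + sqrt((g$x - points[i, 1])^2 + (g$y - points[i, 2])^2)
    }
    c(g$x[which.min(vals)], g$y[which.min(vals)])
  }
  lo <- apply(points, 2, min)
  hi <- apply(points, 2, max)
  cur <- max(max(hi - lo) / 60, step)
  ctr <- eval_grid(seq(lo[1], hi[1], by = cur),
                   seq(lo[2], hi[2], by = cur))
  while (cur > step) {
    margin <- 3 * cur
    cur <- max(cur / 5, step)
    ctr <- eval_grid(seq(ctr[1] - margin, ctr[1] + margin, by = cur),
                     seq(ctr[2] - margin, ctr[2] + margin, by = cur))
  }
  ctr
}

# Small complete measures table for contrast-stage tests.
toy_measures <- function(n_subjects, sector_ids, sessions = "NO_SHIFT",
                         seed = 1) {
  set.seed(seed)
  rows <- expand.grid(subject = seq_len(n_subjects), sector = sector_ids,
                      session = sessions, stringsAsFactors = FALSE)
  for (v in c("HR", "LR", "Mc", "ML1", "RevTimeCV")) rows[[v]] <- rnorm(nrow(rows))
  rows
}

toy_profile <- function(inclines = c(0, 2, 4, 1, -2, -4, 3, 6)) {
  n <- length(inclines)
  terrain_profile(
    data.frame(sector = seq_len(n) + 3L,
               start_s = (seq_len(n) - 1) * 60,
               end_s = seq_len(n) * 60,
               incline_pct = inclines),
    analysis_ids = seq_len(n) + 3L
  )
}
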