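#' Geometric circle regression by Levenberg-Marquardt
#'
#' Fits a circle to a 2-D point cloud by minimizing the sum of squared
#' orthogonal distances \eqn{\sum_i (\sqrt{(x_i-x_c)^2+(y_i-y_c)^2} - r)^2}.
#' The fit is initialized from the algebraic (Kasa) least-squares circle and
#' refined by damped Gauss-Newton steps; convergence is declared when the
#' parameter step norm falls below `tol`.
#'
#' @param points A `phase_cloud` or an n x 2 numeric matrix.
#' @param max_iter Maximum refinement iterations (default 100).
#' @param tol Step-norm convergence tolerance (default 1e-10).
#' @return A list of class `circle_fit` with `center` (length-2), `radius`,
#'   `converged`, `iterations`, `residual_rms`.
#' @export
fit_circle_lm <- function(points, max_iter = 100L, tol = 1e-10) {
  pts <- cloud_points(points)
  n <- nrow(pts)
  if (n < 3L) stop("circle fit needs at least 3 points")
  x <- pts[, 1L]; y <- pts[, 2L]

  # Kasa algebraic fit: x^2 + y^2 = 2a x + 2b y + c
  A <- cbind(2 * x, 2 * y, 1)
  rhs <- x^2 + y^2
  ata <- crossprod(A)
  if (rcond(ata) < 1e-12) {
    # collinear (or otherwise degenerate) clouds have no algebraic circle
    if (collinear_points(pts)) stop("circle fit undefined: points are collinear")
    par <- c(0, 0, sqrt(mean(rhs)))
  } else {
    sol <- solve(ata, crossprod(A, rhs))
    r0 <- sqrt(max(sol[3L] + sol[1L]^2 + sol[2L]^2, .Machine$double.eps))
    par <- c(sol[1L], sol[2L], r0)
  }

  resid_fun <- function(p) sqrt((x - p[1L])^2 + (y - p[2L])^2) - p[3L]
  obj <- function(p) sum(resid_fun(p)^2)

  lambda <- 1e-3
  converged <- FALSE
  iter <- 0L
  f <- resid_fun(par)
  ssq <- sum(f^2)
  while (iter < max_iter) {
    iter <- iter + 1L
    d <- sqrt((x - par[1L])^2 + (y - par[2L])^2)
    d[d < .Machine$double.eps] <- .Machine$double.eps
    J <- cbind(-(x - par[1L]) / d, -(y - par[2L]) / d, -1)
    g <- crossprod(J, f)
    H <- crossprod(J)
    repeat {
      Haug <- H + lambda * diag(diag(H), nrow = 3L)
      step <- tryCatch(solve(Haug, -g), error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      cand <- par + as.numeric(step)
      fc <- resid_fun(cand)
      ssq_c <- sum(fc^2)
      if (ssq_c <= ssq) {
        par <- cand; f <- fc; ssq <- ssq_c
        lambda <- max(lambda / 10, 1e-12)
        break
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (sqrt(sum(step^2)) < tol || lambda > 1e12) {
      converged <- sqrt(sum(step^2)) < tol
      break
    }
  }
  structure(
    list(center = c(par[1L], par[2L]), radius = abs(par[3L]),
         converged = converged, iterations = iter,
         residual_rms = sqrt(ssq / n)),
    class = "circle_fit"
  )
}

#' Distance from the phase-space origin to the fitted circle center
#'
#' After z-scoring the cloud's arithmetic center is the coordinate origin,
#' so this is the offset between the two centers,
#' \eqn{L_R = \sqrt{x_c^2 + y_c^2}}.
#'
#' @param fit A `circle_fit` from [fit_circle_lm].
#' @return Non-negative scalar.
#' @export
compute_LR <- function(fit) {
  if (!isTRUE(fit$converged)) stop("circle fit did not converge")
  sqrt(sum(fit$center^2))
}

#' Componentwise median of a point cloud
#'
#' The point whose coordinates are the per-dimension medians (even counts
#' average the two middle order statistics).
#'
#' @param points A `phase_cloud` or n x 2 matrix.
#' @return Length-2 numeric vector.
#' @export
componentwise_median <- function(points) {
  pts <- cloud_points(points)
  if (nrow(pts) < 1L) stop("empty point cloud")
  c(stats::median(pts[, 1L]), stats::median(pts[, 2L]))
}

#' Geometric (L1) median of a point cloud by Weiszfeld iteration
#'
#' Minimizes the sum of Euclidean distances to the points. Uses the
#' Vardi-Zhang step when the iterate lands on a data point, so coincident
#' iterates are handled rather than dividing by zero. A single point is its
#' own median; for two points the midpoint is returned (any point of the
#' segment minimizes; the midpoint is the symmetric choice).
#'
#' @param points A `phase_cloud` or n x 2 matrix.
#' @param tol Convergence: successive iterates closer than this (default 1e-8).
#' @param max_iter Iteration cap (default 1000).
#' @return Length-2 numeric vector.
#' @export
geometric_median <- function(points, tol = 1e-8, max_iter = 1000L) {
  pts <- cloud_points(points)
  n <- nrow(pts)
  if (n < 1L) stop("empty point cloud")
  if (n == 1L) return(as.numeric(pts[1L, ]))
  if (n == 2L) return(as.numeric(colMeans(pts)))

  y <- componentwise_median(pts)
  for (iter in seq_len(max_iter)) {
    dx <- pts[, 1L] - y[1L]
    dy <- pts[, 2L] - y[2L]
    d <- sqrt(dx^2 + dy^2)
    on_point <- d < .Machine$double.eps^0.75
    if (any(on_point)) {
      # Vardi-Zhang: treat the coincident point's pull separately
      w <- 1 / d[!on_point]
      Tnum <- c(sum(pts[!on_point, 1L] * w), sum(pts[!on_point, 2L] * w))
      Tden <- sum(w)
      Ty <- Tnum / Tden
      Rvec <- c(sum((pts[!on_point, 1L] - y[1L]) / d[!on_point]),
                sum((pts[!on_point, 2L] - y[2L]) / d[!on_point]))
      Rnorm <- sqrt(sum(Rvec^2))
      eta <- sum(on_point)  # multiplicity of the coincident data point
      if (Rnorm <= eta) return(as.numeric(y))  # y is the median
      gamma <- min(1, eta / Rnorm)
      y_new <- (1 - gamma) * Ty + gamma * y
    } else {
      w <- 1 / d
      y_new <- c(sum(pts[, 1L] * w), sum(pts[, 2L] * w)) / sum(w)
    }
    if (sqrt(sum((y_new - y)^2)) < tol) return(as.numeric(y_new))
    y <- y_new
  }
  as.numeric(y)
}

#' Revolution-time coefficient of variation, percent
#'
#' Linear variability of cycle durations within a terrain sector:
#' 100 * sample SD / mean of the revolution times.
#'
#' @param revolution_times Positive durations in seconds, at least 2.
#' @return CV in percent.
#' @export
rev_time_cv <- function(revolution_times) {
  if (length(revolution_times) < 2L) {
    stop("revolution-time CV needs at least 2 cycles")
  }
  if (any(revolution_times <= 0)) stop("revolution times must be positive")
  100 * stats::sd(revolution_times) / mean(revolution_times)
}

#' Mean heart rate within a time window
#'
#' @param hr An [hr_series].
#' @param start_s,end_s Window bounds in seconds; samples with
#'   `start_s <= t < end_s` are averaged.
#' @return Mean heart rate in bpm.
#' @export
sector_mean_hr <- function(hr, start_s, end_s) {
  t <- sample_times(hr)
  inside <- t >= start_s & t < end_s
  if (!any(inside)) stop("no heart-rate samples inside the window")
  mean(hr$values[inside])
}

cloud_points <- function(points) {
  if (inherits(points, "phase_cloud")) points <- points$points
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("points must be an n x 2 matrix")
  storage.mode(pts) <- "double"
  pts
}

collinear_points <- function(pts) {
  if (nrow(pts) < 3L) return(TRUE)
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2L, ctr), nu = 0, nv = 0)$d
  sv[2L] < 1e-10 * max(sv[1L], 1)
}
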