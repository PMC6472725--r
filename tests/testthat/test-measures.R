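test_that("exact circles are recovered to machine precision", {
  pts <- circle_points(c(3, 4), 5, (0:7) * pi / 4)
  fit <- fit_circle_lm(pts)
  expect_true(fit$converged)
  expect_equal(fit$center, c(3, 4), tolerance = 1e-9)
  expect_equal(fit$radius, 5, tolerance = 1e-9)
  expect_lt(fit$residual_rms, 1e-9)
  expect_equal(compute_LR(fit), 5, tolerance = 1e-9)
})

test_that("noisy circles are fit within tight bounds and match a grid oracle", {
  set.seed(90)
  ang <- seq(0, 2 * pi, length.out = 501)[-501]
  pts <- circle_points(c(0, 0), 1, ang) + matrix(rnorm(1000, 0, 0.01), 500, 2)
  fit <- fit_circle_lm(pts)
  expect_true(fit$converged)
  expect_lt(sqrt(sum(fit$center^2)), 0.005)
  expect_lt(abs(fit$radius - 1), 0.005)

  # oracle equivalence on a small cloud: dense 2-D center grid with the
  # radius profiled out analytically
  set.seed(91)
  small <- circle_points(c(0.3, -0.2), 0.8, runif(50, 0, 2 * pi)) +
    matrix(rnorm(100, 0, 0.02), 50, 2)
  fit_s <- fit_circle_lm(small)
  oracle <- grid_circle_fit(small,
                            xc_range = fit_s$center[1] + c(-0.02, 0.02),
                            yc_range = fit_s$center[2] + c(-0.02, 0.02),
                            step = 0.002)
  expect_lt(max(abs(fit_s$center - oracle$center)), 0.002)
  expect_lt(abs(fit_s$radius - oracle$radius), 0.002)
})

test_that("collinear points are rejected by the circle fit", {
  expect_error(fit_circle_lm(cbind(0:2, 0:2)), "collinear")
  expect_error(fit_circle_lm(cbind(0:1, 0:1)), "at least 3")
})

test_that("LR is the center norm and requires convergence", {
  mk <- function(center, conv = TRUE) {
    structure(list(center = center, radius = 1, converged = conv,
                   iterations = 1L, residual_rms = 0), class = "circle_fit")
  }
  expect_equal(compute_LR(mk(c(0, 0))), 0)
  expect_equal(compute_LR(mk(c(3, 4))), 5)
  expect_equal(compute_LR(mk(c(-0.1, 0))), 0.1)
  expect_error(compute_LR(mk(c(1, 1), conv = FALSE)), "converge")
})

test_that("componentwise median follows the even/odd conventions", {
  expect_equal(componentwise_median(rbind(c(0, 0), c(1, 10), c(2, -10))),
               c(1, 0))
  expect_equal(componentwise_median(rbind(c(0, 0), c(1, 1))), c(0.5, 0.5))
  expect_equal(componentwise_median(rbind(c(1, 2), c(1, -2), c(-1, 2),
                                          c(-1, -2))),
               c(0, 0))
  # agrees with a sort-based reference exactly
  set.seed(7)
  for (n in c(5, 8, 31)) {
    pts <- matrix(rnorm(2 * n), n, 2)
    sorted_mid <- function(v) {
      s <- sort(v)
      if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    }
    expect_identical(componentwise_median(pts),
                     c(sorted_mid(pts[, 1]), sorted_mid(pts[, 2])))
  }
})

test_that("geometric median handles degenerate counts and symmetric cases", {
  expect_equal(geometric_median(rbind(c(2, 7))), c(2, 7))
  expect_equal(geometric_median(rbind(c(0, 0), c(4, 2))), c(2, 1))
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(geometric_median(tri), c(0.5, sqrt(3) / 6), tolerance = 1e-6)
})

test_that("geometric median matches the enumeration oracle", {
  pts <- rbind(c(0, 0), c(4, 0), c(1, 0), c(1, 1))
  gm <- geometric_median(pts)
  oracle <- grid_geometric_median(pts)
  expect_lt(max(abs(gm - oracle)), 2e-3)

  set.seed(21)
  for (rep in 1:5) {
    pts <- matrix(rnorm(2 * sample(5:20, 1)), ncol = 2)
    gm <- geometric_median(pts)
    oracle <- grid_geometric_median(pts)
    expect_lt(max(abs(gm - oracle)), 2e-3)
  }
})

test_that("geometric median survives iterates landing on data points", {
  # the componentwise-median start coincides with a data point here
  pts <- rbind(c(0, 0), c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  gm <- geometric_median(pts)
  expect_equal(gm, c(0, 0), tolerance = 1e-8)
})

test_that("attractor location measures vanish for a pure sinusoid", {
  # enough cycles that the truncated tail (the embedding drops the last
  # quarter cycle) no longer biases the medians
  seg <- segment_from_wave(sin(2 * pi * (0:99) / 100), 20)
  cl <- embed_phase(seg, 0.25)
  expect_lt(compute_LR(fit_circle_lm(cl)), 0.05)
  expect_lt(sqrt(sum(componentwise_median(cl)^2)), 0.05)
  expect_lt(sqrt(sum(geometric_median(cl)^2)), 0.05)
})

test_that("revolution-time CV is the percent SD/mean and scale invariant", {
  expect_equal(rev_time_cv(c(1, 1, 1, 1)), 0)
  expect_equal(rev_time_cv(c(0.9, 1.0, 1.1)), 10.0)
  t <- c(0.71, 0.78, 0.74, 0.81)
  expect_equal(rev_time_cv(7 * t), rev_time_cv(t))
  expect_error(rev_time_cv(1.0), "at least 2")
})

test_that("sector heart rate averages the in-window samples", {
  hr <- hr_series(c(100, 110, 120, 95), sample_rate = 1)
  expect_equal(sector_mean_hr(hr, 0, 3), 110)
  expect_equal(sector_mean_hr(hr, 3, 4), 95)
  expect_error(sector_mean_hr(hr, 10, 20), "no heart-rate samples")
})
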