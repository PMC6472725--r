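#' Lambda weights from terrain inclinations
#'
#' The contrast coefficients are the z-standardized inclinations of the
#' analysis sectors (sample SD, divisor n - 1), in sector order. They sum
#' to zero by construction.
#'
#' @param profile A [terrain_profile].
#' @return A list of class `contrast_weights` with `sector_ids` and
#'   `lambdas`.
#' @export
make_weights <- function(profile) {
  rows <- analysis_sectors(profile)
  incl <- rows$incline_pct
  s <- stats::sd(incl)
  if (!is.finite(s) || s == 0) {
    stop("analysis-sector inclinations are identical: weights undefined")
  }
  lam <- (incl - mean(incl)) / s
  lam <- lam - mean(lam)  # exact zero sum despite rounding
  structure(list(sector_ids = rows$sector, lambdas = lam),
            class = "contrast_weights")
}

#' Effect size of a one-sample contrast from its t statistic
#'
#' The standardized mean contrast score: for a one-sample contrast of n
#' subject scores, mean(L)/sd(L) = t / sqrt(n). No small-sample correction
#' factor is applied.
#'
#' @param t Contrast t statistic.
#' @param n_subjects Number of subjects.
#' @return Effect size (same sign as t).
#' @export
contrast_effect_size <- function(t, n_subjects) {
  if (n_subjects < 2L) stop("need at least 2 subjects")
  t / sqrt(n_subjects)
}

#' One-tailed p-value of a contrast t statistic
#'
#' Upper-tail Student-t probability with `df` degrees of freedom — the
#' directional test of a positive association between the outcome pattern
#' and the inclination pattern.
#'
#' @param t Contrast t statistic.
#' @param df Degrees of freedom (subjects - 1).
#' @return One-tailed p in (0, 1).
#' @export
contrast_p_value <- function(t, df) {
  stats::pt(t, df = df, lower.tail = FALSE)
}

#' Planned-contrast test of one outcome variable against the terrain pattern
#'
#' Each subject's sector values are collapsed to a single contrast score
#' L_i = sum_j lambda_j * value_ij; the scores are tested against zero with
#' a one-sample t test (one-tailed, upper). The effect size is the
#' standardized mean contrast score t/sqrt(n).
#'
#' @param values n_subjects x n_sectors numeric matrix, one outcome
#'   variable; column order must match `weights$sector_ids`.
#' @param weights A `contrast_weights` from [make_weights].
#' @param alpha Significance level for the decision flag (default 0.01);
#'   affects only `significant`, never t, p or g.
#' @param check_prerequisites Attach Shapiro-Wilk / Bartlett p-values
#'   (default TRUE; they are reported, never fatal).
#' @return A list of class `contrast_result` with `n_subjects`, `t`, `p`,
#'   `g`, `df`, `shapiro_p`, `bartlett_p`, `significant`, `scores`.
#' @export
contrast_test <- function(values, weights, alpha = 0.01,
                          check_prerequisites = TRUE) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("contrast matrix has missing cells")
  lam <- weights$lambdas
  if (ncol(values) != length(lam)) {
    stop("matrix has ", ncol(values), " sector columns but ",
         length(lam), " weights")
  }
  n <- nrow(values)
  if (n < 2L) stop("contrast needs at least 2 subjects")
  scores <- as.numeric(values %*% lam)
  s <- stats::sd(scores)
  # a pattern identical across sectors gives scores of pure rounding noise
  if (!is.finite(s) || s <= 1e-10 * max(1, max(abs(values)))) {
    stop("contrast scores have zero variance: t undefined")
  }
  tval <- mean(scores) / (s / sqrt(n))
  df <- n - 1L
  p <- contrast_p_value(tval, df)
  prereq <- if (check_prerequisites) {
    prerequisites(values, weights)
  } else {
    c(shapiro_p = NA_real_, bartlett_p = NA_real_)
  }
  structure(
    list(n_subjects = n, t = tval, p = p,
         g = contrast_effect_size(tval, n), df = df,
         shapiro_p = unname(prereq["shapiro_p"]),
         bartlett_p = unname(prereq["bartlett_p"]),
         significant = p < alpha, scores = scores),
    class = "contrast_result"
  )
}

#' Prerequisite checks for the contrast analysis
#'
#' Shapiro-Wilk normality test on the n per-subject contrast scores, and
#' Bartlett's test of variance homogeneity across the sector-wise groups of
#' subject values.
#'
#' @inheritParams contrast_test
#' @return Named vector `c(shapiro_p=, bartlett_p=)`.
#' @export
prerequisites <- function(values, weights) {
  values <- as.matrix(values)
  scores <- as.numeric(values %*% weights$lambdas)
  if (length(scores) < 3L) stop("Shapiro-Wilk needs at least 3 subjects")
  shapiro_p <- stats::shapiro.test(scores)$p.value
  groups <- lapply(seq_len(ncol(values)), function(j) values[, j])
  if (any(vapply(groups, function(g) stats::sd(g) == 0, logical(1)))) {
    stop("a sector group has zero variance: Bartlett statistic undefined")
  }
  bartlett_p <- stats::bartlett.test(groups)$p.value
  c(shapiro_p = shapiro_p, bartlett_p = bartlett_p)
}

#' Contrast table across conditions and outcome variables
#'
#' Runs [contrast_test] for every condition x variable cell of a measures
#' table (the per-sector outcome variables of all subjects), reproducing a
#' condition-by-variable summary of t, one-tailed p and effect size g with
#' the prerequisite p-values attached.
#'
#' @param measures data.frame with columns `subject`, `session`, `sector`
#'   and the outcome variables.
#' @param profile A [terrain_profile]; its analysis sectors define the
#'   lambda weights.
#' @param config A [run_config] (supplies alpha).
#' @param variables Outcome columns to test
#'   (default `c("HR","LR","Mc","ML1","RevTimeCV")`).
#' @return data.frame, one row per condition x variable, columns
#'   `condition,variable,n_subjects,t,p,g,shapiro_p,bartlett_p,significant`.
#' @export
run_contrast_table <- function(measures, profile, config = run_config(),
                               variables = c("HR", "LR", "Mc", "ML1",
                                             "RevTimeCV")) {
  weights <- make_weights(profile)
  conditions <- unique(measures$session)
  out <- list()
  for (cond in conditions) {
    sub <- measures[measures$session == cond, , drop = FALSE]
    mats <- build_design_matrix(sub, weights$sector_ids, variables, cond)
    for (v in variables) {
      res <- contrast_test(mats[[v]], weights, alpha = config$alpha)
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, variable = v, n_subjects = res$n_subjects,
        t = res$t, p = res$p, g = res$g,
        shapiro_p = res$shapiro_p, bartlett_p = res$bartlett_p,
        significant = res$significant, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Complete subject x sector matrices for each variable; errors name the
# first missing (subject, sector) cell.
build_design_matrix <- function(sub, sector_ids, variables, cond) {
  subjects <- sort(unique(sub$subject))
  mats <- lapply(variables, function(v) {
    m <- matrix(NA_real_, nrow = length(subjects), ncol = length(sector_ids),
                dimnames = list(subjects, sector_ids))
    for (i in seq_along(subjects)) {
      for (j in seq_along(sector_ids)) {
        row <- sub[sub$subject == subjects[i] & sub$sector == sector_ids[j], v]
        if (length(row) != 1L || !is.finite(row)) {
          stop(sprintf(
            "incomplete design in condition %s: subject %s, sector %s, %s",
            cond, subjects[i], sector_ids[j], v))
        }
        m[i, j] <- row
      }
    }
    m
  })
  names(mats) <- variables
  mats
}
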