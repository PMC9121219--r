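#' Covariate-adjusted (partial) Pearson correlation
#'
#' Residualizes `x` and `y` on an intercept plus the covariate columns by
#' least squares and correlates the residuals. The two-sided p-value uses
#' `t = r * sqrt((n - 2 - k) / (1 - r^2))` on `n - 2 - k` degrees of freedom,
#' where `k` is the number of covariates; the 95% confidence interval uses the
#' Fisher z transform with covariate-adjusted effective sample size,
#' `tanh(atanh(r) +/- 1.96 / sqrt(n - 3 - k))`. With no covariates this
#' reduces to the plain Pearson correlation and its textbook test.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Optional numeric matrix or data frame (n rows) of
#'   covariates to adjust for.
#' @return A list with `r`, `ci95` (length-2), `p`, `n`, `k`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) {
      stop("covariates must have one row per observation", call. = FALSE)
    }
    storage.mode(covariates) <- "double"
  }
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n <= k + 3L) stop("need n > k + 3 observations", call. = FALSE)
  Z <- cbind(rep(1, n), covariates)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    stop("covariate matrix is rank deficient (with intercept)", call. = FALSE)
  }
  rx <- qr.resid(qz, x)
  ry <- qr.resid(qz, y)
  tol <- 1e-10
  if (stats::sd(rx) <= tol * max(1, stats::sd(x)) ||
      stats::sd(ry) <= tol * max(1, stats::sd(y))) {
    stop("zero-variance residuals", call. = FALSE)
  }
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - 2L - k
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(r) * sqrt(df / (1 - r^2)), df)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  half <- 1.96 / sqrt(n - 3L - k)
  list(r = r, ci95 = tanh(c(z - half, z + half)), p = p,
       n = n, k = as.integer(k))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values (adjusted
#' values are monotone, capped at 1 and returned in input order).
#'
#' @param pvalues Numeric vector with all values in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Feature-MoCA partial correlation table
#'
#' For each of the six drawing features, computes the partial Pearson
#' correlation with the MoCA score controlling for age, sex and years of
#' education, then applies the Benjamini-Hochberg correction within the
#' six-test family.
#'
#' @param records Data frame from [participant_records()] (columns: the six
#'   features plus `age`, `sex`, `education_years`, `moca`).
#' @return Data frame with one row per feature: `feature`, `r`, `ci_low`,
#'   `ci_high`, `p`, `p_bh`, `n`, `k`.
#' @export
feature_moca_table <- function(records) {
  if (nrow(records) < 10L) stop("need at least 10 records", call. = FALSE)
  covs <- as.matrix(records[, c("age", "sex", "education_years")])
  rows <- lapply(drawing_feature_names(), function(f) {
    pc <- partial_correlation(records[[f]], records$moca, covs)
    data.frame(feature = f, r = pc$r, ci_low = pc$ci95[1L],
               ci_high = pc$ci95[2L], p = pc$p, n = pc$n, k = pc$k,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- bh_adjust(pmin(pmax(out$p, .Machine$double.xmin), 1))
  out[, c("feature", "r", "ci_low", "ci_high", "p", "p_bh", "n", "k")]
}

#' Demographic contrasts between two cohorts
#'
#' Compares the two cohorts' age, education and MoCA distributions with
#' pooled-variance (Student) two-sided t tests, and the sex proportions with
#' a 1-df chi-square test without continuity correction — the conventions
#' under which a 55-versus-37 split of 39 and 19 women yields a chi-square
#' statistic of about 3.63.
#'
#' @param records Data frame from [participant_records()] containing exactly
#'   two cohorts.
#' @return Data frame with columns `variable`, `test`, `statistic`, `df`, `p`.
#' @export
cohort_compare <- function(records) {
  cohorts <- unique(records$cohort)
  if (length(cohorts) != 2L) stop("need exactly two cohorts", call. = FALSE)
  a <- records[records$cohort == cohorts[1L], ]
  b <- records[records$cohort == cohorts[2L], ]
  if (nrow(a) < 2L || nrow(b) < 2L) {
    stop("each cohort needs at least 2 members", call. = FALSE)
  }
  cont <- lapply(c(age = "age", education_years = "education_years",
                   moca = "moca"), function(v) {
    tt <- stats::t.test(a[[v]], b[[v]], var.equal = TRUE)
    data.frame(variable = v, test = "pooled_t",
               statistic = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  tab <- rbind(table(factor(a$sex, levels = 0:1)),
               table(factor(b$sex, levels = 0:1)))
  # small expected counts only trigger the usual approximation caveat
  cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  out <- rbind(do.call(rbind, cont),
               data.frame(variable = "sex", test = "chi_square",
                          statistic = unname(cs$statistic),
                          df = unname(cs$parameter), p = cs$p.value,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
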