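# Nonlinear Mendelian randomization by residual stratification: the cohort
# is divided into quantile strata of the IV-free exposure (the residual of
# the exposure regressed on the GRS and covariates, which avoids collider
# bias from stratifying on the raw exposure), a localized average causal
# effect (LACE) is estimated in each stratum as the ratio of the stratum
# genetic-outcome and genetic-exposure associations, and nonlinearity is
# tested by Cochran's Q over strata and by a trend ("quadratic") test of
# LACE against stratum mean exposure.

#' Stratify a cohort by residual exposure variation
#'
#' Computes `r = exposure - fitted(exposure ~ grs + covariates)` and cuts
#' the sample into `K` quantile groups of `r`. Ties are broken by stable
#' participant order (first-occurrence ranking), so stratum sizes differ by
#' at most one.
#'
#' @param cohort A `cohort_table` (used only for covariates; may be `NULL`
#'   when `covariates` is `NULL`).
#' @param grs Numeric GRS vector.
#' @param exposure Exposure column name, or a numeric vector.
#' @param covariates Covariate column names included in the residual
#'   regression (default: the basic tier, for consistency with the linear
#'   models).
#' @param K Number of strata (default 3).
#' @return Integer vector of stratum indices in `1..K` (NA where exposure,
#'   GRS or covariates are missing); attribute `tie_policy`.
#' @export
stratify_by_residual <- function(cohort, grs, exposure, covariates = NULL,
                                 K = 3) {
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  x <- if (is.character(exposure)) as.numeric(cohort[[exposure]]) else
    as.numeric(exposure)
  df <- data.frame(.x = x, .g = grs)
  if (!is.null(covariates)) {
    df <- cbind(df, as.data.frame(cohort)[, covariates, drop = FALSE])
    if (!is.null(df$assessment_center))
      df$assessment_center <- factor(df$assessment_center)
  }
  ok <- stats::complete.cases(df)
  rhs <- paste(c(".g", covariates), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(".x ~", rhs)), data = df[ok, ])
  r <- stats::resid(fit)
  if (length(unique(r)) < K)
    stop("K exceeds the number of distinct residual values", call. = FALSE)
  # stable quantile partition: first-occurrence ranks, equal-size groups
  rk <- rank(r, ties.method = "first")
  strata_ok <- ceiling(rk * K / length(rk))
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer(strata_ok)
  attr(out, "tie_policy") <- "stable participant order (ties.method='first')"
  out
}

#' Localized average causal effects per residual stratum
#'
#' Within each stratum, estimates the genetic association with the exposure
#' (`beta_gx`, linear) and with the outcome (`beta_gy`, logistic for the
#' binary endpoint), both adjusted for the covariates, and forms
#' `lace = beta_gy / beta_gx` with the delta-method standard error
#' `|1/beta_gx| * sqrt(se_gy^2 + lace^2 * se_gx^2)`. Strata whose
#' `|beta_gx|` falls below `beta_gx_tol` are flagged unstable and excluded
#' from the nonlinearity tests.
#'
#' @param strata Stratum assignment from [stratify_by_residual()].
#' @param cohort A `cohort_table`.
#' @param grs Numeric GRS vector.
#' @param exposure Exposure column name or numeric vector (hours).
#' @param outcome Analysis target name or binary vector.
#' @param covariates Covariate columns for both stratum regressions.
#' @param denominator `"stratum"` uses the stratum-specific `beta_gx`
#'   (the default of the stratified-IV framework); `"global"` uses the
#'   whole-sample first-stage coefficient in every stratum.
#' @param beta_gx_tol Instability tolerance for the denominator.
#' @return A `stratum_lace` data frame: stratum, n, n_events,
#'   mean_exposure, beta_gx, se_gx, beta_gy, se_gy, lace, se, unstable.
#' @export
lace_per_stratum <- function(strata, cohort, grs, exposure, outcome,
                             covariates = NULL,
                             denominator = c("stratum", "global"),
                             beta_gx_tol = 1e-8) {
  denominator <- match.arg(denominator)
  x <- if (is.character(exposure)) as.numeric(cohort[[exposure]]) else
    as.numeric(exposure)
  y <- if (is.character(outcome) && length(outcome) == 1)
    endpoint_outcome(cohort, outcome)$event else as.numeric(outcome)
  df <- data.frame(.x = x, .g = grs, .y = y, .s = strata)
  if (!is.null(covariates)) {
    df <- cbind(df, as.data.frame(cohort)[, covariates, drop = FALSE])
    if (!is.null(df$assessment_center))
      df$assessment_center <- factor(df$assessment_center)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  rhs <- paste(c(".g", covariates), collapse = " + ")

  bx_global <- NULL
  if (denominator == "global") {
    fg <- stats::lm(stats::as.formula(paste(".x ~", rhs)), data = df)
    bx_global <- summary(fg)$coefficients[".g", 1:2]
  }
  ks <- sort(unique(df$.s))
  rows <- lapply(ks, function(k) {
    d <- df[df$.s == k, , drop = FALSE]
    f1 <- stats::lm(stats::as.formula(paste(".x ~", rhs)), data = d)
    c1 <- summary(f1)$coefficients[".g", ]
    f2 <- suppressWarnings(
      stats::glm(stats::as.formula(paste(".y ~", rhs)), data = d,
                 family = stats::binomial()))
    c2 <- summary(f2)$coefficients[".g", ]
    bx <- if (denominator == "global") bx_global[[1]] else c1[[1]]
    sx <- if (denominator == "global") bx_global[[2]] else c1[[2]]
    unstable <- abs(bx) < beta_gx_tol
    lace <- if (unstable) NA_real_ else c2[[1]] / bx
    se <- if (unstable) NA_real_ else
      abs(1 / bx) * sqrt(c2[[2]]^2 + lace^2 * sx^2)
    data.frame(stratum = k, n = nrow(d), n_events = sum(d$.y),
               mean_exposure = mean(d$.x), beta_gx = c1[[1]], se_gx = c1[[2]],
               beta_gy = c2[[1]], se_gy = c2[[2]], lace = lace, se = se,
               unstable = unstable)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stratum_lace", "data.frame")
  out
}

#' Test for nonlinearity across stratum-specific causal effects
#'
#' Cochran's Q: `Q = sum w_k (lace_k - theta_ivw)^2` with `w_k = 1/se_k^2`,
#' referred to a chi-square with `K - 1` degrees of freedom. Quadratic
#' (trend) test: fixed-effect inverse-variance-weighted meta-regression of
#' LACE on stratum mean exposure, Wald test of zero slope. Unstable strata
#' are excluded.
#'
#' @param laces A `stratum_lace` table.
#' @return A `nonlinearity_report`: `quadratic` (slope, se, z, p),
#'   `cochran_q` (Q, df, p), `theta_ivw`, `laces`.
#' @export
test_nonlinearity <- function(laces) {
  l <- laces[!laces$unstable & !is.na(laces$lace), , drop = FALSE]
  K <- nrow(l)
  if (K < 2) stop("Cochran's Q requires >= 2 usable strata", call. = FALSE)
  w <- 1 / l$se^2
  theta_ivw <- sum(w * l$lace) / sum(w)
  Q <- sum(w * (l$lace - theta_ivw)^2)
  q_p <- stats::pchisq(Q, df = K - 1, lower.tail = FALSE)

  quadratic <- NULL
  if (K >= 3) {
    X <- cbind(1, l$mean_exposure)
    XtWX <- crossprod(X, w * X)
    beta <- solve(XtWX, crossprod(X, w * l$lace))
    V <- solve(XtWX)  # fixed-effect: known variances, no residual scaling
    slope <- beta[2]; se_s <- sqrt(V[2, 2])
    quadratic <- list(slope = slope, se = se_s, z = slope / se_s,
                      p = 2 * stats::pnorm(-abs(slope / se_s)))
  }
  structure(list(quadratic = quadratic,
                 cochran_q = list(Q = Q, df = K - 1, p = q_p),
                 theta_ivw = theta_ivw, laces = laces),
            class = "nonlinearity_report")
}

#' @export
print.nonlinearity_report <- function(x, ...) {
  cat("<nonlinearity_report>\n")
  print(as.data.frame(x$laces), row.names = FALSE, digits = 4)
  cat(sprintf("  pooled IVW LACE: %.4f\n", x$theta_ivw))
  cat(sprintf("  Cochran's Q = %.3f on %d df, p = %.3g\n",
              x$cochran_q$Q, x$cochran_q$df, x$cochran_q$p))
  if (!is.null(x$quadratic))
    cat(sprintf("  quadratic (trend) slope = %.4f per unit exposure (SE %.4f), p = %.3g\n",
                x$quadratic$slope, x$quadratic$se, x$quadratic$p))
  invisible(x)
}

#' Residual-stratified nonlinear MR in one call
#'
#' Convenience wrapper: stratifies by residual exposure, estimates the
#' per-stratum LACEs, and runs the nonlinearity tests. An alternative
#' pooled quadratic second stage (outcome on fitted exposure and its
#' square) is available via `quadratic = "pooled"` and reported alongside.
#'
#' @inheritParams lace_per_stratum
#' @param K Strata count.
#' @param quadratic `"meta_regression"` (default, the trend test of
#'   [test_nonlinearity()]) or `"pooled"` (adds a pooled
#'   fitted-exposure-squared Wald test).
#' @return A `nonlinearity_report`; with `quadratic = "pooled"` the report
#'   gains a `pooled_quadratic` element.
#' @export
nonlinear_mr <- function(cohort, grs, exposure, outcome, covariates = NULL,
                         K = 3, quadratic = c("meta_regression", "pooled"),
                         denominator = "stratum") {
  quadratic <- match.arg(quadratic)
  strata <- stratify_by_residual(cohort, grs, exposure, covariates, K)
  laces <- lace_per_stratum(strata, cohort, grs, exposure, outcome,
                            covariates, denominator = denominator)
  rep_ <- test_nonlinearity(laces)
  if (quadratic == "pooled") {
    x <- if (is.character(exposure)) as.numeric(cohort[[exposure]]) else
      as.numeric(exposure)
    y <- if (is.character(outcome) && length(outcome) == 1)
      endpoint_outcome(cohort, outcome)$event else as.numeric(outcome)
    df <- data.frame(.x = x, .g = grs, .y = y)
    if (!is.null(covariates)) {
      df <- cbind(df, as.data.frame(cohort)[, covariates, drop = FALSE])
      if (!is.null(df$assessment_center))
        df$assessment_center <- factor(df$assessment_center)
    }
    df <- df[stats::complete.cases(df), , drop = FALSE]
    rhs <- paste(c(".g", covariates), collapse = " + ")
    s1 <- stats::lm(stats::as.formula(paste(".x ~", rhs)), data = df)
    df$.xhat <- stats::fitted(s1)
    df$.xhat2 <- df$.xhat^2
    rhs2 <- paste(c(".xhat", ".xhat2", covariates), collapse = " + ")
    s2 <- suppressWarnings(
      stats::glm(stats::as.formula(paste(".y ~", rhs2)), data = df,
                 family = stats::binomial()))
    c2 <- summary(s2)$coefficients[".xhat2", ]
    rep_$pooled_quadratic <- list(coef = c2[[1]], se = c2[[2]], p = c2[[4]])
  }
  rep_
}
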