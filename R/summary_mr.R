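# Summary-statistic MR sensitivity estimators over per-variant association
# pairs: inverse-variance-weighted (IVW) pooling of Wald ratios, MR-Egger
# regression, the weighted median, radial MR with per-variant heterogeneity
# and outlier removal, and leave-one-out reanalysis.

#' Construct a per-variant association table
#'
#' Validates and augments a data frame of per-variant summary statistics:
#' per-allele exposure effect `beta_gx` (se `se_gx`) and outcome effect
#' `beta_gy` (se `se_gy`, log-OR scale). Orientation is normalized so
#' `beta_gx >= 0` (flipping the sign of `beta_gy` accordingly), and the
#' Wald ratio `theta = beta_gy / beta_gx` with its first-order weight
#' `w = (se_gy / |beta_gx|)^-2` is attached.
#'
#' @param df Data frame with columns `snp_id`, `beta_gx`, `se_gx`,
#'   `beta_gy`, `se_gy`.
#' @return A `variant_assoc` data frame with extra columns `theta`, `se_theta`,
#'   `w`, `flipped`.
#' @export
variant_assoc <- function(df) {
  req <- c("snp_id", "beta_gx", "se_gx", "beta_gy", "se_gy")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("variant association table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$se_gx <= 0 | df$se_gy <= 0))
    stop("standard errors must be positive", call. = FALSE)
  if (anyDuplicated(df$snp_id))
    stop("duplicated variant ids", call. = FALSE)
  flip <- df$beta_gx < 0
  df$beta_gx <- abs(df$beta_gx)
  df$beta_gy[flip] <- -df$beta_gy[flip]
  df$flipped <- flip
  df$theta <- df$beta_gy / df$beta_gx
  df$se_theta <- df$se_gy / abs(df$beta_gx)  # first-order delta
  df$w <- 1 / df$se_theta^2
  class(df) <- c("variant_assoc", "data.frame")
  df
}

#' Read per-variant summary statistics from TSV
#'
#' External-summary entry point for two-sample-style reanalysis; columns
#' `snp_id, beta_exposure, se_exposure, beta_outcome, se_outcome` (the
#' instrument-table convention) or the internal `beta_gx/...` names.
#' @param path Tab-separated file.
#' @return A `variant_assoc` table.
#' @export
read_variant_assocs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ren <- c(beta_exposure = "beta_gx", se_exposure = "se_gx",
           beta_outcome = "beta_gy", se_outcome = "se_gy")
  for (old in names(ren))
    if (old %in% names(df)) names(df)[names(df) == old] <- ren[[old]]
  variant_assoc(df)
}

#' Derive per-variant associations from individual-level data
#'
#' For each instrument variant: `beta_gx` from a linear regression of the
#' exposure on the dosage and `beta_gy` from a logistic (binary outcome) or
#' linear regression of the outcome, both adjusted for the covariates.
#' Variants monomorphic in the analysis sample are dropped with a log entry
#' (attribute `dropped`).
#'
#' @param cohort A `cohort_table`.
#' @param dosages Harmonized dosage matrix (columns named by variant).
#' @param instruments Instrument table (its `snp_id` order is kept).
#' @param exposure Exposure column name.
#' @param outcome Analysis target name or binary/numeric vector.
#' @param covariates Covariate columns (default: basic tier).
#' @return A `variant_assoc` table.
#' @export
derive_variant_assocs <- function(cohort, dosages, instruments, exposure,
                                  outcome, covariates = NULL) {
  x <- as.numeric(cohort[[exposure]])
  target <- NULL
  if (is.character(outcome) && length(outcome) == 1) {
    target <- match.arg(outcome, analysis_targets())
    y <- endpoint_outcome(cohort, target)$event
  } else y <- as.numeric(outcome)
  binary <- all(y[!is.na(y)] %in% 0:1)
  base <- data.frame(.x = x, .y = y)
  if (!is.null(covariates)) {
    base <- cbind(base, as.data.frame(cohort)[, covariates, drop = FALSE])
    if (!is.null(base$assessment_center))
      base$assessment_center <- factor(base$assessment_center)
  }
  rhs_tail <- if (is.null(covariates)) "" else
    paste("+", paste(covariates, collapse = " + "))
  dropped <- character()
  rows <- list()
  for (id in instruments$snp_id) {
    d <- dosages[, id]
    df <- cbind(base, .d = d)
    df <- df[stats::complete.cases(df), , drop = FALSE]
    if (stats::var(df$.d) == 0) { dropped <- c(dropped, id); next }
    f1 <- stats::lm(stats::as.formula(paste(".x ~ .d", rhs_tail)), data = df)
    c1 <- summary(f1)$coefficients[".d", ]
    f2 <- if (binary)
      suppressWarnings(stats::glm(stats::as.formula(paste(".y ~ .d", rhs_tail)),
                                  data = df, family = stats::binomial()))
    else stats::lm(stats::as.formula(paste(".y ~ .d", rhs_tail)), data = df)
    c2 <- summary(f2)$coefficients[".d", ]
    rows[[id]] <- data.frame(snp_id = id, beta_gx = c1[[1]], se_gx = c1[[2]],
                             beta_gy = c2[[1]], se_gy = c2[[2]],
                             stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("no polymorphic instrument variants in the analysis sample",
         call. = FALSE)
  out <- variant_assoc(do.call(rbind, rows))
  rownames(out) <- NULL
  # variants with no detectable exposure effect give unstable Wald ratios
  out$near_null <- abs(out$beta_gx) < 2 * out$se_gx
  attr(out, "dropped") <- dropped
  out
}

#' Inverse-variance-weighted causal estimate
#'
#' `theta_ivw = sum(w theta) / sum(w)` with first-order ratio weights
#' `w = (se_gy/|beta_gx|)^-2`; fixed-effect SE `(sum w)^-1/2`, optionally
#' inflated by the multiplicative random-effects factor
#' `max(1, sqrt(Q/(m-1)))`.
#'
#' @param assocs A `variant_assoc` table.
#' @param random Use the multiplicative random-effects SE.
#' @return An `effect_estimate` row (term `"ivw"`; `"wald_ratio"` and a
#'   `single_variant` note when only one variant is supplied).
#' @export
mr_ivw <- function(assocs, random = FALSE) {
  m <- nrow(assocs)
  if (m == 1) {
    est <- effect_estimate("wald_ratio", assocs$theta, assocs$se_theta,
                           "log-OR", n = 1)
    est$note <- "single-variant"
    return(est)
  }
  w <- assocs$w
  theta <- sum(w * assocs$theta) / sum(w)
  se <- sqrt(1 / sum(w))
  if (random) {
    Q <- sum(w * (assocs$theta - theta)^2)
    se <- se * max(1, sqrt(Q / (m - 1)))
  }
  est <- effect_estimate("ivw", theta, se, "log-OR", n = m)
  est$note <- if (random) "multiplicative random effects" else "fixed effect"
  est
}

#' MR-Egger regression
#'
#' Weighted least squares of `beta_gy` on `beta_gx` with a free intercept
#' and weights `1/se_gy^2`, after orienting all variants to `beta_gx >= 0`
#' (the InSIDE convention). A non-zero intercept signals directional
#' pleiotropy; the slope is the pleiotropy-adjusted causal estimate.
#' Standard errors use the WLS fit with residual dispersion bounded below
#' by 1, and p-values a t reference on `m - 2` df.
#'
#' @param assocs A `variant_assoc` table with at least 3 variants.
#' @return List of class `mr_egger`: `slope` and `intercept`
#'   (`effect_estimate` rows), `i_squared_gx` note on regression-dilution
#'   reliability.
#' @export
mr_egger <- function(assocs) {
  m <- nrow(assocs)
  if (m < 3) stop("MR-Egger requires >= 3 variants", call. = FALSE)
  if (stats::var(assocs$beta_gx) == 0)
    stop("MR-Egger needs variation in beta_gx", call. = FALSE)
  fit <- stats::lm(beta_gy ~ beta_gx, data = assocs, weights = 1 / se_gy^2)
  s <- summary(fit)
  # dispersion bounded to [eps, 1]: SEs are never deflated below the
  # known-variance level, and an exact fit (sigma = 0) stays finite
  disp <- max(min(s$sigma, 1), .Machine$double.eps)
  co <- s$coefficients
  se_int <- co[1, 2] / disp
  se_slo <- co[2, 2] / disp
  pt2 <- function(est, se) 2 * stats::pt(-abs(est / se), df = m - 2)
  slope <- effect_estimate("egger_slope", co[2, 1], se_slo, "log-OR", n = m,
                           p = pt2(co[2, 1], se_slo))
  intercept <- effect_estimate("egger_intercept", co[1, 1], se_int, "linear",
                               n = m, p = pt2(co[1, 1], se_int))
  low_spread <- stats::sd(assocs$beta_gx) / mean(abs(assocs$beta_gx)) < 0.1
  if (low_spread)
    warning("low regression dilution reliability: little spread in beta_gx",
            call. = FALSE)
  structure(list(slope = slope, intercept = intercept,
                 low_spread = low_spread), class = "mr_egger")
}

#' @export
print.mr_egger <- function(x, ...) {
  cat("<mr_egger>\n")
  cat(sprintf("  slope     : %s\n", .fmt_effect(x$slope)))
  cat(sprintf("  intercept : %.4f (SE %.4f), p = %.3g\n",
              x$intercept$estimate, x$intercept$se, x$intercept$p))
  invisible(x)
}

# cumulative-weight interpolation at probability 0.5 (Bowden's estimator)
.weighted_median_point <- function(theta, w) {
  o <- order(theta)
  th <- theta[o]; ww <- w[o] / sum(w)
  cw <- cumsum(ww) - ww / 2
  if (0.5 <= cw[1]) return(th[1])
  if (0.5 >= cw[length(cw)]) return(th[length(th)])
  j <- max(which(cw < 0.5))
  th[j] + (th[j + 1] - th[j]) * (0.5 - cw[j]) / (cw[j + 1] - cw[j])
}

#' Weighted-median causal estimate
#'
#' Linear interpolation of the ordered Wald ratios at cumulative normalized
#' weight 0.5 (inverse-variance weights); consistent as long as valid
#' instruments carry at least half the weight. The standard error comes
#' from a seeded parametric bootstrap of the `(beta_gx, beta_gy)` pairs.
#'
#' @param assocs A `variant_assoc` table with at least 3 variants.
#' @param bootstrap_reps Bootstrap replicates (warning below 100).
#' @param seed Integer seed for the bootstrap.
#' @return An `effect_estimate` row (term `"weighted_median"`).
#' @export
mr_weighted_median <- function(assocs, bootstrap_reps = 1000, seed) {
  m <- nrow(assocs)
  if (m < 3) stop("weighted median requires >= 3 variants", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (bootstrap_reps < 100)
    warning("fewer than 100 bootstrap replicates", call. = FALSE)
  est <- .weighted_median_point(assocs$theta, assocs$w)
  set.seed(seed)
  bs <- vapply(seq_len(bootstrap_reps), function(b) {
    bx <- stats::rnorm(m, assocs$beta_gx, assocs$se_gx)
    by <- stats::rnorm(m, assocs$beta_gy, assocs$se_gy)
    th <- by / bx
    ww <- (abs(bx) / assocs$se_gy)^2
    .weighted_median_point(th, ww)
  }, 0)
  out <- effect_estimate("weighted_median", est, stats::sd(bs), "log-OR",
                         n = m)
  out$note <- sprintf("parametric bootstrap SE (%d reps)", bootstrap_reps)
  out
}

#' Radial MR: per-variant heterogeneity and outlier detection
#'
#' Decomposes the IVW heterogeneity into per-variant contributions
#' `Q_j = w_j (theta_j - theta_ivw)^2` (so `sum Q_j` is Cochran's global Q,
#' referred to chi-square on `m - 1` df) and flags as outliers the variants
#' whose `Q_j` exceeds the chi-square(1) quantile at `alpha` (Bonferroni
#' `0.05/m` by default). The IVW fit after removing the outliers is
#' returned alongside.
#'
#' @param assocs A `variant_assoc` table with at least 2 variants.
#' @param alpha Per-variant outlier level; default `0.05 / m`.
#' @return A `radial_mr` list: `ivw`, `q`, `df`, `p`, `q_j` (named),
#'   `outliers`, `refit` (IVW without outliers, `NULL` if none or all
#'   flagged).
#' @export
mr_radial <- function(assocs, alpha = NULL) {
  m <- nrow(assocs)
  if (m < 2) stop("radial MR requires >= 2 variants", call. = FALSE)
  if (is.null(alpha)) alpha <- 0.05 / m
  ivw <- mr_ivw(assocs)
  q_j <- assocs$w * (assocs$theta - ivw$estimate)^2
  names(q_j) <- assocs$snp_id
  Q <- sum(q_j)
  cut <- stats::qchisq(1 - alpha, df = 1)
  outliers <- assocs$snp_id[q_j > cut]
  refit <- NULL
  if (length(outliers) && length(outliers) < m - 1)
    refit <- mr_ivw(assocs[!assocs$snp_id %in% outliers, , drop = FALSE])
  structure(list(ivw = ivw, q = Q, df = m - 1,
                 p = stats::pchisq(Q, m - 1, lower.tail = FALSE),
                 q_j = q_j, alpha = alpha, outliers = outliers,
                 refit = refit),
            class = "radial_mr")
}

#' @export
print.radial_mr <- function(x, ...) {
  cat(sprintf("<radial_mr> global Q = %.3f on %d df (p = %.3g); %d outlier(s) at alpha = %.3g\n",
              x$q, x$df, x$p, length(x$outliers), x$alpha))
  if (length(x$outliers)) {
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
    if (!is.null(x$refit))
      cat(sprintf("  IVW after removal: %s\n", .fmt_effect(x$refit)))
  }
  invisible(x)
}

#' Leave-one-out IVW reanalysis
#'
#' Re-estimates the IVW effect `m` times, omitting one variant each, and
#' flags variants whose omission moves the estimate across zero or changes
#' it by more than `change_frac` of the full-set estimate.
#'
#' @param assocs A `variant_assoc` table with at least 3 variants.
#' @param change_frac Relative-change flag threshold.
#' @return Data frame of class `mr_loo`: `left_out`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `p`, `flag`; attribute `full` (full-set IVW).
#' @export
mr_leave_one_out <- function(assocs, change_frac = 0.2) {
  m <- nrow(assocs)
  if (m < 3) stop("leave-one-out requires >= 3 variants", call. = FALSE)
  full <- mr_ivw(assocs)
  rows <- lapply(seq_len(m), function(j) {
    e <- mr_ivw(assocs[-j, , drop = FALSE])
    data.frame(left_out = assocs$snp_id[j], estimate = e$estimate, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, p = e$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  crossed <- sign(out$estimate) != sign(full$estimate) & full$estimate != 0
  moved <- abs(out$estimate - full$estimate) >
    change_frac * abs(full$estimate)
  out$flag <- crossed | moved
  structure(out, full = full, class = c("mr_loo", "data.frame"))
}

#' Run the whole sensitivity suite
#'
#' IVW, MR-Egger, weighted median, radial MR with outlier removal, and
#' leave-one-out on one variant-association table.
#'
#' @param assocs A `variant_assoc` table.
#' @param bootstrap_reps Weighted-median bootstrap replicates.
#' @param seed Integer seed.
#' @param alpha Radial outlier level (default Bonferroni `0.05/m`).
#' @return An `mr_sensitivity` list with elements `ivw`, `egger`,
#'   `weighted_median`, `radial`, `loo`.
#' @export
mr_sensitivity <- function(assocs, bootstrap_reps = 1000, seed, alpha = NULL) {
  structure(list(ivw = mr_ivw(assocs),
                 egger = mr_egger(assocs),
                 weighted_median = mr_weighted_median(assocs, bootstrap_reps,
                                                      seed),
                 radial = mr_radial(assocs, alpha),
                 loo = mr_leave_one_out(assocs)),
            class = "mr_sensitivity")
}

#' @export
print.mr_sensitivity <- function(x, ...) {
  cat("<mr_sensitivity>\n")
  cat(sprintf("  IVW             : %s\n", .fmt_effect(x$ivw)))
  cat(sprintf("  Egger slope     : %s\n", .fmt_effect(x$egger$slope)))
  cat(sprintf("  Egger intercept : %.4f, p = %.3g\n",
              x$egger$intercept$estimate, x$egger$intercept$p))
  cat(sprintf("  weighted median : %s\n", .fmt_effect(x$weighted_median)))
  cat(sprintf("  radial Q        : %.2f (p = %.3g), %d outlier(s)\n",
              x$radial$q, x$radial$p, length(x$radial$outliers)))
  cat(sprintf("  leave-one-out   : %d/%d flagged\n", sum(x$loo$flag),
              nrow(x$loo)))
  invisible(x)
}
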