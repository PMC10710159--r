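# Kaplan-Meier estimation, log-rank comparison across sleep-trait groups,
# and covariate-adjusted survival curves from the Cox fits. Estimation is
# delegated to survival::survfit / survdiff; this layer owns endpoint
# wiring, group handling and the exported curve tables.

#' Kaplan-Meier survival curves by group
#'
#' Product-limit estimate `S(t) = prod(1 - d_i/n_i)` over event times, per
#' level of a grouping column, with Greenwood standard errors. Censored
#' observations tied with events at the same time are kept at risk for
#' those events (the standard convention).
#'
#' @param cohort A `cohort_table` filtered to the analysis sample.
#' @param group Grouping column name, or `NULL` for a single overall curve.
#' @param target Endpoint, see [analysis_targets()].
#' @return A `km_curves` data frame: `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `se` (Greenwood, on the survival scale); empty
#'   groups are flagged in attribute `empty_groups`.
#' @export
km_estimate <- function(cohort, group = NULL, target = "all_cause_mortality") {
  out <- endpoint_outcome(cohort, target)
  g <- if (is.null(group)) factor(rep("all", nrow(cohort))) else
    factor(cohort[[group]])
  empty <- levels(g)[tabulate(g, nbins = nlevels(g)) == 0]
  keep <- !is.na(g)
  dat <- data.frame(time = out$time[keep], event = out$event[keep],
                    g = g[keep])
  fit <- survival::survfit(survival::Surv(time, event) ~ g, data = dat,
                           conf.type = "plain")
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(levels(droplevels(dat$g)), length(s$time))
  else sub("^g=", "", as.character(s$strata))
  curves <- data.frame(group = grp, time = s$time, n_risk = s$n.risk,
                       n_event = s$n.event, n_censor = s$n.censor,
                       surv = s$surv, se = s$std.err,
                       stringsAsFactors = FALSE)
  structure(curves, empty_groups = empty, target = target,
            class = c("km_curves", "data.frame"))
}

#' Log-rank test across groups
#'
#' Standard log-rank statistic from observed versus hypergeometric-expected
#' events at each distinct event time, referred to chi-square with
#' `groups - 1` df.
#'
#' @inheritParams km_estimate
#' @return A `log_rank` list: `statistic`, `df`, `p`, `n`, `obs`, `exp`.
#' @export
log_rank <- function(cohort, group, target = "all_cause_mortality") {
  out <- endpoint_outcome(cohort, target)
  g <- factor(cohort[[group]])
  keep <- !is.na(g)
  g <- droplevels(g[keep])
  if (nlevels(g) < 2)
    stop("log-rank needs >= 2 non-empty groups", call. = FALSE)
  dat <- data.frame(time = out$time[keep], event = out$event[keep], g = g)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = dat)
  df <- nlevels(g) - 1
  structure(list(statistic = sd_$chisq, df = df,
                 p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE),
                 n = nrow(dat), obs = sd_$obs, exp = sd_$exp),
            class = "log_rank")
}

#' @export
print.log_rank <- function(x, ...) {
  cat(sprintf("<log_rank> chi-square = %.4f on %d df, p = %.3g (n = %d)\n",
              x$statistic, x$df, x$p, x$n))
  invisible(x)
}

# reference profile: covariate means for continuous, modes for
# categorical/logical
.reference_profile <- function(df) {
  prof <- lapply(df, function(v) {
    if (is.factor(v) || is.character(v) || is.logical(v)) {
      tab <- table(v)
      md <- names(tab)[which.max(tab)]
      if (is.logical(v)) as.logical(md) else
        if (is.factor(v)) factor(md, levels = levels(v)) else md
    } else mean(v, na.rm = TRUE)
  })
  as.data.frame(prof, stringsAsFactors = FALSE)
}

#' Covariate-adjusted survival curves from a Cox fit
#'
#' Predicted survival per exposure group at a fixed reference covariate
#' profile: the Breslow (Nelson-Aalen) baseline cumulative hazard raised to
#' `exp(linear predictor)`. The default profile sets continuous covariates
#' to their means and categorical ones to their modes in the analysis
#' sample.
#'
#' @param fit A `cox_tier_fit` from [fit_cox()] (must have converged).
#' @param profile Optional one-row data frame overriding the reference
#'   covariate profile; must contain every model covariate.
#' @return A `km_curves`-shaped data frame (`group`, `time`, `surv`, `se`)
#'   with attribute `profile`.
#' @export
adjusted_curves <- function(fit, profile = NULL) {
  stopifnot(inherits(fit, "cox_tier_fit"))
  if (!fit$converged) stop("Cox fit did not converge", call. = FALSE)
  mf <- stats::model.frame(fit$fit)
  covs <- setdiff(names(mf), c("survival::Surv(time, event)", ".exposure"))
  default_prof <- .reference_profile(mf[covs])
  if (is.null(profile)) profile <- default_prof
  else {
    miss <- setdiff(covs, names(profile))
    if (length(miss))
      stop("profile lacks model covariate(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    profile <- profile[covs]
  }
  lev <- levels(mf$.exposure)
  newdata <- data.frame(.exposure = factor(lev, levels = lev))
  if (ncol(profile)) newdata <- cbind(newdata, profile[rep(1, length(lev)), ,
                                                       drop = FALSE])
  sf <- survival::survfit(fit$fit, newdata = newdata, stype = 2, ctype = 1,
                          conf.type = "plain")
  surv <- as.matrix(sf$surv)
  # survfit's std.err is on the cumulative-hazard scale; delta-method back
  # to the survival scale
  se <- surv * as.matrix(sf$std.err)
  curves <- do.call(rbind, lapply(seq_along(lev), function(j) {
    data.frame(group = lev[j], time = sf$time, surv = surv[, j],
               se = se[, j], stringsAsFactors = FALSE)
  }))
  structure(curves, profile = profile, exposure = fit$exposure,
            target = fit$target, class = c("km_curves", "data.frame"))
}

#' Write survival curves as TSV
#' @param curves A `km_curves` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  utils::write.table(as.data.frame(curves), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
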