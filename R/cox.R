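# Tiered multivariable Cox proportional-hazards models of the sleep traits
# against the incidence and mortality endpoints. Fitting is delegated to
# survival::coxph (Efron ties by default); the surrounding layer owns tier
# definitions, exposure coding with declared reference levels, and the
# per-level hazard-ratio table.

#' Covariates of an adjustment tier
#'
#' Three nested tiers: `basic` (age, sex, assessment centre, top 10 genetic
#' principal components, genotyping array), `further` (adds lifestyle,
#' socioeconomic and clinical covariates; the mortality endpoints
#' additionally add self-reported cancer count, operation and treatment
#' count), `full` (adds the other sleep traits as numeric adjustments).
#'
#' @param tier `"basic"`, `"further"` or `"full"`.
#' @param target Analysis target (mortality targets extend the further
#'   tier).
#' @param exposure Exposure column, removed from the tier's sleep-trait
#'   adjustments in the full model.
#' @return Character vector of covariate column names.
#' @export
tier_covariates <- function(tier = c("basic", "further", "full"),
                            target = "incidence", exposure = NULL) {
  tier <- match.arg(tier)
  basic <- c("age", "sex", "assessment_center", paste0("pc", 1:10),
             "genotyping_array")
  further <- c(basic, "bmi", "employment_status", "townsend_index",
               "smoking", "drinking", "mental_health", "veg_fruit_serves",
               "sedentary_h", "comorbidity_count", "tpa_group", "education",
               "ethnicity", "family_history")
  if (!is.null(target) && target != "incidence")
    further <- c(further, "n_self_reported_cancers", "operation",
                 "n_treatments")
  sleep <- c("chronotype", "sleep_duration_h", "insomnia")
  full <- c(further, sleep)
  covs <- switch(tier, basic = basic, further = further, full = full)
  if (!is.null(exposure)) {
    drop <- exposure
    if (exposure == "duration_bin") drop <- c(drop, "sleep_duration_h")
    covs <- setdiff(covs, drop)
  }
  covs
}

# default reference levels: 7 h duration, never/rarely insomnia,
# definite-morning chronotype
.default_ref <- c(duration_bin = 2, chronotype = 0, insomnia = 0)

# model frame builder shared by the Cox and MR layers: exposure handling,
# covariate coercion (ordinals numeric, centre as factor), NA-complete rows
.build_frame <- function(cohort, columns) {
  df <- as.data.frame(cohort)[, columns, drop = FALSE]
  if (!is.null(df$assessment_center))
    df$assessment_center <- factor(df$assessment_center)
  keep <- stats::complete.cases(df)
  list(df = df[keep, , drop = FALSE], keep = keep)
}

#' Fit a tiered Cox proportional-hazards model for a sleep trait
#'
#' Fits `Surv(time, event) ~ exposure + tier covariates` on the analysis
#' sample of an endpoint, with the exposure entered as category indicators
#' against a declared reference level (defaults: 7 h sleep, never/rarely
#' insomnia, definite-morning chronotype) and Efron handling of tied event
#' times. Exposure levels with no events are reported with an undefined
#' (NA) estimate and flagged rather than dropped silently.
#'
#' @param cohort A `cohort_table`, already filtered to the analysis sample
#'   (see [apply_exclusions()]).
#' @param exposure Sleep-trait column: `"duration_bin"`, `"chronotype"` or
#'   `"insomnia"` (any categorical column works).
#' @param tier Adjustment tier, see [tier_covariates()].
#' @param target Endpoint, see [analysis_targets()].
#' @param ref Reference level of the exposure.
#' @param ties Tie-handling method passed to [survival::coxph()].
#' @param covariates Optional explicit covariate vector overriding the tier.
#' @return A `cox_tier_fit`: `fit` (the `coxph` object), `estimates` (an
#'   `effect_estimate` table for the non-reference exposure levels, with
#'   `undefined` flags), `covariate_estimates`, plus metadata (`exposure`,
#'   `tier`, `target`, `ref`, `n`, `n_events`, `converged`).
#' @export
fit_cox <- function(cohort, exposure, tier = "basic", target = "incidence",
                    ref = NULL, ties = c("efron", "breslow"),
                    covariates = NULL) {
  ties <- match.arg(ties)
  stopifnot(inherits(cohort, "cohort_table"))
  if (is.null(ref))
    ref <- if (exposure %in% names(.default_ref)) .default_ref[[exposure]] else
      sort(unique(cohort[[exposure]]))[1]
  if (is.null(covariates))
    covariates <- intersect(tier_covariates(tier, target, exposure),
                            names(cohort))

  out <- endpoint_outcome(cohort, target)
  dat <- cbind(out, as.data.frame(cohort)[, c(exposure, covariates),
                                          drop = FALSE])
  if (!is.null(dat$assessment_center))
    dat$assessment_center <- factor(dat$assessment_center)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  dat$.exposure <- stats::relevel(factor(dat[[exposure]]), ref = as.character(ref))

  rhs <- paste(c(".exposure", covariates), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties, model = TRUE),
    warning = function(w) {
      if (grepl("converge|infinite", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })

  cf <- summary(fit)$coefficients
  lev <- setdiff(levels(dat$.exposure), as.character(ref))
  terms_exp <- paste0(".exposure", lev)
  ev_by_lev <- tapply(dat$event, dat$.exposure, sum)
  est <- effect_estimate(term = paste0(exposure, "=", lev),
                         estimate = cf[terms_exp, "coef"],
                         se = cf[terms_exp, "se(coef)"],
                         scale = "log-HR", n = nrow(dat),
                         n_events = sum(dat$event),
                         p = cf[terms_exp, "Pr(>|z|)"])
  est$undefined <- ev_by_lev[lev] == 0
  est$estimate[est$undefined] <- NA_real_
  est$se[est$undefined] <- NA_real_
  est$ci_low[est$undefined] <- est$ci_high[est$undefined] <- NA_real_
  est$p[est$undefined] <- NA_real_

  cov_terms <- setdiff(rownames(cf), terms_exp)
  cov_est <- if (length(cov_terms))
    effect_estimate(term = cov_terms, estimate = cf[cov_terms, "coef"],
                    se = cf[cov_terms, "se(coef)"], scale = "log-HR",
                    n = nrow(dat), n_events = sum(dat$event),
                    p = cf[cov_terms, "Pr(>|z|)"]) else NULL

  structure(list(fit = fit, estimates = est, covariate_estimates = cov_est,
                 exposure = exposure, tier = tier, target = target,
                 ref = ref, ties = ties, n = nrow(dat),
                 n_events = sum(dat$event), converged = converged),
            class = "cox_tier_fit")
}

#' @export
print.cox_tier_fit <- function(x, ...) {
  cat(sprintf("<cox_tier_fit> %s ~ %s [%s tier, %s ties] n = %d, events = %d\n",
              x$target, x$exposure, x$tier, x$ties, x$n, x$n_events))
  e <- x$estimates
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %-18s %s%s\n", e$term[i],
                if (isTRUE(e$undefined[i])) "undefined (no events)" else
                  .fmt_effect(e[i, ]),
                ""))
  invisible(x)
}

#' @export
coef.cox_tier_fit <- function(object, ...) {
  setNames(object$estimates$estimate, object$estimates$term)
}

#' @export
confint.cox_tier_fit <- function(object, parm, level = 0.95, ...) {
  e <- object$estimates
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- cbind(e$estimate - z * e$se, e$estimate + z * e$se)
  dimnames(m) <- list(e$term, sprintf("%.1f %%", c((1 - level) / 2,
                                                   1 - (1 - level) / 2) * 100))
  m
}

#' Export Cox results as a tidy table
#' @param fits A list of `cox_tier_fit` objects.
#' @return Data frame: endpoint, tier, term, HR, ci_low, ci_high, p, n,
#'   n_events.
#' @export
cox_results_table <- function(fits) {
  if (inherits(fits, "cox_tier_fit")) fits <- list(fits)
  do.call(rbind, lapply(fits, function(f) {
    e <- f$estimates
    data.frame(endpoint = f$target, tier = f$tier, term = e$term,
               hr = exp(e$estimate), ci_low = exp(e$ci_low),
               ci_high = exp(e$ci_high), p = e$p, n = e$n,
               n_events = e$n_events, stringsAsFactors = FALSE)
  }))
}
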