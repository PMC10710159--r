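# One-sample two-stage Mendelian randomization: a linear first stage of the
# exposure on the unweighted GRS and a logistic (or linear, for continuous
# outcomes) second stage of the outcome on the genetically fitted exposure,
# with the same tier covariates in both stages.

#' Two-stage one-sample Mendelian randomization
#'
#' Stage 1 regresses the exposure (ordinal trait as numeric, or continuous
#' hours) on the GRS plus tier covariates; stage 2 regresses the outcome on
#' the stage-1 fitted values plus the same covariates — logistic for a
#' binary outcome (effect reported as log-OR per exposure unit), linear for
#' a continuous one. The first-stage partial F statistic is reported as the
#' instrument-strength diagnostic, with a warning below 10. Second-stage
#' standard errors are model-based by default (they ignore first-stage
#' uncertainty); a seeded nonparametric bootstrap over participants is
#' available for honest intervals.
#'
#' @param cohort A `cohort_table`.
#' @param grs Numeric GRS vector, row-aligned with `cohort`.
#' @param exposure Exposure column name.
#' @param outcome An analysis target name (see [analysis_targets()]; its
#'   event indicator is the binary outcome), a logical/binary vector, or a
#'   continuous numeric vector.
#' @param tier Adjustment tier (see [tier_covariates()]).
#' @param covariates Optional explicit covariate columns overriding the
#'   tier.
#' @param bootstrap Number of participant-resampling bootstrap replicates
#'   for the second-stage SE (0 = model-based SE).
#' @param seed Seed for the bootstrap (required when `bootstrap > 0`).
#' @return A `two_stage_mr` object: `first_stage` (effect of GRS on
#'   exposure, with `F`), `second_stage` (causal effect per exposure unit),
#'   `estimate`, `se`, `or`/`ci` on the ratio scale for binary outcomes,
#'   `n`, `tier`, `separation` flag.
#' @export
two_stage_mr <- function(cohort, grs, exposure, outcome, tier = "basic",
                         covariates = NULL, bootstrap = 0, seed = NULL) {
  stopifnot(inherits(cohort, "cohort_table"), length(grs) == nrow(cohort))
  target <- NULL
  if (is.character(outcome) && length(outcome) == 1) {
    target <- match.arg(outcome, analysis_targets())
    y <- endpoint_outcome(cohort, target)$event
  } else y <- outcome
  binary <- is.logical(y) || all(y[!is.na(y)] %in% 0:1)
  y <- as.numeric(y)
  if (is.null(covariates))
    covariates <- intersect(tier_covariates(tier, target, exposure),
                            names(cohort))

  df <- as.data.frame(cohort)[, c(exposure, covariates), drop = FALSE]
  names(df)[1] <- ".x"
  df$.x <- as.numeric(df$.x)
  df$.g <- grs
  df$.y <- y
  if (!is.null(df$assessment_center))
    df$assessment_center <- factor(df$assessment_center)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (stats::var(df$.g) == 0)
    stop("uninformative instrument: GRS is constant in the analysis sample",
         call. = FALSE)

  rhs <- paste(c(".g", covariates), collapse = " + ")
  s1 <- stats::lm(stats::as.formula(paste(".x ~", rhs)), data = df)
  co1 <- summary(s1)$coefficients[".g", ]
  f_stat <- (co1[[1]] / co1[[2]])^2  # partial F for the instrument
  if (f_stat < 10)
    warning(sprintf("weak instrument: first-stage F = %.2f < 10", f_stat),
            call. = FALSE)
  df$.xhat <- stats::fitted(s1)

  rhs2 <- paste(c(".xhat", covariates), collapse = " + ")
  separation <- FALSE
  if (binary) {
    s2 <- withCallingHandlers(
      stats::glm(stats::as.formula(paste(".y ~", rhs2)), data = df,
                 family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) separation <<- TRUE
        invokeRestart("muffleWarning")
      })
  } else {
    s2 <- stats::lm(stats::as.formula(paste(".y ~", rhs2)), data = df)
  }
  co2 <- summary(s2)$coefficients[".xhat", ]
  est <- co2[[1]]; se <- co2[[2]]
  se_source <- "model"

  if (bootstrap > 0) {
    if (is.null(seed)) stop("seed required when bootstrap > 0", call. = FALSE)
    set.seed(seed)
    bs <- vapply(seq_len(bootstrap), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      d <- df[idx, , drop = FALSE]
      f1 <- stats::lm(stats::as.formula(paste(".x ~", rhs)), data = d)
      d$.xhat <- stats::fitted(f1)
      f2 <- if (binary)
        suppressWarnings(stats::glm(stats::as.formula(paste(".y ~", rhs2)),
                                    data = d, family = stats::binomial()))
      else stats::lm(stats::as.formula(paste(".y ~", rhs2)), data = d)
      stats::coef(f2)[".xhat"]
    }, 0)
    se <- stats::sd(bs)
    se_source <- sprintf("bootstrap (%d reps)", bootstrap)
  }

  scale2 <- if (binary) "log-OR" else "linear"
  first <- effect_estimate("grs", co1[[1]], co1[[2]], "linear", n = n)
  first$F <- f_stat
  second <- effect_estimate(paste0(exposure, " (per unit)"), est, se, scale2,
                            n = n,
                            n_events = if (binary) sum(df$.y) else NA_integer_)
  structure(list(first_stage = first, second_stage = second,
                 estimate = est, se = se, n = n, tier = tier,
                 exposure = exposure, outcome = if (!is.null(target)) target
                 else scale2, binary = binary, separation = separation,
                 se_source = se_source,
                 s1 = s1, s2 = s2),
            class = "two_stage_mr")
}

#' @export
print.two_stage_mr <- function(x, ...) {
  cat(sprintf("<two_stage_mr> %s -> %s [%s tier] n = %d\n",
              x$exposure, x$outcome, x$tier, x$n))
  cat(sprintf("  first stage : beta = %.4f (SE %.4f), F = %.1f\n",
              x$first_stage$estimate, x$first_stage$se, x$first_stage$F))
  cat(sprintf("  causal      : %s [SE: %s]\n", .fmt_effect(x$second_stage),
              x$se_source))
  if (x$separation) cat("  ! second-stage separation flagged\n")
  invisible(x)
}

#' @export
coef.two_stage_mr <- function(object, ...) {
  c(causal_estimate = object$estimate)
}

#' @export
confint.two_stage_mr <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(object$estimate + c(-1, 1) * z * object$se, 1)
  dimnames(m) <- list("causal_estimate",
                      sprintf("%.1f %%", c((1 - level) / 2,
                                           1 - (1 - level) / 2) * 100))
  m
}

# trait -> exposure column used when the trait's GRS is the instrument
.trait_exposure <- c(chronotype = "chronotype", short_sleep = "duration_bin",
                     long_sleep = "duration_bin", duration = "duration_bin",
                     insomnia = "insomnia")

#' Run the full linear-MR grid
#'
#' One two-stage fit per (instrument trait, endpoint): the endpoint's
#' eligibility filters are applied, the trait's GRS is screened against the
#' other sleep traits, participants carrying a flagged interferential trait
#' are excluded, and the fit is labelled against the Bonferroni threshold
#' `0.05 / number of fits` (`strong` below it, `suggestive` between it and
#' 0.05, `null` otherwise). Failures of individual cells are recorded, not
#' fatal.
#'
#' @param cohort A `cohort_table` (the unfiltered study population).
#' @param grs_list Named list of GRS vectors (one per instrument trait),
#'   row-aligned with `cohort`.
#' @param targets Endpoints to analyse.
#' @param tier Adjustment tier for both stages.
#' @param screen_exclude Apply the interferential-trait screen/exclusion.
#' @param alpha Family-wise error rate.
#' @return An `mr_grid` data frame: trait, endpoint, tier, or, ci_low,
#'   ci_high, p, label, first_stage_F, n, n_excluded, error; attribute
#'   `threshold`.
#' @export
run_mr_grid <- function(cohort, grs_list, targets = analysis_targets(),
                        tier = "basic", screen_exclude = TRUE, alpha = 0.05) {
  stopifnot(is.list(grs_list), !is.null(names(grs_list)))
  cells <- expand.grid(trait = names(grs_list), endpoint = targets,
                       stringsAsFactors = FALSE)
  threshold <- alpha / nrow(cells)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    trait <- cells$trait[i]; endpoint <- cells$endpoint[i]
    exposure <- if (trait %in% names(.trait_exposure))
      .trait_exposure[[trait]] else trait
    out <- data.frame(trait = trait, endpoint = endpoint, tier = tier,
                      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      p = NA_real_, label = NA_character_,
                      first_stage_F = NA_real_, n = NA_integer_,
                      n_excluded = 0L, error = NA_character_,
                      stringsAsFactors = FALSE)
    res <- try({
      excl <- apply_exclusions(cohort, endpoint)
      sub <- excl$cohort
      g <- grs_list[[trait]][match(sub$participant_id, cohort$participant_id)]
      if (screen_exclude) {
        other <- setdiff(c("chronotype", "duration_bin", "insomnia"), exposure)
        rep_ <- screen_confounders(setNames(list(g), trait), sub, other)
        ie <- exclude_interferential(sub, rep_)
        out$n_excluded <- sum(ie$ledger)
        sub <- ie$cohort
        g <- grs_list[[trait]][match(sub$participant_id, cohort$participant_id)]
      }
      fit <- suppressWarnings(two_stage_mr(sub, g, exposure, endpoint, tier))
      out$or <- exp(fit$estimate)
      out$ci_low <- exp(fit$second_stage$ci_low)
      out$ci_high <- exp(fit$second_stage$ci_high)
      out$p <- fit$second_stage$p
      out$first_stage_F <- fit$first_stage$F
      out$n <- fit$n
      out$label <- if (out$p < threshold) "strong" else
        if (out$p < alpha) "suggestive" else "null"
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      out$error <- conditionMessage(attr(res, "condition"))
    out
  })
  structure(do.call(rbind, rows), threshold = threshold,
            class = c("mr_grid", "data.frame"))
}

#' @export
print.mr_grid <- function(x, ...) {
  cat(sprintf("<mr_grid> %d fits, Bonferroni threshold %.3g\n",
              nrow(x), attr(x, "threshold")))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}
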