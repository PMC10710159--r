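# Synthetic biobank-style cohort generator with known causal parameters.
#
# The generator draws independent biallelic variants in Hardy-Weinberg and
# linkage equilibrium, builds polygenic latent exposures (chronotype, sleep
# duration, insomnia) sharing one unobserved confounder U, discretizes them
# to the ordinal codings of the phenotype model by fixed quantile cut-points,
# and draws incident cancer and post-diagnosis death from exponential
# proportional-hazards models whose log-hazards are linear (or a configured
# smooth function) in the realized exposure. Every realized parameter is
# returned so parameter-recovery tests can compare estimates against truth.

# ordinal margins the discretization targets (frequencies among non-missing
# responses of a large population cohort)
.trait_margins <- list(
  chronotype = c(0.2668, 0.3597, 0.2821, 0.0914),
  insomnia   = c(0.2596, 0.4739, 0.2665),
  duration_hours = c(`3` = 0.0040, `4` = 0.0090, `5` = 0.0357,
                     `6` = 0.1893, `7` = 0.4009, `8` = 0.2903,
                     `9` = 0.0560, `10` = 0.0100, `11` = 0.0028,
                     `12` = 0.0013, `13` = 0.0007)
)

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic cohort generator.
#' Defaults emulate the margins of a large population biobank: five
#' instrument sets of 12 (evening chronotype), 27 (short sleep), 8 (long
#' sleep), 78 (continuous duration) and 57 (insomnia) variants; four-level
#' chronotype, integer-hour sleep duration binned at ≤5/6/7/8/≥9 h, and
#' three-level insomnia; ~11-year follow-up with ~13% cancer incidence and
#' ~15% mortality among baseline cancer patients, of which ~78% are cancer
#' deaths.
#'
#' @param n Number of participants.
#' @param n_variants Named integer vector of instrument-set sizes.
#' @param first_stage_r2 Named vector: fraction of each latent exposure's
#'   variance explained by its instruments (chronotype, duration, insomnia).
#' @param cross_trait_r2 Variance share of the duration latent contributed by
#'   the short- and long-sleep sets, and of the insomnia/chronotype latents
#'   contributed by the short-/long-sleep sets (the interferential-trait
#'   structure the confounder screen is meant to find).
#' @param confounder_sd Effect (per SD of the shared confounder U) on each
#'   latent exposure.
#' @param incidence_model List: `exposure` (cohort column the hazard acts
#'   on), `beta` (log-hazard per unit), `ref` (value at which the exposure
#'   contributes zero), `fn` (optional function overriding the linear term),
#'   `confounder` (log-hazard per SD of U), `target` (marginal incidence
#'   proportion the baseline hazard is calibrated to).
#' @param mortality_model Same fields for death after a baseline cancer
#'   diagnosis; `target` is the case-mortality proportion.
#' @param cancer_death_frac Probability a simulated death is cancer-caused.
#' @param baseline_cancer_prob Probability of a prevalent cancer diagnosis at
#'   enrollment.
#' @param followup_years_max Administrative censoring horizon (years).
#' @param missing_rates Named vector of missingness proportions for the three
#'   sleep traits.
#' @param covariate_outcome_sd Log-hazard per SD of age (and half that for
#'   male sex) in both outcome models, so covariate adjustment matters.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n = 20000,
                       n_variants = c(chronotype = 12, short_sleep = 27,
                                      long_sleep = 8, duration = 78,
                                      insomnia = 57),
                       first_stage_r2 = c(chronotype = 0.05, duration = 0.05,
                                          insomnia = 0.05),
                       cross_trait_r2 = c(short_on_duration = 0.015,
                                          long_on_duration = 0.005,
                                          short_on_insomnia = 0.010,
                                          long_on_chronotype = 0.010),
                       confounder_sd = c(chronotype = 0.25, duration = 0.25,
                                         insomnia = 0.25),
                       incidence_model = list(),
                       mortality_model = list(),
                       cancer_death_frac = 2864 / 3687,
                       baseline_cancer_prob = 0.07,
                       followup_years_max = 11,
                       missing_rates = c(chronotype = 0.091,
                                         duration = 0.0014,
                                         insomnia = 0.0004),
                       covariate_outcome_sd = 0.4) {
  inc <- utils::modifyList(
    list(exposure = "sleep_duration_h", beta = 0, ref = 7, fn = NULL,
         confounder = 0.5, target = 0.13), incidence_model)
  mort <- utils::modifyList(
    list(exposure = "sleep_duration_h", beta = 0, ref = 7, fn = NULL,
         confounder = 0.5, target = 0.1539), mortality_model)
  cfg <- list(n = as.integer(n), n_variants = n_variants,
              first_stage_r2 = first_stage_r2, cross_trait_r2 = cross_trait_r2,
              confounder_sd = confounder_sd, incidence_model = inc,
              mortality_model = mort, cancer_death_frac = cancer_death_frac,
              baseline_cancer_prob = baseline_cancer_prob,
              followup_years_max = followup_years_max,
              missing_rates = missing_rates,
              covariate_outcome_sd = covariate_outcome_sd)
  if (cfg$n < 1) stop("n must be >= 1", call. = FALSE)
  if (any(n_variants < 1)) stop("instrument sets need >= 1 variant", call. = FALSE)
  if (any(first_stage_r2 <= 0 | first_stage_r2 >= 1))
    stop("first_stage_r2 must lie in (0,1)", call. = FALSE)
  for (m in list(inc, mort))
    if (m$target <= 0 || m$target >= 1)
      stop("outcome target proportions must lie in (0,1)", call. = FALSE)
  # latent variances must leave room for independent noise
  for (tr in names(first_stage_r2)) {
    tot <- first_stage_r2[[tr]] + confounder_sd[[tr]]^2 +
      sum(cross_trait_r2[grepl(paste0("on_", tr), names(cross_trait_r2))])
    if (tot >= 1)
      stop("latent variance budget exceeds 1 for exposure: ", tr, call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate hard-call genotype dosages
#'
#' Independent biallelic variants in Hardy-Weinberg and linkage equilibrium:
#' each dosage is Binomial(2, freq).
#'
#' @param n Participants (rows).
#' @param freq Vector of effect-allele frequencies in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return Integer matrix `n x length(freq)` with values in `{0, 1, 2}`.
#' @export
simulate_genotypes <- function(n, freq, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(freq < 0 | freq > 1)) stop("allele frequencies must be in [0,1]", call. = FALSE)
  m <- length(freq)
  mat <- vapply(seq_len(m), function(j) stats::rbinom(n, 2L, freq[j]),
                integer(n))
  dim(mat) <- c(n, m)
  mat
}

# map a latent N(0, sd) variable to categories with fixed target margins via
# its probability-integral transform; returns 0-based codes
.discretize <- function(latent, sd_latent, probs) {
  u <- stats::pnorm(latent, sd = sd_latent)
  findInterval(u, cumsum(probs), left.open = TRUE)
}

# non-strand-ambiguous allele pairs
.allele_pairs <- rbind(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                       c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))

#' Simulate a biobank-style cohort with known causal structure
#'
#' Generates genotypes, ordinal sleep traits, covariates, a shared latent
#' confounder, incident cancer and post-diagnosis cause-specific death, all
#' under the configuration in `config`. Baseline hazards are calibrated so
#' the marginal incidence and case-mortality proportions hit the configured
#' targets in expectation. The full realized truth (per-variant effects,
#' causal parameters, confounder values, cut-points, baseline hazards) is
#' returned for parameter-recovery testing.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (mandatory: every run is reproducible).
#' @return A `sim_cohort` list: `cohort` (a `cohort_table`), `dosages`
#'   (n x M integer matrix, columns named by variant), `instruments`
#'   (instrument table with trait labels and realized per-allele exposure
#'   effects), `truth`.
#' @export
simulate_cohort <- function(config = sim_config(), seed) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  n <- config$n

  ## covariates ------------------------------------------------------------
  cov <- data.frame(
    age = stats::rnorm(n, 56, 8),
    sex = stats::runif(n) < 0.49,
    assessment_center = factor(sample(paste0("C", 1:5), n, replace = TRUE)),
    genotyping_array = stats::runif(n) < 0.2,
    bmi = stats::rnorm(n, 27.3, 4.6),
    townsend_index = stats::rnorm(n, -1.45, 3),
    smoking = sample(0:2, n, TRUE, prob = c(0.55, 0.35, 0.10)),
    drinking = sample(0:2, n, TRUE, prob = c(0.04, 0.03, 0.93)),
    mental_health = stats::runif(n) < 0.11,
    veg_fruit_serves = pmax(stats::rnorm(n, 4.4, 2.9), 0),
    sedentary_h = pmax(stats::rnorm(n, 4.8, 2.4), 0),
    comorbidity_count = stats::rpois(n, 1.8),
    employment_status = sample(0:2, n, TRUE, prob = c(0.52, 0.38, 0.10)),
    tpa_group = sample(0:2, n, TRUE, prob = c(0.24, 0.37, 0.39)),
    education = stats::runif(n) < 0.42,
    ethnicity = stats::runif(n) < 0.953,
    family_history = stats::runif(n) < 0.35,
    n_self_reported_cancers = stats::rpois(n, 0.9),
    operation = stats::runif(n) < 0.93,
    n_treatments = stats::rpois(n, 3),
    shift_work_frequency = sample(0:3, n, TRUE, prob = c(0.90, 0.05, 0.03, 0.02)))
  for (j in 1:10) cov[[paste0("pc", j)]] <- stats::rnorm(n)
  U <- stats::rnorm(n)

  ## genotypes and instrument sets -----------------------------------------
  sets <- names(config$n_variants)
  freq <- effects <- list()
  dos <- list()
  for (s in sets) {
    m <- config$n_variants[[s]]
    freq[[s]] <- stats::runif(m, 0.1, 0.9)
    dos[[s]] <- simulate_genotypes(n, freq[[s]])
    colnames(dos[[s]]) <- sprintf("rs_%s_%02d", s, seq_len(m))
  }

  # per-variant effects scaled so each set contributes its variance budget
  scale_effects <- function(s, r2, sign = 1) {
    m <- config$n_variants[[s]]
    raw <- sign * abs(stats::rnorm(m, 1, 0.25))
    v <- sum(raw^2 * 2 * freq[[s]] * (1 - freq[[s]]))
    raw * sqrt(r2 / v)
  }
  r2 <- config$first_stage_r2; xr2 <- config$cross_trait_r2
  effects$chronotype <- scale_effects("chronotype", r2[["chronotype"]])
  effects$duration <- scale_effects("duration", r2[["duration"]])
  effects$short_sleep <- scale_effects("short_sleep", xr2[["short_on_duration"]], -1)
  effects$long_sleep <- scale_effects("long_sleep", xr2[["long_on_duration"]])
  effects$insomnia <- scale_effects("insomnia", r2[["insomnia"]])
  # interferential cross-trait paths
  x_short_ins <- scale_effects("short_sleep", xr2[["short_on_insomnia"]])
  x_long_chr <- scale_effects("long_sleep", xr2[["long_on_chronotype"]])

  latent <- function(parts, conf_sd) {
    gvar <- sum(vapply(parts, function(p)
      sum(p$eff^2 * 2 * freq[[p$set]] * (1 - freq[[p$set]])), 0))
    gmean <- sum(vapply(parts, function(p)
      sum(p$eff * 2 * freq[[p$set]]), 0))
    g <- Reduce(`+`, lapply(parts, function(p) drop(dos[[p$set]] %*% p$eff)))
    noise_var <- 1 - gvar - conf_sd^2
    # centred and unit-variance by construction
    (g - gmean) + conf_sd * U + stats::rnorm(n, 0, sqrt(noise_var))
  }
  lat_chr <- latent(list(list(set = "chronotype", eff = effects$chronotype),
                         list(set = "long_sleep", eff = x_long_chr)),
                    config$confounder_sd[["chronotype"]])
  lat_dur <- latent(list(list(set = "duration", eff = effects$duration),
                         list(set = "short_sleep", eff = effects$short_sleep),
                         list(set = "long_sleep", eff = effects$long_sleep)),
                    config$confounder_sd[["duration"]])
  lat_ins <- latent(list(list(set = "insomnia", eff = effects$insomnia),
                         list(set = "short_sleep", eff = x_short_ins)),
                    config$confounder_sd[["insomnia"]])

  ## discretize to the ordinal phenotype codings ---------------------------
  chronotype <- .discretize(lat_chr, 1, .trait_margins$chronotype)
  insomnia <- .discretize(lat_ins, 1, .trait_margins$insomnia)
  dur_p <- .trait_margins$duration_hours / sum(.trait_margins$duration_hours)
  hours <- as.integer(names(dur_p))[
    .discretize(lat_dur, 1, dur_p) + 1L]

  mr <- config$missing_rates
  chronotype[stats::runif(n) < mr[["chronotype"]]] <- NA
  hours[stats::runif(n) < mr[["duration"]]] <- NA
  insomnia[stats::runif(n) < mr[["insomnia"]]] <- NA

  ## outcomes --------------------------------------------------------------
  std_age <- (cov$age - 56) / 8
  cov_lp <- config$covariate_outcome_sd * (std_age + 0.5 * cov$sex)
  exposure_term <- function(model, hours, chronotype, insomnia) {
    x <- switch(model$exposure,
                sleep_duration_h = hours, duration_bin = duration_bin(hours),
                chronotype = chronotype, insomnia = insomnia,
                stop("unknown exposure column in outcome model: ",
                     model$exposure, call. = FALSE))
    x0 <- ifelse(is.na(x), model$ref, x)  # missing exposure contributes ref
    if (!is.null(model$fn)) model$fn(x0) else model$beta * (x0 - model$ref)
  }
  C <- config$followup_years_max

  baseline_cancer <- stats::runif(n) < config$baseline_cancer_prob
  dx_offset <- rep(NA_real_, n)
  dx_offset[baseline_cancer] <- -stats::runif(sum(baseline_cancer), 0, 10)

  # incident cancer among the cancer-free
  lp_inc <- exposure_term(config$incidence_model, hours, chronotype, insomnia) +
    config$incidence_model$confounder * U + cov_lp
  h0_inc <- -log(1 - config$incidence_model$target) / C / mean(exp(lp_inc))
  t_inc <- stats::rexp(n, h0_inc * exp(lp_inc))
  incident <- !baseline_cancer & t_inc <= C
  dx_offset[incident] <- t_inc[incident]

  # death after a baseline cancer diagnosis
  lp_m <- exposure_term(config$mortality_model, hours, chronotype, insomnia) +
    config$mortality_model$confounder * U + cov_lp
  if (any(baseline_cancer)) {
    h0_m <- -log(1 - config$mortality_model$target) / C /
      mean(exp(lp_m[baseline_cancer]))
    t_death <- stats::rexp(n, h0_m * exp(lp_m))
  } else {
    h0_m <- NA_real_
    t_death <- rep(Inf, n)
  }
  death <- baseline_cancer & t_death <= C
  death_cause <- ifelse(!death, "none",
                        ifelse(stats::runif(n) < config$cancer_death_frac,
                               "cancer", "noncancer"))
  followup <- ifelse(baseline_cancer, pmin(t_death, C), pmin(t_inc, C))

  cohort <- as_cohort(data.frame(
    participant_id = sprintf("ID%07d", seq_len(n)),
    chronotype = chronotype, sleep_duration_h = hours, insomnia = insomnia,
    cov,
    cancer_baseline = baseline_cancer, cancer_incident = incident,
    cancer_dx_offset_years = dx_offset,
    death = death, death_cause = death_cause, followup_years = followup,
    stringsAsFactors = FALSE))

  instruments <- do.call(rbind, lapply(sets, function(s) {
    m <- config$n_variants[[s]]
    pair <- .allele_pairs[sample(nrow(.allele_pairs), m, TRUE), , drop = FALSE]
    data.frame(trait = s, snp_id = colnames(dos[[s]]),
               effect_allele = pair[, 1], other_allele = pair[, 2],
               eaf = freq[[s]], beta_exposure = effects[[s]],
               stringsAsFactors = FALSE)
  }))
  rownames(instruments) <- NULL

  truth <- list(config = config, seed = seed, confounder = U,
                latent = list(chronotype = lat_chr, duration = lat_dur,
                              insomnia = lat_ins),
                effects = effects,
                cross_effects = list(short_on_insomnia = x_short_ins,
                                     long_on_chronotype = x_long_chr),
                freq = freq,
                causal = list(incidence = config$incidence_model,
                              mortality = config$mortality_model),
                baseline_hazards = c(incidence = h0_inc, mortality = h0_m),
                margins = .trait_margins)

  structure(list(cohort = cohort, dosages = do.call(cbind, dos),
                 instruments = instruments, truth = truth),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> n = %d, %d variants in %d instrument sets (seed %d)\n",
              nrow(x$cohort), ncol(x$dosages),
              length(unique(x$instruments$trait)), x$truth$seed))
  cat(sprintf("  incidence: %.1f%% of cancer-free | case mortality: %.1f%% of %d baseline cases\n",
              100 * mean(x$cohort$cancer_incident[!x$cohort$cancer_baseline]),
              100 * mean(x$cohort$death[x$cohort$cancer_baseline]),
              sum(x$cohort$cancer_baseline)))
  invisible(x)
}

#' Write a simulated cohort's artifacts to disk
#'
#' Writes the phenotype TSV, the dosage matrix (plain CSV, participants in
#' rows), the instrument TSV and the truth/run parameters as JSON.
#'
#' @param sim A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_sim_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(phenotypes = file.path(dir, "phenotypes.tsv"),
             dosages = file.path(dir, "dosages.csv"),
             instruments = file.path(dir, "instruments.tsv"),
             truth = file.path(dir, "truth.json"))
  write_cohort(sim$cohort, paths[["phenotypes"]])
  utils::write.csv(data.frame(participant_id = sim$cohort$participant_id,
                              sim$dosages, check.names = FALSE),
                   paths[["dosages"]], row.names = FALSE, quote = FALSE)
  utils::write.table(sim$instruments, paths[["instruments"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- sim$truth
  tr$confounder <- NULL; tr$latent <- NULL  # keep the JSON small
  tr$config$incidence_model$fn <- tr$config$mortality_model$fn <- NULL
  tr$causal$incidence$fn <- tr$causal$mortality$fn <- NULL
  jsonlite::write_json(tr, paths[["truth"]], auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(paths)
}

#' Simulate per-variant summary associations
#'
#' Draws the per-variant exposure/outcome association statistics that the
#' summary-statistic estimators consume, under a known causal slope with
#' optional directional pleiotropy in a fraction of invalid variants:
#' `beta_gy = theta * beta_gx_true + alpha_j + noise`.
#'
#' @param m Number of variants.
#' @param theta True causal slope.
#' @param se_gx,se_gy Standard errors (scalars or length-m vectors).
#' @param beta_gx_range Range the true per-allele exposure effects are drawn
#'   from (uniform).
#' @param invalid_fraction Fraction of variants given a direct outcome
#'   (pleiotropic) effect.
#' @param pleiotropy_mean,pleiotropy_sd Distribution of the pleiotropic
#'   effects among invalid variants.
#' @param seed Integer seed.
#' @return A `variant_assoc` data frame (see [derive_variant_assocs()]);
#'   attribute `truth` holds the planted parameters.
#' @export
simulate_variant_assocs <- function(m, theta, se_gx = 0.01, se_gy = 0.02,
                                    beta_gx_range = c(0.05, 0.15),
                                    invalid_fraction = 0,
                                    pleiotropy_mean = 0, pleiotropy_sd = 0,
                                    seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  se_gx <- rep_len(se_gx, m); se_gy <- rep_len(se_gy, m)
  bx_true <- stats::runif(m, beta_gx_range[1], beta_gx_range[2])
  invalid <- seq_len(m) <= floor(invalid_fraction * m)
  alpha <- ifelse(invalid, stats::rnorm(m, pleiotropy_mean, pleiotropy_sd), 0)
  bx <- stats::rnorm(m, bx_true, se_gx)
  by <- stats::rnorm(m, theta * bx_true + alpha, se_gy)
  out <- variant_assoc(data.frame(
    snp_id = sprintf("rs_sim_%03d", seq_len(m)),
    beta_gx = bx, se_gx = se_gx, beta_gy = by, se_gy = se_gy,
    stringsAsFactors = FALSE))
  attr(out, "truth") <- list(theta = theta, beta_gx_true = bx_true,
                             alpha = alpha, invalid = invalid, seed = seed)
  out
}
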