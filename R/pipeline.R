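# Config-driven orchestration of the full study design: simulate (or read)
# a cohort, apply eligibility filters, build the genetic risk scores and
# the confounder screen, fit the Cox tiers, run the linear-MR grid, the
# nonlinear MR, the sensitivity suite and the survival curves, writing
# TSV/JSON artifacts and a reproducibility manifest.

#' Default pipeline configuration
#'
#' @param seed Integer seed (mandatory: every stage's randomness derives
#'   from it).
#' @param n Cohort size for the simulation stage.
#' @param stages Stages to run, a subset of `simulate`, `filter`, `grs`,
#'   `cox`, `mr_linear`, `mr_nonlinear`, `mr_sensitivity`, `survival`.
#' @param targets Endpoints analysed by the modelling stages.
#' @param tiers Cox adjustment tiers to fit.
#' @param mr_tier Tier for both MR stages.
#' @param K Strata for nonlinear MR.
#' @param bootstrap_reps Weighted-median bootstrap replicates.
#' @param outlier_alpha Radial-MR outlier level (`NULL` = Bonferroni 0.05/m).
#' @param simulation Extra arguments for [sim_config()].
#' @param inputs Optional named paths (`phenotypes`, `dosages`,
#'   `instruments`) to read instead of simulating.
#' @return A `run_config` list.
#' @export
run_config <- function(seed, n = 5000,
                       stages = c("simulate", "filter", "grs", "cox",
                                  "mr_linear", "mr_nonlinear",
                                  "mr_sensitivity", "survival"),
                       targets = c("incidence", "all_cause_mortality"),
                       tiers = c("basic", "full"), mr_tier = "basic",
                       K = 3, bootstrap_reps = 200, outlier_alpha = NULL,
                       simulation = list(), inputs = NULL) {
  if (missing(seed)) stop("config error: seed is mandatory", call. = FALSE)
  cfg <- list(seed = as.integer(seed), n = as.integer(n), stages = stages,
              targets = targets, tiers = tiers, mr_tier = mr_tier, K = K,
              bootstrap_reps = bootstrap_reps, outlier_alpha = outlier_alpha,
              simulation = simulation, inputs = inputs)
  bad <- setdiff(stages, c("simulate", "filter", "grs", "cox", "mr_linear",
                           "mr_nonlinear", "mr_sensitivity", "survival"))
  if (length(bad))
    stop("config error: unknown stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#' @param path Config file (`.yaml`/`.yml` requires the yaml package).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is needed to read YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, lst)
}

.write_json <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)

.write_tsv <- function(df, path)
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order and writes each stage's artifacts
#' under `out_dir`, plus `manifest.json` recording the package version, the
#' seed, the serialized config and the MD5 digest of every file written.
#' Failures of individual grid cells are recorded in the linear-MR table,
#' not fatal; an invalid config aborts before any stage runs.
#'
#' @param config A `run_config` (or path readable by [read_run_config()]).
#' @param out_dir Output directory.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  log <- character()
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
  on_stage <- function(s) s %in% config$stages

  ## inputs ----------------------------------------------------------------
  if (on_stage("simulate") || is.null(config$inputs)) {
    sim <- simulate_cohort(do.call(sim_config,
                                   c(list(n = config$n), config$simulation)),
                           seed = config$seed)
    cohort <- sim$cohort; dosages <- sim$dosages; instruments <- sim$instruments
    if (on_stage("simulate")) {
      paths <- write_sim_cohort(sim, file.path(out_dir, "simulated"))
      written <- c(written, paths)
      note("simulate: n = %d, %d variants", nrow(cohort), ncol(dosages))
    }
  } else {
    cohort <- read_cohort(config$inputs$phenotypes)
    dmat <- utils::read.csv(config$inputs$dosages, check.names = FALSE)
    dosages <- as.matrix(dmat[, -1]); rownames(dosages) <- dmat[[1]]
    instruments <- read_instruments(config$inputs$instruments)
    note("inputs: read %d participants, %d variants", nrow(cohort),
         ncol(dosages))
  }

  traits <- unique(instruments$trait)
  grs_list <- lapply(setNames(traits, traits), function(tr)
    compute_grs(dosages, instruments[instruments$trait == tr, ]))

  ## filter ----------------------------------------------------------------
  filtered <- list()
  for (tg in config$targets) {
    ex <- apply_exclusions(cohort, tg, drop_missing_covariates = TRUE)
    filtered[[tg]] <- ex
    note("filter[%s]: %d -> %d rows", tg, nrow(cohort), nrow(ex$cohort))
  }
  if (on_stage("filter")) {
    p <- file.path(out_dir, "exclusion_ledgers.json")
    .write_json(lapply(filtered, function(e) as.list(e$ledger)), p)
    written <- c(written, p)
  }

  ## grs + screen ----------------------------------------------------------
  if (on_stage("grs")) {
    gtab <- data.frame(participant_id = cohort$participant_id,
                       as.data.frame(grs_list), check.names = FALSE)
    p1 <- file.path(out_dir, "grs.tsv"); .write_tsv(gtab, p1)
    cand <- intersect(c("chronotype", "duration_bin", "insomnia", "bmi",
                        "townsend_index", "smoking", "education",
                        "sedentary_h"), names(cohort))
    scr <- screen_confounders(grs_list, cohort, cand)
    p2 <- file.path(out_dir, "screen_report.tsv"); .write_tsv(scr, p2)
    p3 <- file.path(out_dir, "screen_report.json")
    .write_json(list(threshold = attr(scr, "threshold"),
                     n_tests = attr(scr, "n_tests"),
                     flagged = scr$candidate[scr$flag],
                     report = as.data.frame(scr)), p3)
    written <- c(written, p1, p2, p3)
    note("grs: %d scores, screen %d tests, %d flagged",
         length(grs_list), attr(scr, "n_tests"), sum(scr$flag))
  }

  ## cox -------------------------------------------------------------------
  if (on_stage("cox")) {
    fits <- list()
    for (tg in config$targets)
      for (tier in config$tiers)
        for (exp_ in c("duration_bin", "chronotype", "insomnia")) {
          f <- try(fit_cox(filtered[[tg]]$cohort, exp_, tier, tg),
                   silent = TRUE)
          if (!inherits(f, "try-error")) fits[[length(fits) + 1]] <- f
          else note("cox[%s,%s,%s]: failed (%s)", tg, tier, exp_,
                    conditionMessage(attr(f, "condition")))
        }
    p <- file.path(out_dir, "cox_results.tsv")
    .write_tsv(cox_results_table(fits), p)
    written <- c(written, p)
    note("cox: %d fits", length(fits))
  }

  ## linear MR grid --------------------------------------------------------
  if (on_stage("mr_linear")) {
    grid <- run_mr_grid(cohort, grs_list, config$targets, config$mr_tier)
    p <- file.path(out_dir, "mr_linear_grid.tsv"); .write_tsv(grid, p)
    written <- c(written, p)
    note("mr_linear: %d fits, threshold %.3g", nrow(grid),
         attr(grid, "threshold"))
  }

  ## nonlinear MR ----------------------------------------------------------
  if (on_stage("mr_nonlinear") && "duration" %in% traits) {
    covs <- intersect(tier_covariates("basic"), names(cohort))
    res <- list()
    for (tg in config$targets) {
      ch <- filtered[[tg]]$cohort
      g <- grs_list$duration[match(ch$participant_id, cohort$participant_id)]
      rp <- try(nonlinear_mr(ch, g, "sleep_duration_h", tg, covs,
                             K = config$K), silent = TRUE)
      if (inherits(rp, "try-error")) {
        note("mr_nonlinear[%s]: failed", tg); next
      }
      res[[tg]] <- list(strata = as.data.frame(rp$laces),
                        theta_ivw = rp$theta_ivw,
                        cochran_q = rp$cochran_q, quadratic = rp$quadratic)
      .write_tsv(rp$laces, file.path(out_dir,
                                     sprintf("mr_nonlinear_strata_%s.tsv", tg)))
      written <- c(written,
                   file.path(out_dir, sprintf("mr_nonlinear_strata_%s.tsv", tg)))
    }
    p <- file.path(out_dir, "mr_nonlinear.json"); .write_json(res, p)
    written <- c(written, p)
    note("mr_nonlinear: %d endpoints", length(res))
  }

  ## sensitivity suite -----------------------------------------------------
  if (on_stage("mr_sensitivity")) {
    covs <- intersect(tier_covariates("basic"), names(cohort))
    res <- list()
    for (tg in config$targets) {
      ch <- filtered[[tg]]$cohort
      for (tr in traits) {
        ins <- instruments[instruments$trait == tr, ]
        dsub <- dosages[match(ch$participant_id, cohort$participant_id),
                        ins$snp_id, drop = FALSE]
        exp_col <- if (tr %in% names(.trait_exposure)) .trait_exposure[[tr]]
        else tr
        a <- try(derive_variant_assocs(ch, dsub, ins, exp_col, tg, covs),
                 silent = TRUE)
        if (inherits(a, "try-error")) next
        suite <- try(suppressWarnings(
          mr_sensitivity(a, config$bootstrap_reps, seed = config$seed + 1,
                         alpha = config$outlier_alpha)), silent = TRUE)
        if (inherits(suite, "try-error")) next
        res[[paste(tr, tg, sep = ".")]] <- list(
          ivw = as.list(suite$ivw[c("estimate", "se", "p")]),
          egger_slope = as.list(suite$egger$slope[c("estimate", "se", "p")]),
          egger_intercept = as.list(
            suite$egger$intercept[c("estimate", "se", "p")]),
          weighted_median = as.list(
            suite$weighted_median[c("estimate", "se", "p")]),
          radial = list(q = suite$radial$q, p = suite$radial$p,
                        outliers = suite$radial$outliers),
          loo_flagged = suite$loo$left_out[suite$loo$flag])
      }
    }
    p <- file.path(out_dir, "mr_sensitivity.json"); .write_json(res, p)
    written <- c(written, p)
    note("mr_sensitivity: %d trait-endpoint suites", length(res))
  }

  ## survival curves -------------------------------------------------------
  if (on_stage("survival")) {
    for (tg in intersect(config$targets, analysis_targets()[-1])) {
      ch <- filtered[[tg]]$cohort
      for (exp_ in c("duration_bin", "chronotype", "insomnia")) {
        km <- km_estimate(ch, exp_, tg)
        pk <- file.path(out_dir, sprintf("km_%s_%s.tsv", tg, exp_))
        write_curves(km, pk); written <- c(written, pk)
        lr <- try(log_rank(ch, exp_, tg), silent = TRUE)
        if (!inherits(lr, "try-error")) {
          pl <- file.path(out_dir, sprintf("logrank_%s_%s.json", tg, exp_))
          .write_json(lr[c("statistic", "df", "p", "n")], pl)
          written <- c(written, pl)
        }
      }
      note("survival[%s]: curves + log-rank written", tg)
    }
  }

  ## manifest --------------------------------------------------------------
  cfg_out <- config; class(cfg_out) <- NULL
  manifest <- list(package = "sleepmr",
                   version = as.character(utils::packageVersion("sleepmr")),
                   seed = config$seed, config = cfg_out, log = log,
                   files = {
                     md5 <- tools::md5sum(sort(unname(written)))
                     # keyed by path relative to out_dir so manifests are
                     # location-independent
                     names(md5) <- sub(paste0("^", normalizePath(out_dir),
                                              .Platform$file.sep), "",
                                       normalizePath(names(md5)))
                     as.list(md5)
                   })
  .write_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
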