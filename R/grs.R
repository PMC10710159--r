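# Unweighted genetic risk scores: allele harmonization between instrument
# definitions and a genotype source, risk-allele counting, and the
# GRS-confounder screen that gates the MR models.

.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_ambiguous <- function(a1, a2) .complement[a1] == a2

#' Read an instrument definition table
#'
#' TSV with columns `snp_id`, `effect_allele`, `other_allele`, optionally
#' `trait`, `eaf`, `beta_exposure`, `se_exposure`, `beta_outcome`,
#' `se_outcome`.
#'
#' @param path Path to the tab-separated instrument file.
#' @return Data frame of instruments (one row per variant).
#' @export
read_instruments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ins <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("snp_id", "effect_allele", "other_allele")
  miss <- setdiff(req, names(ins))
  if (length(miss))
    stop("instrument file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  validate_instruments(ins)
}

#' Validate an instrument set
#' @param instruments Data frame with `snp_id`, `effect_allele`,
#'   `other_allele`.
#' @return The validated data frame.
#' @export
validate_instruments <- function(instruments) {
  if (anyDuplicated(instruments$snp_id))
    stop("duplicated variant ids in instrument set", call. = FALSE)
  if (any(instruments$effect_allele == instruments$other_allele))
    stop("effect and other allele must differ", call. = FALSE)
  ok <- c("A", "C", "G", "T")
  if (!all(instruments$effect_allele %in% ok & instruments$other_allele %in% ok))
    stop("alleles must be single nucleotides A/C/G/T", call. = FALSE)
  instruments
}

#' Harmonize instrument alleles against a genotype source
#'
#' Determines, per variant, whether the genotype file's counted allele is
#' the instrument's effect allele (dosage used as-is), its other allele
#' (dosage reflected, `d -> 2 - d`), or the strand-complement of either
#' (treated the same after complementing). Strand-ambiguous (A/T, C/G)
#' variants cannot be oriented from alleles alone and are handled by
#' `ambiguous_policy`.
#'
#' @param instruments Instrument data frame (see [read_instruments()]).
#' @param variant_meta Data frame describing the genotype source:
#'   `snp_id`, `counted_allele`, `other_allele`.
#' @param ambiguous_policy `"drop"` (exclude and log) or `"assume_forward"`
#'   (orient as if both files share a strand).
#' @return A `harmonization` list: `flip` (named logical over kept
#'   variants), `dropped` (ids of ambiguous variants removed), `policy`.
#' @export
harmonize <- function(instruments, variant_meta,
                      ambiguous_policy = c("drop", "assume_forward")) {
  ambiguous_policy <- match.arg(ambiguous_policy)
  validate_instruments(instruments)
  absent <- setdiff(instruments$snp_id, variant_meta$snp_id)
  if (length(absent))
    stop("instrument variant(s) absent from genotype source: ",
         paste(absent, collapse = ", "), call. = FALSE)
  meta <- variant_meta[match(instruments$snp_id, variant_meta$snp_id), ]

  ea <- instruments$effect_allele; oa <- instruments$other_allele
  ca <- meta$counted_allele; fa <- meta$other_allele
  ambiguous <- .is_ambiguous(ea, oa)

  flip <- rep(NA, nrow(instruments))
  same <- ea == ca & oa == fa
  refl <- ea == fa & oa == ca
  same_c <- .complement[ea] == ca & .complement[oa] == fa
  refl_c <- .complement[ea] == fa & .complement[oa] == ca
  flip[same | same_c] <- FALSE
  flip[refl | refl_c] <- TRUE
  # ambiguous variants match both orientations; resolve by policy
  dropped <- character()
  if (any(ambiguous)) {
    if (ambiguous_policy == "drop") {
      dropped <- instruments$snp_id[ambiguous]
      flip <- flip[!ambiguous]
      names(flip) <- instruments$snp_id[!ambiguous]
      flip[] <- ifelse(is.na(flip), NA, flip)
    } else {
      flip[ambiguous] <- (ea == fa)[ambiguous]  # forward-strand match
      names(flip) <- instruments$snp_id
    }
  } else names(flip) <- instruments$snp_id

  if (anyNA(flip))
    stop("allele pair incompatible with either orientation for: ",
         paste(names(flip)[is.na(flip)], collapse = ", "), call. = FALSE)
  structure(list(flip = flip, dropped = dropped, policy = ambiguous_policy),
            class = "harmonization")
}

#' @export
print.harmonization <- function(x, ...) {
  cat(sprintf("<harmonization> %d variants oriented (%d reflected), %d dropped as strand-ambiguous [policy: %s]\n",
              length(x$flip), sum(x$flip), length(x$dropped), x$policy))
  invisible(x)
}

#' Compute an unweighted genetic risk score
#'
#' Sums risk-allele dosages (0/1/2 on the instrument's effect allele) across
#' the variants of one instrument set. With a `harmonization`, dosages of
#' reflected variants are counted as `2 - d` and dropped variants are
#' omitted.
#'
#' @param dosages Numeric matrix, participants x variants, columns named by
#'   variant id, values in `[0, 2]`.
#' @param instruments Instrument data frame.
#' @param harmonization Optional [harmonize()] result; if `NULL`, dosage
#'   columns are assumed to already count the effect allele.
#' @param missing Missing-dosage policy: `"mean_impute"` substitutes the
#'   per-variant mean and flags affected participants (attribute
#'   `imputed`); `"fail"` raises an error.
#' @return Numeric vector of scores in `[0, 2m]`, named by rownames of
#'   `dosages` when present.
#' @export
compute_grs <- function(dosages, instruments, harmonization = NULL,
                        missing = c("mean_impute", "fail")) {
  missing <- match.arg(missing)
  ids <- instruments$snp_id
  flip <- setNames(rep(FALSE, length(ids)), ids)
  if (!is.null(harmonization)) {
    ids <- setdiff(ids, harmonization$dropped)
    flip <- harmonization$flip[ids]
  }
  absent <- setdiff(ids, colnames(dosages))
  if (length(absent))
    stop("dosage matrix lacks variant(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  d <- dosages[, ids, drop = FALSE]
  if (any(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]
  imputed <- logical(nrow(d))
  if (anyNA(d)) {
    if (missing == "fail") stop("missing dosages with policy 'fail'", call. = FALSE)
    imputed <- rowSums(is.na(d)) > 0
    for (j in which(colSums(is.na(d)) > 0)) {
      mu <- mean(d[, j], na.rm = TRUE)
      d[is.na(d[, j]), j] <- mu
    }
  }
  score <- rowSums(d)
  names(score) <- rownames(dosages)
  attr(score, "n_variants") <- length(ids)
  attr(score, "imputed") <- imputed
  score
}

#' Screen candidate confounders against genetic risk scores
#'
#' For every (GRS, candidate) pair, regresses the candidate on the score:
#' logistic for binary candidates, linear with the ordinal treated as
#' numeric otherwise. Pairs with p below the Bonferroni threshold
#' `0.05 / number of tests` are flagged; constant candidates are marked
#' untestable (and do not enter the test count).
#'
#' @param grs A numeric GRS vector, or a named list of them (one per trait).
#' @param cohort A `cohort_table`, row-aligned with the score(s).
#' @param candidates Column names of candidate confounders / sleep traits.
#' @param alpha Family-wise error rate before correction.
#' @return A `screen_report` data frame (`grs`, `candidate`, `model`,
#'   `estimate`, `se`, `p`, `flag`, `untestable`) with attributes
#'   `threshold` and `n_tests`.
#' @export
screen_confounders <- function(grs, cohort, candidates, alpha = 0.05) {
  if (!is.list(grs)) grs <- list(grs = grs)
  absent <- setdiff(candidates, names(cohort))
  if (length(absent))
    stop("candidate column(s) not in cohort: ", paste(absent, collapse = ", "),
         call. = FALSE)
  rows <- list()
  for (gname in names(grs)) {
    g <- grs[[gname]]
    stopifnot(length(g) == nrow(cohort))
    for (cand in candidates) {
      v <- cohort[[cand]]
      ok <- !is.na(v) & !is.na(g)
      vv <- v[ok]; gg <- g[ok]
      binary <- is.logical(v) || length(unique(vv)) == 2
      if (length(unique(vv)) < 2 || stats::var(gg) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          grs = gname, candidate = cand, model = NA_character_,
          estimate = NA_real_, se = NA_real_, p = NA_real_,
          flag = FALSE, untestable = TRUE)
        next
      }
      if (binary) {
        fit <- stats::glm(as.numeric(vv) - min(as.numeric(vv)) > 0 ~ gg,
                          family = stats::binomial())
        co <- summary(fit)$coefficients["gg", ]
        model <- "logistic"
      } else {
        fit <- stats::lm(as.numeric(vv) ~ gg)
        co <- summary(fit)$coefficients["gg", ]
        model <- "linear"
      }
      rows[[length(rows) + 1]] <- data.frame(
        grs = gname, candidate = cand, model = model,
        estimate = co[[1]], se = co[[2]], p = co[[4]],
        flag = FALSE, untestable = FALSE)
    }
  }
  rep_df <- do.call(rbind, rows)
  n_tests <- sum(!rep_df$untestable)
  threshold <- alpha / n_tests
  rep_df$flag <- !rep_df$untestable & rep_df$p < threshold
  structure(rep_df, threshold = threshold, n_tests = n_tests,
            class = c("screen_report", "data.frame"))
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %d tests, Bonferroni threshold %.3g, %d flagged\n",
              attr(x, "n_tests"), attr(x, "threshold"), sum(x$flag)))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Exclude participants with interferential sleep traits
#'
#' Removes participants carrying a sleep trait that the confounder screen
#' flagged as strongly associated with the analysis GRS (for example,
#' excluding anyone with insomnia symptoms before instrumenting short sleep
#' duration). Traits in `rules` that are not flagged in the report trigger a
#' warning and no exclusion.
#'
#' @param cohort A `cohort_table` (the one the report was computed on).
#' @param report A `screen_report`, or a character vector of trait columns
#'   to treat as flagged.
#' @param rules Named list: trait column -> ordinal levels whose carriers
#'   are removed. Default: any insomnia symptoms; evening chronotypes;
#'   short (bins 0-1) or long (bin 4) sleep.
#' @return A `cohort_exclusion` (filtered cohort + ledger).
#' @export
exclude_interferential <- function(cohort, report,
                                   rules = list(insomnia = 1:2,
                                                chronotype = 2:3,
                                                duration_bin = c(0, 1, 4))) {
  flagged <- if (is.character(report)) report else
    unique(report$candidate[report$flag])
  if (!is.character(report)) {
    unknown <- setdiff(names(rules), report$candidate)
    if (length(unknown))
      warning("exclusion rule(s) reference trait(s) the screen did not flag or test: ",
              paste(unknown, collapse = ", "), call. = FALSE)
  }
  ledger <- integer()
  claimed <- rep(FALSE, nrow(cohort))
  for (trait in intersect(names(rules), flagged)) {
    hit <- !is.na(cohort[[trait]]) & cohort[[trait]] %in% rules[[trait]] &
      !claimed
    ledger[trait] <- sum(hit)
    claimed <- claimed | hit
  }
  structure(list(cohort = cohort[!claimed, , drop = FALSE], ledger = ledger,
                 target = NULL),
            class = "cohort_exclusion")
}
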