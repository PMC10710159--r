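# Cohort data model: validated per-participant table of sleep traits,
# covariates and time-to-event outcomes, plus eligibility filters and
# Table-1-style descriptive summaries.

#' Canonical cohort column sets
#'
#' Column names recognised by [as_cohort()]. `required` must be present;
#' `ordinal` columns are small non-negative integers; `covariates` is the
#' full adjustment vocabulary used by the tier definitions.
#' @keywords internal
.cohort_cols <- list(
  required  = c("participant_id", "followup_years"),
  logical   = c("cancer_baseline", "cancer_incident", "death",
                "genotyping_array", "mental_health", "education",
                "ethnicity", "family_history", "operation", "sex"),
  ordinal   = list(chronotype = 0:3, insomnia = 0:2, duration_bin = 0:4,
                   smoking = 0:2, drinking = 0:2, employment_status = 0:2,
                   tpa_group = 0:2, shift_work_frequency = 0:3),
  numeric   = c("sleep_duration_h", "age", "bmi", "townsend_index",
                "veg_fruit_serves", "sedentary_h", "comorbidity_count",
                "n_self_reported_cancers", "n_treatments",
                "cancer_dx_offset_years", "followup_years",
                paste0("pc", 1:10)),
  factor    = "assessment_center",
  character = c("participant_id", "death_cause")
)

#' Standard covariate vocabulary
#'
#' Covariate columns (beyond the sleep traits and outcomes) that the
#' adjustment tiers and missing-covariate exclusions draw from.
#' @return Character vector of column names.
#' @export
cohort_covariates <- function() {
  c("age", "sex", "assessment_center", paste0("pc", 1:10),
    "genotyping_array", "bmi", "employment_status", "townsend_index",
    "smoking", "drinking", "mental_health", "veg_fruit_serves",
    "sedentary_h", "comorbidity_count", "tpa_group", "education",
    "ethnicity", "family_history", "n_self_reported_cancers", "operation",
    "n_treatments", "shift_work_frequency")
}

#' Derive the five-category sleep-duration bin
#'
#' Maps integer hours of habitual sleep to the ordinal bins
#' `<=5 h -> 0`, `6 h -> 1`, `7 h -> 2`, `8 h -> 3`, `>=9 h -> 4`.
#'
#' @param hours Numeric vector of sleep duration in whole hours (NA allowed).
#' @return Integer vector in `0:4` with NA propagated.
#' @examples
#' duration_bin(c(4, 6, 7, 8, 10, NA))
#' @export
duration_bin <- function(hours) {
  out <- rep(NA_integer_, length(hours))
  ok <- !is.na(hours)
  h <- hours[ok]
  out[ok] <- ifelse(h <= 5, 0L, ifelse(h >= 9, 4L, as.integer(round(h)) - 5L))
  out
}

#' Construct and validate a cohort table
#'
#' Coerces a data frame to the canonical cohort layout, derives
#' `duration_bin` from `sleep_duration_h`, and checks the structural
#' invariants: non-negative follow-up, `death_cause == "none"` exactly when
#' `death` is FALSE, and incident cancer only among participants free of
#' cancer at baseline.
#'
#' @param df A data frame with at least `participant_id` and
#'   `followup_years`; outcome flags default to FALSE when absent.
#' @return A `cohort_table` (a data frame).
#' @export
as_cohort <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_req <- setdiff(.cohort_cols$required, names(df))
  if (length(missing_req))
    stop("cohort is missing required column(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  df$participant_id <- as.character(df$participant_id)
  if (anyDuplicated(df$participant_id))
    stop("duplicated participant_id values", call. = FALSE)
  for (col in c("cancer_baseline", "cancer_incident", "death"))
    if (is.null(df[[col]])) df[[col]] <- FALSE else df[[col]] <- as.logical(df[[col]])
  if (is.null(df$death_cause)) df$death_cause <- ifelse(df$death, "cancer", "none")
  df$death_cause <- as.character(df$death_cause)
  if (!all(df$death_cause %in% c("cancer", "noncancer", "none")))
    stop("death_cause must be one of cancer/noncancer/none", call. = FALSE)

  df$followup_years <- as.numeric(df$followup_years)
  if (anyNA(df$followup_years) || any(df$followup_years < 0))
    stop("followup_years must be non-negative and non-missing", call. = FALSE)
  if (any(df$death_cause[!df$death] != "none") ||
      any(df$death_cause[df$death] == "none"))
    stop("death_cause must be 'none' iff death is FALSE", call. = FALSE)
  if (any(df$cancer_incident & df$cancer_baseline, na.rm = TRUE))
    stop("cancer_incident requires cancer_baseline = FALSE", call. = FALSE)

  if (!is.null(df$sleep_duration_h)) {
    df$sleep_duration_h <- as.numeric(df$sleep_duration_h)
    df$duration_bin <- duration_bin(df$sleep_duration_h)
  }
  for (col in names(.cohort_cols$ordinal)) {
    if (is.null(df[[col]])) next
    v <- as.integer(df[[col]])
    rng <- .cohort_cols$ordinal[[col]]
    if (any(!is.na(v) & !(v %in% rng)))
      stop(sprintf("column '%s' outside its ordinal range %d..%d", col,
                   min(rng), max(rng)), call. = FALSE)
    df[[col]] <- v
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d participants, %d columns\n", nrow(x), ncol(x)))
  cat(sprintf("  baseline cancer: %d | incident cancer: %d | deaths: %d\n",
              sum(x$cancer_baseline, na.rm = TRUE),
              sum(x$cancer_incident, na.rm = TRUE),
              sum(x$death, na.rm = TRUE)))
  invisible(x)
}

#' Read a phenotype table into a cohort
#'
#' Reads a tab-separated phenotype file, renames columns through an optional
#' schema map, converts "don't know / prefer not to answer" style sentinels
#' to missing, and validates row by row. Rows whose values cannot be parsed
#' under the declared types are dropped with line-numbered diagnostics
#' (attribute `"row_errors"`, also raised as a warning).
#'
#' @param path Path to a UTF-8 tab-separated file with a header row.
#' @param schema Optional named character vector mapping canonical column
#'   names (names) to the file's column names (values).
#' @param na_strings Sentinels mapped to missing.
#' @return A `cohort_table`; attribute `row_errors` holds a data frame of
#'   rejected input lines (file line number, column, offending value).
#' @export
read_cohort <- function(path, schema = NULL,
                        na_strings = c("NA", "", "Do not know",
                                       "Prefer not to answer",
                                       "Unknown", "Unknown/prefer not to answer")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    absent <- setdiff(unname(schema), names(raw))
    if (length(absent))
      stop("schema refers to column(s) absent from file: ",
           paste(absent, collapse = ", "), call. = FALSE)
    idx <- match(unname(schema), names(raw))
    names(raw)[idx] <- names(schema)
  }
  missing_req <- setdiff(.cohort_cols$required, names(raw))
  if (length(missing_req))
    stop("phenotype file lacks required column(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)

  for (col in names(raw)) raw[[col]][raw[[col]] %in% na_strings] <- NA

  # typed parse with per-cell failure capture; line numbers are 1-based file
  # lines (header = line 1)
  errs <- list()
  parse_num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(v))
    if (length(bad))
      errs[[length(errs) + 1]] <<- data.frame(line = bad + 1L, column = col,
                                              value = raw[[col]][bad])
    v
  }
  parse_logical <- function(col) {
    s <- tolower(raw[[col]])
    v <- rep(NA, nrow(raw))
    v[s %in% c("true", "t", "1", "yes")] <- TRUE
    v[s %in% c("false", "f", "0", "no")] <- FALSE
    bad <- which(!is.na(raw[[col]]) & is.na(v))
    if (length(bad))
      errs[[length(errs) + 1]] <<- data.frame(line = bad + 1L, column = col,
                                              value = raw[[col]][bad])
    v
  }
  out <- data.frame(participant_id = raw$participant_id,
                    stringsAsFactors = FALSE)
  for (col in intersect(c(.cohort_cols$numeric, names(.cohort_cols$ordinal)),
                        names(raw)))
    if (col != "duration_bin") out[[col]] <- parse_num(col)
  for (col in intersect(.cohort_cols$logical, names(raw)))
    out[[col]] <- parse_logical(col)
  for (col in intersect(c(.cohort_cols$factor, "death_cause"), names(raw)))
    out[[col]] <- raw[[col]]

  row_errors <- if (length(errs)) do.call(rbind, errs) else
    data.frame(line = integer(), column = character(), value = character())
  if (nrow(row_errors)) {
    drop <- unique(row_errors$line - 1L)
    warning(sprintf("dropped %d row(s) with unparseable values (see attr 'row_errors'), e.g. line %d column '%s' value '%s'",
                    length(drop), row_errors$line[1], row_errors$column[1],
                    row_errors$value[1]), call. = FALSE)
    out <- out[-drop, , drop = FALSE]
  }
  cohort <- as_cohort(out)
  attr(cohort, "row_errors") <- row_errors
  cohort
}

#' Write a cohort table as TSV
#' @param cohort A `cohort_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Analysis targets
#'
#' The four endpoints of the study design: incident pan-cancer in the
#' cancer-free cohort, and all-cause, 5-year cancer, and cancer-specific
#' mortality in the baseline cancer-patient cohort.
#' @return Character vector of target names.
#' @export
analysis_targets <- function()
  c("incidence", "all_cause_mortality", "five_year_cancer_mortality",
    "cancer_mortality")

#' Apply eligibility filters for an analysis target
#'
#' Filters a cohort down to the analysis sample for a target, applying the
#' exclusion rules in a fixed, logged order: target population (baseline
#' cancer status and, for the 5-year mortality cohort, diagnosis within the
#' 2-year pre-enrollment window plus removal of non-cancer deaths), then
#' missing covariates, shift work, extreme sleep duration (<4 h or >11 h),
#' and minimum age. Each removed row is counted once, under the first rule
#' that matches it.
#'
#' @param cohort A `cohort_table`.
#' @param target One of [analysis_targets()], or `NULL` to skip the
#'   population rule.
#' @param drop_missing_covariates Drop rows with any missing value among
#'   `covariates`.
#' @param covariates Covariate columns whose missingness triggers exclusion;
#'   default: every standard covariate present in the table.
#' @param drop_shift_workers Drop participants reporting current shift work
#'   (`shift_work_frequency > 0`, i.e. sometimes/usually/always).
#' @param drop_extreme_duration Drop sleep durations below 4 h or above 11 h.
#' @param min_age Keep only participants strictly older than this age
#'   (e.g. 50), or `NULL`.
#' @return List of class `cohort_exclusion`: `cohort` (filtered table),
#'   `ledger` (named integer, rule -> rows removed), `target`.
#' @export
apply_exclusions <- function(cohort, target = NULL,
                             drop_missing_covariates = FALSE,
                             covariates = NULL,
                             drop_shift_workers = FALSE,
                             drop_extreme_duration = FALSE,
                             min_age = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!is.null(target)) target <- match.arg(target, analysis_targets())
  if (drop_missing_covariates && is.null(covariates))
    covariates <- intersect(cohort_covariates(), names(cohort))
  if (!is.null(covariates)) {
    absent <- setdiff(covariates, names(cohort))
    if (length(absent))
      stop("exclusion spec requests covariate(s) absent from the cohort: ",
           paste(absent, collapse = ", "), call. = FALSE)
  }
  if (drop_shift_workers && is.null(cohort$shift_work_frequency))
    stop("exclusion spec requests covariate(s) absent from the cohort: shift_work_frequency",
         call. = FALSE)

  claimed <- rep(FALSE, nrow(cohort))
  ledger <- integer()
  claim <- function(hit, rule) {
    hit <- hit & !claimed
    ledger[rule] <<- sum(hit)
    claimed <<- claimed | hit
  }

  if (!is.null(target)) {
    if (target == "incidence") {
      claim(cohort$cancer_baseline, "baseline_cancer")
    } else {
      claim(!cohort$cancer_baseline, "no_baseline_cancer")
      if (target == "five_year_cancer_mortality") {
        off <- cohort$cancer_dx_offset_years
        in_window <- !is.na(off) & off >= -2 & off <= 0
        claim(!in_window, "outside_diagnosis_window")
      }
      if (target %in% c("five_year_cancer_mortality", "cancer_mortality"))
        claim(cohort$death & cohort$death_cause == "noncancer",
              "noncancer_death")
    }
  }
  if (drop_missing_covariates && length(covariates)) {
    miss <- Reduce(`|`, lapply(cohort[covariates], is.na))
    claim(miss, "missing_covariates")
  }
  if (drop_shift_workers)
    claim(!is.na(cohort$shift_work_frequency) & cohort$shift_work_frequency > 0,
          "shift_work")
  if (drop_extreme_duration)
    claim(!is.na(cohort$sleep_duration_h) &
            (cohort$sleep_duration_h < 4 | cohort$sleep_duration_h > 11),
          "extreme_duration")
  if (!is.null(min_age))
    claim(is.na(cohort$age) | cohort$age <= min_age, "age_at_most_min")

  out <- cohort[!claimed, , drop = FALSE]
  attr(out, "row_errors") <- NULL
  structure(list(cohort = out, ledger = ledger, target = target),
            class = "cohort_exclusion")
}

#' @export
print.cohort_exclusion <- function(x, ...) {
  cat(sprintf("<cohort_exclusion> target: %s | %d rows retained\n",
              if (is.null(x$target)) "(none)" else x$target, nrow(x$cohort)))
  if (length(x$ledger))
    for (i in seq_along(x$ledger))
      cat(sprintf("  - %-26s %d removed\n", names(x$ledger)[i], x$ledger[i]))
  else cat("  (no exclusions applied)\n")
  invisible(x)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up in absolute value, the convention of
#' printed baseline-characteristics tables (in contrast to R's banker's
#' rounding).
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Baseline-characteristics summary by group
#'
#' Builds a Table-1-style summary: per-group counts and percentages for each
#' categorical field (missing values shown as their own level so that
#' percentages over all shown levels total 100% of the group) and per-group
#' mean and SD for each continuous field. Percentages use the group size as
#' denominator and are rounded half-up to two decimals.
#'
#' @param cohort A `cohort_table`.
#' @param by Name of a logical or categorical grouping column.
#' @param fields Columns to summarise; default: sleep traits plus every
#'   standard covariate present.
#' @return A `cohort_summary` list: `by`, `n` (group sizes with percentages
#'   of the total), `categorical` (named list of data frames), `continuous`
#'   (data frame of group/field/mean/sd, `undefined` flagged for empty
#'   groups).
#' @export
summarize_cohort <- function(cohort, by, fields = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!by %in% names(cohort)) stop("grouping column not found: ", by, call. = FALSE)
  g <- cohort[[by]]
  if (is.numeric(g) && length(unique(g[!is.na(g)])) > 10)
    stop("grouping field must be boolean or categorical", call. = FALSE)
  if (!is.factor(g)) g <- factor(g)  # factors keep declared (possibly empty) levels
  if (is.null(fields))
    fields <- intersect(c("chronotype", "duration_bin", "insomnia",
                          cohort_covariates()), setdiff(names(cohort), by))

  sizes <- as.integer(table(g))
  n_tab <- data.frame(group = levels(g), n = sizes,
                      pct = round_half_up(100 * sizes / max(nrow(cohort), 1), 2))

  # ordinal codes (small non-negative integers) print as categories;
  # anything else numeric is summarised as mean/SD
  cat_like <- function(v) is.logical(v) || is.factor(v) || is.character(v) ||
    (is.numeric(v) && all(v[!is.na(v)] %in% 0:6))

  categorical <- list(); continuous <- NULL
  for (f in fields) {
    v <- cohort[[f]]
    if (cat_like(v)) {
      lev <- factor(ifelse(is.na(v), "missing", as.character(v)),
                    levels = c(sort(unique(as.character(v[!is.na(v)]))),
                               if (anyNA(v)) "missing"))
      tab <- table(lev, g)
      out <- data.frame(level = rep(rownames(tab), ncol(tab)),
                        group = rep(colnames(tab), each = nrow(tab)),
                        n = as.vector(tab))
      denom <- sizes[match(out$group, levels(g))]
      out$pct <- ifelse(denom > 0, round_half_up(100 * out$n / denom, 2), 0)
      categorical[[f]] <- out
    } else {
      for (lv in levels(g)) {
        vv <- v[!is.na(g) & g == lv]
        row <- data.frame(group = lv, field = f,
                          mean = if (length(vv)) mean(vv, na.rm = TRUE) else NaN,
                          sd = if (length(vv) > 1) stats::sd(vv, na.rm = TRUE) else NaN,
                          undefined = length(vv) == 0 || all(is.na(vv)))
        continuous <- rbind(continuous, row)
      }
    }
  }
  structure(list(by = by, n = n_tab, categorical = categorical,
                 continuous = continuous),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> grouped by '%s'\n", x$by))
  print(x$n, row.names = FALSE)
  for (f in names(x$categorical)) {
    cat(sprintf("\n%s (n, %%):\n", f))
    print(x$categorical[[f]], row.names = FALSE)
  }
  if (!is.null(x$continuous)) {
    cat("\ncontinuous (mean, SD):\n")
    print(x$continuous, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Event indicator and follow-up time for an analysis target
#'
#' Derives the survival outcome pair for a target cohort: incidence uses the
#' first cancer diagnosis as the event with censoring at end of follow-up;
#' the mortality targets use death (all-cause or cancer-specific) with the
#' 5-year target additionally truncating follow-up at 5 years.
#'
#' @param cohort A `cohort_table` already filtered by [apply_exclusions()].
#' @param target One of [analysis_targets()].
#' @return Data frame with columns `time` (years) and `event` (0/1).
#' @export
endpoint_outcome <- function(cohort, target) {
  target <- match.arg(target, analysis_targets())
  n <- nrow(cohort)
  if (target == "incidence") {
    event <- as.integer(cohort$cancer_incident)
    time <- ifelse(event == 1 & !is.na(cohort$cancer_dx_offset_years),
                   cohort$cancer_dx_offset_years, cohort$followup_years)
  } else if (target == "all_cause_mortality") {
    event <- as.integer(cohort$death)
    time <- cohort$followup_years
  } else if (target == "cancer_mortality") {
    event <- as.integer(cohort$death & cohort$death_cause == "cancer")
    time <- cohort$followup_years
  } else { # five_year_cancer_mortality
    ev <- cohort$death & cohort$death_cause == "cancer" &
      cohort$followup_years <= 5
    event <- as.integer(ev)
    time <- pmin(cohort$followup_years, 5)
  }
  if (any(time < 0 | is.na(time))) stop("invalid follow-up times", call. = FALSE)
  data.frame(time = time, event = event)
}
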