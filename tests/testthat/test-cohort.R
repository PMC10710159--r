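test_that("duration bins reproduce the five printed categories", {
  expect_identical(duration_bin(c(3, 4, 5)), c(0L, 0L, 0L))
  expect_identical(duration_bin(6:8), 1:3)
  expect_identical(duration_bin(c(9, 10, 13)), c(4L, 4L, 4L))
  expect_identical(duration_bin(NA), NA_integer_)
  # round-trip: every integer hour lands in the bin its category implies
  h <- 1:16
  b <- duration_bin(h)
  expect_true(all(b[h <= 5] == 0))
  expect_true(all(b[h >= 9] == 4))
  expect_identical(b[h %in% 6:8], h[h %in% 6:8] - 5L)
})

test_that("reading a phenotype file parses, derives bins and maps sentinels", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("participant_id\tsleep_duration_h\tage\tfollowup_years",
               "A\t6\t50\t10.5",
               "B\tPrefer not to answer\t61\t8.2",
               "C\t9\t47\t11"), tsv)
  co <- read_cohort(tsv)
  expect_s3_class(co, "cohort_table")
  expect_equal(nrow(co), 3)
  expect_identical(co$duration_bin, c(1L, NA_integer_, 4L))
  # sentinel maps to missing but the row is retained
  expect_true(is.na(co$sleep_duration_h[co$participant_id == "B"]))
})

test_that("schema errors name the missing column; bad rows are line-diagnosed", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("participant_id\tsleep_duration_h", "A\t7"), tsv)
  expect_error(read_cohort(tsv), "followup_years")

  tsv2 <- tempfile(fileext = ".tsv")
  writeLines(c("participant_id\tbmi\tfollowup_years",
               "A\t25.1\t10", "B\ttwenty\t9", "C\t30\t8"), tsv2)
  expect_warning(co <- read_cohort(tsv2), "line 3")
  expect_equal(nrow(co), 2)
  errs <- attr(co, "row_errors")
  expect_equal(errs$line, 3L)
  expect_equal(errs$column, "bmi")
})

test_that("schema map renames file columns to canonical names", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("id\tfu", "A\t10"), tsv)
  co <- read_cohort(tsv, schema = c(participant_id = "id",
                                    followup_years = "fu"))
  expect_equal(co$followup_years, 10)
  expect_error(read_cohort(tsv, schema = c(participant_id = "nope")),
               "absent")
})

test_that("cohort validation enforces the structural invariants", {
  base <- data.frame(participant_id = "A", followup_years = 1)
  expect_error(as_cohort(transform(base, followup_years = -1)),
               "non-negative")
  expect_error(as_cohort(transform(base, death = FALSE,
                                   death_cause = "cancer")), "iff")
  expect_error(as_cohort(data.frame(participant_id = "A", followup_years = 1,
                                    cancer_baseline = TRUE,
                                    cancer_incident = TRUE)),
               "cancer_baseline")
  expect_error(as_cohort(data.frame(participant_id = c("A", "A"),
                                    followup_years = c(1, 2))), "duplicated")
})

test_that("exclusion rules remove the expected rows in the declared order", {
  co <- toy_cohort(10)
  co$shift_work_frequency[c(1, 2)] <- 2L
  co$sleep_duration_h[3] <- 12
  co$duration_bin <- duration_bin(co$sleep_duration_h)
  co$bmi[4] <- NA
  res <- apply_exclusions(co, drop_missing_covariates = TRUE,
                          covariates = c("age", "sex", "bmi"),
                          drop_shift_workers = TRUE,
                          drop_extreme_duration = TRUE)
  expect_equal(nrow(res$cohort), 6)
  expect_equal(res$ledger[["missing_covariates"]], 1)
  expect_equal(res$ledger[["shift_work"]], 2)
  expect_equal(res$ledger[["extreme_duration"]], 1)
  # conservation: retained + ledger = input
  expect_equal(nrow(res$cohort) + sum(res$ledger), nrow(co))
})

test_that("exclusions with all flags off are the identity", {
  co <- toy_cohort(8)
  res <- apply_exclusions(co)
  expect_equal(nrow(res$cohort), 8)
  expect_length(res$ledger, 0)
})

test_that("incidence target drops baseline cancer; overlaps counted once", {
  co <- toy_cohort(5)
  co$cancer_baseline[1] <- TRUE
  res <- apply_exclusions(co, target = "incidence")
  expect_equal(nrow(res$cohort), 4)
  expect_equal(res$ledger[["baseline_cancer"]], 1)

  # a baseline-cancer row that is also a shift worker is claimed by the
  # first rule only
  co$shift_work_frequency[1] <- 3L
  res2 <- apply_exclusions(co, target = "incidence",
                           drop_shift_workers = TRUE)
  expect_equal(res2$ledger[["baseline_cancer"]], 1)
  expect_equal(res2$ledger[["shift_work"]], 0)
  expect_equal(nrow(res2$cohort) + sum(res2$ledger), nrow(co))
})

test_that("requesting an absent covariate is a configuration error", {
  co <- toy_cohort(5)
  expect_error(apply_exclusions(co, drop_missing_covariates = TRUE,
                                covariates = "townsend_index"),
               "townsend_index")
})

test_that("five-year mortality cohort applies the diagnosis-window rule", {
  df <- data.frame(participant_id = sprintf("M%02d", 1:6),
                   followup_years = c(2, 3, 6, 4, 4, 4),
                   cancer_baseline = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
                   cancer_dx_offset_years = c(-1, -5, -0.5, -1.5, -1, NA),
                   death = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                   death_cause = c("cancer", "cancer", "cancer", "noncancer",
                                   "none", "none"))
  co <- as_cohort(df)
  res <- apply_exclusions(co, target = "five_year_cancer_mortality")
  # row 2 outside the 2-year window, row 4 a noncancer death, row 6 no
  # baseline cancer
  expect_setequal(res$cohort$participant_id, c("M01", "M03", "M05"))
  out <- endpoint_outcome(res$cohort, "five_year_cancer_mortality")
  # cancer death at 6 y is censored at the 5-year horizon
  expect_equal(out$event, c(1L, 0L, 0L))
  expect_equal(out$time, c(2, 5, 4))
})

test_that("cohort summary counts, percentages and group sizes are coherent", {
  co <- toy_cohort(40)
  co$cancer_incident[1:10] <- TRUE
  s <- summarize_cohort(co, by = "cancer_incident",
                        fields = c("insomnia", "age"))
  expect_equal(sum(s$n$n), nrow(co))
  expect_equal(s$n$pct[s$n$group == "TRUE"], 25)
  # categorical percentages sum to 100 within each group
  tab <- s$categorical$insomnia
  for (g in unique(tab$group))
    expect_equal(sum(tab$pct[tab$group == g]), 100, tolerance = 0.02)
  # continuous: mean/SD per group match direct computation
  a <- s$continuous[s$continuous$group == "TRUE", ]
  expect_equal(a$mean, mean(co$age[co$cancer_incident]))
  expect_equal(a$sd, sd(co$age[co$cancer_incident]))
})

test_that("empty groups are flagged, not fabricated", {
  co <- toy_cohort(6)
  co$cancer_incident <- factor(rep("no", 6), levels = c("no", "yes"))
  s <- summarize_cohort(co, by = "cancer_incident", fields = "age")
  expect_equal(s$n$n[s$n$group == "yes"], 0)
  expect_equal(s$n$pct[s$n$group == "yes"], 0)
  expect_true(s$continuous$undefined[s$continuous$group == "yes"])
})

test_that("continuous grouping fields are rejected", {
  co <- toy_cohort(30)
  expect_error(summarize_cohort(co, by = "followup_years"), "categorical")
})

test_that("percentages round half-up to two decimals", {
  expect_equal(round_half_up(13.135, 2), 13.14)
  expect_equal(round_half_up(15.385, 2), 15.39)
  expect_equal(round_half_up(-2.005, 2), -2.01)
})
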