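ins3 <- data.frame(snp_id = c("rs1", "rs2", "rs3"),
                   effect_allele = c("A", "G", "C"),
                   other_allele = c("G", "T", "A"),
                   stringsAsFactors = FALSE)

test_that("harmonization orients, reflects and complements correctly", {
  # identity: file counts the effect allele
  meta_same <- data.frame(snp_id = ins3$snp_id,
                          counted_allele = ins3$effect_allele,
                          other_allele = ins3$other_allele)
  h <- harmonize(ins3, meta_same)
  expect_false(any(h$flip))

  # reflection: file counts the other allele -> dosage 2 becomes 0
  meta_refl <- data.frame(snp_id = ins3$snp_id,
                          counted_allele = ins3$other_allele,
                          other_allele = ins3$effect_allele)
  h2 <- harmonize(ins3, meta_refl)
  expect_true(all(h2$flip))
  dos <- matrix(c(2, 1, 0), 1, 3, dimnames = list(NULL, ins3$snp_id))
  g <- compute_grs(dos, ins3, h2)
  # recount by hand: effect-allele copies are 2 - counted
  expect_equal(as.numeric(g), sum(2 - c(2, 1, 0)))

  # strand complement of the same orientation is not flipped
  meta_comp <- data.frame(snp_id = ins3$snp_id,
                          counted_allele = c("T", "C", "G"),
                          other_allele = c("C", "A", "T"))
  h3 <- harmonize(ins3, meta_comp)
  expect_false(any(h3$flip))
})

test_that("strand-ambiguous variants follow the configured policy", {
  ins <- data.frame(snp_id = c("rs1", "rs2"),
                    effect_allele = c("A", "C"), other_allele = c("T", "A"))
  meta <- data.frame(snp_id = c("rs1", "rs2"),
                     counted_allele = c("A", "C"), other_allele = c("T", "A"))
  h <- harmonize(ins, meta)  # default: drop
  expect_identical(h$dropped, "rs1")
  expect_named(h$flip, "rs2")
  h2 <- harmonize(ins, meta, ambiguous_policy = "assume_forward")
  expect_length(h2$dropped, 0)
  expect_false(h2$flip[["rs1"]])
})

test_that("harmonization errors on absent or incompatible variants", {
  meta <- data.frame(snp_id = c("rs1", "rs2"),
                     counted_allele = c("A", "G"), other_allele = c("G", "T"))
  expect_error(harmonize(ins3, meta), "rs3")
  meta_bad <- data.frame(snp_id = ins3$snp_id,
                         counted_allele = c("A", "G", "G"),
                         other_allele = c("G", "T", "C"))
  expect_error(harmonize(ins3, meta_bad), "incompatible.*rs3")
})

test_that("unweighted GRS equals a brute-force allele recount", {
  dos <- matrix(c(2, 1, 0), 1, 3, dimnames = list(NULL, ins3$snp_id))
  expect_equal(as.numeric(compute_grs(dos, ins3)), 3)
  zero <- matrix(0, 4, 3, dimnames = list(NULL, ins3$snp_id))
  expect_equal(as.numeric(compute_grs(zero, ins3)), rep(0, 4))

  set.seed(31)
  ins4 <- data.frame(snp_id = paste0("v", 1:4),
                     effect_allele = rep("A", 4), other_allele = rep("G", 4))
  d <- matrix(sample(0:2, 20, TRUE), 5, 4,
              dimnames = list(NULL, ins4$snp_id))
  g <- compute_grs(d, ins4)
  # exhaustive recount, one participant and variant at a time
  oracle <- sapply(1:5, function(i) {
    tot <- 0
    for (j in 1:4) tot <- tot + d[i, j]
    tot
  })
  expect_equal(as.numeric(g), as.numeric(oracle))
})

test_that("GRS is invariant to variant order and file orientation", {
  set.seed(12)
  m <- 6
  ins <- data.frame(snp_id = paste0("v", 1:m),
                    effect_allele = c("A", "G", "C", "T", "A", "G"),
                    other_allele = c("G", "T", "A", "G", "C", "T"))
  d <- matrix(sample(0:2, 40 * m, TRUE), 40, m,
              dimnames = list(NULL, ins$snp_id))
  meta <- data.frame(snp_id = ins$snp_id, counted_allele = ins$effect_allele,
                     other_allele = ins$other_allele)
  g0 <- compute_grs(d, ins, harmonize(ins, meta))

  # permute variant order in the instrument table
  perm <- sample(m)
  g1 <- compute_grs(d, ins[perm, ], harmonize(ins[perm, ], meta))
  expect_equal(g1, g0, ignore_attr = TRUE)

  # reflect a subset of file columns (swap counted/other + reflect dosage)
  flip_cols <- c(2, 5)
  d2 <- d; d2[, flip_cols] <- 2 - d2[, flip_cols]
  meta2 <- meta
  meta2$counted_allele[flip_cols] <- ins$other_allele[flip_cols]
  meta2$other_allele[flip_cols] <- ins$effect_allele[flip_cols]
  g2 <- compute_grs(d2, ins, harmonize(ins, meta2))
  expect_equal(g2, g0, ignore_attr = TRUE)
})

test_that("missing dosages follow the declared policy", {
  ins <- ins3
  d <- matrix(c(2, 1, 0,
                NA, 1, 1,
                0, 0, 2), 3, 3, byrow = TRUE,
              dimnames = list(NULL, ins$snp_id))
  expect_error(compute_grs(d, ins, missing = "fail"), "missing")
  g <- compute_grs(d, ins)  # mean imputation
  expect_equal(attr(g, "imputed"), c(FALSE, TRUE, FALSE))
  expect_equal(unname(g[2]), mean(c(2, 0)) + 1 + 1)
})

test_that("confounder screen applies the exact Bonferroni threshold", {
  set.seed(8)
  n <- 400
  co <- toy_cohort(n)
  cand <- c("age", "bmi", "insomnia", "chronotype", "sex",
            "sleep_duration_h")
  grs4 <- setNames(lapply(1:4, function(i) rnorm(n)), paste0("g", 1:4))
  rep_ <- screen_confounders(grs4, co, cand)
  expect_equal(attr(rep_, "n_tests"), 24)
  expect_equal(attr(rep_, "threshold"), 0.05 / 24)
  expect_equal(signif(attr(rep_, "threshold"), 3), 2.08e-03)
})

test_that("screen flags a real association and skips constants", {
  set.seed(9)
  n <- 20000
  g <- rnorm(n)
  co <- as_cohort(data.frame(participant_id = as.character(1:n),
                             followup_years = 1,
                             bmi = 0.2 * g + rnorm(n),
                             sedentary_h = 3))
  rep_ <- screen_confounders(g, co, c("bmi", "sedentary_h"))
  expect_true(rep_$flag[rep_$candidate == "bmi"])
  expect_true(rep_$untestable[rep_$candidate == "sedentary_h"])
  expect_equal(attr(rep_, "n_tests"), 1)  # untestable pairs don't count
})

test_that("interferential-trait exclusion removes flagged carriers only", {
  co <- toy_cohort(10)
  co$insomnia <- c(1, 2, 1, 2, 0, 0, 0, 0, 0, 0)
  res <- exclude_interferential(co, "insomnia")
  expect_equal(nrow(res$cohort), 6)
  expect_equal(res$ledger[["insomnia"]], 4)

  # empty flag set: identity
  res2 <- exclude_interferential(co, character(0))
  expect_equal(nrow(res2$cohort), 10)

  # flagged chronotype but no evening types present: ledger records zero
  co$chronotype <- rep(0L, 10)
  res3 <- exclude_interferential(co, "chronotype")
  expect_equal(nrow(res3$cohort), 10)
  expect_equal(res3$ledger[["chronotype"]], 0)
})

test_that("rules referencing unscreened traits warn, not error", {
  co <- toy_cohort(10)
  g <- rnorm(10)
  rep_ <- screen_confounders(g, co, "bmi")
  expect_warning(exclude_interferential(co, rep_,
                                        rules = list(insomnia = 1:2)),
                 "insomnia")
})

test_that("screen p-values are null-calibrated under independence", {
  set.seed(101)
  n <- 250
  ps <- replicate(400, {
    g <- rnorm(n)
    co <- suppressWarnings(as_cohort(
      data.frame(participant_id = as.character(1:n), followup_years = 1,
                 bmi = rnorm(n))))
    screen_confounders(g, co, "bmi")$p
  })
  rate <- mean(ps < 0.05)
  expect_gt(rate, 0.025)
  expect_lt(rate, 0.085)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
})
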