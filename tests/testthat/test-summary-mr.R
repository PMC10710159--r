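assoc_from <- function(theta, se, bx = NULL) {
  m <- length(theta)
  if (is.null(bx)) bx <- rep(1, m)
  variant_assoc(data.frame(snp_id = paste0("v", seq_len(m)),
                           beta_gx = bx, se_gx = 1e-6,
                           beta_gy = theta * bx, se_gy = se * bx))
}

test_that("IVW matches the hand-computed weighted mean and SE", {
  a <- assoc_from(c(0.2, 0.4), c(0.1, 0.2))
  est <- mr_ivw(a)
  # by hand: w = (100, 25); sum(w*theta)/sum(w) = (20+10)/125 = 0.24
  expect_equal(est$estimate, 0.24, tolerance = 1e-10)
  expect_equal(est$se, 1 / sqrt(125), tolerance = 1e-10)
  expect_equal(round(est$se, 4), 0.0894)
})

test_that("IVW degenerate cases: constancy, single variant, equal weights", {
  a <- assoc_from(rep(0.3, 4), c(0.05, 0.1, 0.2, 0.4))
  expect_equal(mr_ivw(a)$estimate, 0.3, tolerance = 1e-12)

  one <- assoc_from(0.5, 0.1)[1, ]
  est1 <- mr_ivw(one)
  expect_equal(est1$estimate, 0.5)
  expect_equal(est1$note, "single-variant")

  th <- c(0.1, 0.25, 0.4, 0.55)
  aeq <- assoc_from(th, rep(0.1, 4))
  expect_equal(mr_ivw(aeq)$estimate, mean(th), tolerance = 1e-12)
})

test_that("orientation is normalized to non-negative exposure effects", {
  a <- variant_assoc(data.frame(snp_id = c("v1", "v2"),
                                beta_gx = c(-0.1, 0.2), se_gx = 0.01,
                                beta_gy = c(-0.05, 0.08), se_gy = 0.02))
  expect_equal(a$beta_gx, c(0.1, 0.2))
  expect_equal(a$beta_gy, c(0.05, 0.08))
  expect_identical(a$flipped, c(TRUE, FALSE))
})

test_that("MR-Egger recovers an exact line and reduces to IVW at zero intercept", {
  a <- variant_assoc(data.frame(snp_id = paste0("v", 1:3),
                                beta_gx = c(1, 2, 3), se_gx = 1e-6,
                                beta_gy = c(0.8, 1.3, 1.8), se_gy = 0.1))
  e <- suppressWarnings(mr_egger(a))
  expect_equal(e$intercept$estimate, 0.3, tolerance = 1e-10)
  expect_equal(e$slope$estimate, 0.5, tolerance = 1e-10)

  # exact proportionality: intercept 0, slope = IVW estimate
  b <- variant_assoc(data.frame(snp_id = paste0("v", 1:3),
                                beta_gx = c(1, 2, 3), se_gx = 1e-6,
                                beta_gy = 0.4 * c(1, 2, 3), se_gy = 0.1))
  eb <- suppressWarnings(mr_egger(b))
  expect_equal(eb$intercept$estimate, 0, tolerance = 1e-10)
  expect_equal(eb$slope$estimate, mr_ivw(b)$estimate, tolerance = 1e-10)

  expect_error(mr_egger(a[1:2, ]), ">= 3")
})

test_that("weighted median interpolates cumulative weight exactly", {
  a <- assoc_from(c(0.1, 0.2, 0.3), rep(0.1, 3))
  wm <- mr_weighted_median(a, bootstrap_reps = 200, seed = 2)
  expect_equal(wm$estimate, 0.2, tolerance = 1e-12)

  # unequal weights (1, 1, 2): check against the step-by-step oracle
  theta <- c(0.1, 0.2, 0.3)
  w <- c(1, 1, 2)
  se_target <- 1 / sqrt(w)          # se(theta) giving weights (1,1,2)
  au <- assoc_from(theta, se_target)
  expect_equal(au$w, w, tolerance = 1e-9)
  wm2 <- mr_weighted_median(au, bootstrap_reps = 200, seed = 3)
  expect_equal(wm2$estimate, weighted_median_by_hand(theta, w),
               tolerance = 1e-10)
  expect_equal(wm2$estimate, 0.2 + 0.1 * (0.5 - 0.375) / (0.75 - 0.375),
               tolerance = 1e-10)

  expect_warning(mr_weighted_median(a, bootstrap_reps = 50, seed = 1),
                 "100")
})

test_that("radial Q decomposes additively and flags a planted outlier", {
  set.seed(91)
  a <- assoc_from(rnorm(12, 0.2, 0.02), runif(12, 0.05, 0.2))
  r <- mr_radial(a)
  expect_equal(sum(r$q_j), r$q, tolerance = 1e-12)
  expect_equal(r$df, 11)

  # all identical ratios: zero heterogeneity, no outliers
  r0 <- mr_radial(assoc_from(rep(0.2, 8), rep(0.1, 8)))
  expect_equal(r0$q, 0, tolerance = 1e-12)
  expect_length(r0$outliers, 0)

  # one variant shifted by 10 SE: flagged, and removal shrinks Q
  b <- assoc_from(rep(0.2, 21), rep(0.05, 21))
  b$beta_gy[7] <- b$beta_gy[7] + 10 * b$se_gy[7]
  b <- variant_assoc(b[, c("snp_id", "beta_gx", "se_gx", "beta_gy", "se_gy")])
  rb <- mr_radial(b)
  expect_identical(rb$outliers, "v7")
  after <- mr_radial(b[b$snp_id != "v7", ])
  expect_lt(after$q, rb$q)
})

test_that("leave-one-out reproduces the reduced-set IVW exactly", {
  a <- assoc_from(c(0.1, 0.2, 0.6), c(0.02, 0.2, 0.3))  # v1 dominates
  loo <- mr_leave_one_out(a)
  expect_equal(nrow(loo), 3)
  # omitting the dominant variant leaves the 2-variant IVW, by hand:
  w <- (c(0.2, 0.3) / 1)^-2
  th <- c(0.2, 0.6)
  expect_equal(loo$estimate[loo$left_out == "v1"],
               sum(w * th) / sum(w), tolerance = 1e-12)
  expect_true(loo$flag[loo$left_out == "v1"])
})

test_that("estimators are invariant to variant ordering", {
  set.seed(93)
  a <- assoc_from(rnorm(9, 0.25, 0.05), runif(9, 0.05, 0.3),
                  bx = runif(9, 0.5, 1.5))
  perm <- sample(9)
  b <- variant_assoc(as.data.frame(a)[perm, c("snp_id", "beta_gx", "se_gx",
                                              "beta_gy", "se_gy")])
  expect_equal(mr_ivw(b)$estimate, mr_ivw(a)$estimate, tolerance = 1e-12)
  expect_equal(suppressWarnings(mr_egger(b))$slope$estimate,
               suppressWarnings(mr_egger(a))$slope$estimate,
               tolerance = 1e-10)
  expect_equal(mr_weighted_median(b, 150, seed = 4)$estimate,
               mr_weighted_median(a, 150, seed = 4)$estimate,
               tolerance = 1e-12)
})

test_that("IVW agrees with an independent fixed-effect meta-analysis", {
  skip_if_not_installed("metafor")
  set.seed(94)
  a <- assoc_from(rnorm(15, 0.2, 0.07), runif(15, 0.05, 0.25))
  fe <- metafor::rma(yi = a$theta, sei = a$se_theta, method = "FE")
  est <- mr_ivw(a)
  expect_equal(est$estimate, as.numeric(fe$beta), tolerance = 1e-8)
  expect_equal(est$se, fe$se, tolerance = 1e-8)
})

test_that("individual-level derivation recovers planted variant effects", {
  set.seed(95)
  n <- 4000
  m <- 6
  freq <- runif(m, 0.2, 0.8)
  dos <- simulate_genotypes(n, freq)
  colnames(dos) <- paste0("s", 1:m)
  eff <- c(0.3, 0.25, 0.2, 0.15, 0.1, 0)   # last variant inert
  x <- drop(dos %*% eff) + rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.3 * x))
  co <- as_cohort(data.frame(participant_id = as.character(1:n),
                             followup_years = 1, hours = x))
  ins <- data.frame(snp_id = colnames(dos), effect_allele = "A",
                    other_allele = "G")
  a <- derive_variant_assocs(co, dos, ins, "hours", y)
  expect_equal(nrow(a), m)
  expect_equal(a$beta_gx, eff, tolerance = 0.12)
  expect_true(a$near_null[m])       # the inert variant is flagged
  expect_false(any(a$near_null[1:3]))

  # a monomorphic variant is dropped with a log entry
  dos2 <- cbind(dos, mono = 0L)
  ins2 <- rbind(ins, data.frame(snp_id = "mono", effect_allele = "A",
                                other_allele = "G"))
  a2 <- derive_variant_assocs(co, dos2, ins2, "hours", y)
  expect_equal(nrow(a2), m)
  expect_identical(attr(a2, "dropped"), "mono")
})

test_that("the bundled sensitivity suite is internally consistent", {
  a <- simulate_variant_assocs(25, theta = 0.2, seed = 8)
  suite <- suppressWarnings(mr_sensitivity(a, bootstrap_reps = 150, seed = 9))
  expect_equal(nrow(suite$loo), 25)
  expect_equal(suite$radial$ivw$estimate, suite$ivw$estimate)
  expect_lt(abs(suite$ivw$estimate - 0.2), 0.05)
  expect_lt(abs(suite$weighted_median$estimate - 0.2), 0.07)
})
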