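tiny_sets <- c(chronotype = 3, short_sleep = 3, long_sleep = 2,
               duration = 8, insomnia = 4)

# minimal continuous-outcome cohort with a single-variant instrument
single_variant_data <- function(n = 500, seed = 77) {
  set.seed(seed)
  g <- rbinom(n, 2, 0.4)
  x <- 0.4 * g + rnorm(n)
  y <- 0.25 * x + rnorm(n)
  co <- as_cohort(data.frame(participant_id = as.character(1:n),
                             followup_years = 1, exposure_x = x))
  list(cohort = co, g = g, y = y, x = x)
}

test_that("two-stage estimate equals the Wald ratio for one instrument", {
  d <- single_variant_data()
  fit <- suppressWarnings(two_stage_mr(d$cohort, d$g, "exposure_x", d$y,
                                       covariates = character(0)))
  bgx <- coef(lm(d$x ~ d$g))[[2]]
  bgy <- coef(lm(d$y ~ d$g))[[2]]
  expect_equal(fit$estimate, bgy / bgx, tolerance = 1e-10)
})

test_that("two-stage estimate is invariant to affine GRS recoding", {
  d <- single_variant_data(seed = 78)
  f0 <- suppressWarnings(two_stage_mr(d$cohort, d$g, "exposure_x", d$y,
                                      covariates = character(0)))
  f1 <- suppressWarnings(two_stage_mr(d$cohort, 5.5 * d$g - 3, "exposure_x",
                                      d$y, covariates = character(0)))
  expect_equal(f1$estimate, f0$estimate, tolerance = 1e-8)
  expect_equal(f1$se, f0$se, tolerance = 1e-8)
})

test_that("a constant GRS is rejected as uninformative", {
  d <- single_variant_data()
  expect_error(two_stage_mr(d$cohort, rep(2, nrow(d$cohort)), "exposure_x",
                            d$y, covariates = character(0)),
               "uninformative")
})

test_that("two-stage MR removes confounding bias that the naive fit keeps", {
  # strong confounding, zero causal effect
  cfg <- sim_config(n = 50000, n_variants = tiny_sets,
                    first_stage_r2 = c(chronotype = 0.05, duration = 0.2,
                                       insomnia = 0.05),
                    confounder_sd = c(chronotype = 0.25, duration = 0.5,
                                      insomnia = 0.25),
                    incidence_model = list(confounder = 0.8),
                    baseline_cancer_prob = 0)
  sim <- simulate_cohort(cfg, seed = 19)
  co <- sim$cohort
  g <- compute_grs(sim$dosages,
                   sim$instruments[sim$instruments$trait == "duration", ])
  naive <- glm(cancer_incident ~ sleep_duration_h + age + sex, data = co,
               family = binomial())
  z_naive <- summary(naive)$coefficients["sleep_duration_h", 3]
  fit <- suppressWarnings(two_stage_mr(co, g, "sleep_duration_h",
                                       "incidence"))
  z_mr <- fit$estimate / fit$se
  expect_gt(abs(z_naive), 6)   # naive estimate strongly biased away from 0
  expect_lt(abs(z_mr), 3)      # genetic estimate consistent with the null
})

test_that("naive and two-stage estimates agree without confounding", {
  cfg <- sim_config(n = 40000, n_variants = tiny_sets,
                    first_stage_r2 = c(chronotype = 0.05, duration = 0.25,
                                       insomnia = 0.05),
                    confounder_sd = c(chronotype = 0.2, duration = 0,
                                      insomnia = 0.2),
                    incidence_model = list(beta = 0.15, confounder = 0,
                                           target = 0.1),
                    covariate_outcome_sd = 0, baseline_cancer_prob = 0)
  sim <- simulate_cohort(cfg, seed = 23)
  g <- compute_grs(sim$dosages,
                   sim$instruments[sim$instruments$trait == "duration", ])
  fit <- suppressWarnings(two_stage_mr(sim$cohort, g, "sleep_duration_h",
                                       "incidence",
                                       covariates = character(0)))
  naive <- glm(cancer_incident ~ sleep_duration_h, data = sim$cohort,
               family = binomial())
  b_naive <- coef(naive)[["sleep_duration_h"]]
  se_naive <- summary(naive)$coefficients["sleep_duration_h", 2]
  expect_lt(abs(fit$estimate - b_naive),
            3 * sqrt(fit$se^2 + se_naive^2))
})

test_that("second-stage precision scales as sqrt(n)", {
  ses <- vapply(c(10000, 40000), function(n) {
    cfg <- sim_config(n = n, n_variants = tiny_sets,
                      first_stage_r2 = c(chronotype = 0.05, duration = 0.2,
                                         insomnia = 0.05),
                      baseline_cancer_prob = 0)
    sim <- simulate_cohort(cfg, seed = 37)
    g <- compute_grs(sim$dosages,
                     sim$instruments[sim$instruments$trait == "duration", ])
    suppressWarnings(two_stage_mr(sim$cohort, g, "sleep_duration_h",
                                  "incidence"))$se
  }, 0)
  expect_equal(ses[1] / ses[2], 2, tolerance = 0.25)
})

test_that("bootstrap standard errors are seeded and comparable", {
  d <- single_variant_data(n = 400, seed = 81)
  f1 <- suppressWarnings(two_stage_mr(d$cohort, d$g, "exposure_x", d$y,
                                      covariates = character(0),
                                      bootstrap = 120, seed = 5))
  f2 <- suppressWarnings(two_stage_mr(d$cohort, d$g, "exposure_x", d$y,
                                      covariates = character(0),
                                      bootstrap = 120, seed = 5))
  expect_identical(f1$se, f2$se)
  expect_gt(f1$se, 0)
  expect_error(two_stage_mr(d$cohort, d$g, "exposure_x", d$y,
                            covariates = character(0), bootstrap = 10),
               "seed")
})

test_that("the MR grid sizes its Bonferroni family and labels correctly", {
  cfg <- sim_config(n = 4000, n_variants = tiny_sets)
  sim <- simulate_cohort(cfg, seed = 41)
  traits <- unique(sim$instruments$trait)
  grs_list <- lapply(setNames(traits, traits), function(tr)
    compute_grs(sim$dosages, sim$instruments[sim$instruments$trait == tr, ]))
  grid <- suppressWarnings(run_mr_grid(sim$cohort, grs_list,
                                       targets = analysis_targets()))
  expect_equal(nrow(grid), 20)
  expect_equal(attr(grid, "threshold"), 0.05 / 20)
  ok <- !is.na(grid$p)
  expect_true(any(ok))
  lab_expected <- ifelse(grid$p[ok] < 0.05 / 20, "strong",
                         ifelse(grid$p[ok] < 0.05, "suggestive", "null"))
  expect_identical(grid$label[ok], lab_expected)
  # cell failures (e.g. too few events at the 5-year endpoint) are recorded
  expect_true(all(is.na(grid$or) == !is.na(grid$error) | ok))
})
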