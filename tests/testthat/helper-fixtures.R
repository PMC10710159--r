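# Shared fixtures: tiny hand-checkable cohorts and independent oracles.

# minimal mortality cohort from explicit time/event vectors (all baseline
# cancer patients, so the all-cause endpoint keeps every row)
toy_mortality_cohort <- function(time, event, ...) {
  n <- length(time)
  extra <- list(...)
  df <- data.frame(participant_id = sprintf("P%03d", seq_len(n)),
                   followup_years = time,
                   death = as.logical(event),
                   death_cause = ifelse(event == 1, "cancer", "none"),
                   cancer_baseline = TRUE, cancer_incident = FALSE,
                   stringsAsFactors = FALSE)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  as_cohort(df)
}

# independent Efron partial log-likelihood for a single covariate
efron_loglik <- function(beta, time, status, x) {
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    d <- length(D)
    rs <- sum(exp(beta * x[R]))
    ds <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D]) -
      sum(log(rs - (seq_len(d) - 1) / d * ds))
  }
  ll
}

# independent two-group log-rank statistic: observed vs hypergeometric
# expected events at each distinct event time
logrank_by_hand <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(max(g) == 2)
  OmE <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n1 <- sum(at_risk & g == 1); n <- sum(at_risk)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    OmE <- OmE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  OmE^2 / V
}

# independent cumulative-weight interpolation for the weighted median,
# written step by step from the definition
weighted_median_by_hand <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]; w <- w[o]
  S <- sum(w)
  p <- numeric(length(w))
  acc <- 0
  for (j in seq_along(w)) {
    p[j] <- (acc + w[j] / 2) / S
    acc <- acc + w[j]
  }
  if (p[1] >= 0.5) return(theta[1])
  j <- max(which(p < 0.5))
  theta[j] + (theta[j + 1] - theta[j]) * (0.5 - p[j]) / (p[j + 1] - p[j])
}

# small fully-populated cohort for exclusion/summary tests
toy_cohort <- function(n = 10, seed = 42) {
  set.seed(seed)
  as_cohort(data.frame(
    participant_id = sprintf("T%03d", seq_len(n)),
    age = round(runif(n, 40, 70)),
    sex = runif(n) < 0.5,
    bmi = round(rnorm(n, 27, 4), 1),
    sleep_duration_h = sample(4:10, n, replace = TRUE),
    chronotype = sample(0:3, n, replace = TRUE),
    insomnia = sample(0:2, n, replace = TRUE),
    shift_work_frequency = 0L,
    cancer_baseline = FALSE, cancer_incident = FALSE,
    followup_years = round(runif(n, 5, 11), 2),
    death = FALSE, death_cause = "none",
    stringsAsFactors = FALSE))
}
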