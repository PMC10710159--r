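# The universal result record shared by every estimator: estimate, Wald
# standard error, normal-theory CI and p-value, scale tag and sample sizes.

#' Construct an effect-estimate record
#'
#' @param term Term label(s).
#' @param estimate Point estimate(s) on the stated scale (log for ratio
#'   scales).
#' @param se Standard error(s); `NA` marks an undefined estimate.
#' @param scale One of `"log-HR"`, `"log-OR"`, `"linear"`.
#' @param n Analysis sample size.
#' @param n_events Number of events (NA where not applicable).
#' @param level Confidence level (default 0.95).
#' @param p Optional p-values; computed from the Wald statistic when `NULL`.
#' @return Data frame of class `effect_estimate` with columns `term`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `p`, `scale`, `n`, `n_events`.
#' @export
effect_estimate <- function(term, estimate, se, scale = c("linear", "log-OR",
                                                          "log-HR"),
                            n = NA_integer_, n_events = NA_integer_,
                            level = 0.95, p = NULL) {
  scale <- match.arg(scale)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(estimate / se))
  data.frame(term = term, estimate = estimate, se = se,
             ci_low = estimate - z * se, ci_high = estimate + z * se,
             p = p, scale = scale, n = n, n_events = n_events,
             stringsAsFactors = FALSE)
}

# format an effect_estimate row as "RR (lo-hi), p" exponentiating ratio scales
.fmt_effect <- function(e) {
  ratio <- e$scale %in% c("log-OR", "log-HR")
  f <- function(v) if (ratio) exp(v) else v
  lab <- if (e$scale == "log-HR") "HR" else if (e$scale == "log-OR") "OR" else "beta"
  sprintf("%s %.3f (95%% CI %.3f-%.3f), p = %.3g", lab, f(e$estimate),
          f(e$ci_low), f(e$ci_high), e$p)
}
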