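#' Convert a cumulative probability to a constant event rate
#'
#' Converts a probability of an event occurring over a given time horizon into
#' the constant instantaneous rate (per month) that would produce it, using the
#' standard actuarial relation \eqn{r = -\ln(1 - p) / t}. This is the inverse
#' of [rate_to_prob()], and the pair is how the model rescales annual and
#' six-month probabilities to the quarterly Markov cycle length.
#'
#' @param p probability in `[0, 1)` of the event over `horizon` months.
#' @param horizon time horizon in months over which `p` applies.
#' @return Event rate per month (vectorised over `p`).
#' @examples
#' prob_to_rate(0.088, 12)            # annual incidence as a monthly rate
#' rate_to_prob(prob_to_rate(0.088, 12), 3)  # quarterly probability
#' @seealso [rate_to_prob()]
#' @export
prob_to_rate <- function(p, horizon = 1) {
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    stop("'horizon' must be a single positive number of months")
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1))
    stop("'p' must lie in [0, 1): p = 1 implies an infinite rate and cannot be converted")
  -log(1 - p) / horizon
}

#' Convert a constant event rate to a cumulative probability
#'
#' @param r event rate per month, `r >= 0`.
#' @param horizon time horizon in months.
#' @return Probability of the event occurring within `horizon` months,
#'   \eqn{1 - e^{-r t}}.
#' @examples
#' rate_to_prob(0.007677, 3)
#' @seealso [prob_to_rate()]
#' @export
rate_to_prob <- function(r, horizon = 1) {
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    stop("'horizon' must be a single positive number of months")
  if (any(!is.finite(r)) || any(r < 0)) stop("'r' must be a non-negative rate")
  1 - exp(-r * horizon)
}

#' Rescale a probability to a different time horizon
#'
#' Convenience wrapper: converts a probability over `from` months to the
#' equivalent probability over `to` months under a constant-rate assumption.
#'
#' @param p probability in `[0, 1)`.
#' @param from,to horizons in months.
#' @return Probability over `to` months.
#' @export
rescale_probability <- function(p, from, to) {
  rate_to_prob(prob_to_rate(p, from), to)
}

#' Apply an odds ratio to a baseline risk
#'
#' Converts a baseline probability to odds, multiplies by the odds ratio, and
#' converts back: \eqn{p_1 = \mathrm{OR}\,\omega / (1 + \mathrm{OR}\,\omega)}
#' with \eqn{\omega = p_0 / (1 - p_0)}. This is the textbook odds-scale route
#' for translating a treatment-effect OR into an absolute risk.
#'
#' @param p0 baseline probability in `[0, 1)`.
#' @param or odds ratio, `or >= 0`.
#' @return Treated probability in `[0, 1)`. `apply_odds_ratio(p, 1)` is the
#'   identity; the result is strictly increasing in both arguments.
#' @examples
#' apply_odds_ratio(0.196, 0.66)
#' @export
apply_odds_ratio <- function(p0, or) {
  if (any(!is.finite(p0)) || any(p0 < 0) || any(p0 >= 1))
    stop("'p0' must lie in [0, 1)")
  if (any(!is.finite(or)) || any(or < 0)) stop("'or' must be non-negative")
  omega <- or * p0 / (1 - p0)
  omega / (1 + omega)
}

#' Odds ratio and its log-scale standard error from a 2x2 table
#'
#' Computes the odds ratio of the event under treatment versus control from
#' event counts and group sizes, with the Woolf standard error of the log OR.
#' Tables containing a zero cell receive the Haldane–Anscombe continuity
#' correction (0.5 added to every cell), flagged in the result.
#'
#' @param events_treat,n_treat events and total in the treated group.
#' @param events_control,n_control events and total in the control group.
#' @return A list with elements `or`, `se_log_or`, `ci_low`, `ci_high`
#'   (Wald 95% CI) and `corrected` (logical, continuity correction applied).
#' @examples
#' odds_ratio_from_counts(10, 100, 20, 100)
#' @export
odds_ratio_from_counts <- function(events_treat, n_treat, events_control, n_control) {
  counts <- c(events_treat, n_treat, events_control, n_control)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be non-negative")
  if (n_treat < 1 || n_control < 1) stop("group sizes must be at least 1")
  if (events_treat > n_treat || events_control > n_control)
    stop("events cannot exceed the group size")

  a <- events_treat
  b <- n_treat - events_treat
  c <- events_control
  d <- n_control - events_control
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    if (a + b == 0 || c + d == 0) stop("empty margin: a group has size zero after correction")
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(
    or = or,
    se_log_or = se,
    ci_low = exp(log(or) - 1.96 * se),
    ci_high = exp(log(or) + 1.96 * se),
    corrected = corrected
  )
}

#' Method-of-moments beta distribution parameters
#'
#' @param mean mean in `(0, 1)`.
#' @param se standard error; must satisfy `se^2 < mean * (1 - mean)`.
#' @param name parameter name used in error messages.
#' @return List with `shape1` (alpha) and `shape2` (beta).
#' @examples
#' beta_from_mean_se(0.088, 0.0084)
#' @export
beta_from_mean_se <- function(mean, se, name = "parameter") {
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop(sprintf("%s: beta distribution requires mean in (0, 1), got %g", name, mean))
  if (!is.finite(se) || se <= 0)
    stop(sprintf("%s: beta distribution requires a positive standard error", name))
  v <- se^2
  if (v >= mean * (1 - mean))
    stop(sprintf(
      "%s: infeasible beta moments (se^2 = %g >= mean*(1-mean) = %g)",
      name, v, mean * (1 - mean)
    ))
  nu <- mean * (1 - mean) / v - 1
  list(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Method-of-moments gamma distribution parameters
#'
#' @param mean,se positive mean and standard error.
#' @param name parameter name used in error messages.
#' @return List with `shape` and `scale` (`shape = mean^2/se^2`,
#'   `scale = se^2/mean`).
#' @examples
#' gamma_from_mean_se(100, 50)  # shape 4, scale 25
#' @export
gamma_from_mean_se <- function(mean, se, name = "parameter") {
  if (!is.finite(mean) || mean <= 0)
    stop(sprintf("%s: gamma distribution requires mean > 0", name))
  if (!is.finite(se) || se <= 0)
    stop(sprintf("%s: gamma distribution requires se > 0", name))
  list(shape = mean^2 / se^2, scale = se^2 / mean)
}

#' Log-normal parameters for an odds ratio from its 95% confidence interval
#'
#' Sets the log-scale location to `log(or)` and derives the log-scale standard
#' deviation from the width of the 95% CI:
#' \eqn{\sigma = (\ln u - \ln l) / (2 \times 1.96)}.
#'
#' @param or point estimate of the odds ratio.
#' @param ci_low,ci_high 95% confidence bounds, `0 < ci_low < or < ci_high`.
#' @param name parameter name used in error messages.
#' @return List with `meanlog` and `sdlog` for [stats::rlnorm()].
#' @examples
#' lognormal_from_or_ci(0.6, 0.3, 1.2)  # sdlog = log(4)/3.92
#' @export
lognormal_from_or_ci <- function(or, ci_low, ci_high, name = "parameter") {
  if (!is.finite(or) || or <= 0)
    stop(sprintf("%s: log-normal requires or > 0", name))
  if (!is.finite(ci_low) || !is.finite(ci_high) ||
      ci_low <= 0 || ci_low >= or || ci_high <= or)
    stop(sprintf("%s: requires 0 < ci_low < or < ci_high", name))
  list(meanlog = log(or), sdlog = (log(ci_high) - log(ci_low)) / (2 * 1.96))
}
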