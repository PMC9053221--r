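#' Sufficient statistics for an exponential first-event model
#'
#' Under the exponential occurrence model, all information about the event
#' rate of an outcome in a group is carried by the number of individuals
#' `n_events` with at least one occurrence and the total observation time
#' `total_time` accumulated up to each individual's first occurrence (censored
#' individuals contribute their full observed time).
#'
#' @param data A data frame with one row per individual, holding a
#'   non-negative time-at-risk column and a logical event indicator.
#' @param time,observed Tidy-eval columns giving time at risk (years) and
#'   whether the outcome was observed (`TRUE`) or censored (`FALSE`).
#' @return A one-row tibble with columns `n_events` and `total_time`.
#' @examples
#' suff_stats(data.frame(time = c(10, 20, 5), observed = c(TRUE, FALSE, TRUE)))
#' @export
suff_stats <- function(data, time = time, observed = observed) {
  tm <- dplyr::pull(data, {{ time }})
  ev <- dplyr::pull(data, {{ observed }})
  if (length(tm) && any(tm < 0, na.rm = TRUE)) {
    stop("negative observation times are not allowed")
  }
  tibble::tibble(
    n_events = sum(as.logical(ev)) %0% 0L,
    total_time = sum(tm) %0% 0
  )
}

#' Posterior of a single event rate (uniform prior)
#'
#' With a uniform prior over the rate, the posterior given `n` first events
#' in `t` person-years is proportional to \eqn{\lambda^n e^{-\lambda t}},
#' i.e. a Gamma(n + 1, t) distribution with mode n/t and mean (n + 1)/t.
#'
#' @param n_events Non-negative integer event count.
#' @param total_time Positive person-time.
#' @return A one-row tibble with the Gamma shape/rate, posterior mean, mode
#'   and standard deviation (all rates per person-year).
#' @export
rate_posterior <- function(n_events, total_time) {
  stopifnot(n_events >= 0, total_time >= 0)
  if (total_time == 0 && n_events > 0) {
    stop("n_events > 0 requires total_time > 0")
  }
  tibble::tibble(
    n_events = n_events,
    total_time = total_time,
    shape = n_events + 1,
    rate = total_time,
    mean = if (total_time > 0) (n_events + 1) / total_time else NA_real_,
    mode = if (total_time > 0) n_events / total_time else NA_real_,
    sd = if (total_time > 0) sqrt(n_events + 1) / total_time else NA_real_
  )
}

#' Quantiles of the single-rate posterior
#' @param posterior A row from [rate_posterior()].
#' @param probs Probabilities.
#' @return Numeric vector of rate quantiles.
#' @export
rate_posterior_quantiles <- function(posterior, probs = c(0.025, 0.5, 0.975)) {
  stats::qgamma(probs, shape = posterior$shape, rate = posterior$rate)
}
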