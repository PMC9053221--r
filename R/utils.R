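#' @importFrom rlang %||% .data
#' @importFrom stats integrate optimize rexp rbinom runif rgamma quantile
#' @importFrom utils combn
NULL

DAYS_PER_YEAR <- 365.25

#' Convert a day difference between two dates to fractional years
#' @noRd
years_between <- function(from, to) {
  as.numeric(to - from) / DAYS_PER_YEAR
}

#' Shift a Date by a (possibly fractional) number of years
#' @noRd
add_years <- function(date, years) {
  date + round(years * DAYS_PER_YEAR)
}

#' log(exp(a) + exp(b)), elementwise, safe for -Inf
#' @noRd
log_add <- function(a, b) {
  hi <- pmax(a, b)
  lo <- pmin(a, b)
  out <- hi + log1p(exp(lo - hi))
  out[hi == -Inf] <- -Inf
  out
}

#' Signed log-space addition: s1*exp(l1) + s2*exp(l2)
#'
#' Returns list(sign, log) vectors. A zero result is (0, -Inf).
#' @noRd
signed_log_add <- function(s1, l1, s2, l2) {
  n <- max(length(l1), length(l2))
  s1 <- rep_len(s1, n); l1 <- rep_len(l1, n)
  s2 <- rep_len(s2, n); l2 <- rep_len(l2, n)
  hi <- pmax(l1, l2)
  lo <- pmin(l1, l2)
  s_hi <- ifelse(l1 >= l2, s1, s2)
  same <- s1 == s2 | l1 == -Inf | l2 == -Inf
  if (any(l1 == -Inf)) s_hi[l1 == -Inf] <- s2[l1 == -Inf]
  if (any(l2 == -Inf)) s_hi[l2 == -Inf] <- s1[l2 == -Inf]
  out_l <- ifelse(same, log_add(l1, l2), hi + log1p(-exp(lo - hi)))
  out_s <- s_hi
  zero <- !same & lo == hi
  out_l[zero] <- -Inf
  out_s[out_l == -Inf] <- 0
  list(sign = out_s, log = out_l)
}

#' Derive a bounded integer sub-seed from a master seed and a string key
#'
#' Used so that every simulated section (demographics, exposures, each
#' outcome) consumes its own stream: adding an outcome to a configuration
#' never perturbs draws for existing ones.
#' @noRd
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * (seq_len(nchar(key)) + 31))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587) + 1L
}

`%0%` <- function(x, default) if (length(x) == 0) default else x
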