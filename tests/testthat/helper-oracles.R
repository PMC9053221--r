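# Independent oracles for the rate-difference machinery. These share no code
# with the package's closed form: the quadrature oracle integrates the
# defining integral directly (log-rescaled around the integrand's mode so the
# absolute scale never underflows), and the sampling oracle draws from the
# two Gamma posteriors whose difference the posterior density describes.

# log of  integral_{max(0,-d)}^Inf  l^n1 e^{-l t1} (l+d)^n2 e^{-(l+d) t2} dl
oracle_delta_ld <- function(n1, t1, n2, t2, delta, rel_tol = 1e-10) {
  vapply(delta, function(d) {
    lo <- max(0, -d)
    h <- function(l) {
      la <- ifelse(l == 0, ifelse(n1 == 0, 0, -Inf), n1 * log(l))
      lb <- ifelse(l + d == 0, ifelse(n2 == 0, 0, -Inf), n2 * log(l + d))
      la - l * t1 + lb - (l + d) * t2
    }
    hi <- lo + (n1 + n2 + 10) / (t1 + t2) * 10 + abs(d) + 1
    opt <- stats::optimize(h, c(lo, hi), maximum = TRUE, tol = 1e-12)
    hmax <- max(opt$objective, h(lo + 1e-12))
    val <- stats::integrate(function(l) exp(h(l) - hmax), lo, Inf,
                            rel.tol = rel_tol, subdivisions = 500L)$value
    hmax + log(val)
  }, numeric(1))
}

# Monte-Carlo oracle: the posterior of the rate difference is exactly the
# law of Gamma(n2 + 1, t2) - Gamma(n1 + 1, t1) for independent draws.
oracle_mc <- function(n1, t1, n2, t2, n_draws = 1e6) {
  d <- stats::rgamma(n_draws, n2 + 1, t2) - stats::rgamma(n_draws, n1 + 1, t1)
  p <- mean(d <= 0)
  list(p_negative = p,
       se = sqrt(max(p * (1 - p), 1 / n_draws) / n_draws),
       mean = mean(d),
       mean_se = stats::sd(d) / sqrt(n_draws))
}

one_stratum <- function(n1, t1, n2, t2) {
  tibble::tibble(events_unexposed = n1, time_unexposed = t1,
                 events_exposed = n2, time_exposed = t2)
}

# Draw one null cohort (single exposure, no effect) and run the
# unconditional test, returning the screening decision ingredients.
null_cohort_test <- function(n = 1000, rate = 0.02, years = 15, prev = 0.5) {
  x <- stats::rbinom(n, 1, prev)
  tt <- pmin(stats::rexp(n, rate), years)
  ev <- tt < years
  delta_test(one_stratum(sum(ev[x == 0]), sum(tt[x == 0]),
                         sum(ev[x == 1]), sum(tt[x == 1])))
}

# A tiny hand-built cohort used across the cohort-model tests.
tiny_cohort <- function() {
  ind <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    sex = c("male", "female", "male", "female"),
    group = c("survivor", "survivor", "survivor", "control"),
    index_date = as.Date("2000-01-01"),
    end_of_followup = as.Date(c("2015-01-01", "2012-06-30",
                                "2004-01-01", "2015-01-01")),
    chemo = c(1L, 0L, 1L, 0L),
    radio = c(0L, 1L, 1L, 0L))
  ev <- tibble::tibble(
    id = c("a", "a", "b"),
    outcome_code = c("H04", "H04", "J45"),
    event_date = as.Date(c("2007-03-16", "2003-01-01", "2008-01-01")),
    source = c("inpatient", "outpatient", "outpatient"))
  read_cohort(ind, ev, quiet = TRUE)
}
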