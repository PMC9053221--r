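#' Configuration for the synthetic registry-cohort generator
#'
#' Describes a planted causal structure under the package's own model
#' assumptions: binary exposures with configurable prevalence and pairwise
#' co-assignment, exponential time to first outcome occurrence with
#' additive per-cause rate increments, and right censoring at end of
#' follow-up. Optional adversarial layers emulate known registry
#' pathologies: calendar-era confounding (an exposure-prevalence shift and
#' an outcome-coding-rate shift at the same cutoff year), spurious
#' pre-index and acute-window codes, and outpatient-only coding.
#'
#' @param n_survivors,n_controls Cohort sizes. Controls carry no exposures.
#' @param causes Tibble with columns `cause`, `prevalence`, and optionally
#'   `class` (treatment / diagnosis / predisposition) and
#'   `prevalence_shift` (added to prevalence for index dates at or after
#'   the era cutoff).
#' @param outcomes Tibble with columns `outcome` (ICD-10-like code),
#'   `base_rate` (per person-year), and optionally `sex`
#'   ("none"/"male"/"female"; sex-specific outcomes occur in that sex
#'   only) and `rate_shift` (added to the base rate for index dates at or
#'   after the era cutoff).
#' @param effects Tibble with columns `cause`, `outcome`, `delta`: the
#'   planted additive rate increments (the ground truth).
#' @param co_assignment Optional tibble `cause_a`, `cause_b`, `prob`: with
#'   probability `prob` an individual's value of `cause_a` is copied onto
#'   `cause_b` (prob 1 gives perfectly correlated exposures).
#' @param followup_years Length of follow-up after the index date; a
#'   scalar or a `c(min, max)` range sampled uniformly.
#' @param index_years Calendar-year range of index dates, sampled
#'   uniformly.
#' @param window_offset Years post-index at which the outcome process
#'   starts (matches the observation plan's window).
#' @param era_cutoff_year Calendar year activating the `prevalence_shift`
#'   and `rate_shift` columns (NULL: no era effects).
#' @param p_pre_index,p_acute Per-individual probabilities of a spurious
#'   code of each outcome before the index date / in the 0.5-5 year acute
#'   window.
#' @param p_outpatient Probability that any generated event is coded in
#'   the outpatient setting (otherwise inpatient).
#' @param mortality Optional list `list(survivor =, control =)` of death
#'   rates per person-year from the index date; deaths truncate follow-up
#'   and add a death-source event (code "R99").
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_survivors = 2000, n_controls = 0,
                       causes, outcomes, effects = NULL,
                       co_assignment = NULL,
                       followup_years = 20, index_years = c(1970, 2012),
                       window_offset = 5, era_cutoff_year = NULL,
                       p_pre_index = 0, p_acute = 0, p_outpatient = 0.3,
                       mortality = NULL) {
  causes <- tibble::as_tibble(causes)
  outcomes <- tibble::as_tibble(outcomes)
  if (!"class" %in% names(causes)) causes$class <- "treatment"
  if (!"prevalence_shift" %in% names(causes)) causes$prevalence_shift <- 0
  if (!"sex" %in% names(outcomes)) outcomes$sex <- "none"
  if (!"rate_shift" %in% names(outcomes)) outcomes$rate_shift <- 0
  effects <- if (is.null(effects)) {
    tibble::tibble(cause = character(0), outcome = character(0),
                   delta = numeric(0))
  } else tibble::as_tibble(effects)
  stopifnot(
    all(causes$prevalence >= 0 & causes$prevalence <= 1),
    all(outcomes$base_rate >= 0), all(effects$delta >= 0),
    p_pre_index >= 0, p_pre_index <= 1, p_acute >= 0, p_acute <= 1,
    p_outpatient >= 0, p_outpatient <= 1)
  if (!is.null(co_assignment)) {
    co_assignment <- tibble::as_tibble(co_assignment)
    stopifnot(all(co_assignment$prob >= 0 & co_assignment$prob <= 1),
              all(co_assignment$cause_a %in% causes$cause),
              all(co_assignment$cause_b %in% causes$cause))
  }
  stopifnot(all(effects$cause %in% causes$cause),
            all(effects$outcome %in% outcomes$outcome))
  structure(
    list(n_survivors = n_survivors, n_controls = n_controls,
         causes = causes, outcomes = outcomes, effects = effects,
         co_assignment = co_assignment,
         followup_years = followup_years, index_years = index_years,
         window_offset = window_offset, era_cutoff_year = era_cutoff_year,
         p_pre_index = p_pre_index, p_acute = p_acute,
         p_outpatient = p_outpatient, mortality = mortality),
    class = "sim_config")
}

#' Simulate a registry-style cohort with known ground truth
#'
#' Draws a cohort from a [sim_config()]: exposures per individual, then for
#' each individual and outcome a first-event time from the exponential
#' distribution with rate `base_rate + sum of increments of the exposed
#' causes`, measured from the observation-window start and censored at end
#' of follow-up. Every simulated section (demographics, exposures, each
#' outcome) draws from its own sub-seed derived from `seed` and the
#' section name, so the same seed reproduces the cohort bit-exactly and
#' adding an outcome to the configuration never perturbs the draws of the
#' existing ones.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed.
#' @return A list: `cohort` (a [read_cohort()]-compatible `cohort`
#'   object), `truth` (the planted cause-outcome increments), `config`.
#' @export
simulate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  n_s <- config$n_survivors
  n_c <- config$n_controls
  n <- n_s + n_c
  cause_names <- config$causes$cause

  set.seed(derive_seed(seed, "demographics"))
  sex <- sample(c("male", "female"), n, replace = TRUE)
  yr0 <- config$index_years[1]
  yr1 <- config$index_years[2]
  index_date <- as.Date(sprintf("%d-01-01", yr0)) +
    floor(runif(n) * (365.25 * (yr1 - yr0 + 1)))
  fy <- if (length(config$followup_years) == 2) {
    runif(n, config$followup_years[1], config$followup_years[2])
  } else rep(config$followup_years, n)
  birth_date <- index_date - floor(runif(n, 0, 18) * DAYS_PER_YEAR)
  end_of_followup <- add_years(index_date, fy)
  index_year <- as.integer(format(index_date, "%Y"))
  late_era <- if (is.null(config$era_cutoff_year)) rep(FALSE, n) else
    index_year >= config$era_cutoff_year

  individuals <- tibble::tibble(
    id = sprintf("S%05d", seq_len(n)),
    sex = sex,
    group = rep(c("survivor", "control"), c(n_s, n_c)),
    index_date = index_date,
    end_of_followup = end_of_followup,
    birth_date = birth_date)

  set.seed(derive_seed(seed, "exposures"))
  surv <- individuals$group == "survivor"
  expo <- matrix(0L, n, length(cause_names),
                 dimnames = list(NULL, cause_names))
  for (j in seq_along(cause_names)) {
    prev <- config$causes$prevalence[j] +
      config$causes$prevalence_shift[j] * late_era
    prev <- pmin(pmax(prev, 0), 1)
    expo[surv, j] <- rbinom(sum(surv), 1, prev[surv])
  }
  if (!is.null(config$co_assignment)) {
    for (r in seq_len(nrow(config$co_assignment))) {
      a <- config$co_assignment$cause_a[r]
      b <- config$co_assignment$cause_b[r]
      copy <- surv & (runif(n) < config$co_assignment$prob[r])
      expo[copy, b] <- expo[copy, a]
    }
  }
  individuals <- dplyr::bind_cols(
    individuals, tibble::as_tibble(expo))

  events <- list()
  # deaths first: they truncate follow-up for the outcome processes
  if (!is.null(config$mortality)) {
    set.seed(derive_seed(seed, "mortality"))
    rate <- ifelse(surv, config$mortality$survivor, config$mortality$control)
    td <- rexp(n, pmax(rate, 1e-12))
    dies <- rate > 0 & td < fy
    if (any(dies)) {
      dd <- add_years(individuals$index_date[dies], td[dies])
      individuals$end_of_followup[dies] <- dd
      events[["death"]] <- tibble::tibble(
        id = individuals$id[dies], outcome_code = "R99",
        event_date = dd, source = "death")
    }
  }
  horizon <- years_between(individuals$index_date, individuals$end_of_followup) -
    config$window_offset

  for (j in seq_len(nrow(config$outcomes))) {
    oc <- config$outcomes$outcome[j]
    set.seed(derive_seed(seed, paste0("outcome:", oc)))
    rate <- rep(config$outcomes$base_rate[j], n) +
      config$outcomes$rate_shift[j] * late_era
    for (r in which(config$effects$outcome == oc)) {
      cs <- config$effects$cause[r]
      rate <- rate + config$effects$delta[r] * expo[, cs]
    }
    if (config$outcomes$sex[j] != "none") {
      rate[individuals$sex != config$outcomes$sex[j]] <- 0
    }
    tt <- ifelse(rate > 0, rexp(n, pmax(rate, 1e-12)), Inf)
    hit <- tt < horizon & horizon > 0
    if (any(hit)) {
      ed <- add_years(individuals$index_date[hit],
                      config$window_offset + tt[hit])
      src <- ifelse(runif(sum(hit)) < config$p_outpatient,
                    "outpatient", "inpatient")
      events[[paste0("late:", oc)]] <- tibble::tibble(
        id = individuals$id[hit], outcome_code = oc,
        event_date = ed, source = src)
    }
    if (config$p_pre_index > 0) {
      pre <- runif(n) < config$p_pre_index
      if (any(pre)) {
        ed <- individuals$index_date[pre] -
          floor(runif(sum(pre), 30, 3 * DAYS_PER_YEAR))
        src <- ifelse(runif(sum(pre)) < config$p_outpatient,
                      "outpatient", "inpatient")
        events[[paste0("pre:", oc)]] <- tibble::tibble(
          id = individuals$id[pre], outcome_code = oc,
          event_date = ed, source = src)
      }
    }
    if (config$p_acute > 0) {
      ac <- runif(n) < config$p_acute &
        years_between(individuals$index_date, individuals$end_of_followup) > 0.5
      if (any(ac)) {
        ed <- add_years(individuals$index_date[ac],
                        runif(sum(ac), 0.5, 5))
        ed <- pmin(ed, individuals$end_of_followup[ac])
        src <- ifelse(runif(sum(ac)) < config$p_outpatient,
                      "outpatient", "inpatient")
        events[[paste0("acute:", oc)]] <- tibble::tibble(
          id = individuals$id[ac], outcome_code = oc,
          event_date = ed, source = src)
      }
    }
  }
  events <- if (length(events)) {
    dplyr::arrange(dplyr::bind_rows(events), .data$id, .data$event_date,
                   .data$outcome_code)
  } else {
    tibble::tibble(id = character(0), outcome_code = character(0),
                   event_date = as.Date(character(0)), source = character(0))
  }
  sexspec <- config$outcomes$sex
  names(sexspec) <- config$outcomes$outcome
  schema <- list(
    causes = as.list(stats::setNames(config$causes$class, cause_names)),
    sex_specific_outcomes = as.list(sexspec[sexspec != "none"]))
  cohort <- read_cohort(individuals, events, schema, quiet = TRUE)
  list(cohort = cohort, truth = config$effects, config = config)
}

#' Write a cohort to the delimited-text schema
#'
#' Produces `individuals.csv`, `events.csv` and `schema.yaml` in `dir`,
#' the same format [read_cohort()] consumes.
#'
#' @param cohort A `cohort` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$individuals, file.path(dir, "individuals.csv"))
  readr::write_csv(cohort$events, file.path(dir, "events.csv"))
  yaml::write_yaml(cohort$schema %||% list(),
                   file.path(dir, "schema.yaml"))
  invisible(dir)
}

#' Named small fixture cohorts covering the pipeline's corner cases
#'
#' Deterministic, seed-fixed mini-cohorts: a global null; a single strong
#' effect; a confounded pair (80% co-assignment, only one true cause); an
#' identical pair (perfect co-assignment, forces ambiguity); an
#' era-confounded exposure (prevalence and coding rate both jump at the
#' cutoff year, no true effect); an era-balanced true effect; pre-index
#' coding noise; and a sex-specific outcome.
#'
#' @param seed Master seed.
#' @param names Subset of fixtures to build (default: all).
#' @return Named list of [simulate_cohort()] results.
#' @export
fixture_suite <- function(seed = 1, names = NULL) {
  cfgs <- list(
    null = sim_config(
      n_survivors = 1000,
      causes = tibble::tibble(cause = "exposure", prevalence = 0.5),
      outcomes = tibble::tibble(outcome = "J45", base_rate = 0.05),
      followup_years = 15),
    single_effect = sim_config(
      n_survivors = 2000,
      causes = tibble::tibble(cause = "alkylating", prevalence = 0.5),
      outcomes = tibble::tibble(outcome = "H04", base_rate = 0.02),
      effects = tibble::tibble(cause = "alkylating", outcome = "H04",
                               delta = 0.05),
      followup_years = 20),
    confounded_pair = sim_config(
      n_survivors = 2000,
      causes = tibble::tibble(cause = c("radiation", "proxy"),
                              prevalence = c(0.5, 0.3)),
      co_assignment = tibble::tibble(cause_a = "radiation",
                                     cause_b = "proxy", prob = 0.8),
      outcomes = tibble::tibble(outcome = "E03", base_rate = 0.02),
      effects = tibble::tibble(cause = "radiation", outcome = "E03",
                               delta = 0.1),
      followup_years = 20),
    identical_pair = sim_config(
      n_survivors = 2000,
      causes = tibble::tibble(cause = c("drug_a", "drug_b"),
                              prevalence = c(0.5, 0.5)),
      co_assignment = tibble::tibble(cause_a = "drug_a",
                                     cause_b = "drug_b", prob = 1),
      outcomes = tibble::tibble(outcome = "I42", base_rate = 0.02),
      effects = tibble::tibble(cause = "drug_a", outcome = "I42",
                               delta = 0.08),
      followup_years = 20),
    era_confounded = sim_config(
      n_survivors = 3000,
      causes = tibble::tibble(cause = "topoisomerase", prevalence = 0.1,
                              prevalence_shift = 0.5),
      outcomes = tibble::tibble(outcome = "B34", base_rate = 0.01,
                                rate_shift = 0.04),
      era_cutoff_year = 1988,
      index_years = c(1975, 2000),
      followup_years = 20),
    era_balanced = sim_config(
      n_survivors = 3000,
      causes = tibble::tibble(cause = "anthracycline", prevalence = 0.4),
      outcomes = tibble::tibble(outcome = "I42", base_rate = 0.02),
      effects = tibble::tibble(cause = "anthracycline", outcome = "I42",
                               delta = 0.05),
      index_years = c(1975, 2000),
      followup_years = 20),
    preindex_noise = sim_config(
      n_survivors = 2000,
      causes = tibble::tibble(cause = "surgery", prevalence = 0.5),
      outcomes = tibble::tibble(outcome = "A08", base_rate = 0.02),
      effects = tibble::tibble(cause = "surgery", outcome = "A08",
                               delta = 0.05),
      p_pre_index = 0.1, p_acute = 0.1,
      followup_years = 20),
    sex_specific = sim_config(
      n_survivors = 3000,
      causes = tibble::tibble(cause = "cervical_ca", prevalence = 0.3),
      outcomes = tibble::tibble(outcome = "N71", base_rate = 0.01,
                                sex = "female"),
      effects = tibble::tibble(cause = "cervical_ca", outcome = "N71",
                               delta = 0.04),
      followup_years = 20))
  names <- names %||% base::names(cfgs)
  purrr::imap(cfgs[names], function(cfg, nm) {
    simulate_cohort(cfg, derive_seed(seed, paste0("fixture:", nm)))
  })
}
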