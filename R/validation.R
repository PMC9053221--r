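#' Era-split confounder control for one link
#'
#' Calendar-time confounding (a treatment entering protocols at the same
#' time as an outcome-coding change) is controlled by splitting the time
#' axis at a cutoff year: a binary era indicator (index date before /
#' from the cutoff year on) is added to the link's conditioning set and
#' the pooled conditional test is re-run. The association survives if the
#' controlled p-value stays below `validation_alpha` (0.001 by default,
#' deliberately separate from the discovery levels). Era assignment uses
#' the index date -- the confounder is the treatment era, not the event
#' date. If all individuals fall in one era the link cannot be assessed
#' and is flagged rather than silently passed or failed. The cutoff years
#' 1988 and 1996 are the named presets used for treatment-protocol shifts.
#'
#' @param cohort A [read_cohort()] object.
#' @param cause,outcome The link under scrutiny.
#' @param cutoff_year Calendar year at which to split (e.g. 1988 or 1996).
#' @param conditioning_set Exposures already conditioned on (typically the
#'   other kept causes of the same outcome).
#' @param plan An [observation_plan()].
#' @param validation_alpha Significance level for survival (default 0.001).
#' @param population,sex Population scope, as in [stratify()].
#' @return One-row tibble: `cutoff_year`, `p_after_control`, `survives`,
#'   `assessable`.
#' @export
era_split_retest <- function(cohort, cause, outcome, cutoff_year,
                             conditioning_set = character(),
                             plan = observation_plan(),
                             validation_alpha = 0.001,
                             population = "survivors", sex = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  co2 <- cohort
  era <- as.integer(format(co2$individuals$index_date, "%Y") >= cutoff_year)
  co2$individuals$.era <- era
  pop_ind <- filter_population(co2$individuals, population, sex)
  if (length(unique(pop_ind$.era)) < 2) {
    return(tibble::tibble(cutoff_year = cutoff_year,
                          p_after_control = NA_real_,
                          survives = NA, assessable = FALSE))
  }
  st <- stratify(co2, cause, c(conditioning_set, ".era"), outcome,
                 plan, population, sex)
  tst <- delta_test(st)
  if (!tst$informative) {
    return(tibble::tibble(cutoff_year = cutoff_year,
                          p_after_control = NA_real_,
                          survives = NA, assessable = FALSE))
  }
  tibble::tibble(cutoff_year = cutoff_year,
                 p_after_control = tst$p_value,
                 survives = tst$p_value < validation_alpha &
                   tst$expected_delta > 0,
                 assessable = TRUE)
}

#' Timing of a link's outcome codes relative to the index diagnosis
#'
#' Among individuals exposed to the link's cause, computes the fraction of
#' those with any occurrence of the outcome code whose code appears
#' (a) before the index date, (b) in the acute window (0.5-5 years
#' post-index by default), and (c) at or beyond the observation-window
#' start. The windows are non-exclusive: an individual with codes at 2 and
#' 7 years counts in both (b) and (c). Codes from all sources count.
#' High fractions in (a) or (b) point to routine code repetition rather
#' than genuine late effects.
#'
#' @inheritParams era_split_retest
#' @return One-row tibble: `n_with_code`, `frac_pre_index`, `frac_acute`,
#'   `frac_late`, `empty`.
#' @export
classify_event_timing <- function(cohort, cause, outcome,
                                  plan = observation_plan(),
                                  population = "survivors", sex = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  ind <- filter_population(cohort$individuals, population, sex)
  ind <- ind[ind[[cause]] == 1, , drop = FALSE]
  ev <- cohort$events
  ev <- ev[code_matches(ev$outcome_code, outcome, plan$code_match) &
             ev$id %in% ind$id, , drop = FALSE]
  if (nrow(ev) == 0) {
    return(tibble::tibble(n_with_code = 0L, frac_pre_index = 0,
                          frac_acute = 0, frac_late = 0, empty = TRUE))
  }
  ev <- dplyr::inner_join(ev, ind[, c("id", "index_date")], by = "id")
  ev$yrs <- years_between(ev$index_date, ev$event_date)
  per <- ev |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      pre = any(.data$yrs < 0),
      acute = any(.data$yrs >= plan$acute_window[1] &
                    .data$yrs < plan$acute_window[2]),
      late = any(.data$yrs >= plan$window_start_offset),
      .groups = "drop")
  tibble::tibble(
    n_with_code = nrow(per),
    frac_pre_index = mean(per$pre),
    frac_acute = mean(per$acute),
    frac_late = mean(per$late),
    empty = FALSE)
}

#' Does a link rest solely on outpatient-sourced codes?
#'
#' TRUE iff every event supporting the link -- in-window, code-matching
#' events of exposed individuals from the plan's counted sources -- has
#' source `outpatient`. Outpatient-only links are flagged because the
#' reliability of those codes is more uncertain. Zero supporting events
#' yield FALSE with `empty = TRUE`.
#'
#' @inheritParams era_split_retest
#' @return One-row tibble: `outpatient_only`, `n_supporting`, `empty`.
#' @export
source_restriction_flag <- function(cohort, cause, outcome,
                                    plan = observation_plan(),
                                    population = "survivors", sex = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  ind <- filter_population(cohort$individuals, population, sex)
  ind <- ind[ind[[cause]] == 1, , drop = FALSE]
  entry <- add_years(ind$index_date, plan$window_start_offset)
  if (!is.null(plan$registry_start)) entry <- pmax(entry, plan$registry_start)
  ev <- cohort$events
  ev <- ev[ev$source %in% plan$source_filter &
             code_matches(ev$outcome_code, outcome, plan$code_match) &
             ev$id %in% ind$id, , drop = FALSE]
  if (nrow(ev)) {
    i <- match(ev$id, ind$id)
    keep <- ev$event_date >= entry[i] & ev$event_date <= ind$end_of_followup[i]
    ev <- ev[keep, , drop = FALSE]
  }
  tibble::tibble(
    outpatient_only = nrow(ev) > 0 && all(ev$source == "outpatient"),
    n_supporting = nrow(ev),
    empty = nrow(ev) == 0)
}

#' Person-year frequency of an outcome in a subgroup
#'
#' Individuals with at least one in-window occurrence divided by the
#' accumulated in-window person-time -- the descriptive rate used to
#' compare the control population, survivors without, and survivors with
#' a given exposure. Equals n/t of [suff_stats()] on the same risk set.
#'
#' @param cohort A [read_cohort()] object.
#' @param outcome_code Outcome of interest.
#' @param plan An [observation_plan()].
#' @param ids Optional subset of individual ids defining the subgroup.
#' @param population,sex Scope, as in [first_occurrence()].
#' @return One-row tibble: `n_individuals`, `n_events`, `person_years`,
#'   `rate` (per person-year).
#' @export
person_year_frequency <- function(cohort, outcome_code,
                                  plan = observation_plan(), ids = NULL,
                                  population = "all", sex = NULL) {
  fo <- first_occurrence(cohort, outcome_code, plan, population, sex)
  if (!is.null(ids)) fo <- fo[fo$id %in% ids, , drop = FALSE]
  ss <- suff_stats(fo)
  if (nrow(fo) == 0 || ss$total_time == 0) {
    stop("subgroup has no person-time in the observation window")
  }
  tibble::tibble(n_individuals = nrow(fo), n_events = ss$n_events,
                 person_years = ss$total_time,
                 rate = ss$n_events / ss$total_time)
}

#' Person-year frequencies for a link across the three standard subgroups
#'
#' Controls, survivors without the exposure, survivors with the exposure.
#'
#' @inheritParams era_split_retest
#' @return Tibble (class `py_frequency`) with one row per subgroup.
#' @export
frequency_by_exposure <- function(cohort, cause, outcome,
                                  plan = observation_plan(), sex = NULL) {
  ind <- cohort$individuals
  if (!is.null(sex) && sex != "none") ind <- ind[ind$sex == sex, , drop = FALSE]
  grp <- list(
    control = ind$id[ind$group == "control"],
    survivor_unexposed = ind$id[ind$group == "survivor" & ind[[cause]] == 0],
    survivor_exposed = ind$id[ind$group == "survivor" & ind[[cause]] == 1])
  out <- purrr::imap(grp, function(ids, nm) {
    if (length(ids) == 0) return(NULL)
    dplyr::mutate(
      person_year_frequency(cohort, outcome, plan, ids = ids, sex = sex),
      subgroup = nm, .before = 1)
  })
  out <- dplyr::bind_rows(out)
  out$cause <- cause
  out$outcome <- outcome
  class(out) <- c("py_frequency", class(out))
  out
}

#' Validation report for the kept links of a discovery run
#'
#' Runs [era_split_retest()] (conditioning on the link's fellow kept
#' causes), [classify_event_timing()] and [source_restriction_flag()] for
#' every kept or ambiguous link and appends the results as columns.
#'
#' @param cohort A [read_cohort()] object.
#' @param links A `causal_links` table from [prune_step2()].
#' @param cutoff_year Era cutoff (preset years: 1988 or 1996).
#' @param plan An [observation_plan()].
#' @param validation_alpha Significance level for era survival.
#' @return `links` restricted to surviving statuses, with validation
#'   columns appended.
#' @export
validate_links <- function(cohort, links, cutoff_year = 1988,
                           plan = observation_plan(),
                           validation_alpha = 0.001) {
  config <- attr(links, "config") %||% discovery_config()
  keep <- links[links$status %in% c("kept", "ambiguous"), , drop = FALSE]
  if (nrow(keep) == 0) return(keep)
  rows <- purrr::map(seq_len(nrow(keep)), function(i) {
    li <- keep[i, ]
    sx <- if (li$sex_restriction == "none") NULL else li$sex_restriction
    others <- setdiff(keep$cause[keep$outcome == li$outcome &
                                   keep$status == "kept"], li$cause)
    era <- era_split_retest(cohort, li$cause, li$outcome, cutoff_year,
                            conditioning_set = others, plan = plan,
                            validation_alpha = validation_alpha,
                            population = config$population, sex = sx)
    tim <- classify_event_timing(cohort, li$cause, li$outcome, plan,
                                 population = config$population, sex = sx)
    src <- source_restriction_flag(cohort, li$cause, li$outcome, plan,
                                   population = config$population, sex = sx)
    dplyr::bind_cols(li, era, tim[, c("frac_pre_index", "frac_acute",
                                      "frac_late")],
                     src[, "outpatient_only"])
  })
  dplyr::bind_rows(rows)
}
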