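#' ICD-10 chapter of a diagnosis code
#'
#' Deterministic mapping of codes to chapter labels for chapter-level
#' health-care-use comparisons. Infectious chapters A and B merge into
#' "AB", the D block splits into neoplasms "D'" (D00-D48) and blood /
#' immune "D''" (D50-D89), injury chapters S and T merge into "ST", and
#' the eye and ear blocks are a single "H". External-cause and
#' supplementary prefixes (U-Z) and anything unrecognized map to "other".
#'
#' @param codes Character vector of ICD-10 codes (e.g. "H04", "B34.1").
#' @return Character vector of chapter labels.
#' @examples
#' chapter_of(c("H04", "B34", "D23", "D60"))
#' @export
chapter_of <- function(codes) {
  letter <- toupper(substr(codes, 1, 1))
  num <- suppressWarnings(as.integer(substr(codes, 2, 3)))
  out <- dplyr::case_when(
    letter %in% c("A", "B") ~ "AB",
    letter == "C" ~ "C",
    letter == "D" & num <= 48 ~ "D'",
    letter == "D" & num >= 50 ~ "D''",
    letter %in% c("E", "F", "G", "H", "I", "J", "K", "L",
                  "M", "N", "O", "P", "Q", "R") ~ letter,
    letter %in% c("S", "T") ~ "ST",
    .default = "other")
  out[is.na(num)] <- "other"
  out
}

#' All chapter labels in canonical order
#' @noRd
chapter_levels <- function() {
  c("AB", "C", "D'", "D''", "E", "F", "G", "H", "I", "J", "K", "L",
    "M", "N", "O", "P", "Q", "R", "ST", "other")
}

#' Chapter-level frequency comparison between two groups
#'
#' For each ICD-10 chapter and care setting, estimates the posterior of the
#' occurrence frequency (percent per year) in two compared groups --
#' survivors vs controls, or males vs females within one group -- and the
#' posterior of their difference, with a logarithmic significance grade.
#' An individual's chapter-level time-to-event is the first event of any
#' code within the chapter. The difference posterior is the same
#' [delta_posterior()] machinery used in discovery; group 2 is the first
#' compared group, so a positive difference means a higher frequency there.
#'
#' @param cohort A [read_cohort()] object.
#' @param comparison `"cohort"` compares survivors (group 2) against
#'   controls (group 1); `"sex"` compares males (group 2) against females
#'   (group 1) within `population`.
#' @param population For `comparison = "sex"`: which group to compare
#'   within (`"survivors"` or `"controls"`).
#' @param plan An [observation_plan()] (the source filter is overridden
#'   per care setting).
#' @param sources Care settings analyzed separately.
#' @param chapters Chapter labels to include (default: all present).
#' @return A tibble (class `chapter_comparison`), one row per chapter and
#'   source: per-group event counts, person-years, posterior mean and SD of
#'   the frequency in percent per year, the difference posterior's mean,
#'   p-value and grade (`ns`, `0.01`, `0.001`, `0.0001`).
#' @export
compare_groups <- function(cohort, comparison = c("cohort", "sex"),
                           population = "survivors",
                           plan = observation_plan(),
                           sources = c("inpatient", "outpatient"),
                           chapters = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  comparison <- match.arg(comparison)
  chapters <- chapters %||%
    intersect(chapter_levels(), unique(chapter_of(cohort$events$outcome_code)))
  rows <- purrr::map(sources, function(src) {
    pl <- plan
    pl$source_filter <- src
    purrr::map(chapters, function(ch) {
      if (comparison == "cohort") {
        fo1 <- first_occurrence(cohort, ch, pl, population = "controls",
                                match = "chapter")
        fo2 <- first_occurrence(cohort, ch, pl, population = "survivors",
                                match = "chapter")
        labs <- c("control", "survivor")
      } else {
        fo1 <- first_occurrence(cohort, ch, pl, population = population,
                                sex = "female", match = "chapter")
        fo2 <- first_occurrence(cohort, ch, pl, population = population,
                                sex = "male", match = "chapter")
        labs <- c("female", "male")
      }
      if (nrow(fo1) == 0 || nrow(fo2) == 0) {
        stop("empty comparison group for chapter ", ch)
      }
      s1 <- suff_stats(fo1)
      s2 <- suff_stats(fo2)
      tst <- delta_test(tibble::tibble(
        events_unexposed = s1$n_events, time_unexposed = s1$total_time,
        events_exposed = s2$n_events, time_exposed = s2$total_time))
      tibble::tibble(
        source = src, chapter = ch,
        group1 = labs[1], group2 = labs[2],
        n1 = s1$n_events, py1 = s1$total_time,
        n2 = s2$n_events, py2 = s2$total_time,
        freq1_pct_py = 100 * (s1$n_events + 1) / s1$total_time,
        freq1_sd_pct_py = 100 * sqrt(s1$n_events + 1) / s1$total_time,
        freq2_pct_py = 100 * (s2$n_events + 1) / s2$total_time,
        freq2_sd_pct_py = 100 * sqrt(s2$n_events + 1) / s2$total_time,
        delta_pct_py = 100 * tst$expected_delta,
        p_value = tst$p_value,
        grade = significance_grade(tst$p_value))
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("chapter_comparison", class(out))
  out
}

#' Logarithmic significance grade used in chapter comparisons
#'
#' @param p Numeric vector.
#' @return `"ns"` for p >= 0.01, otherwise the largest of 0.01 / 0.001 /
#'   0.0001 that still exceeds p (grades monotone in the tail area).
#' @export
significance_grade <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 1e-4 ~ "0.0001",
    p < 1e-3 ~ "0.001",
    p < 1e-2 ~ "0.01",
    .default = "ns")
}

#' Kaplan-Meier product-limit survival estimate
#'
#' Plain product-limit estimator over the distinct event times, with
#' optional delayed entry (left truncation): an individual contributes to
#' the risk set at time u only if `entry < u <= time`. Used for mortality
#' curves by attained age, where entry is the age at index plus the
#' observation offset.
#'
#' @param times Non-negative event/censoring times.
#' @param events Logical (or 0/1): TRUE if the event occurred at `times`.
#' @param entry Optional entry times (same length), default 0.
#' @return A tibble (class `survival_curve`): `time`, `n_risk`, `n_event`,
#'   `survival`, one row per distinct event time, survival non-increasing
#'   and starting at 1.
#' @examples
#' kaplan_meier(c(1, 2, 3), c(FALSE, TRUE, TRUE))
#' @export
kaplan_meier <- function(times, events, entry = NULL) {
  stopifnot(length(times) == length(events), all(times >= 0))
  events <- as.logical(events)
  entry <- entry %||% rep(0, length(times))
  stopifnot(all(entry <= times))
  ut <- sort(unique(times[events]))
  surv <- 1
  out <- purrr::map(ut, function(u) {
    n_risk <- sum(entry < u & times >= u)
    n_event <- sum(events & times == u)
    if (n_risk > 0) surv <<- surv * (1 - n_event / n_risk)
    tibble::tibble(time = u, n_risk = n_risk, n_event = n_event,
                   survival = surv)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    out <- tibble::tibble(time = numeric(0), n_risk = integer(0),
                          n_event = integer(0), survival = numeric(0))
  }
  class(out) <- c("survival_curve", class(out))
  attr(out, "n") <- length(times)
  out
}

#' Mortality curves for a cohort, by attained age or time since index
#'
#' Individuals are dead if they carry any death-source event. When the
#' individuals table has a `birth_date` column the time axis is attained
#' age with delayed entry at age-at-index plus the observation offset;
#' otherwise it is years since the index date.
#'
#' @param cohort A [read_cohort()] object.
#' @param by Split curves by `"group"` (survivor / control) or `"sex"`.
#' @param plan An [observation_plan()] (supplies the entry offset).
#' @return A tibble of survival curves stacked with a `stratum` column.
#' @export
mortality_curves <- function(cohort, by = c("group", "sex"),
                             plan = observation_plan()) {
  by <- match.arg(by)
  ind <- cohort$individuals
  dead_ids <- unique(cohort$events$id[cohort$events$source == "death"])
  died <- ind$id %in% dead_ids
  if ("birth_date" %in% names(ind) && !all(is.na(ind$birth_date))) {
    entry <- years_between(ind$birth_date, ind$index_date) +
      plan$window_start_offset
    exit <- years_between(ind$birth_date, ind$end_of_followup)
  } else {
    entry <- rep(plan$window_start_offset, nrow(ind))
    exit <- years_between(ind$index_date, ind$end_of_followup)
  }
  ok <- exit > entry
  purrr::map(sort(unique(ind[[by]])), function(g) {
    sel <- ok & ind[[by]] == g
    km <- kaplan_meier(exit[sel], died[sel], entry[sel])
    km$stratum <- g
    km
  }) |> dplyr::bind_rows()
}
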