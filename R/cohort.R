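#' Observation plan for outcome ascertainment
#'
#' Defines the window in which outcome codes count as late effects. By
#' default observation starts 5 years after the index diagnosis (late
#' effects only), counts events from all three registry sources, and the
#' 0.5-5 year post-index window is reserved for the acute-effect timing
#' checks in the validation step.
#'
#' @param window_start_offset Years after the index date at which outcome
#'   observation begins (default 5).
#' @param source_filter Subset of `c("inpatient", "outpatient", "death")`
#'   whose events are counted.
#' @param registry_start Optional `Date` (or ISO string) before which the
#'   counted sources are unobserved; entry into the risk set is delayed to
#'   this date (left truncation), e.g. the 1997 start of outpatient
#'   registration when restricting to outpatient records.
#' @param code_match `"category"` matches on the 3-character ICD-10
#'   category (an event code "H04.1" matches outcome "H04");
#'   `"prefix"` matches any code starting with the outcome string.
#' @param acute_window Two-element numeric, years post-index delimiting the
#'   acute window used by [classify_event_timing()].
#' @return A list of class `observation_plan`.
#' @export
observation_plan <- function(window_start_offset = 5,
                             source_filter = c("inpatient", "outpatient", "death"),
                             registry_start = NULL,
                             code_match = c("category", "prefix"),
                             acute_window = c(0.5, 5)) {
  stopifnot(window_start_offset >= 0, length(acute_window) == 2)
  source_filter <- match.arg(source_filter, several.ok = TRUE)
  if (!is.null(registry_start)) registry_start <- as.Date(registry_start)
  structure(
    list(window_start_offset = window_start_offset,
         source_filter = source_filter,
         registry_start = registry_start,
         code_match = match.arg(code_match),
         acute_window = as.numeric(acute_window)),
    class = "observation_plan")
}

CORE_IND_COLS <- c("id", "sex", "group", "index_date", "end_of_followup", "birth_date")

#' Assemble and validate a registry-style cohort
#'
#' Builds a `cohort` object from an individuals table (one row per subject:
#' `id`, `sex` in male/female, `group` in survivor/control, ISO dates
#' `index_date` and `end_of_followup`, optionally `birth_date`, plus one 0/1
#' column per candidate cause) and an events table (`id`, `outcome_code`,
#' `event_date`, `source` in inpatient/outpatient/death). Controls carry the
#' index date of their matched survivor so that person-time is comparable,
#' and must have all cause exposures equal to zero.
#'
#' Rows with a missing id or unparseable dates are rejected and reported
#' (see `attr(cohort, "rejected")`); duplicated individual ids and events
#' referencing an id never present in the individuals table are errors.
#'
#' @param individuals,events Data frames, or paths to CSV files (UTF-8,
#'   header row).
#' @param schema Optional schema: a list (or path to a YAML file) with
#'   `causes` (named list/vector mapping cause column to class:
#'   treatment / diagnosis / predisposition) and `sex_specific_outcomes`
#'   (named list/vector mapping outcome code to "male" or "female").
#' @param quiet Suppress the rejected-row report message.
#' @return A `cohort` object: list with tibbles `individuals` and `events`,
#'   a `causes` catalogue (cause, class), an `outcomes` catalogue
#'   (outcome, sex), and the schema.
#' @export
read_cohort <- function(individuals, events, schema = NULL, quiet = FALSE) {
  if (is.character(individuals)) {
    individuals <- readr::read_csv(individuals, show_col_types = FALSE)
  }
  if (is.character(events)) {
    events <- readr::read_csv(events, show_col_types = FALSE)
  }
  if (is.character(schema)) schema <- yaml::read_yaml(schema)
  individuals <- tibble::as_tibble(individuals)
  events <- tibble::as_tibble(events)

  need_i <- c("id", "sex", "group", "index_date", "end_of_followup")
  if (!all(need_i %in% names(individuals))) {
    stop("individuals table needs columns ", paste(need_i, collapse = ", "))
  }
  need_e <- c("id", "outcome_code", "event_date", "source")
  if (!all(need_e %in% names(events))) {
    stop("events table needs columns ", paste(need_e, collapse = ", "))
  }

  individuals$id <- as.character(individuals$id)
  events$id <- as.character(events$id)
  parse_date <- function(x) {
    if (inherits(x, "Date")) return(x)
    as.Date(suppressWarnings(readr::parse_date(as.character(x))))
  }
  individuals$index_date <- parse_date(individuals$index_date)
  individuals$end_of_followup <- parse_date(individuals$end_of_followup)
  if ("birth_date" %in% names(individuals)) {
    individuals$birth_date <- parse_date(individuals$birth_date)
  }
  events$event_date <- parse_date(events$event_date)

  bad_i <- is.na(individuals$id) | individuals$id == "" |
    is.na(individuals$index_date) | is.na(individuals$end_of_followup)
  rejected_i <- tibble::tibble(
    row = which(bad_i),
    reason = vapply(which(bad_i), function(r) {
      if (is.na(individuals$id[r]) || individuals$id[r] == "") "missing id"
      else "unparseable date"
    }, character(1)))
  rejected_ids <- individuals$id[bad_i]
  rejected_ids <- rejected_ids[!is.na(rejected_ids)]
  individuals <- individuals[!bad_i, , drop = FALSE]

  if (anyDuplicated(individuals$id)) {
    stop("duplicate individual id(s): ",
         paste(unique(individuals$id[duplicated(individuals$id)]), collapse = ", "))
  }
  if (any(individuals$end_of_followup < individuals$index_date)) {
    stop("end_of_followup before index_date for id(s): ",
         paste(individuals$id[individuals$end_of_followup < individuals$index_date],
               collapse = ", "))
  }

  bad_e <- is.na(events$id) | events$id == "" | is.na(events$event_date) |
    events$id %in% rejected_ids
  rejected_e <- tibble::tibble(
    row = which(bad_e),
    reason = dplyr::case_when(
      is.na(events$id[bad_e]) | events$id[bad_e] == "" ~ "missing id",
      events$id[bad_e] %in% rejected_ids ~ "individual row rejected",
      .default = "unparseable date"))
  events <- events[!bad_e, , drop = FALSE]

  unknown <- setdiff(unique(events$id), individuals$id)
  if (length(unknown)) {
    stop("events reference unknown individual id(s): ",
         paste(sort(unknown), collapse = ", "))
  }
  ok_src <- events$source %in% c("inpatient", "outpatient", "death")
  if (!all(ok_src)) {
    stop("unknown event source value(s): ",
         paste(unique(events$source[!ok_src]), collapse = ", "))
  }
  ok_code <- grepl("^[A-Z][0-9]{2}", events$outcome_code)
  if (!all(ok_code)) {
    stop("outcome codes must look like ICD-10 (letter + digits); offending: ",
         paste(unique(events$outcome_code[!ok_code]), collapse = ", "))
  }

  cause_cols <- setdiff(names(individuals), CORE_IND_COLS)
  for (cc in cause_cols) {
    v <- individuals[[cc]]
    if (!all(v %in% c(0, 1))) stop("cause column `", cc, "` must be 0/1")
    individuals[[cc]] <- as.integer(v)
  }
  ctrl <- individuals$group == "control"
  if (length(cause_cols) && any(ctrl)) {
    exp_ctrl <- as.matrix(individuals[ctrl, cause_cols, drop = FALSE])
    if (any(exp_ctrl != 0)) {
      stop("controls must have all cause exposures equal to 0")
    }
  }

  cause_class <- rep("treatment", length(cause_cols))
  names(cause_class) <- cause_cols
  if (!is.null(schema$causes)) {
    sc <- unlist(schema$causes)
    cause_class[names(sc)[names(sc) %in% cause_cols]] <- sc[names(sc) %in% cause_cols]
  }
  sexspec <- unlist(schema$sex_specific_outcomes) %||% character(0)
  outcome_codes <- sort(unique(substr(events$outcome_code, 1, 3)))
  outcomes <- tibble::tibble(
    outcome = outcome_codes,
    sex = ifelse(outcome_codes %in% names(sexspec),
                 unname(sexspec[outcome_codes]), "none"))

  rejected <- list(individuals = rejected_i, events = rejected_e)
  if (!quiet && (nrow(rejected_i) || nrow(rejected_e))) {
    message(nrow(rejected_i), " individual row(s) and ", nrow(rejected_e),
            " event row(s) rejected; see attr(, 'rejected')")
  }
  structure(
    list(individuals = individuals,
         events = events,
         causes = tibble::tibble(cause = cause_cols,
                                 class = unname(cause_class)),
         outcomes = outcomes,
         schema = schema),
    class = "cohort", rejected = rejected)
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", nrow(x$individuals), "individuals (",
      sum(x$individuals$group == "survivor"), "survivors,",
      sum(x$individuals$group == "control"), "controls ),",
      nrow(x$events), "events\n")
  cat("  causes:", nrow(x$causes), " outcomes:", nrow(x$outcomes), "\n")
  invisible(x)
}

#' Restrict a cohort's individuals
#' @noRd
filter_population <- function(individuals, population = "all", sex = NULL) {
  if (population == "survivors") {
    individuals <- individuals[individuals$group == "survivor", , drop = FALSE]
  } else if (population == "controls") {
    individuals <- individuals[individuals$group == "control", , drop = FALSE]
  }
  if (!is.null(sex) && sex != "none") {
    individuals <- individuals[individuals$sex == sex, , drop = FALSE]
  }
  individuals
}

#' Does an event code match an outcome under the plan's matching mode?
#' @noRd
code_matches <- function(codes, outcome, mode = "category") {
  if (mode == "chapter") {
    chapter_of(codes) == outcome
  } else if (mode == "prefix" || nchar(outcome) != 3) {
    startsWith(codes, outcome)
  } else {
    substr(codes, 1, 3) == outcome
  }
}

#' Time to first occurrence of an outcome within the observation window
#'
#' For each individual still under follow-up at window start, computes the
#' time in years from entry (index date + window offset, delayed to
#' `registry_start` when the plan sets one) to the first counted event
#' matching the outcome, or to the end of follow-up if none occurs
#' (censored). Events before entry -- including any in the 0.5-5 year
#' acute window -- do not count. Individuals whose follow-up ends at or
#' before entry are excluded from the risk set. Death censors observation
#' through `end_of_followup`; cause-of-death codes count as events when the
#' `death` source is included in the plan.
#'
#' @param cohort A [read_cohort()] object.
#' @param outcome_code Outcome to match (3-character ICD-10 category by
#'   default; a chapter label when `match = "chapter"`).
#' @param plan An [observation_plan()].
#' @param population `"all"`, `"survivors"` or `"controls"`.
#' @param sex Optionally restrict to `"male"` or `"female"`.
#' @param match Overrides the plan's code matching mode; `"chapter"`
#'   matches any code whose [chapter_of()] equals `outcome_code`.
#' @return A tibble with columns `id`, `time` (years at risk) and
#'   `observed` (logical), one row per individual in the risk set.
#' @export
first_occurrence <- function(cohort, outcome_code, plan = observation_plan(),
                             population = "all", sex = NULL, match = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  match <- match %||% plan$code_match
  ind <- filter_population(cohort$individuals, population, sex)
  entry <- add_years(ind$index_date, plan$window_start_offset)
  if (!is.null(plan$registry_start)) {
    entry <- pmax(entry, plan$registry_start)
  }
  at_risk <- ind$end_of_followup > entry
  ind <- ind[at_risk, , drop = FALSE]
  entry <- entry[at_risk]
  if (nrow(ind) == 0) {
    return(tibble::tibble(id = character(0), time = numeric(0),
                          observed = logical(0)))
  }
  ev <- cohort$events
  ev <- ev[ev$source %in% plan$source_filter &
             code_matches(ev$outcome_code, outcome_code, match) &
             ev$id %in% ind$id, , drop = FALSE]
  if (nrow(ev)) {
    # only events inside the individual's own window can be "first"
    i <- match(ev$id, ind$id)
    ev <- ev[ev$event_date >= entry[i] &
               ev$event_date <= ind$end_of_followup[i], , drop = FALSE]
  }
  fmap <- if (nrow(ev)) {
    first <- stats::aggregate(ev$event_date, by = list(id = ev$id), FUN = min)
    first$x[match(ind$id, first$id)]
  } else as.Date(rep(NA, nrow(ind)))
  in_window <- !is.na(fmap)
  time <- ifelse(in_window, years_between(entry, fmap),
                 years_between(entry, ind$end_of_followup))
  tibble::tibble(id = ind$id, time = as.numeric(time), observed = in_window)
}

#' Stratified sufficient statistics for a cause-outcome pair
#'
#' Collects the conditioning causes into a joint variable G; each observed
#' combination of their values defines one stratum (absent combinations are
#' omitted), split into the exposed and unexposed side by the cause flag.
#' Sufficient statistics come from [first_occurrence()] + [suff_stats()],
#' so summing (n, t) over strata and sides reproduces the unstratified
#' totals exactly.
#'
#' @param cohort A [read_cohort()] object.
#' @param cause Name of the exposure column under test.
#' @param conditioning_set Character vector of other exposure columns
#'   (must not contain `cause`).
#' @inheritParams first_occurrence
#' @return A tibble with columns `stratum`, `events_unexposed`,
#'   `time_unexposed`, `events_exposed`, `time_exposed`, ready for
#'   [delta_posterior()].
#' @export
stratify <- function(cohort, cause, conditioning_set = character(),
                     outcome_code, plan = observation_plan(),
                     population = "survivors", sex = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (cause %in% conditioning_set) {
    stop("`cause` must not be part of the conditioning set")
  }
  fo <- first_occurrence(cohort, outcome_code, plan, population, sex)
  ind <- cohort$individuals[, c("id", cause, conditioning_set), drop = FALSE]
  stratify_fo(dplyr::inner_join(fo, ind, by = "id"), cause, conditioning_set)
}

#' Stratum table from a precomputed risk-set table (internal fast path)
#' @noRd
stratify_fo <- function(fo, cause, conditioning_set = character()) {
  if (length(conditioning_set)) {
    g <- do.call(paste, c(fo[conditioning_set], sep = "/"))
  } else {
    g <- rep("all", nrow(fo))
  }
  x <- fo[[cause]]
  df <- tibble::tibble(g = g, x = x, time = fo$time, observed = fo$observed)
  out <- df |>
    dplyr::group_by(.data$g) |>
    dplyr::summarise(
      events_unexposed = sum(.data$observed[.data$x == 0]),
      time_unexposed = sum(.data$time[.data$x == 0]),
      events_exposed = sum(.data$observed[.data$x == 1]),
      time_exposed = sum(.data$time[.data$x == 1]),
      .groups = "drop") |>
    dplyr::arrange(.data$g) |>
    dplyr::rename(stratum = "g")
  out
}
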