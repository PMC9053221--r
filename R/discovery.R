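#' Configuration for causal discovery
#'
#' @param alpha_screen Significance level used both for screening marginal
#'   associations and for pruning by conditioning (default 0.01).
#' @param alpha_report Final reporting level; only links with p below this
#'   are flagged reportable (default 1e-4).
#' @param max_cond_size Optional cap on the conditioning-set size
#'   (default `Inf`: none).
#' @param population Population used for discovery (default survivors only;
#'   controls carry no exposures so including them only dilutes baselines).
#' @return A list of class `discovery_config`.
#' @export
discovery_config <- function(alpha_screen = 0.01, alpha_report = 1e-4,
                             max_cond_size = Inf,
                             population = c("survivors", "all")) {
  stopifnot(alpha_report > 0, alpha_report <= alpha_screen, alpha_screen < 1)
  structure(list(alpha_screen = alpha_screen,
                 alpha_report = alpha_report,
                 max_cond_size = max_cond_size,
                 population = match.arg(population)),
            class = "discovery_config")
}

#' Risk-set table with exposures for one outcome (internal)
#' @noRd
outcome_risk_set <- function(cohort, outcome, plan, config, sex = "none") {
  fo <- first_occurrence(cohort, outcome, plan,
                         population = config$population,
                         sex = if (sex == "none") NULL else sex)
  dplyr::inner_join(fo, cohort$individuals[, c("id", cohort$causes$cause)],
                    by = "id")
}

#' Step 1: screen all cause-outcome pairs for marginal association
#'
#' For every outcome, tests every candidate cause with the unconditional
#' (single-stratum) rate-difference test and keeps those with
#' p < `alpha_screen` and a positive expected rate difference -- the model
#' treats exposures as possible rate increases, so protective effects are
#' never causal candidates. Outcomes flagged sex-specific in the cohort's
#' catalogue are tested within the relevant sex only, and the restriction
#' is recorded on each candidate.
#'
#' @param cohort A [read_cohort()] object.
#' @param plan An [observation_plan()].
#' @param config A [discovery_config()].
#' @param causes,outcomes Optional subsets of the catalogues (default all).
#' @return A tibble of candidates: `outcome`, `cause`, `sex_restriction`,
#'   `p_unconditional`, `expected_delta`. The total number of screening
#'   tests is attached as attribute `n_tests`.
#' @export
screen_step1 <- function(cohort, plan = observation_plan(),
                         config = discovery_config(),
                         causes = NULL, outcomes = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  causes <- sort(causes %||% cohort$causes$cause)
  outcomes <- sort(outcomes %||% cohort$outcomes$outcome)
  n_tests <- 0L
  rows <- purrr::map(outcomes, function(oc) {
    sex <- outcome_sex(cohort, oc)
    fo <- outcome_risk_set(cohort, oc, plan, config, sex)
    if (nrow(fo) == 0 || sum(fo$observed) == 0) return(NULL)
    res <- purrr::map(causes, function(cs) {
      st <- stratify_fo(fo, cs)
      tst <- delta_test(st)
      n_tests <<- n_tests + 1L
      tibble::tibble(outcome = oc, cause = cs, sex_restriction = sex,
                     p_unconditional = tst$p_value,
                     expected_delta = tst$expected_delta,
                     informative = tst$informative)
    })
    dplyr::bind_rows(res)
  })
  all_rows <- dplyr::bind_rows(rows)
  out <- if (nrow(all_rows)) {
    dplyr::filter(all_rows,
                  .data$informative,
                  .data$p_unconditional < config$alpha_screen,
                  .data$expected_delta > 0) |>
      dplyr::select(-"informative")
  } else {
    tibble::tibble(outcome = character(0), cause = character(0),
                   sex_restriction = character(0),
                   p_unconditional = numeric(0), expected_delta = numeric(0))
  }
  attr(out, "n_tests") <- n_tests
  out
}

#' @noRd
outcome_sex <- function(cohort, outcome) {
  i <- match(outcome, cohort$outcomes$outcome)
  if (is.na(i)) "none" else cohort$outcomes$sex[i]
}

#' Step 2: prune indirect links by conditioning (order-independent)
#'
#' For each outcome, candidates from [screen_step1()] are re-tested while
#' conditioning on subsets of the other candidates, growing the subset size
#' s = 1, 2, ... All tests at level s use the candidate set as it stood
#' entering the level, and removals are applied in batch at level end
#' (PC-stable synchronization), which makes the result independent of the
#' order in which causes and outcomes are supplied. Faithfulness is
#' exploited throughout: conditioning only ever uses screened candidates.
#'
#' A candidate is removable at level s if some size-s subset of the other
#' remaining candidates drives its conditional p to `alpha_screen` or
#' above, flips its expected rate difference non-positive, or makes the
#' pooled posterior non-normalizable (perfectly correlated exposures; such
#' tests are treated as non-significant). Removable candidates whose every
#' explaining subset itself contains a removable candidate form mutual-
#' elimination clusters: these are reported as `ambiguous` with all
#' alternative explanations listed rather than silently dropped, since the
#' data cannot decide which of, say, two co-administered treatments is the
#' actual cause. Surviving candidates are `kept`, with `p_final` from
#' conditioning on the other kept causes of the same outcome; ambiguous
#' candidates get `p_final` conditioning on the kept causes only, since
#' their cluster partners are interchangeable explanations of a real
#' association, not confounders to control away.
#'
#' @param cohort A [read_cohort()] object.
#' @param candidates Output of [screen_step1()].
#' @inheritParams screen_step1
#' @return A `causal_links` tibble: `cause`, `outcome`, `sex_restriction`,
#'   `p_unconditional`, `p_final`, `expected_delta`,
#'   `expected_delta_per_1000py`, `significance_bin`, `reportable`,
#'   `status` (kept / removed / ambiguous), `explained_by` (the recorded
#'   explaining subset for removed links), `explaining_sets` (alternative
#'   minimal cause sets, `;`-separated, members joined by `+`; non-empty
#'   only for ambiguous links).
#' @export
prune_step2 <- function(cohort, candidates, plan = observation_plan(),
                        config = discovery_config()) {
  stopifnot(inherits(cohort, "cohort"))
  n_cond_tests <- 0L
  links <- purrr::map(sort(unique(candidates$outcome)), function(oc) {
    cand <- dplyr::filter(candidates, .data$outcome == oc) |>
      dplyr::arrange(.data$cause)
    sex <- cand$sex_restriction[1]
    fo <- outcome_risk_set(cohort, oc, plan, config, sex)
    test_cond <- function(cs, sub) {
      n_cond_tests <<- n_cond_tests + 1L
      delta_test(stratify_fo(fo, cs, sub))
    }
    active <- cand$cause
    status <- stats::setNames(rep("kept", length(active)), active)
    explained_by <- stats::setNames(rep("", length(active)), active)
    explaining_sets <- stats::setNames(rep("", length(active)), active)
    p_final <- stats::setNames(cand$p_unconditional, cand$cause)
    delta_final <- stats::setNames(cand$expected_delta, cand$cause)

    s <- 1L
    while (length(active) >= 2 && s <= min(length(active) - 1, config$max_cond_size)) {
      level_set <- active
      kills <- stats::setNames(vector("list", length(level_set)), level_set)
      kill_p <- stats::setNames(rep(NA_real_, length(level_set)), level_set)
      kill_d <- stats::setNames(rep(NA_real_, length(level_set)), level_set)
      for (x in level_set) {
        others <- setdiff(level_set, x)
        subs <- utils::combn(others, s, simplify = FALSE)
        for (sub in subs) {
          tst <- test_cond(x, sub)
          dead <- !tst$informative || tst$p_value >= config$alpha_screen ||
            tst$expected_delta <= 0
          if (dead) {
            kills[[x]] <- c(kills[[x]], list(sub))
            if (is.na(kill_p[x])) {
              kill_p[x] <- tst$p_value %||% NA_real_
              kill_d[x] <- tst$expected_delta %||% NA_real_
            }
          }
        }
      }
      killed <- names(kills)[lengths(kills) > 0]
      if (length(killed)) {
        for (x in killed) {
          # explaining subsets made entirely of candidates that survive this
          # level mean a genuine indirect path: plain removal
          clean <- purrr::keep(kills[[x]], ~ !any(.x %in% killed))
          if (length(clean)) {
            status[x] <- "removed"
            explained_by[x] <- paste(clean[[1]], collapse = "+")
          } else {
            # every explanation is itself eliminated here: mutual cluster
            status[x] <- "ambiguous"
            alts <- unique(c(list(x), kills[[x]]))
            alts <- alts[order(vapply(alts, paste, "", collapse = "+"))]
            explaining_sets[x] <- paste(
              vapply(alts, paste, "", collapse = "+"), collapse = ";")
          }
          p_final[x] <- kill_p[x]
          delta_final[x] <- kill_d[x]
        }
        active <- setdiff(active, killed)
      }
      s <- s + 1L
    }
    # final conditional p: kept links condition on the other kept causes;
    # ambiguous links condition on the kept causes only (their mutual
    # partners are interchangeable explanations, not confounders to control)
    for (x in c(active, names(status)[status == "ambiguous"])) {
      others <- setdiff(active, x)
      tst <- if (length(others)) test_cond(x, others) else
        tibble::tibble(p_value = cand$p_unconditional[cand$cause == x],
                       expected_delta = cand$expected_delta[cand$cause == x])
      p_final[x] <- tst$p_value
      delta_final[x] <- tst$expected_delta
    }
    tibble::tibble(
      cause = cand$cause, outcome = oc, sex_restriction = sex,
      p_unconditional = cand$p_unconditional,
      p_final = unname(p_final[cand$cause]),
      expected_delta = unname(delta_final[cand$cause]),
      status = unname(status[cand$cause]),
      explained_by = unname(explained_by[cand$cause]),
      explaining_sets = unname(explaining_sets[cand$cause]))
  })
  out <- dplyr::bind_rows(links)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      cause = character(0), outcome = character(0),
      sex_restriction = character(0), p_unconditional = numeric(0),
      p_final = numeric(0), expected_delta = numeric(0),
      status = character(0), explained_by = character(0),
      explaining_sets = character(0))
  }
  out <- out |>
    dplyr::mutate(
      expected_delta_per_1000py = .data$expected_delta * 1000,
      significance_bin = bin_significance(.data$p_final),
      reportable = .data$status %in% c("kept", "ambiguous") &
        !is.na(.data$p_final) & .data$p_final < config$alpha_report) |>
    dplyr::arrange(.data$outcome, .data$cause)
  structure(out,
            class = c("causal_links", class(out)),
            config = config,
            n_screen_tests = attr(candidates, "n_tests"),
            n_cond_tests = n_cond_tests)
}

#' Run both discovery steps
#'
#' @inheritParams screen_step1
#' @return A `causal_links` tibble; see [prune_step2()].
#' @export
discover_links <- function(cohort, plan = observation_plan(),
                           config = discovery_config(),
                           causes = NULL, outcomes = NULL) {
  cand <- screen_step1(cohort, plan, config, causes, outcomes)
  prune_step2(cohort, cand, plan, config)
}

#' Significance bins for reporting
#'
#' Lower-inclusive, upper-exclusive bins partitioning (0, 0.01):
#' `"<0.0001"` (the reportable bin), `"0.0001-0.001"`, `"0.001-0.01"`, and
#' `">=0.01"` for everything else (including exactly 0.01).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of bin labels.
#' @examples
#' bin_significance(c(0.005, 5e-5, 0.01))
#' @export
bin_significance <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 1e-4 ~ "<0.0001",
    p < 1e-3 ~ "0.0001-0.001",
    p < 1e-2 ~ "0.001-0.01",
    .default = ">=0.01")
}

#' Expected number of false-positive reported links
#'
#' The reporting level times the number of cause-outcome pairs whose final
#' significance is assessed against it (links surviving pruning as kept or
#' ambiguous).
#'
#' @param links A `causal_links` table from [prune_step2()].
#' @param config The [discovery_config()] used (default: taken from the
#'   table's attributes).
#' @return A single number.
#' @export
expected_false_positives <- function(links, config = NULL) {
  config <- config %||% attr(links, "config")
  config$alpha_report * sum(links$status %in% c("kept", "ambiguous"))
}

#' Write a link table as delimited text with a run-metadata header
#'
#' @param links A `causal_links` table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_links <- function(links, path) {
  config <- attr(links, "config")
  hdr <- c(
    "# ratelink causal link table",
    sprintf("# alpha_screen: %g", config$alpha_screen),
    sprintf("# alpha_report: %g", config$alpha_report),
    sprintf("# population: %s", config$population),
    sprintf("# screen_tests: %s", attr(links, "n_screen_tests") %||% NA),
    sprintf("# conditional_tests: %s", attr(links, "n_cond_tests") %||% NA),
    sprintf("# expected_false_positives: %g", expected_false_positives(links)))
  writeLines(hdr, path)
  readr::write_tsv(as.data.frame(links), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Status counts and error expectations for a link table
#'
#' @param x A `causal_links` table.
#' @param ... Unused.
#' @return One-row tibble: candidates, kept / removed / ambiguous counts,
#'   reportable count, expected false positives.
#' @method glance causal_links
#' @export
glance.causal_links <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x),
    n_kept = sum(x$status == "kept"),
    n_removed = sum(x$status == "removed"),
    n_ambiguous = sum(x$status == "ambiguous"),
    n_reportable = sum(x$reportable),
    expected_false_positives = expected_false_positives(x))
}
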