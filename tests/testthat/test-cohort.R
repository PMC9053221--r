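test_that("a well-formed table round-trips into a cohort with catalogues", {
  co <- tiny_cohort()
  expect_s3_class(co, "cohort")
  expect_equal(nrow(co$individuals), 4)
  expect_setequal(co$causes$cause, c("chemo", "radio"))
  expect_setequal(co$outcomes$outcome, c("H04", "J45"))
})

test_that("referential and schema violations are hard errors", {
  ind <- tibble::tibble(id = c("a", "a"), sex = "male", group = "survivor",
                        index_date = "2000-01-01",
                        end_of_followup = "2010-01-01")
  ev0 <- tibble::tibble(id = character(0), outcome_code = character(0),
                        event_date = as.Date(character(0)),
                        source = character(0))
  expect_error(read_cohort(ind, ev0), "duplicate")

  co_ind <- tibble::tibble(id = "a", sex = "male", group = "survivor",
                           index_date = "2000-01-01",
                           end_of_followup = "2010-01-01")
  bad_ev <- tibble::tibble(id = "zz", outcome_code = "H04",
                           event_date = "2007-01-01", source = "inpatient")
  expect_error(read_cohort(co_ind, bad_ev), "zz")

  ctrl <- tibble::tibble(id = "c1", sex = "male", group = "control",
                         index_date = "2000-01-01",
                         end_of_followup = "2010-01-01", chemo = 1L)
  expect_error(read_cohort(ctrl, ev0), "controls")
})

test_that("rows with missing ids or unparseable dates are rejected with a report", {
  ind <- tibble::tibble(id = c("a", NA, "b"), sex = "male", group = "survivor",
                        index_date = c("2000-01-01", "2000-01-01", "not-a-date"),
                        end_of_followup = "2010-01-01")
  ev <- tibble::tibble(id = "b", outcome_code = "H04",
                       event_date = "2007-01-01", source = "inpatient")
  expect_message(co <- read_cohort(ind, ev), "rejected")
  expect_equal(co$individuals$id, "a")
  rej <- attr(co, "rejected")
  expect_equal(nrow(rej$individuals), 2)
  expect_true("individual row rejected" %in% rej$events$reason)
})

test_that("an empty events table yields a cohort with everything censored", {
  ind <- tibble::tibble(id = "a", sex = "male", group = "survivor",
                        index_date = "2000-01-01",
                        end_of_followup = "2015-01-01")
  ev0 <- tibble::tibble(id = character(0), outcome_code = character(0),
                        event_date = as.Date(character(0)),
                        source = character(0))
  co <- read_cohort(ind, ev0, quiet = TRUE)
  expect_equal(nrow(co$events), 0)
  fo <- first_occurrence(co, "H04")
  expect_false(any(fo$observed))
})

test_that("first occurrence applies the observation window correctly", {
  co <- tiny_cohort()
  fo <- first_occurrence(co, "H04")
  # 'a': events at ~3y (acute window, ignored) and ~7.2y -> 2.2y past entry
  expect_equal(fo$time[fo$id == "a"], 2.2, tolerance = 0.01)
  expect_true(fo$observed[fo$id == "a"])
  # 'b': no H04 events, censored at end of follow-up
  expect_false(fo$observed[fo$id == "b"])
  entry_b <- as.Date("2000-01-01") + round(5 * 365.25)
  expect_equal(fo$time[fo$id == "b"],
               as.numeric(as.Date("2012-06-30") - entry_b) / 365.25)
  # 'c': only 4 years of follow-up -> excluded from the risk set
  expect_false("c" %in% fo$id)
})

test_that("registry start delays entry for source-restricted analyses", {
  ind <- tibble::tibble(id = "a", sex = "male", group = "survivor",
                        index_date = "1985-01-01",
                        end_of_followup = "2010-01-01")
  ev <- tibble::tibble(id = "a", outcome_code = "H04",
                       event_date = "1999-01-01", source = "outpatient")
  co <- read_cohort(ind, ev, quiet = TRUE)
  plan <- observation_plan(source_filter = "outpatient",
                           registry_start = "1997-01-01")
  fo <- first_occurrence(co, "H04", plan)
  # entry moves from 1990 to 1997; event is ~2y after entry
  expect_equal(fo$time, 2, tolerance = 0.01)
  expect_true(fo$observed)
})

test_that("first occurrence ignores event-row order and repeated codes", {
  co <- tiny_cohort()
  co2 <- co
  co2$events <- co2$events[rev(seq_len(nrow(co2$events))), ]
  fo1 <- dplyr::arrange(first_occurrence(co, "H04"), id)
  fo2 <- dplyr::arrange(first_occurrence(co2, "H04"), id)
  expect_identical(as.data.frame(fo1), as.data.frame(fo2))
})

test_that("restricting sources never increases event counts", {
  sim <- fixture_suite(7, "preindex_noise")[[1]]
  all_src <- observation_plan()
  inpat <- observation_plan(source_filter = "inpatient")
  n_all <- sum(first_occurrence(sim$cohort, "A08", all_src)$observed)
  n_in <- sum(first_occurrence(sim$cohort, "A08", inpat)$observed)
  expect_lte(n_in, n_all)
})

test_that("stratification enumerates observed strata and conserves totals", {
  sim <- fixture_suite(11, "confounded_pair")[[1]]
  co <- sim$cohort
  s0 <- stratify(co, "radiation", character(), "E03")
  expect_equal(nrow(s0), 1)
  s1 <- stratify(co, "radiation", "proxy", "E03")
  expect_equal(nrow(s1), 2)  # proxy is binary and both values occur
  # conservation of events and person-time
  expect_equal(sum(s1$events_unexposed) + sum(s1$events_exposed),
               s0$events_unexposed + s0$events_exposed)
  expect_equal(sum(s1$time_unexposed) + sum(s1$time_exposed),
               s0$time_unexposed + s0$time_exposed, tolerance = 1e-9)
  expect_error(stratify(co, "radiation", "radiation", "E03"), "conditioning")
})

test_that("conditioning on a perfect proxy empties one side of every stratum", {
  sim <- fixture_suite(13, "identical_pair")[[1]]
  st <- stratify(sim$cohort, "drug_a", "drug_b", "I42")
  one_sided <- (st$time_unexposed == 0) | (st$time_exposed == 0)
  expect_true(all(one_sided))
  # the pooled posterior is then near-flat between the two group rates, so
  # the conditional test cannot stay significant
  tst <- delta_test(st)
  expect_true(!tst$informative || tst$p_value > 0.01)
})
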