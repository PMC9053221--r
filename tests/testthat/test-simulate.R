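test_that("the same seed reproduces a cohort bit-exactly", {
  cfg <- fixture_suite(1, "confounded_pair")[[1]]$config
  a <- simulate_cohort(cfg, 123)
  b <- simulate_cohort(cfg, 123)
  expect_identical(as.data.frame(a$cohort$individuals),
                   as.data.frame(b$cohort$individuals))
  expect_identical(as.data.frame(a$cohort$events),
                   as.data.frame(b$cohort$events))
  c <- simulate_cohort(cfg, 124)
  expect_false(identical(as.data.frame(a$cohort$events),
                         as.data.frame(c$cohort$events)))
})

test_that("adding an outcome never perturbs the existing outcome's draws", {
  causes <- tibble::tibble(cause = "x", prevalence = 0.5)
  cfg1 <- sim_config(n_survivors = 400, causes = causes,
                     outcomes = tibble::tibble(outcome = "H04",
                                               base_rate = 0.03))
  cfg2 <- sim_config(n_survivors = 400, causes = causes,
                     outcomes = tibble::tibble(outcome = c("H04", "B34"),
                                               base_rate = c(0.03, 0.02)))
  e1 <- simulate_cohort(cfg1, 5)$cohort$events
  e2 <- simulate_cohort(cfg2, 5)$cohort$events
  h1 <- dplyr::filter(e1, substr(outcome_code, 1, 3) == "H04")
  h2 <- dplyr::filter(e2, substr(outcome_code, 1, 3) == "H04")
  expect_identical(as.data.frame(h1), as.data.frame(h2))
})

test_that("null configurations realize their base rates", {
  sim <- fixture_suite(51, "null")[[1]]
  fo <- first_occurrence(sim$cohort, "J45", population = "survivors")
  ss <- suff_stats(fo)
  rate <- ss$n_events / ss$total_time
  se <- sqrt(ss$n_events) / ss$total_time
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("planted additive increments are realized in the exposed group", {
  sim <- fixture_suite(52, "single_effect")[[1]]
  ind <- sim$cohort$individuals
  for (grp in list(c(0, 0.02), c(1, 0.07))) {
    ids <- ind$id[ind$alkylating == grp[1]]
    fo <- first_occurrence(sim$cohort, "H04")
    fo <- fo[fo$id %in% ids, ]
    ss <- suff_stats(fo)
    rate <- ss$n_events / ss$total_time
    se <- sqrt(ss$n_events) / ss$total_time
    expect_lt(abs(rate - grp[2]), 3 * se)
  }
})

test_that("two planted causes add up in doubly exposed individuals", {
  cfg <- sim_config(
    n_survivors = 4000,
    causes = tibble::tibble(cause = c("a", "b"), prevalence = c(0.5, 0.5)),
    outcomes = tibble::tibble(outcome = "H04", base_rate = 0.01),
    effects = tibble::tibble(cause = c("a", "b"), outcome = "H04",
                             delta = c(0.03, 0.04)),
    followup_years = 20)
  sim <- simulate_cohort(cfg, 53)
  ind <- sim$cohort$individuals
  both <- ind$id[ind$a == 1 & ind$b == 1]
  fo <- first_occurrence(sim$cohort, "H04")
  fo <- fo[fo$id %in% both, ]
  ss <- suff_stats(fo)
  rate <- ss$n_events / ss$total_time
  se <- sqrt(ss$n_events) / ss$total_time
  expect_lt(abs(rate - 0.08), 3 * se)
})

test_that("full co-assignment duplicates the exposure column exactly", {
  sim <- fixture_suite(54, "identical_pair")[[1]]
  ind <- sim$cohort$individuals
  expect_identical(ind$drug_a, ind$drug_b)
})

test_that("cohorts round-trip through the CSV schema", {
  sim <- fixture_suite(55, "sex_specific")[[1]]
  dir <- withr::local_tempdir()
  write_cohort(sim$cohort, dir)
  co2 <- read_cohort(file.path(dir, "individuals.csv"),
                     file.path(dir, "events.csv"),
                     file.path(dir, "schema.yaml"), quiet = TRUE)
  expect_equal(as.data.frame(sim$cohort$individuals),
               as.data.frame(co2$individuals))
  expect_equal(as.data.frame(sim$cohort$events),
               as.data.frame(co2$events))
  expect_equal(sim$cohort$outcomes, co2$outcomes)
  expect_equal(sim$cohort$causes, co2$causes)
})

test_that("the null fixture reports no links at the reporting level", {
  hits <- vapply(1:5, function(s) {
    sim <- fixture_suite(s, "null")[[1]]
    links <- discover_links(sim$cohort)
    sum(links$reportable)
  }, numeric(1))
  expect_equal(sum(hits), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(
    causes = tibble::tibble(cause = "x", prevalence = 1.5),
    outcomes = tibble::tibble(outcome = "H04", base_rate = 0.01)))
  expect_error(sim_config(
    causes = tibble::tibble(cause = "x", prevalence = 0.5),
    outcomes = tibble::tibble(outcome = "H04", base_rate = 0.01),
    effects = tibble::tibble(cause = "y", outcome = "H04", delta = 0.01)))
})
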