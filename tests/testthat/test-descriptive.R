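test_that("ICD-10 chapters map with the merged and split blocks", {
  expect_equal(chapter_of(c("H04", "B34", "A08", "D23", "D60",
                            "S12", "T80", "C53", "N71", "Z99")),
               c("H", "AB", "AB", "D'", "D''", "ST", "ST", "C", "N", "other"))
  expect_equal(chapter_of("H60"), "H")   # ear block folds into H
  expect_equal(chapter_of("bogus"), "other")
})

test_that("identical groups grade as not significant everywhere", {
  # controls are literal copies of the survivors (same dates and events),
  # so every chapter's statistics are exactly symmetric
  base <- fixture_suite(41, "null")[[1]]$cohort
  ind_s <- base$individuals
  ind_c <- ind_s
  ind_c$id <- paste0("c_", ind_c$id)
  ind_c$group <- "control"
  ind_c$exposure <- 0L
  ev_c <- base$events
  ev_c$id <- paste0("c_", ev_c$id)
  co <- read_cohort(dplyr::bind_rows(ind_s, ind_c),
                    dplyr::bind_rows(base$events, ev_c), quiet = TRUE)
  cmp <- compare_groups(co, "cohort", sources = "inpatient")
  expect_true(all(cmp$grade == "ns"))
  expect_true(all(cmp$p_value == 0.5))
})

test_that("a planted chapter excess is graded significant, others not", {
  cfg <- sim_config(
    n_survivors = 1000, n_controls = 3000,
    causes = tibble::tibble(cause = "treated", prevalence = 1),
    outcomes = tibble::tibble(outcome = c("H04", "J45", "K52"),
                              base_rate = c(0.01, 0.04, 0.03)),
    effects = tibble::tibble(cause = "treated", outcome = "H04",
                             delta = 0.02),  # rate ratio 3 in chapter H
    p_outpatient = 0)
  sim <- simulate_cohort(cfg, 42)
  cmp <- compare_groups(sim$cohort, "cohort", sources = "inpatient")
  expect_false(cmp$grade[cmp$chapter == "H"] == "ns")
  expect_gt(cmp$delta_pct_py[cmp$chapter == "H"], 0)
  expect_true(all(cmp$grade[cmp$chapter != "H"] == "ns"))
})

test_that("the larger group gets the narrower frequency posterior", {
  sim <- fixture_suite(43, "null")[[1]]
  co <- sim$cohort
  cfg <- sim_config(
    n_survivors = 500, n_controls = 2500,
    causes = tibble::tibble(cause = "x", prevalence = 0),
    outcomes = tibble::tibble(outcome = "J45", base_rate = 0.05))
  sim2 <- simulate_cohort(cfg, 44)
  cmp <- compare_groups(sim2$cohort, "cohort", sources = "inpatient")
  expect_lt(cmp$freq1_sd_pct_py, cmp$freq2_sd_pct_py)  # control sd < survivor sd
})

test_that("product-limit estimator handles the canonical hand cases", {
  # no deaths: survival identically 1 (no event rows)
  km0 <- kaplan_meier(c(3, 5, 7), c(FALSE, FALSE, FALSE))
  expect_equal(nrow(km0), 0)
  # censored at 1, deaths at 2 and 3: risk sets 2 then 1
  km <- kaplan_meier(c(1, 2, 3), c(FALSE, TRUE, TRUE))
  expect_equal(km$survival, c(1 / 2, 0))
  expect_equal(km$n_risk, c(2, 1))
  # everyone dies at once
  km1 <- kaplan_meier(rep(4, 10), rep(TRUE, 10))
  expect_equal(km1$survival, 0)
})

test_that("product-limit estimate matches the reference implementation", {
  skip_if_not_installed("survival")
  set.seed(77)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    tt <- round(rexp(n, 0.2), 2) + 0.01
    ev <- rbinom(n, 1, 0.7) == 1
    if (!any(ev)) next
    km <- kaplan_meier(tt, ev)
    sf <- survival::survfit(survival::Surv(tt, ev) ~ 1)
    ref <- summary(sf, times = km$time)
    expect_equal(km$survival, ref$surv, tolerance = 1e-12)
    expect_equal(km$n_risk, ref$n.risk)
  }
})

test_that("left truncation matches the reference on delayed-entry data", {
  skip_if_not_installed("survival")
  set.seed(78)
  for (i in 1:30) {
    n <- sample(5:30, 1)
    entry <- runif(n, 0, 2)
    tt <- entry + rexp(n, 0.3) + 0.01
    ev <- rbinom(n, 1, 0.8) == 1
    if (!any(ev)) next
    km <- kaplan_meier(tt, ev, entry = entry)
    sf <- survival::survfit(survival::Surv(entry, tt, ev) ~ 1)
    ref <- summary(sf, times = km$time)
    expect_equal(km$survival, ref$surv, tolerance = 1e-12)
  }
})

test_that("mortality curves separate a high-mortality group", {
  cfg <- sim_config(
    n_survivors = 1500, n_controls = 1500,
    causes = tibble::tibble(cause = "x", prevalence = 0),
    outcomes = tibble::tibble(outcome = "J45", base_rate = 0.001),
    followup_years = 25,
    mortality = list(survivor = 0.01, control = 0.002))
  sim <- simulate_cohort(cfg, 45)
  mc <- mortality_curves(sim$cohort, by = "group")
  tail_surv <- vapply(split(mc$survival, mc$stratum), min, numeric(1))
  expect_lt(tail_surv["survivor"], tail_surv["control"])
  expect_true(all(diff(mc$survival[mc$stratum == "survivor"]) <= 0))
})
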