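test_that("persons are conserved every cycle in both worlds", {
  p <- base_case()
  for (w in c("without", "with")) {
    led <- run_world(p, w)
    expect_equal(led$alive_end, led$alive_start - led$deaths, tolerance = 1e-12)
    n <- nrow(led)
    expect_equal(led$alive_start[-1], led$alive_end[-n] + led$entrants[-1],
                 tolerance = 1e-12)
    # prevalent pools and treated never exceed the living population
    expect_true(all(led$ph_prevalent <= led$alive_end + 1e-9))
    expect_true(all(led$ckd_prevalent <= led$alive_end + 1e-9))
    expect_true(all(led$treated <= led$alive_start + 1e-9))
    expect_true(all(led$life_years_ph <= led$life_years))
  }
})

test_that("a null treatment makes the two worlds identical", {
  p <- zero_uptake_params()
  wo <- run_world(p, "without")
  wi <- run_world(p, "with")
  expect_equal(as.data.frame(wo)[, setdiff(names(wo), "coverage")],
               as.data.frame(wi)[, setdiff(names(wi), "coverage")],
               tolerance = 1e-12)
})

test_that("a single closed cohort follows the geometric survival closed form", {
  lambda <- 0.01
  h <- 20
  p <- single_cohort_params(n0 = 6100, hazard = lambda, horizon = h)
  led <- run_world(p, "without")
  expect_equal(led$alive_end[h], 6100 * (1 - lambda)^h, tolerance = 1e-9)
  expect_equal(sum(led$deaths), 6100 * (1 - (1 - lambda)^h), tolerance = 1e-9)
  # half-cycle corrected person-years
  expected_ly <- 6100 * (1 - lambda / 2) * sum((1 - lambda)^(0:(h - 1)))
  expect_equal(sum(led$life_years), expected_ly, tolerance = 1e-9)
})

test_that("a two-year run matches independent spreadsheet arithmetic exactly", {
  sched <- c(`2023` = 220, `2024` = 275)
  p <- fixed_hazard_params(
    hazard = 0.02,
    population = list(prevalent_n0 = 1000, incident_n0 = 100,
                      incident_growth = 0),
    uptake = list(schedule_override = sched),
    engine = list(entrant_years = 2, seed_prevalence = FALSE),
    run = list(horizon_years = 2, end_year = 2025)
  )
  led <- run_world(p, "with")

  # independent scalar arithmetic ------------------------------------------
  f <- c(0.180, 0.195, 0.625)
  rr <- c(stroke = 0.59, PH = 0.43, CKD = 0.47)
  sig <- function(x) 1 / (1 + exp(-x))
  w_morb <- vapply(rr, function(r) {
    sum(f * c(1, 1 - (1 - r) * sig(0), 1 - (1 - r) * sig(25 * (1.3 - 0.9))))
  }, numeric(1))
  w_death <- 0.36
  rate <- vapply(c(stroke = 0.129, PH = 0.49, CKD = 0.266),
                 function(pr) 1 - (1 - pr)^(1 / 55), numeric(1))

  # 2023
  alive <- 1000 + 100
  cov <- 220 / alive
  md <- (1 - cov) + cov * w_death
  d1 <- alive * 0.02 * md
  ly1 <- alive - d1 / 2
  surv <- alive - d1
  mo <- (1 - cov) + cov * w_morb
  ev1 <- c(surv, surv, surv) * rate * mo
  ph_pool <- ev1[["PH"]]; ckd_pool <- ev1[["CKD"]]

  expect_equal(led$deaths[1], d1, tolerance = 1e-12)
  expect_equal(led$life_years[1], ly1, tolerance = 1e-12)
  expect_equal(led$stroke_incident[1], ev1[["stroke"]], tolerance = 1e-12)
  expect_equal(led$ph_prevalent[1], ph_pool, tolerance = 1e-12)

  # 2024
  alive <- surv + 100
  cov <- 275 / alive
  md <- (1 - cov) + cov * w_death
  d2 <- alive * 0.02 * md
  surv2 <- alive - d2
  ph_pool <- ph_pool * (1 - 0.02 * md)
  ckd_pool <- ckd_pool * (1 - 0.02 * md)
  mo <- (1 - cov) + cov * w_morb
  ev2 <- c(surv2, surv2 - ph_pool, surv2 - ckd_pool) * rate * mo
  ph_pool <- ph_pool + ev2[[2]]
  ckd_pool <- ckd_pool + ev2[[3]]

  expect_equal(led$deaths[2], d2, tolerance = 1e-12)
  expect_equal(led$ph_incident[2], ev2[[2]], tolerance = 1e-12)
  expect_equal(led$ckd_incident[2], ev2[[3]], tolerance = 1e-12)
  expect_equal(led$ph_prevalent[2], ph_pool, tolerance = 1e-12)
  expect_equal(led$ckd_prevalent[2], ckd_pool, tolerance = 1e-12)
  expect_equal(led$alive_end[2], surv2, tolerance = 1e-12)
})

test_that("the expected-value engine is linear in population size", {
  make <- function(scale) {
    fixed_hazard_params(
      hazard = 0.0097,
      population = list(prevalent_n0 = 6100 * scale,
                        incident_n0 = 300 * scale),
      uptake = list(schedule_override = NULL) # share-based uptake scales
    )
  }
  a <- run_world(make(1), "with")
  b <- run_world(make(3), "with")
  person_cols <- c("alive_start", "entrants", "treated", "deaths",
                   "stroke_incident", "ph_incident", "ckd_incident",
                   "ph_prevalent", "ckd_prevalent", "life_years", "alive_end")
  for (col in person_cols) {
    expect_equal(b[[col]], 3 * a[[col]], tolerance = 1e-9)
  }
  expect_equal(b$coverage, a$coverage, tolerance = 1e-12)
})

test_that("treatment dominance: with-world events never exceed without-world", {
  cmp <- compare_worlds(base_case())
  wo <- cmp$without
  wi <- cmp$with
  for (col in c("deaths", "stroke_incident", "ph_incident", "ckd_incident")) {
    expect_true(all(wi[[col]] <= wo[[col]] + 1e-9))
  }
  expect_true(all(wi$alive_end >= wo$alive_end - 1e-9))
  expect_gte(life_expectancy(wi), life_expectancy(wo))
})

test_that("mortality calibration hits the crude-rate target on the full engine", {
  p <- calibrate_mortality(base_case(), target = 0.00971)
  lambda <- p$mortality$annual_hazard
  expect_gt(lambda, 0.008)
  expect_lt(lambda, 0.012)
  led <- run_world(p, "without")
  expect_equal(sum(led$deaths) / sum(led$life_years), 0.00971,
               tolerance = 1e-6)
  # idempotence: recalibrating to the achieved crude rate returns the hazard
  achieved <- sum(led$deaths) / sum(led$life_years)
  p2 <- calibrate_mortality(p, target = achieved)
  expect_equal(p2$mortality$annual_hazard, lambda, tolerance = 1e-7)
  expect_error(calibrate_mortality(base_case(), target = 0),
               class = "scd_domain_error")
  expect_error(calibrate_mortality(base_case(), target = 1),
               class = "scd_domain_error")
})

test_that("life expectancy matches the closed form for a closed cohort", {
  lambda <- 0.05
  h <- 30
  p <- single_cohort_params(n0 = 1000, hazard = lambda, horizon = h)
  led <- run_world(p, "without")
  q <- (1 - lambda)^h
  ly <- (1 - lambda / 2) * (1 - q) / lambda
  expect_equal(life_expectancy(led, extrapolation = "none"), ly,
               tolerance = 1e-9)
  expect_equal(life_expectancy(led, extrapolation = "baseline_hazard"),
               ly + q / lambda, tolerance = 1e-9)
  # with a long horizon the extrapolated value approaches the exponential
  # mean 1/lambda (within the half-cycle correction)
  expect_lt(abs(life_expectancy(led, extrapolation = "baseline_hazard") -
                  1 / lambda), 0.5)
  # without treatment the effective-hazard mode reduces to the baseline one
  expect_equal(life_expectancy(led, extrapolation = "effective_hazard"),
               life_expectancy(led, extrapolation = "baseline_hazard"),
               tolerance = 1e-12)
})

test_that("comparison output is tidy and internally consistent", {
  cmp <- compare_worlds(base_case())
  td <- tidy(cmp)
  expect_tibble(td)
  expect_setequal(
    td$metric,
    c("deaths", "life_years", "life_expectancy", "strokes",
      "ph_prevalent_end", "ckd_prevalent_end", "ph_incident", "ckd_incident",
      "life_years_ph", "life_years_ckd")
  )
  expect_equal(td$impact, td$with - td$without, tolerance = 1e-12)
  expect_equal(td$percent, 100 * td$impact / td$without, tolerance = 1e-12)
  gl <- glance(cmp)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$deaths_percent,
               td$percent[td$metric == "deaths"], tolerance = 1e-12)
  long <- tidy(cmp$without)
  expect_setequal(unique(long$world), "without")
})
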