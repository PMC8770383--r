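test_that("anemia classification follows the age-sex cutoffs with strict inequality", {
  expect_true(classify_anemia(13.4, 59, "male"))    # cutoff 13.5
  expect_false(classify_anemia(13.4, 60, "male"))   # cutoff 12.0
  expect_false(classify_anemia(10.5, 65, "female")) # boundary is strict
  expect_true(classify_anemia(10.4, 65, "female"))
  expect_error(classify_anemia(NA, 50, "male"), "present")
  ## monotone: lowering hemoglobin never switches anemic -> non-anemic
  set.seed(1)
  for (i in 1:50) {
    age <- sample(20:85, 1); sex <- sample(c("male", "female"), 1)
    hb <- runif(1, 8, 16)
    if (classify_anemia(hb, age, sex))
      expect_true(classify_anemia(hb - runif(1, 0, 3), age, sex))
  }
})

test_that("exposure panel updates status with hemoglobin and age-band crossings", {
  idx <- as.Date("2015-06-01")
  cu <- function(dates, hb) data.frame(date = as.Date(dates), hb = hb)
  ## single checkup: panel of length 1, A_0 = baseline status
  p1 <- build_exposure_panel(cu("2015-06-01", 12.0), idx, 1960, "male")
  expect_equal(nrow(p1), 1L)
  expect_true(p1$anemia[1])
  ## exposure may switch off as hemoglobin recovers (male, age 55)
  p2 <- build_exposure_panel(cu(c("2015-06-01", "2016-06-01"), c(11.9, 13.9)),
                             idx, 1960, "male")
  expect_equal(as.integer(p2$anemia), c(1L, 0L))
  ## age-band crossing 59 -> 60 at constant Hb 12.5 flips status
  p3 <- build_exposure_panel(cu(c("2015-06-01", "2016-06-01"), c(12.5, 12.5)),
                             idx, 1956, "male")
  expect_equal(as.integer(p3$anemia), c(1L, 0L))
  expect_error(build_exposure_panel(cu("2015-06-01", NA), idx, 1960, "male"),
               "A_0")
})

entry_fixture <- function(index_egfr = 58, index_scr = 1.0) {
  data.frame(subject_id = "s1", index_date = as.Date("2015-01-01"),
             index_egfr = index_egfr, index_scr = index_scr,
             follow_up_end = as.Date("2020-01-01"),
             death_date = as.Date(NA), sex = "male",
             stringsAsFactors = FALSE)
}

no_claims <- data.frame(subject_id = character(0), date = as.Date(character(0)),
                        icd10 = character(0), record_type = character(0),
                        treatment_code = character(0), stringsAsFactors = FALSE)

test_that("renal composite fires at the earliest qualifying component", {
  e <- entry_fixture()
  ser <- function(days, egfr, scr = 1.0)
    data.frame(date = e$index_date + days, egfr = egfr, scr = scr)
  ## 30% rule: 40.0 <= 0.70 * 58 = 40.6 at month 18
  r <- derive_renal_outcome(e, ser(548, 40.0), no_claims)
  expect_equal(r$event, 1L); expect_equal(r$time_days, 548)
  expect_equal(r$component, "egfr_decline_30pct")
  ## 30% decline outside the 3-year window does not fire that component
  r2 <- derive_renal_outcome(e, ser(1200, 40.0), no_claims)
  expect_equal(r2$event, 0L)
  ## SCr doubling is inclusive at exactly 2x
  e2 <- entry_fixture(index_scr = 0.9)
  r3 <- derive_renal_outcome(e2, ser(400, 50, scr = 1.8), no_claims)
  expect_equal(r3$component, "scr_doubling")
  ## eGFR below 15 (outside the 3-year window, so only this component fires)
  r4 <- derive_renal_outcome(e, ser(1200, 14.9), no_claims)
  expect_equal(r4$component, "egfr_lt_15")
  ## dialysis claim
  dial <- data.frame(subject_id = "s1", date = e$index_date + 900,
                     icd10 = "N18.6", record_type = "inpatient",
                     treatment_code = "chronic_dialysis")
  r5 <- derive_renal_outcome(e, ser(300, 55), dial)
  expect_equal(r5$component, "dialysis"); expect_equal(r5$time_days, 900)
  ## censored when nothing fires
  r6 <- derive_renal_outcome(e, ser(c(365, 730), c(56, 55)), no_claims)
  expect_equal(r6$event, 0L)
  expect_equal(r6$time_days, as.numeric(e$follow_up_end - e$index_date))
  empty <- data.frame(date = as.Date(character(0)), egfr = numeric(0),
                      scr = numeric(0))
  expect_error(derive_renal_outcome(e, empty, no_claims), "post-index")
})

test_that("composite event time equals the minimum over components", {
  ## property check against per-component brute force on random fixtures
  set.seed(7)
  e <- entry_fixture()
  for (i in 1:20) {
    days <- sort(sample(30:1800, 5))
    egfr <- runif(5, 12, 60)
    scr <- runif(5, 0.8, 2.2)
    ser <- data.frame(date = e$index_date + days, egfr = egfr, scr = scr)
    r <- derive_renal_outcome(e, ser, no_claims)
    brute <- suppressWarnings(min(
      min(days[egfr <= 0.7 * e$index_egfr & days <= 1096]),
      min(days[scr >= 2 * e$index_scr]),
      min(days[egfr < 15])))
    if (is.finite(brute)) {
      expect_equal(r$time_days, brute)
      expect_equal(r$event, 1L)
    } else {
      expect_equal(r$event, 0L)
    }
  }
})

test_that("cardiovascular composite takes the first qualifying claim", {
  e <- entry_fixture()
  mk <- function(days, codes) data.frame(subject_id = "s1",
                                         date = e$index_date + days,
                                         icd10 = codes,
                                         record_type = "inpatient",
                                         treatment_code = NA)
  r <- derive_cv_outcome(e, mk(400, "I21.0"), load_code_map())
  expect_equal(r$event, 1L); expect_equal(r$time_days, 400)
  expect_equal(r$component, "mi")
  ## composite = first component: unstable angina at 100 beats MI at 300
  r2 <- derive_cv_outcome(e, mk(c(100, 300), c("I20.0", "I21.0")),
                          load_code_map())
  expect_equal(r2$time_days, 100); expect_equal(r2$component, "unstable_angina")
  ## no qualifying claims: censored at follow-up end
  r3 <- derive_cv_outcome(e, mk(200, "J44.9"), load_code_map())
  expect_equal(r3$event, 0L)
  ## death within 30 days of the claim marks the episode fatal
  e_fatal <- entry_fixture()
  e_fatal$death_date <- e_fatal$index_date + 420
  r4 <- derive_cv_outcome(e_fatal, mk(400, "I50.0"), load_code_map())
  expect_equal(r4$component, "fatal_heart_failure")
})

test_that("eGFR slope is the OLS slope per year", {
  expect_equal(egfr_slope(c(0, 365.25), c(60, 58)), -2, tolerance = 1e-12)
  expect_equal(egfr_slope(c(0, 200, 400, 600), rep(55, 4)), 0, tolerance = 1e-12)
  ## n = 2 always equals the closed-form two-point slope
  set.seed(2)
  for (i in 1:10) {
    d <- sort(sample(1:2000, 2)); y <- runif(2, 20, 70)
    expect_equal(egfr_slope(d, y),
                 (y[2] - y[1]) / ((d[2] - d[1]) / 365.25), tolerance = 1e-10)
  }
  ## noisy line, true slope -1.5: estimate within 3 SE
  set.seed(5)
  d <- (0:5) * 365.25
  reps <- replicate(200, {
    y <- 60 - 1.5 * d / 365.25 + rnorm(6, 0, 1)
    egfr_slope(d, y)
  })
  se_theory <- 1 / sqrt(sum((0:5 - 2.5)^2))
  expect_lt(abs(mean(reps) + 1.5), 3 * se_theory / sqrt(200))
  expect_error(egfr_slope(1, 60), ">= 2")
  expect_error(egfr_slope(c(1, 1), c(60, 61)), "spread")
})

test_that("slope differences translate to percent hazard changes", {
  expect_equal(slope_to_hazard(0), 0)
  expect_equal(slope_to_hazard(-0.75), 100 * (1 / 0.73 - 1), tolerance = 1e-12)
  expect_equal(round(slope_to_hazard(-0.75), 2), 36.99)
  expect_equal(round(slope_to_hazard(-0.7)), 34)
  ## positive slope difference lowers the hazard
  expect_lt(slope_to_hazard(0.75), 0)
})

test_that("prevalence reporter recomputes reported percentages", {
  expect_equal(prevalence_pct(1, 3, digits = 2), 33.33)
  expect_error(prevalence_pct(1, 0), "positive")
})
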