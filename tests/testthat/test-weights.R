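test_that("restricted cubic spline basis matches the published macro formula", {
  knots <- c(10, 80, 180, 300, 420)
  x <- seq(0, 500, length.out = 20)
  b <- rcs_basis(x, knots)
  expect_equal(colnames(b), c("t", "s1", "s2", "s3"))
  expect_equal(b[, 1], x)
  expect_lt(max(abs(b[, 2:4] - oracle_rcspline(x, knots))), 1e-10)
  ## nonlinear terms vanish at and below the first knot
  expect_equal(unname(rcs_basis(c(0, 5, 10), knots)[, 2:4]),
               matrix(0, 3, 3))
  ## linear beyond the last knot: vanishing second differences
  far <- rcs_basis(seq(2000, 2100, 10), knots)
  second_diff <- apply(far[, 2:4], 2, function(col) diff(diff(col)))
  expect_lt(max(abs(second_diff)), 1e-8)
  expect_error(rcs_basis(x, c(10, 5, 80, 300, 400)), "increasing")
  expect_error(rcs_basis(x, c(10, 20)), "3")
  expect_error(rcs_knots(x, 2), "3")
})

test_that("simple imputation applies median, mode and LOCF rules", {
  df <- data.frame(subject_id = rep(c("a", "b", "c"), each = 2),
                   k = rep(0:1, 3),
                   hba1c = c(5, NA, 6, 6.5, 7, 7),
                   smoke = c(TRUE, TRUE, FALSE, NA, TRUE, NA),
                   base = c(5, 5, NA, NA, 7, 7))
  ## no missing values: unchanged, empty log
  clean <- df[!is.na(df$hba1c) & !is.na(df$smoke) & !is.na(df$base), ]
  out0 <- simple_impute(clean)
  expect_identical(out0$data, clean)
  expect_equal(nrow(out0$log), 0L)
  ## baseline continuous: cohort median of observed {5, 7} -> 6
  out1 <- simple_impute(df, baseline_continuous = "base")
  expect_equal(out1$data$base[3], 6)
  ## time-varying: carried forward within subject
  out2 <- simple_impute(df, time_varying = c("hba1c", "smoke"))
  expect_equal(out2$data$hba1c[2], 5)      # LOCF from k = 0
  expect_equal(out2$data$smoke[4], FALSE)  # LOCF
  expect_true(all(c("locf") %in% out2$log$method))
  expect_error(simple_impute(data.frame(subject_id = "a", k = 0, x = NA),
                             baseline_continuous = "x"), "fully missing")
  expect_error(simple_impute(data.frame(subject_id = "a", k = 0, x = NA),
                             required = "x"), "required")
})

test_that("baseline stabilized weights center at 1 and match brute force", {
  ## covariates independent of exposure: weights -> 1
  set.seed(11)
  n <- 10000
  df <- data.frame(baseline_anemia = rbinom(n, 1, 0.2) == 1,
                   x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  w <- fit_baseline_ipw(df, covariates = c("x1", "x2"))$weights
  expect_lt(abs(mean(w) - 1), 0.02)
  expect_lt(sd(w), 0.1)
  ## hand-checkable 8-subject example: brute-force the two logistics
  df8 <- data.frame(baseline_anemia = c(1, 0, 1, 0, 1, 0, 1, 0) == 1,
                    x1 = c(1, 0.8, 0.2, -0.2, -0.5, 0.3, -1, 0.6),
                    x2 = c(1, 0, 1, 0, 1, 0, 0, 1))
  res <- fit_baseline_ipw(df8, covariates = c("x1", "x2"))
  num <- glm(baseline_anemia ~ 1, df8, family = binomial())
  den <- glm(baseline_anemia ~ x1 + x2, df8, family = binomial())
  a <- df8$baseline_anemia
  brute <- ifelse(a, fitted(num), 1 - fitted(num)) /
    ifelse(a, fitted(den), 1 - fitted(den))
  expect_equal(res$weights, brute, tolerance = 1e-10)
  ## separation is reported, not regularized
  sep <- data.frame(baseline_anemia = c(rep(TRUE, 5), rep(FALSE, 5)),
                    x1 = c(1:5, -(1:5)))
  expect_error(suppressWarnings(fit_baseline_ipw(sep, covariates = "x1")),
               "separation")
})

sim_pp <- function(n = 1500, seed = 41, ...) {
  sim_person_periods(simulate_cohort(sim_config(n_subjects = n, seed = seed,
                                                ...)), "renal")
}

test_that("identical numerator and denominator specs give weights exactly 1", {
  pp <- sim_pp(400)
  spec <- weight_spec(numerator = c("egfr", "egfr_lag"),
                      denominator = c("egfr", "egfr_lag"),
                      numerator_baseline = TRUE)
  w <- fit_time_varying_ipw(pp, spec)
  expect_equal(w$sw, rep(1, nrow(w)), tolerance = 1e-14)
})

test_that("a single-period panel reduces to the baseline point-exposure weight", {
  pp <- sim_pp(800)
  pp0 <- pp[pp$k == 0L, , drop = FALSE]
  spec <- weight_spec(denominator = c("egfr", "tx"), baseline = c("age", "sex"))
  w <- fit_time_varying_ipw(pp0, spec)
  base <- fit_baseline_ipw(
    transform(pp0, baseline_anemia = exposure == 1),
    covariates = c("age", "sex", "egfr", "tx"))
  expect_equal(w$sw, base$weights, tolerance = 1e-10)
})

test_that("stabilized weights are a running product and center near 1", {
  pp <- sim_pp(3000)
  spec <- weight_spec(denominator = c("egfr", "egfr_lag", "tx", "tx_lag"))
  w <- fit_time_varying_ipw(pp, spec)
  ## exact running-product identity within subject
  w <- w[order(w$subject_id, w$k), ]
  prev <- ave(w$sw, w$subject_id, FUN = function(x) c(1, x[-length(x)]))
  expect_equal(w$sw, prev * w$ratio, tolerance = 1e-12)
  ## per-period mean stabilized weight within 1 +/- 0.1
  per_k <- tapply(w$sw, w$k, mean)
  expect_true(all(abs(per_k - 1) < 0.1))
})

test_that("correctly specified weights balance confounders across exposure", {
  pp <- sim_pp(6000, seed = 47)
  spec <- weight_spec(denominator = c("egfr", "egfr_lag", "tx", "tx_lag"))
  w <- fit_time_varying_ipw(pp, spec)
  later <- w[w$k > 0, ]
  smd_w <- standardized_mean_difference(later$egfr_lag, later$exposure,
                                        later$sw)
  smd_u <- standardized_mean_difference(later$egfr_lag, later$exposure)
  expect_gt(smd_u, 0.3)   # heavily confounded before weighting
  expect_lt(smd_w, 0.1)   # balanced after weighting
})

test_that("weight truncation winsorizes at interpolated percentiles", {
  expect_equal(truncate_weights(rep(2, 10)), rep(2, 10))
  w <- as.numeric(1:100)
  tw <- truncate_weights(w, 1, 99)
  ## linear-interpolation percentile oracle: p99 of 1..100 = 1 + 0.99 * 99
  expect_equal(max(tw), 1 + 0.99 * 99)
  expect_equal(min(tw), 1 + 0.01 * 99)
  expect_true(all(order(tw) == order(w)))
  expect_lt(var(tw), var(w))
  set.seed(3); v <- rlnorm(500)
  expect_lt(var(truncate_weights(v, 5, 95)), var(truncate_weights(v, 1, 99)))
  expect_error(truncate_weights(v, 99, 1), "below")
  expect_error(truncate_weights(numeric(0)), "empty")
})

test_that("hemoglobin quintiles split evenly within sex", {
  set.seed(13)
  hb <- c(rnorm(500, 14.5, 1.3), rnorm(500, 13.0, 1.2))
  sex <- rep(c("male", "female"), each = 500)
  q <- hb_quintiles(hb, sex)
  expect_equal(as.integer(table(q[sex == "male"])), rep(100L, 5))
  expect_equal(as.integer(table(q[sex == "female"])), rep(100L, 5))
  ## lower hemoglobin, lower category
  expect_equal(q[which.min(hb)], 1L)
  expect_equal(q[which.max(hb[sex == "male"])], 5L)
})

test_that("two-category multinomial weights reproduce the binary fit", {
  pp <- sim_pp(700, seed = 19)
  spec_b <- weight_spec(denominator = c("egfr", "tx"))
  wb <- fit_time_varying_ipw(pp, spec_b)
  pp2 <- pp
  pp2$exposure <- pp$exposure + 1L
  pp2$exposure_lag <- pp$exposure_lag  # period-0 history stays 0
  spec_m <- weight_spec(denominator = c("egfr", "tx"), link = "multinomial")
  wm <- fit_quintile_weights(pp2, spec_m)
  expect_equal(wm$sw, wb$sw, tolerance = 1e-4)
  ## empty category cell is an error
  pp_bad <- pp2
  pp_bad$exposure[pp_bad$k == 0L] <- 2L
  expect_error(fit_quintile_weights(pp_bad, spec_m), "empty")
})
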