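#' Specification of a stabilized weight model
#'
#' Describes the pooled numerator and denominator models of the stabilized
#' inverse-probability weights. The numerator conditions on exposure history
#' and the smooth spline function of time only (the literal reading of the
#' stabilized-weight product formula); `numerator_baseline = TRUE` adds the
#' baseline covariates to the numerator, a common alternative. The
#' denominator adds the time-varying covariate set. Exposure history enters
#' as the single lag by default; `cumulative_history = TRUE` also adds the
#' running count of exposed periods.
#'
#' @param numerator Extra numerator covariates (usually none).
#' @param denominator Time-varying covariate columns of the denominator.
#' @param baseline Baseline covariate columns used by both models in the
#'   period-0 special case (and appended to the denominator throughout).
#' @param n_knots Spline knot count for the time intercept (>= 3, default 5).
#' @param link `"logistic"` (binary exposure) or `"multinomial"` (quintile).
#' @param truncation Optional `c(lower, upper)` percentiles for weight
#'   truncation, e.g. `c(1, 99)`.
#' @param numerator_baseline Add baseline covariates to the numerator.
#' @param cumulative_history Add the cumulative exposed-period count to the
#'   history summary.
#' @return list of class `"weight_spec"`.
#' @export
weight_spec <- function(numerator = character(0),
                        denominator = character(0),
                        baseline = c("age", "sex"),
                        n_knots = 5,
                        link = c("logistic", "multinomial"),
                        truncation = NULL,
                        numerator_baseline = FALSE,
                        cumulative_history = FALSE) {
  link <- match.arg(link)
  if (n_knots < 3) stopf("n_knots must be >= 3")
  if (!all(numerator %in% denominator))
    stopf("denominator covariates must be a superset of numerator covariates")
  if (!is.null(truncation) && truncation[1L] >= truncation[2L])
    stopf("lower truncation percentile must be below the upper")
  structure(list(numerator = numerator, denominator = denominator,
                 baseline = baseline, n_knots = n_knots, link = link,
                 truncation = truncation,
                 numerator_baseline = numerator_baseline,
                 cumulative_history = cumulative_history),
            class = "weight_spec")
}

## probability of the observed binary exposure under a fitted logistic model
prob_observed <- function(p1, a) ifelse(a == 1, p1, 1 - p1)

check_probs <- function(p, what) {
  bad <- which(!is.finite(p) | p <= 0)
  if (length(bad))
    stopf("%s produced non-positive predicted probability at rows: %s",
          what, paste(utils::head(bad, 5), collapse = ", "))
  invisible(p)
}

check_separation <- function(fit, what) {
  p <- stats::fitted(fit)
  if (!fit$converged || any(p < 1e-10) || any(p > 1 - 1e-10))
    stopf(paste0("apparent separation in the %s model (fitted probabilities ",
                 "at the boundary); refine the covariate set rather than ",
                 "regularizing"), what)
  invisible(fit)
}

#' Baseline (point-exposure) stabilized weights
#'
#' Stabilized inverse-probability weight for a point exposure:
#' `P(A = a_i) / P(A = a_i | covariates)`, the marginal probability from an
#' intercept-only logistic model over the conditional probability from the
#' full logistic model. The mean stabilized weight is ~1 on any successful
#' fit. Apparent separation raises an error; it is never silently
#' regularized.
#'
#' @param data Cohort table.
#' @param exposure Name of the binary exposure column.
#' @param covariates Baseline covariate column names.
#' @return list(weights, numerator_fit, denominator_fit).
#' @export
fit_baseline_ipw <- function(data, exposure = "baseline_anemia",
                             covariates) {
  a <- as.integer(data[[exposure]])
  num <- stats::glm(a ~ 1, family = stats::binomial())
  den <- stats::glm(stats::reformulate(covariates, response = "a"),
                    data = cbind(data, a = a), family = stats::binomial())
  check_separation(den, "denominator")
  p_num <- prob_observed(stats::fitted(num), a)
  p_den <- check_probs(prob_observed(stats::fitted(den), a), "denominator")
  list(weights = p_num / p_den, numerator_fit = num, denominator_fit = den)
}

## design matrix for a pooled weight model: history + spline time (+ covs)
pooled_design <- function(pp, spec, covariates, knots, with_baseline) {
  parts <- list(exposure_lag = pp$exposure_lag)
  if (spec$cumulative_history) parts$exposure_cum <- pp$exposure_cum
  basis <- rcs_basis(pp$start_day, knots)
  out <- cbind(as.data.frame(parts), as.data.frame(basis))
  covs <- covariates
  if (with_baseline) covs <- unique(c(covs, spec$baseline))
  for (v in covs) out[[v]] <- pp[[v]]
  out
}

fit_pooled_logit <- function(y, design, what) {
  df <- cbind(data.frame(.y = y), design)
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  check_separation(fit, what)
  fit
}

#' Time-varying stabilized weights from pooled logistic models
#'
#' Implements the stabilized-weight product: for each subject i and period k,
#' `sw_ik` is the cumulative product over periods 0..k of the ratio of the
#' numerator predicted probability of the observed exposure (given exposure
#' history and the restricted-cubic-spline function of time) to the
#' denominator predicted probability (the same plus the time-varying
#' covariate history). In the period-0 special case both models use baseline
#' covariates alone: an intercept-only numerator and a denominator logistic
#' on the baseline covariate set. When the numerator and denominator
#' covariate sets coincide a single model is fitted and used in both roles,
#' making every weight exactly 1.
#'
#' @param pp Person-period table with columns `subject_id`, `k`,
#'   `start_day`, `exposure`, `exposure_lag` and the covariates named in
#'   `spec`; one row per subject-period, `k` starting at 0.
#' @param spec A [weight_spec()].
#' @return `pp` with columns `p_num`, `p_den`, `ratio`, `sw` appended, plus
#'   attribute `"fits"` carrying the four fitted models.
#' @export
fit_time_varying_ipw <- function(pp, spec) {
  stopifnot(inherits(spec, "weight_spec"))
  pp <- pp[order(pp$subject_id, pp$k), , drop = FALSE]
  if (spec$cumulative_history && is.null(pp$exposure_cum)) {
    pp$exposure_cum <- stats::ave(pp$exposure_lag, pp$subject_id, FUN = cumsum)
  }
  a <- as.integer(pp$exposure)
  k0 <- pp$k == 0L
  identical_sets <- setequal(spec$numerator, spec$denominator) &&
    spec$numerator_baseline

  ## period 0: baseline covariates alone
  base_covs <- unique(c(spec$baseline, spec$denominator[spec$denominator %in% names(pp)]))
  den0 <- stats::glm(stats::reformulate(base_covs, response = ".y"),
                     data = cbind(data.frame(.y = a[k0]), pp[k0, , drop = FALSE]),
                     family = stats::binomial())
  check_separation(den0, "period-0 denominator")
  num0 <- if (identical_sets) den0 else
    stats::glm(a[k0] ~ 1, family = stats::binomial())

  p_num <- p_den <- numeric(nrow(pp))
  p_num[k0] <- prob_observed(stats::fitted(num0), a[k0])
  p_den[k0] <- prob_observed(stats::fitted(den0), a[k0])

  ## later periods: pooled over k >= 1 with the spline time intercept
  if (any(!k0)) {
    later <- pp[!k0, , drop = FALSE]
    knots <- rcs_knots(later$start_day, spec$n_knots)
    den_design <- pooled_design(later, spec, spec$denominator, knots,
                                with_baseline = TRUE)
    den_fit <- fit_pooled_logit(a[!k0], den_design, "denominator")
    if (identical_sets) {
      num_fit <- den_fit
      p1 <- stats::predict(den_fit, type = "response")
      p_num[!k0] <- p_den[!k0] <- prob_observed(p1, a[!k0])
    } else {
      num_design <- pooled_design(later, spec, spec$numerator, knots,
                                  with_baseline = spec$numerator_baseline)
      num_fit <- fit_pooled_logit(a[!k0], num_design, "numerator")
      p_num[!k0] <- prob_observed(stats::fitted(num_fit), a[!k0])
      p_den[!k0] <- prob_observed(stats::fitted(den_fit), a[!k0])
    }
  } else {
    den_fit <- num_fit <- NULL
  }
  check_probs(p_num, "numerator")
  check_probs(p_den, "denominator")

  pp$p_num <- p_num
  pp$p_den <- p_den
  pp$ratio <- p_num / p_den
  pp$sw <- stats::ave(pp$ratio, pp$subject_id, FUN = cumprod)
  if (!is.null(spec$truncation)) {
    pp$sw <- truncate_weights(pp$sw, spec$truncation[1L], spec$truncation[2L])
  }
  attr(pp, "fits") <- list(numerator0 = num0, denominator0 = den0,
                           numerator = num_fit, denominator = den_fit)
  pp
}

#' Winsorize stabilized weights at empirical percentiles
#'
#' Replaces weights above the upper percentile with the percentile value and
#' weights below the lower percentile with that value (linear-interpolation
#' percentile definition). Order-preserving; contracts the weight spread.
#'
#' @param w Positive weights.
#' @param lower_pct,upper_pct Percentiles (defaults 1 and 99).
#' @return Truncated weights.
#' @export
truncate_weights <- function(w, lower_pct = 1, upper_pct = 99) {
  if (length(w) == 0L) stopf("empty weight vector")
  if (lower_pct >= upper_pct) stopf("lower percentile must be below upper")
  q <- stats::quantile(w, c(lower_pct, upper_pct) / 100, type = 7, names = FALSE)
  pmin(pmax(w, q[1L]), q[2L])
}

#' Sex-specific hemoglobin quintile categories
#'
#' Computes quintile boundaries of baseline hemoglobin within each sex and
#' assigns categories 1 (lowest) to 5 (highest, the reference group in the
#' quintile-exposure analyses).
#'
#' @param hb Hemoglobin values to categorize.
#' @param sex `"male"` / `"female"`, aligned with `hb`.
#' @param baseline_hb,baseline_sex Values defining the boundaries (default:
#'   `hb` and `sex` themselves, i.e. baseline).
#' @return Integer vector in 1..5.
#' @export
hb_quintiles <- function(hb, sex, baseline_hb = hb, baseline_sex = sex) {
  sex <- match_sex(sex); baseline_sex <- match_sex(baseline_sex)
  out <- integer(length(hb))
  for (s in unique(sex)) {
    br <- stats::quantile(baseline_hb[baseline_sex == s], 0:5 / 5, type = 7,
                          names = FALSE)
    br[1L] <- -Inf; br[6L] <- Inf
    out[sex == s] <- cut(hb[sex == s], breaks = br, labels = FALSE,
                         include.lowest = TRUE)
  }
  out
}

multinom_prob_observed <- function(fit, newdata, y, levels) {
  pr <- stats::predict(fit, newdata = newdata, type = "probs")
  if (is.null(dim(pr))) {  # two-level degenerate case: P(second level)
    pr <- cbind(1 - pr, pr)
    colnames(pr) <- levels
  }
  p <- pr[cbind(seq_along(y), match(as.character(y), colnames(pr)))]
  p
}

#' Time-varying stabilized weights for a categorical (quintile) exposure
#'
#' The multinomial analogue of [fit_time_varying_ipw()]: numerator and
#' denominator are pooled multinomial logistic models of the exposure
#' category (hemoglobin quintile) on exposure history and the spline time
#' intercept, the denominator adding the time-varying covariates; `sw` is
#' the cumulative product of probability ratios of the observed category.
#'
#' @param pp Person-period table whose `exposure` column is an integer
#'   category (1..m); `exposure_lag` is the prior category (0 at period 0).
#' @param spec A [weight_spec()] with `link = "multinomial"`.
#' @return `pp` with `p_num`, `p_den`, `ratio`, `sw` appended.
#' @export
fit_quintile_weights <- function(pp, spec) {
  stopifnot(inherits(spec, "weight_spec"))
  if (spec$link != "multinomial") stopf("spec$link must be 'multinomial'")
  pp <- pp[order(pp$subject_id, pp$k), , drop = FALSE]
  y <- factor(pp$exposure)
  if (any(table(y[pp$k == 0L]) == 0L)) stopf("empty exposure category cell")
  lev <- levels(y)
  k0 <- pp$k == 0L

  quiet_multinom <- function(formula, data) {
    fit <- nnet::multinom(formula, data = data, trace = FALSE, maxit = 500)
    if (fit$convergence != 0) stopf("multinomial weight model did not converge")
    fit
  }
  base_covs <- unique(c(spec$baseline,
                        spec$denominator[spec$denominator %in% names(pp)]))
  d0 <- cbind(data.frame(.y = y[k0]), pp[k0, , drop = FALSE])
  den0 <- quiet_multinom(stats::reformulate(base_covs, response = ".y"), d0)
  num0 <- quiet_multinom(.y ~ 1, d0)
  p_num <- p_den <- numeric(nrow(pp))
  p_num[k0] <- multinom_prob_observed(num0, d0, y[k0], lev)
  p_den[k0] <- multinom_prob_observed(den0, d0, y[k0], lev)

  if (any(!k0)) {
    later <- pp[!k0, , drop = FALSE]
    knots <- rcs_knots(later$start_day, spec$n_knots)
    basis <- as.data.frame(rcs_basis(later$start_day, knots))
    hist_df <- data.frame(exposure_lag = factor(later$exposure_lag))
    den_df <- cbind(data.frame(.y = y[!k0]), hist_df, basis,
                    later[, unique(c(spec$denominator, spec$baseline)),
                          drop = FALSE])
    num_df <- cbind(data.frame(.y = y[!k0]), hist_df, basis,
                    later[, spec$numerator, drop = FALSE])
    den_fit <- quiet_multinom(.y ~ ., den_df)
    num_fit <- quiet_multinom(.y ~ ., num_df)
    p_num[!k0] <- multinom_prob_observed(num_fit, num_df, y[!k0], lev)
    p_den[!k0] <- multinom_prob_observed(den_fit, den_df, y[!k0], lev)
  }
  check_probs(p_num, "numerator")
  check_probs(p_den, "denominator")
  pp$p_num <- p_num; pp$p_den <- p_den
  pp$ratio <- p_num / p_den
  pp$sw <- stats::ave(pp$ratio, pp$subject_id, FUN = cumprod)
  if (!is.null(spec$truncation))
    pp$sw <- truncate_weights(pp$sw, spec$truncation[1L], spec$truncation[2L])
  pp
}
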