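#' Weighted Cox model with cluster-robust sandwich variance
#'
#' Maximizes the weighted Cox partial likelihood (Breslow tie handling by
#' default, Efron available) and returns the coefficients, the robust
#' sandwich covariance clustered by subject — accounting for the correlation
#' induced by weighting — and the weighted Breslow cumulative baseline
#' hazard. For the marginal structural model the design is the time-updated
#' exposure alone on (start, stop] person-period intervals; for the baseline
#' risk model it is baseline exposure plus the baseline covariate set.
#'
#' @param formula A `survival::Surv()` formula, e.g.
#'   `Surv(start_day, end_day, event) ~ exposure`.
#' @param data Model data, one row per subject(-period).
#' @param weights Positive case weights (default 1).
#' @param cluster Subject identifier for the sandwich variance (column name
#'   or vector); defaults to `subject_id` when present.
#' @param ties `"breslow"` (default, consistent with the Breslow baseline
#'   hazard) or `"efron"`.
#' @return Object of class `"msm_coxfit"`: `coefficients` (log-HRs),
#'   `robust_var`, `naive_var`, `baseline_cumhaz` (step function, see
#'   [breslow_cumhaz()]), `n_subjects`, `n_events`, `ties`, and the
#'   underlying `coxph` fit.
#' @export
fit_weighted_cox <- function(formula, data, weights = NULL, cluster = NULL,
                             ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (is.null(weights)) weights <- rep(1, nrow(data))
  if (any(weights <= 0)) stopf("weights must be positive")
  cl <- cluster %||% if ("subject_id" %in% names(data)) "subject_id" else NULL
  cl_vec <- if (is.character(cl) && length(cl) == 1L) data[[cl]] else cl
  data$.w <- weights
  ## anchor the formula here so downstream re-evaluation (survfit/basehaz)
  ## finds the fitting data rather than whatever the caller's frame holds
  environment(formula) <- environment()
  if (!is.null(cl_vec)) {
    data$.cl <- cl_vec
    fit <- survival::coxph(formula, data = data, weights = .w,
                           cluster = .cl, ties = ties, x = TRUE, y = TRUE,
                           control = survival::coxph.control(eps = 1e-10,
                                                             iter.max = 100))
  } else {
    fit <- survival::coxph(formula, data = data, weights = .w, robust = TRUE,
                           ties = ties, x = TRUE, y = TRUE,
                           control = survival::coxph.control(eps = 1e-10,
                                                             iter.max = 100))
  }
  if (!is.null(fit$info) && any(grepl("infinite", fit$info))) {
    warning("monotone likelihood suspected: a coefficient may be diverging")
  }
  sm <- summary(fit)
  yy <- fit$y
  lp <- as.numeric(fit$x %*% stats::coef(fit))
  ch <- if (ncol(yy) == 3L) {
    breslow_cumhaz(yy[, 1L], yy[, 2L], yy[, 3L], lp, weights)
  } else {
    breslow_cumhaz(rep(0, nrow(yy)), yy[, 1L], yy[, 2L], lp, weights)
  }
  structure(list(coefficients = stats::coef(fit),
                 robust_var = fit$var,
                 naive_var = fit$naive.var %||% fit$var,
                 baseline_cumhaz = ch,
                 n_subjects = if (!is.null(cl_vec)) length(unique(cl_vec)) else fit$n,
                 n_events = fit$nevent,
                 ties = ties,
                 summary = sm,
                 cox = fit),
            class = "msm_coxfit")
}

#' @export
print.msm_coxfit <- function(x, ...) {
  cat(sprintf("Weighted Cox fit (%s ties): %d subjects, %d events\n",
              x$ties, x$n_subjects, x$n_events))
  se <- sqrt(diag(as.matrix(x$robust_var)))
  est <- x$coefficients
  tab <- data.frame(logHR = est, HR = exp(est), robust_se = se,
                    lower95 = exp(est - 1.96 * se),
                    upper95 = exp(est + 1.96 * se))
  print(round(tab, 4))
  invisible(x)
}

#' Weighted Breslow cumulative baseline hazard
#'
#' Nonparametric estimator of the cumulative baseline hazard of a (weighted)
#' Cox model: at each distinct event time the increment is the weighted
#' number of events divided by the weighted risk-set sum of
#' `exp(linear predictor)`. A non-decreasing step function with jumps only
#' at event times and value 0 at time 0.
#'
#' @param start,stop,event Counting-process interval and event indicator
#'   (use `start = 0` for single-record data).
#' @param lp Linear predictor per row (uncentered).
#' @param w Case weights.
#' @return data.frame(time, cumhaz) at the distinct event times.
#' @export
breslow_cumhaz <- function(start, stop, event, lp, w = rep(1, length(stop))) {
  dt <- sort(unique(stop[event == 1]))
  ew <- w * exp(lp)
  inc <- vapply(dt, function(s) {
    at_risk <- start < s & stop >= s
    sum(w[event == 1 & stop == s]) / sum(ew[at_risk])
  }, numeric(1))
  data.frame(time = dt, cumhaz = cumsum(inc))
}

step_cumhaz <- function(ch, times) {
  stats::approx(c(0, ch$time), c(0, ch$cumhaz), xout = times,
                method = "constant", rule = 2, f = 0)$y
}

#' Counterfactual survival curves under the always/never-exposed regimes
#'
#' From a fitted marginal structural Cox model with the time-updated
#' exposure as sole design term, forms `S(t | regime a) =
#' exp(-Lambda0(t) * exp(beta * a))` with `Lambda0` the weighted Breslow
#' cumulative baseline hazard: the survival curve of the pseudo-population
#' had everyone been continuously exposed (`a = 1`) or never exposed
#' (`a = 0`).
#'
#' @param fit A [fit_weighted_cox()] result whose first coefficient is the
#'   exposure.
#' @param times Evaluation times (default: the event times of the fit).
#' @return data.frame(regime, time, survival) of class `"regime_curves"`.
#' @export
breslow_curves <- function(fit, times = NULL) {
  stopifnot(inherits(fit, "msm_coxfit"))
  beta <- fit$coefficients[1L]
  times <- times %||% fit$baseline_cumhaz$time
  ch <- step_cumhaz(fit$baseline_cumhaz, times)
  out <- rbind(
    data.frame(regime = "always_exposed", time = times,
               survival = exp(-ch * exp(beta))),
    data.frame(regime = "never_exposed", time = times,
               survival = exp(-ch))
  )
  class(out) <- c("regime_curves", class(out))
  out
}

#' Bootstrap confidence bands for regime survival curves
#'
#' Subject-level nonparametric bootstrap: subjects are resampled with
#' replacement, the stabilized weights and the marginal structural Cox model
#' are refitted on each replicate, and percentile intervals are taken at
#' each requested time. Replicates with zero events are redrawn.
#'
#' @param pp Person-period table (input of [fit_time_varying_ipw()]).
#' @param spec A [weight_spec()].
#' @param times Evaluation times (days from index).
#' @param reps Bootstrap replicates (default 200).
#' @param seed Integer seed.
#' @param conf_level Confidence level (default 0.95).
#' @return data.frame(regime, time, survival, ci_lower, ci_upper).
#' @export
boot_regime_curves <- function(pp, spec, times, reps = 200, seed = 1,
                               conf_level = 0.95) {
  wpp <- fit_time_varying_ipw(pp, spec)
  fit <- fit_weighted_cox(survival::Surv(start_day, end_day, event) ~ exposure,
                          data = wpp, weights = wpp$sw)
  point <- breslow_curves(fit, times)
  ids <- unique(pp$subject_id)
  by_id <- split(seq_len(nrow(pp)), pp$subject_id)
  set.seed(seed)
  draws <- array(NA_real_, c(reps, length(times), 2L))
  r <- 1L
  while (r <= reps) {
    take <- sample(ids, length(ids), replace = TRUE)
    rows <- unlist(by_id[as.character(take)], use.names = FALSE)
    bpp <- pp[rows, , drop = FALSE]
    bpp$subject_id <- rep(seq_along(take),
                          lengths(by_id[as.character(take)]))
    if (sum(bpp$event) == 0L) next
    est <- try({
      bw <- fit_time_varying_ipw(bpp, spec)
      bf <- fit_weighted_cox(survival::Surv(start_day, end_day, event) ~ exposure,
                             data = bw, weights = bw$sw)
      breslow_curves(bf, times)
    }, silent = TRUE)
    if (inherits(est, "try-error")) next
    draws[r, , 1L] <- est$survival[est$regime == "always_exposed"]
    draws[r, , 2L] <- est$survival[est$regime == "never_exposed"]
    r <- r + 1L
  }
  alpha <- (1 - conf_level) / 2
  qs <- apply(draws, c(2L, 3L), stats::quantile, probs = c(alpha, 1 - alpha))
  point$ci_lower <- c(qs[1L, , 1L], qs[1L, , 2L])
  point$ci_upper <- c(qs[2L, , 1L], qs[2L, , 2L])
  point
}

#' (Weighted) Kaplan-Meier estimator
#'
#' Product-limit estimator with case weights entering both the risk sets and
#' the event counts, with Greenwood-type variance (via
#' [survival::survfit()]). Used for the descriptive comparison of unweighted
#' and weighted survival by baseline anemia status.
#'
#' @param time,event Follow-up time and event indicator.
#' @param group Optional group labels (e.g. baseline anemia).
#' @param weights Optional case weights.
#' @param conf_level Confidence level (default 0.95).
#' @return data.frame(group, time, n_risk, surv, ci_lower, ci_upper).
#' @export
km_estimator <- function(time, event, group = NULL, weights = NULL,
                         conf_level = 0.95) {
  df <- data.frame(time = time, event = event,
                   group = if (is.null(group)) "all" else as.character(group))
  df$.w <- if (is.null(weights)) rep(1, nrow(df)) else weights
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df,
                          weights = .w, conf.int = conf_level,
                          conf.type = "log")
  strata <- if (is.null(sf$strata)) rep("group=all", length(sf$time)) else
    rep(names(sf$strata), sf$strata)
  data.frame(group = sub("^group=", "", strata), time = sf$time,
             n_risk = sf$n.risk, surv = sf$surv,
             ci_lower = sf$lower, ci_upper = sf$upper)
}

#' Survival probability at given times from a Kaplan-Meier table
#'
#' @param km Output of [km_estimator()].
#' @param times Times at which to read off survival (reporting convention:
#'   years 1, 3 and 6).
#' @return data.frame(group, time, surv, ci_lower, ci_upper).
#' @export
km_at <- function(km, times) {
  out <- lapply(split(km, km$group), function(g) {
    g <- g[order(g$time), , drop = FALSE]
    pick <- function(col) stats::approx(c(0, g$time), c(1, g[[col]]),
                                        xout = times, method = "constant",
                                        rule = 2)$y
    data.frame(group = g$group[1L], time = times, surv = pick("surv"),
               ci_lower = pick("ci_lower"), ci_upper = pick("ci_upper"))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fine-Gray sub-distribution hazard model with case weights
#'
#' Sensitivity analysis treating death as a competing risk for the renal
#' outcome: subjects who die remain in the risk set via
#' inverse-probability-of-censoring weighting of the expanded data
#' ([survival::finegray()]), and the sub-distribution hazard model is fitted
#' by a weighted Cox fit on the expanded intervals, multiplying the
#' expansion weights by any analysis weights. With zero competing events the
#' expansion is the identity and the fit reduces to the cause-specific Cox
#' model (a message notes this).
#'
#' @param data One row per subject with `time`, `status` (factor with
#'   levels `censor`, the event of interest, and competing causes) and the
#'   design covariates.
#' @param formula Right-hand side design, e.g. `~ exposure`.
#' @param etype Event of interest (default `"renal"`).
#' @param weights Optional per-subject analysis weights.
#' @param cluster Subject id column (default `subject_id`).
#' @return `"msm_coxfit"` object on the sub-distribution scale.
#' @export
fit_fine_gray <- function(data, formula = ~exposure, etype = "renal",
                          weights = NULL, cluster = "subject_id") {
  data$status <- as.factor(data$status)
  if (levels(data$status)[1L] != "censor")
    data$status <- stats::relevel(data$status, "censor")
  competing <- setdiff(levels(data$status), c("censor", etype))
  n_comp <- sum(data$status %in% competing)
  if (n_comp == 0L)
    message("no competing events: sub-distribution fit equals the cause-specific fit")
  data$.w0 <- if (is.null(weights)) rep(1, nrow(data)) else weights
  data$.id <- data[[cluster]]
  fg <- survival::finegray(survival::Surv(time, status) ~ ., data = data,
                           etype = etype, id = .id, weights = .w0)
  fml <- stats::update(formula,
                       survival::Surv(fgstart, fgstop, fgstatus) ~ .)
  fit_weighted_cox(fml, data = fg, weights = fg$fgwt, cluster = fg$.id)
}
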