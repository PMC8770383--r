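#' Greedy 1:1 propensity-score matching within a caliper
#'
#' Matches each exposed subject to at most one unexposed subject by greedy
#' nearest neighbor on the logit of the propensity score, processing exposed
#' subjects in descending propensity order (ties broken by subject id for
#' determinism). The caliper is `caliper * SD(logit PS)` by convention
#' (`caliper_scale = "sd"`), or a raw logit distance
#' (`caliper_scale = "raw"`). Unmatched exposed subjects are dropped and
#' counted.
#'
#' @param ps Propensity scores in (0, 1).
#' @param exposure Binary exposure aligned with `ps`.
#' @param ids Subject identifiers.
#' @param caliper Caliper width (default 0.25).
#' @param caliper_scale `"sd"` (default, Rosenbaum-Rubin convention) or
#'   `"raw"`.
#' @return list(pairs = data.frame(exposed_id, control_id, distance),
#'   n_unmatched, caliper_used). Zero matches with exposed subjects present
#'   raises an error (no overlap).
#' @export
ps_match <- function(ps, exposure, ids = seq_along(ps), caliper = 0.25,
                     caliper_scale = c("sd", "raw")) {
  caliper_scale <- match.arg(caliper_scale)
  if (any(ps <= 0 | ps >= 1)) stopf("propensity scores must lie in (0, 1)")
  lp <- logit(ps)
  width <- if (caliper_scale == "sd") caliper * stats::sd(lp) else caliper
  exp_idx <- which(exposure == 1)
  ctl_idx <- which(exposure == 0)
  ord <- exp_idx[order(-ps[exp_idx], ids[exp_idx])]
  avail <- rep(TRUE, length(ctl_idx))
  pairs <- vector("list", length(ord))
  for (j in seq_along(ord)) {
    i <- ord[j]
    cand <- which(avail)
    if (length(cand) == 0L) break
    d <- abs(lp[ctl_idx[cand]] - lp[i])
    best <- cand[order(d, ids[ctl_idx[cand]])[1L]]
    if (abs(lp[ctl_idx[best]] - lp[i]) <= width) {
      pairs[[j]] <- data.frame(exposed_id = ids[i],
                               control_id = ids[ctl_idx[best]],
                               distance = abs(lp[ctl_idx[best]] - lp[i]))
      avail[best] <- FALSE
    }
  }
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(pairs)) {
    if (length(exp_idx) > 0L)
      warning("no overlap: zero matches formed within the caliper")
    pairs <- data.frame(exposed_id = ids[0], control_id = ids[0],
                        distance = numeric(0))
  }
  list(pairs = pairs, n_unmatched = length(exp_idx) - nrow(pairs),
       caliper_used = width)
}

#' Logistic propensity-score model
#'
#' @param data Cohort table.
#' @param exposure Binary exposure column name.
#' @param covariates Covariate column names.
#' @return list(ps = fitted propensity scores, fit = the glm).
#' @export
ps_model <- function(data, exposure = "baseline_anemia", covariates) {
  a <- as.integer(data[[exposure]])
  fit <- stats::glm(stats::reformulate(covariates, response = "a"),
                    data = cbind(data, a = a), family = stats::binomial())
  check_separation(fit, "propensity")
  list(ps = stats::fitted(fit), fit = fit)
}
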