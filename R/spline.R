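#' Knot placement for the restricted cubic spline time intercept
#'
#' Places `n_knots` knots at the standard quantiles of the observed time
#' distribution (for 5 knots: 0.05, 0.275, 0.50, 0.725, 0.95).
#'
#' @param x Observed times (e.g. period start days).
#' @param n_knots Number of knots (>= 3, default 5).
#' @return Strictly increasing knot vector.
#' @export
rcs_knots <- function(x, n_knots = 5) {
  if (n_knots < 3) stopf("need at least 3 knots")
  probs <- switch(as.character(n_knots),
                  "3" = c(0.10, 0.50, 0.90),
                  "4" = c(0.05, 0.35, 0.65, 0.95),
                  "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
                  seq(0.05, 0.95, length.out = n_knots))
  kn <- unname(stats::quantile(x, probs, type = 7, na.rm = TRUE))
  if (any(diff(kn) <= 0))
    kn <- kn + seq_along(kn) * 1e-8 * max(abs(kn), 1)  # degenerate spacing
  kn
}

#' Restricted cubic spline basis (Harrell's parameterization)
#'
#' Returns the linear term plus `n_knots - 2` nonlinear terms. Each
#' nonlinear term is a normalized combination of truncated cubes,
#' `((x-k_j)+^3 - (x-k_{n-1})+^3 (k_n-k_j)/(k_n-k_{n-1})
#'   + (x-k_n)+^3 (k_{n-1}-k_j)/(k_n-k_{n-1})) / (k_n-k_1)^2`,
#' which vanishes for `x` at or below the first knot and is linear beyond the
#' last knot (natural-spline boundary condition). With five knots this gives
#' the smooth time intercept of the pooled logistic weight models: the
#' linear time term plus three polynomial regressors.
#'
#' @param x Evaluation points.
#' @param knots Strictly increasing knot vector (length >= 3; default setup
#'   uses 5).
#' @return Matrix with columns `t`, `s1`, ..., `s[n-2]`.
#' @export
rcs_basis <- function(x, knots) {
  if (length(knots) < 3) stopf("need at least 3 knots")
  if (is.unsorted(knots, strictly = TRUE)) stopf("knots must be strictly increasing")
  nk <- length(knots)
  k1 <- knots[1L]; km <- knots[nk - 1L]; kn <- knots[nk]
  norm <- (kn - k1)^2
  cube <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), nk - 1L,
                dimnames = list(NULL, c("t", paste0("s", seq_len(nk - 2L)))))
  out[, 1L] <- x
  for (j in seq_len(nk - 2L)) {
    kj <- knots[j]
    out[, j + 1L] <- (cube(x - kj) -
                        cube(x - km) * (kn - kj) / (kn - km) +
                        cube(x - kn) * (km - kj) / (kn - km)) / norm
  }
  out
}
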