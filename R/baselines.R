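#' Gompertz distribution function
#'
#' `F(x) = 1 - exp(e^{-mu/sigma} (1 - e^{x/sigma}))` with location `mu`
#' and scale `sigma` (both in the time unit of the data, e.g. years).
#' The parametric marginal used by the copula reference model for adult
#' lifetimes.
#'
#' @param x non-negative quantiles.
#' @param mu location parameter.
#' @param sigma scale parameter (> 0).
#' @return `P(X <= x)`.
#' @export
gompertz_cdf <- function(x, mu, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  1 - exp(exp(-mu / sigma) * (1 - exp(x / sigma)))
}

#' Frank copula
#'
#' `C(u, v) = (1/alpha) log(1 + (e^{alpha u} - 1)(e^{alpha v} - 1) /
#' (e^{alpha} - 1))`.  In this parameterization negative `alpha`
#' corresponds to positive dependence; `alpha = 0` is the independence
#' limit and returns `u * v`.
#'
#' @param u,v marginal probabilities in `[0, 1]`.
#' @param alpha dependence parameter.
#' @return copula value `C(u, v)`.
#' @export
frank_copula <- function(u, v, alpha) {
  if (any(u < 0 | u > 1 | v < 0 | v > 1)) stop("u, v must be in [0, 1]")
  if (abs(alpha) < 1e-12) return(u * v)
  log1p(expm1(alpha * u) * expm1(alpha * v) / expm1(alpha)) / alpha
}

#' Reference parameters of the Gompertz/Frank comparison model
#'
#' Maximum-likelihood parameters for coupled adult lifetimes reported in
#' the joint-annuity literature; shipped as a named preset for comparison
#' tabulations (the fitting procedure itself is out of scope here).
#'
#' @return list with `mu_x`, `sigma_x`, `mu_y`, `sigma_y`, `alpha`.
#' @export
frank_gompertz_preset <- function() {
  list(mu_x = 84.809, sigma_x = 9.926, mu_y = 87.575, sigma_y = 7.792,
       alpha = -4.081)
}

#' Discretized copula model on the integer grid
#'
#' Induces a joint pmf on `[0, x_max] x [0, y_max]` by differencing the
#' copula cdf `C(F_X(x), F_Y(y))` over grid cells, for comparison with
#' the one-factor estimates on the same grid.  Numerically non-monotone
#' cells (possible at extreme tails) are clipped to zero with a warning.
#'
#' @param x_max,y_max grid bounds.
#' @param marginal_x,marginal_y functions mapping a numeric vector of
#'   grid points to cdf values (e.g. a [gompertz_cdf()] closure).
#' @param alpha Frank dependence parameter.
#' @return list with the joint `pmf` matrix and `moments` as in
#'   [model_moments()] restricted to the grid mass.
#' @export
copula_joint_grid <- function(x_max, y_max, marginal_x, marginal_y, alpha) {
  Fx <- c(0, marginal_x(0:x_max))
  Fy <- c(0, marginal_y(0:y_max))
  Cc <- outer(Fx, Fy, frank_copula, alpha = alpha)
  pmf <- Cc[-1, -1] - Cc[-nrow(Cc), -1] - Cc[-1, -ncol(Cc)] +
    Cc[-nrow(Cc), -ncol(Cc)]
  if (any(pmf < 0)) {
    if (min(pmf) < -1e-8)
      warning("copula grid pmf non-monotone beyond rounding; clipped")
    pmf[pmf < 0] <- 0
  }
  xi <- 0:x_max; yi <- 0:y_max
  mass <- sum(pmf)
  Q <- pmf / mass
  px <- rowSums(Q); py <- colSums(Q)
  mx <- sum(xi * px); my <- sum(yi * py)
  vx <- sum(xi^2 * px) - mx^2; vy <- sum(yi^2 * py) - my^2
  cv <- sum(outer(xi, yi) * Q) - mx * my
  list(pmf = pmf, mass = mass,
       moments = list(mean_x = mx, mean_y = my, var_x = vx, var_y = vy,
                      cov = cv, corr = cv / sqrt(vx * vy)))
}
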