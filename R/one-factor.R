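#' Truncation/censoring mechanism of a paired LTRC design
#'
#' Bundles the distribution of the first member's truncation time `T^X`,
#' the truncation lag `eps` (so that `T^Y = T^X + eps`; its support may
#' include negative values) and, optionally, the censoring gap `Delta`
#' (censoring times are `C^X = T^X + Delta`, `C^Y = T^Y + Delta`, which
#' guarantees `P(T <= C) = 1`).  `T^X`, `eps` and `Delta` are mutually
#' independent.
#'
#' @param dist_TX,dist_eps,dist_Delta `discrete_dist` objects;
#'   `dist_Delta` may be `NULL` when only truncation is modelled.
#' @return an object of class `truncation_model`.
#' @export
truncation_model <- function(dist_TX, dist_eps, dist_Delta = NULL) {
  stopifnot(inherits(dist_TX, "discrete_dist"),
            inherits(dist_eps, "discrete_dist"))
  if (dist_TX$offset < 0) stop("T^X must be non-negative")
  if (!is.null(dist_Delta)) {
    stopifnot(inherits(dist_Delta, "discrete_dist"))
    if (dist_Delta$offset < 0) stop("Delta must be non-negative")
  }
  structure(list(dist_TX = dist_TX, dist_eps = dist_eps,
                 dist_Delta = dist_Delta),
            class = "truncation_model")
}

#' One-factor latent convolution model for a dependent pair
#'
#' The bivariate law of `(X, Y)` is built from three independent
#' non-negative latent components via `X = A + B`, `Y = A + C`: all
#' dependence flows through the common component `A`, so
#' `Cov(X, Y) = Var(A) >= 0`.  The joint pmf
#' `p_XY(x, y) = sum_a p_A(a) p_B(x - a) p_C(y - a)` is materialized as a
#' dense table over the full grid at construction, since every E-step and
#' likelihood evaluation reuses it.
#'
#' @param dist_A,dist_B,dist_C `discrete_dist` objects on non-negative
#'   grids.
#' @param trunc optional `truncation_model`.
#' @return an object of class `one_factor_model` carrying the cached
#'   joint pmf table (`$joint`, rows `x = 0..x_M`, columns `y = 0..y_M`)
#'   and the tail table `$S2geq` with entries `P(X >= x, Y >= y)`.
#' @export
one_factor_model <- function(dist_A, dist_B, dist_C, trunc = NULL) {
  rebase <- function(d) {
    stopifnot(inherits(d, "discrete_dist"))
    if (d$offset < 0) stop("latent components must be non-negative")
    if (d$offset > 0)   # embed on the 0-based grid the kernels assume
      d <- discrete_dist(c(numeric(d$offset), d$pmf), offset = 0L)
    d
  }
  dist_A <- rebase(dist_A); dist_B <- rebase(dist_B)
  dist_C <- rebase(dist_C)
  if (!is.null(trunc)) stopifnot(inherits(trunc, "truncation_model"))
  joint <- cpp_joint_pmf(dist_A$pmf, dist_B$pmf, dist_C$pmf)
  # P(X >= x, Y >= y) by double suffix summation (dimension-safe)
  SxP <- joint   # SxP[x+1, y+1] = P(X >= x, Y = y)
  if (nrow(SxP) > 1L)
    for (i in (nrow(SxP) - 1L):1L) SxP[i, ] <- SxP[i, ] + SxP[i + 1L, ]
  S2 <- SxP      # S2[x+1, y+1] = P(X >= x, Y >= y)
  if (ncol(S2) > 1L)
    for (j in (ncol(S2) - 1L):1L) S2[, j] <- S2[, j] + S2[, j + 1L]
  PSy <- joint   # PSy[x+1, y+1] = P(X = x, Y >= y)
  if (ncol(PSy) > 1L)
    for (j in (ncol(PSy) - 1L):1L) PSy[, j] <- PSy[, j] + PSy[, j + 1L]
  structure(list(dist_A = dist_A, dist_B = dist_B, dist_C = dist_C,
                 trunc = trunc, joint = joint, S2geq = S2,
                 SxP = SxP, PSy = PSy,
                 x_M = nrow(joint) - 1L, y_M = ncol(joint) - 1L),
            class = "one_factor_model")
}

#' @export
print.one_factor_model <- function(x, ...) {
  mm <- model_moments(x)
  cat(sprintf(
    "one_factor_model on [0,%d] x [0,%d]: E[X]=%.3f E[Y]=%.3f corr=%.4f\n",
    x$x_M, x$y_M, mm$mean_x, mm$mean_y, mm$corr))
  invisible(x)
}

#' Joint pmf and tail probabilities of the pair
#'
#' `joint_pmf` returns `P(X = x, Y = y)`; `joint_tail` returns, depending
#' on `type`, `P(X > x, Y > y)` (`"gt_gt"`), `P(X >= x, Y >= y)`
#' (`"geq_geq"`), or the mixed tails `P(X > x, Y = y)` (`"gt_eq"`) and
#' `P(X = x, Y > y)` (`"eq_gt"`).  All are table lookups with the natural
#' out-of-grid extensions, vectorized over `x`, `y`.
#'
#' @param model a `one_factor_model`.
#' @param x,y integer vectors.
#' @param type which tail probability to return.
#' @return numeric vector.
#' @export
joint_pmf <- function(model, x, y) {
  ok <- x >= 0 & x <= model$x_M & y >= 0 & y <= model$y_M
  out <- numeric(length(ok))
  out[ok] <- model$joint[cbind(x[ok] + 1L, y[ok] + 1L)]
  out
}

#' @rdname joint_pmf
#' @export
joint_tail <- function(model, x, y,
                       type = c("gt_gt", "geq_geq", "gt_eq", "eq_gt")) {
  type <- match.arg(type)
  if (type == "gt_gt") return(joint_tail(model, x + 1L, y + 1L, "geq_geq"))
  n <- max(length(x), length(y))
  x <- rep_len(as.integer(x), n); y <- rep_len(as.integer(y), n)
  out <- numeric(n)
  if (type == "geq_geq") {
    xc <- pmax(x, 0L); yc <- pmax(y, 0L)
    ok <- xc <= model$x_M & yc <= model$y_M
    out[ok] <- model$S2geq[cbind(xc[ok] + 1L, yc[ok] + 1L)]
    return(out)
  }
  if (type == "gt_eq") {
    # P(X > x, Y = y) = SxP[x + 2, y + 1]
    ok <- y >= 0 & y <= model$y_M & x < model$x_M
    xs <- pmax(x, -1L)
    out[ok] <- model$SxP[cbind(xs[ok] + 2L, y[ok] + 1L)]
    return(out)
  }
  # eq_gt: P(X = x, Y > y) = PSy[x + 1, y + 2]
  ok <- x >= 0 & x <= model$x_M & y < model$y_M
  ys <- pmax(y, -1L)
  out[ok] <- model$PSy[cbind(x[ok] + 1L, ys[ok] + 2L)]
  out
}

#' Moments of the pair under a one-factor model
#'
#' Computed from the cached joint table.  By construction the covariance
#' equals `Var(A)`; this identity is a useful internal consistency check
#' and is exercised by the test suite.
#'
#' @param model a `one_factor_model`.
#' @return list with `mean_x`, `mean_y`, `var_x`, `var_y`, `cov`, `corr`
#'   (`corr` is `NA` with a warning for a degenerate margin).
#' @export
model_moments <- function(model) {
  window_moments(model, c(0L, model$x_M, 0L, model$y_M))
}

#' Window-conditioned moments of the pair
#'
#' Moments of `(X, Y)` conditioned on the rectangle
#' `x_lo <= X <= x_hi, y_lo <= Y <= y_hi`.  Nonparametric estimates are
#' only informative between the smallest and largest exactly-observed
#' values, so summaries of a fit are reported conditioned on that window.
#'
#' @param model a `one_factor_model`.
#' @param window integer vector `c(x_lo, x_hi, y_lo, y_hi)`.
#' @return list as in [model_moments()], plus `mass`, the unconditional
#'   probability of the window.
#' @export
window_moments <- function(model, window) {
  stopifnot(length(window) == 4)
  x_lo <- max(0L, window[1]); x_hi <- min(model$x_M, window[2])
  y_lo <- max(0L, window[3]); y_hi <- min(model$y_M, window[4])
  if (x_lo > x_hi || y_lo > y_hi) stop("window has zero probability")
  xi <- x_lo:x_hi
  yi <- y_lo:y_hi
  Q <- model$joint[xi + 1L, yi + 1L, drop = FALSE]
  mass <- sum(Q)
  if (mass <= 0) stop("window has zero probability")
  Q <- Q / mass
  px <- rowSums(Q); py <- colSums(Q)
  mx <- sum(xi * px); my <- sum(yi * py)
  vx <- sum(xi^2 * px) - mx^2; vy <- sum(yi^2 * py) - my^2
  cv <- sum(outer(xi, yi) * Q) - mx * my
  corr <- if (vx <= 0 || vy <= 0) {
    warning("degenerate margin: correlation undefined")
    NA_real_
  } else cv / sqrt(vx * vy)
  list(mean_x = mx, mean_y = my, var_x = vx, var_y = vy,
       cov = cv, corr = corr, mass = mass)
}

#' Joint cdf of the truncation pair
#'
#' `P(T^X <= x, T^Y <= y) = sum_{t <= x} p_TX(t) P(eps <= y - t)` under
#' the lag construction `T^Y = T^X + eps`.
#'
#' @param trunc a `truncation_model`.
#' @param x,y integer vectors (recycled to a common length).
#' @return numeric vector.
#' @export
truncation_joint_cdf <- function(trunc, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(as.integer(x), n); y <- rep_len(as.integer(y), n)
  tx <- trunc$dist_TX
  sup <- dd_support(tx)
  tt <- sup[1]:sup[2]
  vapply(seq_len(n), function(i) {
    keep <- tt <= x[i]
    if (!any(keep)) return(0)
    sum(tx$pmf[keep] * dd_cdf(trunc$dist_eps, y[i] - tt[keep]))
  }, numeric(1))
}

# Dense truncation-cdf table H[x + 1, y + 1] = P(T^X <= x, T^Y <= y) on
# the grid [0, x_M] x [0, y_M]; the workhorse behind the observation
# probability and the E-step truncation terms.
trunc_cdf_matrix <- function(trunc, x_M, y_M) {
  tx <- trunc$dist_TX
  sup <- dd_support(tx)
  tt <- sup[1]:min(sup[2], x_M)
  # M1[t, y] = p_TX(t) P(eps <= y - t)
  M1 <- matrix(vapply(0:y_M, function(y) dd_cdf(trunc$dist_eps, y - tt),
                      numeric(length(tt))),
               nrow = length(tt))
  M1 <- tx$pmf[seq_along(tt)] * M1
  Hc <- matrix(apply(M1, 2, cumsum), nrow = length(tt))
  H <- matrix(0, x_M + 1L, y_M + 1L)
  rows <- pmin(pmax(0:x_M - tt[1] + 1L, 0L), length(tt))
  ok <- rows >= 1L
  H[ok, ] <- Hc[rows[ok], , drop = FALSE]
  H
}

#' Probability of the observation event
#'
#' Under bivariate left-truncation a pair is observed only on the event
#' `T^X <= X, T^Y <= Y`.  Its probability
#' `p = sum_{x,y} p_XY(x, y) P(T^X <= x, T^Y <= y)` controls the number of
#' phantom (never-observed) samples `M - n` imputed by the EM E-step.
#'
#' @param model a `one_factor_model` with a truncation model attached.
#' @return scalar probability.
#' @export
observation_probability <- function(model) {
  if (is.null(model$trunc)) return(1)
  H <- trunc_cdf_matrix(model$trunc, model$x_M, model$y_M)
  p <- sum(model$joint * H)
  if (p <= 0) stop("observation event has probability zero")
  p
}
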