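#' Discrete distribution on a bounded integer grid
#'
#' A `discrete_dist` stores a probability mass function on a closed integer
#' grid `offset, offset + 1, ..., offset + length(pmf) - 1`, together with its
#' survival function.  Throughout the package `survival(j)` means
#' `P(X > j)`, so `survival(offset - 1) = 1` and the survival reaches 0 at
#' the upper end of the grid.  Negative offsets are allowed (needed e.g. for
#' truncation-lag variables that can be negative).
#'
#' @param pmf numeric vector of probabilities; must be non-negative and sum
#'   to 1 (it is renormalized when `normalize = TRUE`).
#' @param offset integer, the grid point carried by `pmf[1]`.  Default 0.
#' @param normalize logical; divide by `sum(pmf)` instead of insisting the
#'   input is already normalized.
#' @return an object of class `discrete_dist` with fields `offset`, `pmf`
#'   and `survival` (same length as `pmf`).
#' @examples
#' d <- discrete_dist(c(0.25, 0.5, 0.25))
#' dd_survival(d, 0)   # P(X > 0) = 0.75
#' dd_mean(d)
#' @export
discrete_dist <- function(pmf, offset = 0L, normalize = FALSE) {
  pmf <- as.numeric(pmf)
  if (length(pmf) == 0L) stop("pmf must have positive length")
  if (anyNA(pmf) || any(pmf < -1e-12)) stop("pmf must be non-negative")
  pmf[pmf < 0] <- 0
  s <- sum(pmf)
  if (normalize) {
    if (s <= 0) stop("pmf sums to zero; cannot normalize")
    pmf <- pmf / s
  } else if (abs(s - 1) > 1e-9) {
    stop(sprintf("pmf sums to %.12g, not 1 (use normalize = TRUE)", s))
  } else {
    pmf <- pmf / s
  }
  structure(
    list(offset = as.integer(offset), pmf = pmf,
         survival = c(rev(cumsum(rev(pmf)))[-1L], 0)),
    class = "discrete_dist")
}

#' @export
print.discrete_dist <- function(x, ...) {
  sup <- dd_support(x)
  cat(sprintf("discrete_dist on [%d, %d], mean %.4f, var %.4f\n",
              sup[1], sup[2], dd_mean(x), dd_var(x)))
  invisible(x)
}

#' Grid bounds of a discrete distribution
#' @param d a `discrete_dist`
#' @return integer vector `c(lower, upper)`
#' @export
dd_support <- function(d) c(d$offset, d$offset + length(d$pmf) - 1L)

#' Evaluate pmf, survival and cdf at arbitrary integer points
#'
#' Points below the grid have pmf 0, survival 1 and cdf 0; points above have
#' pmf 0, survival 0 and cdf 1.
#' @param d a `discrete_dist`
#' @param j integer vector of evaluation points
#' @return numeric vector
#' @export
dd_pmf <- function(d, j) {
  i <- j - d$offset + 1L
  out <- numeric(length(j))
  ok <- i >= 1L & i <= length(d$pmf)
  out[ok] <- d$pmf[i[ok]]
  out
}

#' @rdname dd_pmf
#' @export
dd_survival <- function(d, j) {
  i <- j - d$offset + 1L
  out <- numeric(length(j))
  out[i < 1L] <- 1
  ok <- i >= 1L & i <= length(d$pmf)
  out[ok] <- d$survival[i[ok]]
  out
}

#' @rdname dd_pmf
#' @export
dd_cdf <- function(d, j) 1 - dd_survival(d, j)

#' Moments of a discrete distribution
#' @param d a `discrete_dist`
#' @return numeric scalar
#' @export
dd_mean <- function(d) {
  sup <- dd_support(d)
  sum(seq(sup[1], sup[2]) * d$pmf)
}

#' @rdname dd_mean
#' @export
dd_var <- function(d) {
  sup <- dd_support(d)
  j <- seq(sup[1], sup[2])
  sum(j^2 * d$pmf) - dd_mean(d)^2
}

#' Parametric constructors on a truncated grid
#'
#' Named families used for priors and simulation recipes.  `dd_poisson`
#' truncates a (possibly shifted) Poisson law to `[offset, offset + qmax]`
#' and renormalizes; `qmax` defaults to a quantile far enough in the tail
#' that the discarded mass is below 1e-12.
#'
#' @param lambda Poisson rate.
#' @param offset integer shift of the support (e.g. `offset = -5` gives
#'   `Poi(lambda) - 5`).
#' @param qmax highest unshifted grid point; default
#'   `qpois(1 - 1e-14, lambda) + 2`.
#' @return a `discrete_dist`
#' @export
dd_poisson <- function(lambda, offset = 0L, qmax = NULL) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (is.null(qmax)) qmax <- stats::qpois(1 - 1e-14, lambda) + 2L
  discrete_dist(stats::dpois(0:qmax, lambda), offset = offset,
                normalize = TRUE)
}

#' @rdname dd_poisson
#' @param a,b inclusive bounds of a discrete uniform law.
#' @export
dd_uniform <- function(a, b) {
  if (b < a) stop("need a <= b")
  discrete_dist(rep(1 / (b - a + 1), b - a + 1), offset = a)
}

#' @rdname dd_poisson
#' @param k location of a point mass.
#' @export
dd_pointmass <- function(k) discrete_dist(1, offset = k)

#' Restrict a distribution to a grid `[lo, hi]`
#'
#' Mass outside the window is discarded and the pmf renormalized.  Used to
#' put parametric priors on the finite working grid of the fit.
#' @param d a `discrete_dist`
#' @param lo,hi integer bounds
#' @return a `discrete_dist` on `[lo, hi]`
#' @export
dd_restrict <- function(d, lo, hi) {
  discrete_dist(dd_pmf(d, lo:hi), offset = lo, normalize = TRUE)
}

#' Draw from a discrete distribution
#' @param d a `discrete_dist`
#' @param n number of draws
#' @return integer vector
#' @export
dd_sample <- function(d, n) {
  sup <- dd_support(d)
  vals <- seq(sup[1], sup[2])
  if (length(vals) == 1L) return(rep(vals, n))
  sample(vals, n, replace = TRUE, prob = d$pmf)
}

#' Named-family parser used by configuration files
#'
#' Accepts specs of the form `list(family = "poisson", lambda = 40,
#' offset = -5)`, `list(family = "uniform", a = 0, b = 3)` or
#' `list(family = "pointmass", k = 2)`.
#' @param spec a named list
#' @return a `discrete_dist`
#' @export
dd_from_spec <- function(spec) {
  if (inherits(spec, "discrete_dist")) return(spec)
  fam <- match.arg(spec$family, c("poisson", "uniform", "pointmass"))
  switch(fam,
    poisson  = dd_poisson(spec$lambda,
                          offset = if (is.null(spec$offset)) 0L else spec$offset),
    uniform  = dd_uniform(spec$a, spec$b),
    pointmass = dd_pointmass(spec$k))
}

#' Write a distribution as TSV (columns j, pmf, survival)
#' @param d a `discrete_dist`
#' @param path output file
#' @export
dd_write_tsv <- function(d, path) {
  sup <- dd_support(d)
  utils::write.table(
    data.frame(j = seq(sup[1], sup[2]), pmf = d$pmf, survival = d$survival),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
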