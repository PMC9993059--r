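#' Urn sequence of a reinforced urn process
#'
#' A discrete beta-Stacy / reinforced-urn configuration: urn `j` holds
#' `G_j` green-ball mass out of `N_j` total mass, and the ratio
#' `G_j / N_j = P(X > j | X > j - 1)` is the conditional survival at `j`.
#' Ball masses need not be integers.  The induced survival function is the
#' running product of the ratios; a final urn with ratio 0 ("closing urn")
#' makes it a proper distribution on a finite grid.
#'
#' @param G,N numeric vectors of green and total masses; `0 <= G <= N`.
#' @param offset integer grid index of the first urn (may be negative).
#' @return an object of class `urn_seq`.
#' @export
urn_seq <- function(G, N, offset = 0L) {
  if (length(G) != length(N)) stop("G and N must have equal length")
  if (any(N < 0) || any(G < -1e-12) || any(G > N + 1e-9))
    stop("need 0 <= G_j <= N_j")
  structure(list(offset = as.integer(offset), G = as.numeric(G),
                 N = as.numeric(N)),
            class = "urn_seq")
}

#' @export
print.urn_seq <- function(x, ...) {
  cat(sprintf("urn_seq: %d urns on [%d, %d]\n", length(x$G), x$offset,
              x$offset + length(x$G) - 1L))
  invisible(x)
}

#' Prior urn configuration centred on a distribution
#'
#' Builds the urns `beta_j = c_j * F0({j})`, `omega_j = c_j * (1 - F0(j))`
#' so that, with no data, the urn distribution is exactly the prior `F0`
#' (the centering identity `beta_j / (beta_j + omega_j) = hazard of F0`).
#' `c` is the strength of belief: large `c` pins the posterior to the
#' prior, `c -> 0` recovers the product-limit estimator.
#'
#' @param prior a `discrete_dist`, the centering distribution `F0`.
#' @param strength scalar or per-urn vector of strengths of belief
#'   `c_j > 0`.
#' @return an `urn_seq` with `G = omega`, `N = beta + omega`, carrying
#'   `beta` and `omega` as fields.
#' @export
urns_from_prior <- function(prior, strength) {
  stopifnot(inherits(prior, "discrete_dist"))
  k <- length(prior$pmf)
  cvec <- rep_len(as.numeric(strength), k)
  if (any(cvec <= 0)) stop("strength of belief must be positive")
  beta <- cvec * prior$pmf
  omega <- cvec * prior$survival
  out <- urn_seq(G = omega, N = beta + omega, offset = prior$offset)
  out$beta <- beta
  out$omega <- omega
  out
}

#' Distribution induced by an urn sequence
#'
#' `S(a) = prod_{j = offset..a} G_j / N_j`, with the empty product equal
#' to 1 below the offset; the pmf follows by differencing.  An urn with
#' `N_j = 0` carries no information and contributes factor 1.  If the last
#' urn leaves survival mass (no closing urn), one extra grid point is
#' appended to carry the remainder, so the survival values over the urn
#' grid are untouched and the result is proper (same convention as
#' [km_product_limit()]).
#'
#' @param urns an `urn_seq`.
#' @return a `discrete_dist`.
#' @export
survival_from_urns <- function(urns) {
  stopifnot(inherits(urns, "urn_seq"))
  ratio <- ifelse(urns$N > 0, urns$G / urns$N, 1)
  surv <- cumprod(ratio)
  pmf <- -diff(c(1, surv))
  tail_mass <- surv[length(surv)]
  if (tail_mass > 1e-12) pmf <- c(pmf, tail_mass)
  discrete_dist(pmf, offset = urns$offset, normalize = TRUE)
}

#' Reinforced-urn posterior under LTRC data
#'
#' The posterior predictive survival of a reinforced urn process with
#' prior urns `(beta_j, omega_j)` and reinforcement `r`, given the LTRC
#' counting statistics:
#' `S(x) = prod_{j <= x} [1 - (beta_j + r m_j) / (beta_j + omega_j + r s_j)]`.
#' With `beta = omega = 0` (vanishing strength of belief) and `r = 1` this
#' is exactly the LTRC product-limit estimator; with `r = 0` it returns
#' the prior.  A grid point with zero denominator contributes factor 1.
#'
#' @param prior an `urn_seq` from [urns_from_prior()] (fields `beta`,
#'   `omega`), or a list with numeric `beta`, `omega` and integer `offset`.
#' @param counts a `count_vectors` on the same 0-based grid.
#' @param r reinforcement, a non-negative scalar.
#' @return a `discrete_dist` (posterior predictive of `X`).
#' @export
rup_posterior <- function(prior, counts, r = 1) {
  if (r < 0) stop("reinforcement r must be >= 0")
  stopifnot(inherits(counts, "count_vectors"))
  off <- if (is.null(prior$offset)) 0L else prior$offset
  if (off != 0L) stop("rup_posterior expects a 0-based grid")
  k <- max(length(prior$beta), counts$grid_max + 1L)
  pad <- function(v, k) c(v, numeric(k - length(v)))
  beta <- pad(prior$beta, k); omega <- pad(prior$omega, k)
  m <- pad(counts$m, k); s <- pad(counts$s, k)
  num <- beta + r * m
  den <- beta + omega + r * s
  haz <- ifelse(den > 0, num / den, 0)
  surv <- cumprod(1 - haz)
  pmf <- -diff(c(1, surv))
  tail_mass <- surv[length(surv)]
  if (tail_mass > 1e-12) pmf <- c(pmf, tail_mass)
  discrete_dist(pmf, offset = 0L, normalize = TRUE)
}

#' Conjugate beta-Stacy update under LTRC counts
#'
#' The reinforced urn process is conjugate to LTRC data: the posterior is
#' again beta-Stacy with `beta*_j = beta_j + r m_j` and
#' `omega*_j = omega_j + r q_j`, where `q_j = s_j - m_j` counts the
#' observations passing through urn `j` without an exact event there.
#'
#' @param beta,omega prior urn parameters on the 0-based grid.
#' @param counts a `count_vectors`.
#' @param r reinforcement mass added per observation (default 1).
#' @return list with updated `beta`, `omega`.
#' @export
conjugate_update <- function(beta, omega, counts, r = 1) {
  stopifnot(inherits(counts, "count_vectors"))
  k <- max(length(beta), counts$grid_max + 1L)
  pad <- function(v, k) c(v, numeric(k - length(v)))
  m <- pad(counts$m, k); s <- pad(counts$s, k)
  q <- s - m
  list(beta = pad(beta, k) + r * m, omega = pad(omega, k) + r * q)
}

#' Serialize an urn sequence as TSV (columns j, G, N, ratio)
#' @param urns an `urn_seq`
#' @param path output file
#' @export
urns_write_tsv <- function(urns, path) {
  j <- urns$offset + seq_along(urns$G) - 1L
  utils::write.table(
    data.frame(j = j, G = urns$G, N = urns$N,
               ratio = ifelse(urns$N > 0, urns$G / urns$N, 1)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
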