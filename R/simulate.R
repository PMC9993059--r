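#' Simulation recipe for paired LTRC data
#'
#' Describes the generating process of a bivariate LTRC sample: latent
#' components `A`, `B`, `C` (lifetimes `X = A + B`, `Y = A + C`),
#' truncation `T^X` with lag `eps` (`T^Y = T^X + eps`) and censoring gap
#' `Delta` (`C^X = T^X + Delta`, `C^Y = T^Y + Delta`, so truncation never
#' exceeds censoring).  A candidate pair is observed only if
#' `T^X <= X` and `T^Y <= Y`.
#'
#' @param A,B,C,TX,eps,Delta `discrete_dist` objects (or family specs).
#' @param n_observed target number of observed pairs.
#' @param seed integer seed making the draw reproducible.
#' @return a `sim_recipe` list.
#' @export
sim_recipe <- function(A, B, C, TX, eps, Delta, n_observed, seed = 1L) {
  r <- lapply(list(A = A, B = B, C = C, TX = TX, eps = eps, Delta = Delta),
              dd_from_spec)
  stopifnot(n_observed >= 1)
  r$n_observed <- as.integer(n_observed)
  r$seed <- as.integer(seed)
  structure(r, class = "sim_recipe")
}

#' The Poisson simulation design
#'
#' The reference synthetic design used throughout the package's tests:
#' `A ~ Poi(40)`, `B ~ Poi(20)`, `C ~ Poi(25)` (so `X ~ Poi(60)`,
#' `Y ~ Poi(65)`, correlation `40 / sqrt(60 * 65) ~ 0.64`),
#' `T^X ~ Poi(70)`, `eps ~ Poi(7) - 5`, `Delta ~ Poi(2)`, with `10^4`
#' observed pairs.  Under this design roughly five of every six candidate
#' pairs are truncated away and about two thirds of the observed pairs are
#' censored in both coordinates.
#'
#' @param seed integer seed.
#' @param n_observed observed sample size (default `1e4`).
#' @return a `sim_recipe`.
#' @export
poisson_example_recipe <- function(seed = 1L, n_observed = 1e4) {
  sim_recipe(A = dd_poisson(40), B = dd_poisson(20), C = dd_poisson(25),
             TX = dd_poisson(70), eps = dd_poisson(7, offset = -5L),
             Delta = dd_poisson(2), n_observed = n_observed, seed = seed)
}

#' Prior distributions used with the Poisson design
#'
#' A deliberately off-centre prior (flat-ish, smaller means than the
#' truth): `F0_A = F0_B = F0_C = Poi(20)`, `F0_TX = Poi(50)`,
#' `F0_eps = Poi(10) - 5` (the shift chosen from the smallest observable
#' lag).
#'
#' @return named list of `discrete_dist` priors for [fit_er()].
#' @export
poisson_example_priors <- function() {
  list(A = dd_poisson(20), B = dd_poisson(20), C = dd_poisson(20),
       TX = dd_poisson(50), eps = dd_poisson(10, offset = -5L))
}

#' Simulate paired LTRC observations by rejection sampling
#'
#' Draws candidate pairs from the recipe's generating process and keeps
#' those passing the bivariate truncation filter until `n_observed`
#' records are collected.  Deterministic given `recipe$seed`.
#'
#' @param recipe a `sim_recipe`.
#' @param keep_latent also return the latent `X`, `Y`, `A`, `B`, `C` and
#'   censoring times of the observed records (for validation only).
#' @param max_draws cap on candidate draws (guards a vanishing
#'   observation probability).
#' @return list with `obs` (an `ltrc_data` with the first `n_observed`
#'   accepted pairs), `n_rejected` (candidate pairs truncated away),
#'   `n_candidates` (total candidate draws; the final block may overshoot,
#'   in which case surplus accepted pairs are discarded), and optionally
#'   `latent`.
#' @export
simulate_ltrc <- function(recipe, keep_latent = FALSE, max_draws = 1e8) {
  stopifnot(inherits(recipe, "sim_recipe"))
  set.seed(recipe$seed)
  need <- recipe$n_observed
  out <- vector("list", 0L)
  latent <- vector("list", 0L)
  n_rejected <- 0L
  n_candidates <- 0L
  got <- 0L
  while (got < need) {
    # draw in blocks sized by the expected acceptance rate so far
    rate <- if (n_candidates > 0L) max(got / n_candidates, 1e-3) else 0.25
    m <- min(ceiling((need - got) / rate * 1.2), max_draws - n_candidates)
    if (m <= 0L)
      stop("candidate-draw cap reached: observation probability too small")
    A <- dd_sample(recipe$A, m); B <- dd_sample(recipe$B, m)
    C <- dd_sample(recipe$C, m)
    X <- A + B; Y <- A + C
    TX <- dd_sample(recipe$TX, m); e <- dd_sample(recipe$eps, m)
    TY <- TX + e
    keep <- TX <= X & TY <= Y
    n_candidates <- n_candidates + m
    n_rejected <- n_rejected + sum(!keep)
    if (!any(keep)) next
    D <- dd_sample(recipe$Delta, sum(keep))
    Xk <- X[keep]; Yk <- Y[keep]; TXk <- TX[keep]; TYk <- TY[keep]
    CX <- TXk + D; CY <- TYk + D
    # a non-positive entry time means entry at the grid origin
    rec <- data.frame(
      x_star = pmin(Xk, CX), delta_x = as.integer(Xk <= CX), t_x = TXk,
      y_star = pmin(Yk, CY), delta_y = as.integer(Yk <= CY),
      t_y = pmax(TYk, 0L))
    out[[length(out) + 1L]] <- rec
    if (keep_latent)
      latent[[length(latent) + 1L]] <-
        data.frame(X = Xk, Y = Yk, A = A[keep], B = B[keep], C = C[keep],
                   CX = CX, CY = CY)
    got <- got + sum(keep)
  }
  df <- do.call(rbind, out)[seq_len(need), , drop = FALSE]
  res <- list(obs = validate_ltrc(df),
              n_rejected = n_rejected,
              n_candidates = n_candidates)
  if (keep_latent) {
    lat <- do.call(rbind, latent)[seq_len(need), , drop = FALSE]
    res$latent <- lat
  }
  res
}
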