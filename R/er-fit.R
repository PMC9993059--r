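#' Configuration of the expectation-reinforcement fit
#'
#' @param r reinforcement: mass added to the urns per (possibly phantom)
#'   observation.  Large `r` lets the data dominate the prior.
#' @param c strength of belief in the prior, scalar or per-urn; `c = 0`
#'   gives the pure EM (maximum-likelihood) fit.  `r` and `c` play
#'   opposite roles: scaling `c` up is equivalent to scaling `r` down.
#' @param tol stopping threshold on the absolute relative change of the
#'   incomplete log-likelihood between iterations.
#' @param max_iter iteration cap.
#' @param x_M,y_M optional support bounds for `X` and `Y`; defaults are
#'   the largest observed `x*` and `max(y*, T^X_max + eps_max)`, the
#'   latter making the truncated infinite sums exact (see
#'   [tail_error_bound()]).
#' @param combine `"each"` applies the reinforcement combination with the
#'   prior urns at every iteration; `"at_convergence"` runs the pure EM
#'   to convergence and blends with the prior once at the end.
#' @return an `er_config` list.
#' @export
er_config <- function(r = 1e4, c = 1, tol = 1e-9, max_iter = 1e4,
                      x_M = NULL, y_M = NULL,
                      combine = c("each", "at_convergence")) {
  stopifnot(r > 0, all(c >= 0), tol > 0, max_iter >= 1)
  structure(list(r = r, c = c, tol = tol, max_iter = as.integer(max_iter),
                 x_M = x_M, y_M = y_M, combine = match.arg(combine)),
            class = "er_config")
}

#' E-step conditional of one latent component given one observation
#'
#' The conditional pmf of `A`, `B` or `C` given a single record
#' `(x, y, dX, dY)` under the current model: the numerator is the term of
#' the convolution consistent with the observed/censored pattern, and the
#' denominator is obtained by summing the numerator, which guarantees
#' exact normalization.
#'
#' @param model a `one_factor_model`.
#' @param x,y observed values; `dX`, `dY` censoring indicators.
#' @param dX,dY censoring indicators (1 = exact).
#' @param which one of `"A"`, `"B"`, `"C"`.
#' @return a `discrete_dist` over the latent component.
#' @export
estep_latent_conditional <- function(model, x, y, dX, dY,
                                     which = c("A", "B", "C")) {
  which <- match.arg(which)
  est <- cpp_estep_obs(
    model$dist_A$pmf, model$dist_A$survival,
    model$dist_B$pmf, model$dist_B$survival,
    model$dist_C$pmf, model$dist_C$survival,
    as.integer(x), as.integer(y), as.integer(dX), as.integer(dY), 1.0)
  if (est$denom[1] <= 0)
    stop("observed event has probability zero under the current model")
  agg <- switch(which, A = est$aggA, B = est$aggB, C = est$aggC)
  discrete_dist(agg, offset = 0L, normalize = TRUE)
}

#' E-step conditionals given the observation event
#'
#' Conditional distributions of the latent components `A`, `B`, `C` and of
#' the truncation variables `T^X`, `eps` given that a pair passes the
#' truncation filter `T^X <= X, T^Y <= Y`.  These feed the phantom-sample
#' (truncated-stratum) terms of the M-step.
#'
#' @param model a `one_factor_model` with a truncation model.
#' @return list with `discrete_dist` entries `A`, `B`, `C`, `TX`, `eps`
#'   and the scalar `p_obs`, the probability of the observation event.
#' @export
estep_observation_conditionals <- function(model) {
  if (is.null(model$trunc)) stop("model carries no truncation model")
  H <- trunc_cdf_matrix(model$trunc, model$x_M, model$y_M)
  p_obs <- sum(model$joint * H)
  if (p_obs <= 0) stop("observation event has probability zero")
  Dw <- cpp_obs_cond_weights(model$dist_A$pmf, model$dist_B$pmf,
                             model$dist_C$pmf, H)
  mk <- function(p, D, off) discrete_dist(p * D, offset = off,
                                          normalize = TRUE)
  tx <- model$trunc$dist_TX; ep <- model$trunc$dist_eps
  tsup <- dd_support(tx); esup <- dd_support(ep)
  tt <- tsup[1]:tsup[2]; ee <- esup[1]:esup[2]
  # W[t, e] = p_TX(t) p_eps(e) P(X >= t, Y >= t + e)
  W <- outer(tx$pmf, ep$pmf) *
    matrix(joint_tail(model, rep(tt, length(ee)),
                      rep(ee, each = length(tt)) + rep(tt, length(ee)),
                      "geq_geq"),
           nrow = length(tt))
  list(A  = mk(model$dist_A$pmf, Dw$DA, 0L),
       B  = mk(model$dist_B$pmf, Dw$DB, 0L),
       C  = mk(model$dist_C$pmf, Dw$DC, 0L),
       TX = discrete_dist(rowSums(W), offset = tsup[1], normalize = TRUE),
       eps = discrete_dist(colSums(W), offset = esup[1], normalize = TRUE),
       p_obs = p_obs)
}

#' Condition a distribution on the truncation (never-observed) event
#'
#' From the mixture identity
#' `p(v) = p(v | truncated) (1 - p_obs) + p(v | observed) p_obs`, recovers
#' the truncated-stratum conditional
#' `[p(v) - p_obs * p(v | observed)] / (1 - p_obs)`.  Tiny negative masses
#' from floating-point cancellation (above `-1e-9`) are clipped to zero
#' and the pmf renormalized; larger negatives indicate an inconsistent
#' input pair and raise an error.
#'
#' @param p_full the marginal `discrete_dist` of the variable.
#' @param p_obs_cond its conditional `discrete_dist` given observation.
#' @param p_obs probability of the observation event, in `(0, 1)`.
#' @return a `discrete_dist`.
#' @export
condition_on_truncation <- function(p_full, p_obs_cond, p_obs) {
  stopifnot(p_obs > 0, p_obs < 1)
  if (p_full$offset != p_obs_cond$offset ||
      length(p_full$pmf) != length(p_obs_cond$pmf))
    stop("distributions must share one grid")
  num <- p_full$pmf - p_obs * p_obs_cond$pmf
  if (any(num < -1e-9))
    stop("inconsistent marginal/conditional pair: negative stratum mass ",
         format(min(num)))
  num[num < 0] <- 0
  discrete_dist(num, offset = p_full$offset, normalize = TRUE)
}

#' Total sample size implied by the observation probability
#'
#' The observed `n` pairs are the survivors of `M` candidate pairs of
#' which a fraction `1 - p_obs` was truncated away, so `M = n / p_obs`.
#'
#' @param n observed sample size.
#' @param p_obs probability of the observation event, in `(0, 1]`.
#' @return real `M >= n`.
#' @export
total_samples <- function(n, p_obs) {
  if (p_obs <= 0) stop("observation probability must be positive")
  n / min(p_obs, 1)
}

# Shared ratio update: given the aggregated observed-stratum survival
# Agg(j) (already including the (M - n) * S(j | truncated) phantom term,
# with Agg(offset - 1) = M), prior urn masses beta/omega and the
# reinforcement r, returns the urn pair (G, N).  beta = omega = 0 gives
# the pure EM M-step; r -> 0 gives back the prior ratios.
er_urns <- function(beta, omega, agg, agg_prev, r) {
  list(G = omega + r * agg, N = beta + omega + r * agg_prev)
}

ratios_to_dist <- function(G, N, offset, floor = 1e-300) {
  ratio <- ifelse(N > floor, G / N, 0)
  ratio <- pmin(pmax(ratio, 0), 1)
  surv <- cumprod(ratio)
  pmf <- -diff(c(1, surv))
  pmf[length(pmf)] <- pmf[length(pmf)] + surv[length(surv)]
  discrete_dist(pmf, offset = offset, normalize = TRUE)
}

#' M-step ratio update for a latent component
#'
#' The maximizer of the expected complete log-likelihood is, urn by urn,
#' `G_j / N_j = Agg(j) / Agg(j - 1)` where
#' `Agg(j) = sum_i S(j | x_i, y_i, dX_i, dY_i) + (M - n) S(j | truncated)`.
#' Once the running denominator is exhausted (below `1e-300`) all later
#' ratios are 0.
#'
#' @param agg_surv numeric vector, `Agg(j)` on the component grid.
#' @param M,n total and observed sample sizes (`Agg(offset - 1) = M`).
#' @param offset grid offset of the component.
#' @return a `discrete_dist`, the updated component distribution.
#' @export
mstep_update <- function(agg_surv, M, n, offset = 0L) {
  ratios_to_dist(agg_surv, c(M, agg_surv[-length(agg_surv)]), offset)
}

#' Reinforcement combination of prior urns with EM aggregates
#'
#' `G_j = omega_j + r * Agg(j)`, `N_j = beta_j + omega_j + r * Agg(j-1)`:
#' the posterior urn configuration blending the prior (via its urn masses)
#' with the data (via the reinforced EM aggregate survivals).
#'
#' @param beta,omega prior urn masses on the component grid.
#' @param agg_surv aggregate EM survivals `Agg(j)` (see [mstep_update()]).
#' @param r reinforcement.
#' @param M value of `Agg(offset - 1)` (total samples).
#' @param offset grid offset.
#' @return an `urn_seq` with the posterior configuration.
#' @export
er_combine <- function(beta, omega, agg_surv, r, M, offset = 0L) {
  u <- er_urns(beta, omega, agg_surv, c(M, agg_surv[-length(agg_surv)]), r)
  urn_seq(G = pmin(u$G, u$N), N = u$N, offset = offset)
}

#' Fit the one-factor model to paired LTRC data by
#' expectation-reinforcement
#'
#' Alternates (i) an E-step computing, under the current component
#' distributions, the conditional laws of `A`, `B`, `C` given every
#' observed record and the conditional laws of all five variables given
#' the truncation event, and (ii) a reinforcement M-step that maximizes
#' the expected complete log-likelihood and blends the resulting urn
#' configuration with the prior urns.  Iterations start from the prior
#' distributions and stop when the relative change of the incomplete
#' log-likelihood falls below `config$tol` or after `config$max_iter`
#' iterations.
#'
#' @param obs an `ltrc_data` object.
#' @param priors named list of prior distributions (`discrete_dist` or
#'   family specs for [dd_from_spec()]) for `A`, `B`, `C` and optionally
#'   `TX` and `eps`; missing truncation priors default to discrete
#'   uniforms over the observed ranges.
#' @param config an [er_config()].
#' @param verbose if `TRUE`, report the log-likelihood every 100
#'   iterations (and the observation probability and implied `M` when
#'   `verbose = 2`).
#' @return an object of class `er_fit`: posterior component distributions
#'   (`$dist`), posterior urns (`$urns`), the fitted `one_factor_model`
#'   (`$model`), observation probability `$p_obs`, implied total samples
#'   `$M`, the log-likelihood trace and convergence flags.
#' @export
fit_er <- function(obs, priors, config = er_config(), verbose = FALSE) {
  stopifnot(inherits(obs, "ltrc_data"), inherits(config, "er_config"))
  n <- nrow(obs)
  if (n == 0L) stop("empty sample")
  priors <- lapply(priors, dd_from_spec)

  e_obs <- obs$t_y - obs$t_x
  x_max <- max(obs$x_star); y_max <- max(obs$y_star)
  tx_max <- max(obs$t_x)
  if (is.null(priors$TX)) priors$TX <- dd_uniform(0L, tx_max)
  if (is.null(priors$eps)) priors$eps <- dd_uniform(min(e_obs), max(e_obs))
  e_lo <- min(min(e_obs), priors$eps$offset)
  e_hi <- max(e_obs)
  x_M <- if (is.null(config$x_M)) x_max else config$x_M
  y_M <- if (is.null(config$y_M)) max(y_max, tx_max + e_hi) else config$y_M
  if (x_M < x_max || y_M < y_max) stop("support bounds below observed data")
  k_A <- min(x_M, y_M)

  grids <- list(A = c(0L, k_A), B = c(0L, x_M), C = c(0L, y_M),
                TX = c(0L, tx_max), eps = c(e_lo, e_hi))
  f0 <- Map(function(p, g) dd_restrict(p, g[1], g[2]),
            priors[c("A", "B", "C", "TX", "eps")], grids)

  # prior urns; c = 0 means flat zero-mass urns (pure EM)
  zero_urns <- function(d) list(beta = numeric(length(d$pmf)),
                                omega = numeric(length(d$pmf)))
  c_eff <- if (config$combine == "each") config$c else 0
  urns0 <- lapply(f0, function(d) {
    if (all(c_eff == 0)) zero_urns(d) else urns_from_prior(d, c_eff)
  })

  # group records once: unique (x, y, dX, dY) with multiplicities
  key <- paste(obs$x_star, obs$y_star, obs$delta_x, obs$delta_y)
  gi <- match(key, unique(key))
  first <- !duplicated(key)
  gx <- obs$x_star[first]; gy <- obs$y_star[first]
  gdx <- obs$delta_x[first]; gdy <- obs$delta_y[first]
  gw <- as.numeric(tabulate(gi, sum(first)))
  # grouped truncation pairs for the likelihood denominator
  tkey <- paste(obs$t_x, obs$t_y)
  tfirst <- !duplicated(tkey)
  gtx <- obs$t_x[tfirst]; gty <- obs$t_y[tfirst]
  gtw <- as.numeric(tabulate(match(tkey, unique(tkey)), sum(tfirst)))
  # empirical "still above j" counts for the truncation M-steps
  emp_gt <- function(vals, lo, hi)
    vapply(lo:hi, function(j) sum(vals > j), numeric(1))
  agg_emp_TX <- emp_gt(obs$t_x, 0L, tx_max)
  agg_emp_eps <- emp_gt(e_obs, e_lo, e_hi)

  cur <- f0
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  p_obs <- NA_real_; M <- n
  est <- NULL; model <- NULL

  for (k in seq_len(config$max_iter)) {
    trunc <- truncation_model(cur$TX, cur$eps)
    model <- one_factor_model(cur$A, cur$B, cur$C, trunc)
    est <- cpp_estep_obs(cur$A$pmf, cur$A$survival,
                         cur$B$pmf, cur$B$survival,
                         cur$C$pmf, cur$C$survival,
                         gx, gy, gdx, gdy, gw)
    if (any(est$denom <= 0)) {
      bad <- which(est$denom <= 0)
      stop("records with zero probability under the initial/current ",
           "model (x, y): ",
           paste(sprintf("(%d, %d)", gx[bad], gy[bad]), collapse = " "))
    }
    p_entry <- joint_tail(model, gtx, gty, "geq_geq")
    if (any(p_entry <= 0)) stop("zero entry probability at some (tX, tY)")
    ll <- sum(gw * log(est$denom)) - sum(gtw * log(p_entry))
    trace <- c(trace, ll)
    if (!isFALSE(verbose) && (k == 1L || k %% 100L == 0L))
      message(sprintf("iter %6d  loglik %.6f%s", k, ll,
                      if (identical(verbose, 2))
                        sprintf("  p_obs %.4f  M %.1f", p_obs, M) else ""))
    if (k > 1L && is.finite(ll_prev) &&
        abs((ll - ll_prev) / abs(ll_prev)) < config$tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll

    oc <- estep_observation_conditionals(model)
    p_obs <- oc$p_obs
    M <- total_samples(n, p_obs)
    phantom <- M - n

    surv_of <- function(pmf) c(rev(cumsum(rev(pmf)))[-1L], 0)
    agg <- list(A = surv_of(est$aggA), B = surv_of(est$aggB),
                C = surv_of(est$aggC), TX = agg_emp_TX,
                eps = agg_emp_eps)
    if (phantom > 1e-12 * n && p_obs < 1) {
      strat <- lapply(c(A = "A", B = "B", C = "C", TX = "TX", eps = "eps"),
                      function(v) condition_on_truncation(cur[[v]], oc[[v]],
                                                          p_obs))
      agg <- Map(function(a, s) a + phantom * s$survival, agg,
                 strat[names(agg)])
    }
    cur <- Map(function(a, u, g) {
      uu <- er_urns(u$beta, u$omega, a, c(M, a[-length(a)]), config$r)
      ratios_to_dist(uu$G, uu$N, offset = g[1])
    }, agg, urns0, grids)
  }

  # one final E-step under the returned estimates, from which the posterior
  # urn configuration (prior urns + reinforced EM aggregates) is assembled
  trunc <- truncation_model(cur$TX, cur$eps)
  model <- one_factor_model(cur$A, cur$B, cur$C, trunc)
  est <- cpp_estep_obs(cur$A$pmf, cur$A$survival,
                       cur$B$pmf, cur$B$survival,
                       cur$C$pmf, cur$C$survival,
                       gx, gy, gdx, gdy, gw)
  oc <- estep_observation_conditionals(model)
  p_obs <- oc$p_obs
  M <- total_samples(n, p_obs)
  surv_of <- function(pmf) c(rev(cumsum(rev(pmf)))[-1L], 0)
  agg <- list(A = surv_of(est$aggA), B = surv_of(est$aggB),
              C = surv_of(est$aggC), TX = agg_emp_TX, eps = agg_emp_eps)
  if (p_obs < 1 && M - n > 1e-12 * n) {
    strat <- lapply(c(A = "A", B = "B", C = "C", TX = "TX", eps = "eps"),
                    function(v) condition_on_truncation(cur[[v]], oc[[v]],
                                                        p_obs))
    agg <- Map(function(a, s) a + (M - n) * s$survival, agg,
               strat[names(agg)])
  }
  prior_urns <- if (all(config$c == 0)) lapply(f0, zero_urns)
                else lapply(f0, urns_from_prior, strength = config$c)
  urns_post <- Map(function(u, a, g)
    er_combine(u$beta, u$omega, a, config$r, M, offset = g[1]),
    prior_urns, agg, grids)

  if (config$combine == "at_convergence")
    cur <- lapply(urns_post, survival_from_urns)

  trunc <- truncation_model(cur$TX, cur$eps)
  model <- one_factor_model(cur$A, cur$B, cur$C, trunc)
  p_obs_final <- observation_probability(model)

  structure(list(dist = cur, urns = urns_post, model = model,
                 p_obs = p_obs_final, M = total_samples(n, p_obs_final),
                 n = n, loglik_trace = trace, iterations = length(trace),
                 converged = converged, config = config),
            class = "er_fit")
}

#' @export
print.er_fit <- function(x, ...) {
  mm <- model_moments(x$model)
  cat(sprintf(paste0(
    "er_fit: %d pairs, %d iterations (%s)\n",
    "  p(observed) = %.4f, implied total samples M = %.1f\n",
    "  E[X] = %.4f, E[Y] = %.4f, corr = %.4f\n"),
    x$n, x$iterations,
    if (x$converged) "converged" else "iteration cap reached",
    x$p_obs, x$M, mm$mean_x, mm$mean_y, mm$corr))
  invisible(x)
}
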