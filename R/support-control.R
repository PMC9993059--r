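#' Tail-error bound for a finite working support
#'
#' The E-step conditional of `T^X` given the observation event involves a
#' sum over the truncation lag that, on a computer, is cut at the `Y`
#' support bound `y_M`.  The resulting approximation error at `t` is
#' bounded by
#' `Omega_{y_M}(t) = [p_TX(t) / p_obs] * S_eps(y_M - t) * P(X >= t, Y >= y_M)`
#' for `t >= y_M - eps_max` and is zero otherwise.  Choosing
#' `y_M = T^X_max + eps_max` makes the bound (and the error) exactly zero.
#'
#' @param model a `one_factor_model` with a truncation model.
#' @param y_M candidate upper support bound for `Y`.
#' @param t integer vector of truncation values; default the whole `T^X`
#'   support.
#' @return list with the per-`t` bound `omega_t` and its sum `omega`.
#' @export
tail_error_bound <- function(model, y_M, t = NULL) {
  if (is.null(model$trunc)) stop("model carries no truncation model")
  tx <- model$trunc$dist_TX; ep <- model$trunc$dist_eps
  if (is.null(t)) {
    sup <- dd_support(tx)
    t <- sup[1]:sup[2]
  }
  p_obs <- observation_probability(model)
  eps_max <- dd_support(ep)[2]
  om <- dd_pmf(tx, t) / p_obs * dd_survival(ep, y_M - t) *
    joint_tail(model, t, rep(y_M, length(t)), "geq_geq")
  om[t < y_M - eps_max] <- 0
  list(t = t, omega_t = om, omega = sum(om))
}

#' Choose finite support bounds for the fit
#'
#' Returns the smallest `y_M` whose aggregate tail-error bound is at most
#' `tol`, capped at the exact value `T^X_max + eps_max` (at which the
#' bound vanishes identically), together with the remaining bounds of a
#' support plan.
#'
#' @param model a `one_factor_model` with a truncation model.
#' @param tol tolerance on the aggregate bound; `tol = 0` forces the
#'   exact cap.
#' @param y_min smallest admissible `y_M` (at least the largest observed
#'   `y`); default the `T^X` support lower bound.
#' @return list with `y_M`, `exact` (logical: is the cut error-free),
#'   `omega` (bound at the chosen `y_M`), `TX_max`, `eps_min`, `eps_max`.
#' @export
choose_support <- function(model, tol = 1e-12, y_min = NULL) {
  if (is.null(model$trunc)) stop("model carries no truncation model")
  tx_max <- dd_support(model$trunc$dist_TX)[2]
  esup <- dd_support(model$trunc$dist_eps)
  cap <- tx_max + esup[2]
  if (is.null(y_min)) y_min <- max(0L, esup[1] + 0L)
  y_M <- cap
  omega <- 0
  for (y in y_min:cap) {
    b <- tail_error_bound(model, y)
    if (b$omega <= tol) {
      y_M <- y; omega <- b$omega
      break
    }
  }
  list(y_M = y_M, exact = y_M >= cap, omega = omega,
       TX_max = tx_max, eps_min = esup[1], eps_max = esup[2])
}
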