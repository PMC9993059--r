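test_that("latent conditionals equal enumeration oracles in every pattern", {
  set.seed(51)
  for (rep in 1:4) {
    dA <- rand_dist(sample(2:4, 1)); dB <- rand_dist(sample(2:4, 1))
    dC <- rand_dist(sample(2:4, 1))
    m <- one_factor_model(dA, dB, dC)
    enum <- enumerate_latent(dA, dB, dC)
    sup <- list(A = 0:(length(dA$pmf) - 1L), B = 0:(length(dB$pmf) - 1L),
                C = 0:(length(dC$pmf) - 1L))
    col <- c(A = "a", B = "b", C = "c")
    for (x in 0:m$x_M) for (y in 0:m$y_M) for (dX in 0:1) for (dY in 0:1) {
      mask <- record_mask(enum, x, y, dX, dY)
      if (sum(enum$w[mask]) <= 1e-14) next
      for (v in c("A", "B", "C")) {
        got <- estep_latent_conditional(m, x, y, dX, dY, v)
        want <- oracle_conditional(enum, mask, col[[v]], sup[[v]])
        expect_equal(dd_pmf(got, sup[[v]]), want, tolerance = 1e-12)
        expect_equal(sum(got$pmf), 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("latent conditional hand examples", {
  # B and C degenerate at 0: A is forced to the observed value
  m <- one_factor_model(dd_uniform(0L, 3L), dd_pointmass(0L),
                        dd_pointmass(0L))
  got <- estep_latent_conditional(m, 2L, 2L, 1L, 1L, "A")
  expect_equal(dd_pmf(got, 0:3), c(0, 0, 1, 0))

  # uniform components, exact record (1, 1): the two latent outcomes
  # (a, b, c) = (0, 1, 1) and (1, 0, 0) are equally likely
  u <- dd_uniform(0L, 1L)
  mu <- one_factor_model(u, u, u)
  got <- estep_latent_conditional(mu, 1L, 1L, 1L, 1L, "A")
  expect_equal(dd_pmf(got, 0:1), c(1 / 2, 1 / 2), tolerance = 1e-12)

  expect_error(estep_latent_conditional(mu, 5L, 5L, 1L, 1L, "A"),
               "probability zero")
})

test_that("observation-event conditionals equal the five-way enumeration", {
  set.seed(52)
  for (rep in 1:3) {
    dA <- rand_dist(sample(2:4, 1)); dB <- rand_dist(sample(2:4, 1))
    dC <- rand_dist(sample(2:4, 1))
    dTX <- rand_dist(sample(2:3, 1))
    dEps <- rand_dist(3, offset = sample(-2:0, 1))
    m <- one_factor_model(dA, dB, dC, truncation_model(dTX, dEps))
    enum <- enumerate_latent(dA, dB, dC, dTX, dEps)
    oc <- estep_observation_conditionals(m)
    expect_equal(oc$p_obs, sum(enum$w[enum$observed]), tolerance = 1e-12)
    specs <- list(A = "a", B = "b", C = "c", TX = "t", eps = "e")
    for (v in names(specs)) {
      lv <- sort(unique(enum[[specs[[v]]]]))
      expect_equal(dd_pmf(oc[[v]], lv),
                   oracle_conditional(enum, enum$observed, specs[[v]], lv),
                   tolerance = 1e-12)
      expect_equal(sum(oc[[v]]$pmf), 1, tolerance = 1e-12)
    }
  }
})

test_that("sure observation makes every conditional unconditional", {
  set.seed(53)
  dA <- rand_dist(3); dB <- rand_dist(3); dC <- rand_dist(3)
  m <- one_factor_model(dA, dB, dC,
                        truncation_model(dd_pointmass(0L),
                                         dd_pointmass(0L)))
  oc <- estep_observation_conditionals(m)
  expect_equal(oc$p_obs, 1, tolerance = 1e-12)
  expect_equal(oc$A$pmf, dA$pmf, tolerance = 1e-12)
  expect_equal(oc$B$pmf, dB$pmf, tolerance = 1e-12)
  expect_equal(oc$C$pmf, dC$pmf, tolerance = 1e-12)
})

test_that("truncated-stratum conditioning inverts the mixture identity", {
  # hand example: full = uniform{0,1}, observed-conditional = point at 0
  res <- condition_on_truncation(dd_uniform(0L, 1L),
                                 discrete_dist(c(1, 0)), 0.5)
  expect_equal(dd_pmf(res, 0:1), c(0, 1))

  # conditional equal to marginal: stratum equals marginal too
  set.seed(54)
  p <- rand_dist(5)
  expect_equal(condition_on_truncation(p, p, 0.3)$pmf, p$pmf,
               tolerance = 1e-12)

  # enumeration oracle on a tiny model
  dA <- rand_dist(3); dB <- rand_dist(3); dC <- rand_dist(3)
  dTX <- rand_dist(3); dEps <- rand_dist(2, offset = -1L)
  m <- one_factor_model(dA, dB, dC, truncation_model(dTX, dEps))
  enum <- enumerate_latent(dA, dB, dC, dTX, dEps)
  oc <- estep_observation_conditionals(m)
  strat <- condition_on_truncation(dA, oc$A, oc$p_obs)
  want <- oracle_conditional(enum, !enum$observed, "a", 0:2)
  expect_equal(dd_pmf(strat, 0:2), want, tolerance = 1e-9)

  # a grossly inconsistent pair is rejected
  expect_error(condition_on_truncation(discrete_dist(c(0.9, 0.1)),
                                       discrete_dist(c(0.1, 0.9)), 0.9),
               "negative stratum mass")
})

test_that("implied total sample size", {
  expect_equal(total_samples(100L, 1), 100)
  expect_equal(total_samples(100L, 0.5), 200)
  expect_error(total_samples(10L, 0), "positive")
})

test_that("M-step ratios telescope back to the aggregate survivals", {
  # point-mass conditional: fitted distribution is that point mass
  d <- mstep_update(c(1, 1, 0, 0), M = 1, n = 1)
  expect_equal(dd_pmf(d, 0:3), c(0, 0, 1, 0))

  # fixed point: aggregate survivals of a pmf scaled by n reproduce it
  set.seed(55)
  p <- rand_dist(6)
  n <- 37
  agg <- n * p$survival
  expect_equal(mstep_update(agg, M = n, n = n)$pmf, p$pmf,
               tolerance = 1e-12)

  # random aggregates: survival of the result equals agg / M exactly
  agg <- sort(runif(8), decreasing = TRUE) * 12
  agg[8] <- 0
  d <- mstep_update(agg, M = 12, n = 12)
  expect_equal(dd_survival(d, 0:7), agg / 12, tolerance = 1e-12)
})

test_that("reinforcement combination blends prior urns and EM aggregates", {
  # hand substitution: omega = beta = 1, r = 1, agg = 0.6, prev = 1.0
  u <- er_combine(beta = 1, omega = 1, agg_surv = 0.6, r = 1, M = 1)
  expect_equal(u$G / u$N, 1.6 / 3, tolerance = 1e-12)

  # r -> 0: prior ratios
  set.seed(56)
  f0 <- rand_dist(5)
  pu <- urns_from_prior(f0, 2)
  agg <- runif(5, 0, 3)
  u0 <- er_combine(pu$beta, pu$omega, sort(agg, decreasing = TRUE),
                   r = 1e-14, M = 5)
  expect_equal(survival_from_urns(u0)$pmf, f0$pmf, tolerance = 1e-6)

  # beta = omega = 0: pure EM estimate, independent of r
  agg <- c(3, 2, 1, 0)
  u1 <- er_combine(numeric(4), numeric(4), agg, r = 1, M = 4)
  u2 <- er_combine(numeric(4), numeric(4), agg, r = 50, M = 4)
  expect_equal(survival_from_urns(u1)$pmf, survival_from_urns(u2)$pmf,
               tolerance = 1e-12)
  expect_equal(survival_from_urns(u1)$pmf,
               mstep_update(agg, M = 4, n = 4)$pmf, tolerance = 1e-12)
})

test_that("EM with no truncation increases the incomplete log-likelihood", {
  rec <- sim_recipe(A = dd_poisson(4), B = dd_poisson(3), C = dd_poisson(3),
                    TX = dd_pointmass(0L), eps = dd_pointmass(0L),
                    Delta = dd_poisson(4), n_observed = 250, seed = 57)
  sim <- simulate_ltrc(rec)
  fit <- fit_er(sim$obs,
                list(A = dd_poisson(3), B = dd_poisson(3),
                     C = dd_poisson(3), TX = dd_pointmass(0L),
                     eps = dd_pointmass(0L)),
                er_config(r = 1, c = 0, tol = 1e-8, max_iter = 150))
  expect_true(all(diff(fit$loglik_trace) > -1e-7))
  expect_equal(fit$p_obs, 1, tolerance = 1e-9)
  expect_equal(fit$M, fit$n, tolerance = 1e-6)
})

test_that("maximum-likelihood fit recovers the marginal law without LTRC", {
  # fully observed pairs: fitted X-marginal should match the empirical one
  rec <- sim_recipe(A = dd_poisson(4), B = dd_poisson(2),
                    C = dd_poisson(3), TX = dd_pointmass(0L),
                    eps = dd_pointmass(0L), Delta = dd_pointmass(50L),
                    n_observed = 2000, seed = 58)
  sim <- simulate_ltrc(rec, keep_latent = TRUE)
  expect_equal(sim$n_rejected, 0L)
  expect_true(all(sim$obs$delta_x == 1L & sim$obs$delta_y == 1L))
  fit <- fit_er(sim$obs,
                list(A = dd_poisson(3), B = dd_poisson(3),
                     C = dd_poisson(3), TX = dd_pointmass(0L),
                     eps = dd_pointmass(0L)),
                er_config(r = 1, c = 0, tol = 1e-9, max_iter = 400))
  px_fit <- rowSums(fit$model$joint)
  emp <- tabulate(sim$obs$x_star + 1L, fit$model$x_M + 1L) / 2000
  tv <- 0.5 * sum(abs(px_fit - emp))
  expect_lt(tv, 0.02)
})

test_that("reinforcement limits: tiny r pins the fit to the prior", {
  rec <- sim_recipe(A = dd_poisson(3), B = dd_poisson(2), C = dd_poisson(2),
                    TX = dd_pointmass(0L), eps = dd_pointmass(0L),
                    Delta = dd_pointmass(50L), n_observed = 100, seed = 59)
  sim <- simulate_ltrc(rec)
  priors <- list(A = dd_poisson(2), B = dd_poisson(2), C = dd_poisson(2),
                 TX = dd_pointmass(0L), eps = dd_pointmass(0L))
  fit <- fit_er(sim$obs, priors, er_config(r = 1e-12, c = 1, tol = 1e-8,
                                           max_iter = 5))
  kA <- length(fit$dist$A$pmf)
  prior_A <- dd_restrict(priors$A, 0L, kA - 1L)
  expect_equal(fit$dist$A$pmf, prior_A$pmf, tolerance = 1e-6)
})
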