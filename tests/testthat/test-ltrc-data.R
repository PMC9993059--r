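test_that("counting statistics match hand enumeration", {
  # records (x*, delta, t): (2,1,0), (3,0,1), (3,1,0)
  cv <- count_events(c(2L, 3L, 3L), c(1L, 0L, 1L), c(0L, 1L, 0L))
  expect_equal(cv$m, c(0L, 0L, 1L, 1L))
  expect_equal(cv$r_cens, c(0L, 0L, 0L, 1L))
  expect_equal(cv$s, c(2L, 3L, 3L, 2L))
  expect_equal(cv$l, c(2L, 3L, 3L, 3L))
  expect_true(all(cv$m + cv$r_cens <= cv$s))
  expect_equal(sum(cv$m + cv$r_cens), cv$n)

  empty <- count_events(integer(0), integer(0), integer(0))
  expect_true(all(empty$m == 0L & empty$s == 0L & empty$l == 0L))

  one <- count_events(5L, 1L, 0L)
  expect_equal(one$s, rep(1L, 6))
  expect_equal(one$m, c(0L, 0L, 0L, 0L, 0L, 1L))

  expect_error(count_events(c(1L, 2L), c(1L, 1L), 0L), "equal length")
  expect_error(count_events(1L, 1L, 2L), "below its truncation")
})

test_that("product-limit estimator reproduces hand products", {
  # single uncensored observation at 5
  km1 <- km_product_limit(count_events(5L, 1L, 0L))
  expect_equal(dd_survival(km1, 0:5), c(1, 1, 1, 1, 1, 0))

  # all censored: survival 1 across the observed grid
  km2 <- km_product_limit(count_events(c(2L, 4L), c(0L, 0L), c(0L, 0L)))
  expect_equal(dd_survival(km2, 0:4), rep(1, 5))

  # three-record example: S(2) = 2/3, S(3) = 1/3
  km3 <- km_product_limit(count_events(c(2L, 3L, 3L), c(1L, 0L, 1L),
                                       c(0L, 1L, 0L)))
  expect_equal(dd_survival(km3, 2L), 2 / 3, tolerance = 1e-12)
  expect_equal(dd_survival(km3, 3L), 1 / 3, tolerance = 1e-12)
})

test_that("without censoring or truncation the estimator is empirical", {
  set.seed(11)
  x <- rpois(60, 4)
  km <- km_product_limit(count_events(x, rep(1L, 60), rep(0L, 60)))
  emp <- vapply(0:max(x), function(j) mean(x > j), numeric(1))
  expect_equal(dd_survival(km, 0:max(x)), emp, tolerance = 1e-12)
  # total-variation distance on the grid is zero
  expect_equal(sum(abs(dd_pmf(km, 0:max(x)) -
                         tabulate(x + 1L, max(x) + 1L) / 60)), 0,
               tolerance = 1e-12)
})

test_that("the product-limit estimate maximizes the LTRC likelihood", {
  # toy sample, candidate pmfs supported on the observed exact points
  x <- c(1L, 2L, 2L, 4L); d <- c(1L, 1L, 0L, 1L); tr <- c(0L, 1L, 0L, 2L)
  cv <- count_events(x, d, tr)
  km <- km_product_limit(cv)
  ll_km <- loglik_univariate(x, d, tr, km)
  set.seed(42)
  pts <- sort(unique(c(x[d == 1], max(x) + 1L)))  # allow tail mass point
  for (i in 1:300) {
    w <- rexp(length(pts))
    pmf <- numeric(max(pts) + 1L)
    pmf[pts + 1L] <- w / sum(w)
    cand <- discrete_dist(pmf, normalize = TRUE)
    expect_lte(loglik_univariate(x, d, tr, cand), ll_km + 1e-9)
  }
})

test_that("univariate log-likelihood matches hand evaluations", {
  unif01 <- dd_uniform(0L, 1L)
  expect_equal(loglik_univariate(0L, 1L, 0L, dd_pointmass(0L)), 0)
  expect_equal(loglik_univariate(0L, 0L, 0L, unif01), log(0.5))
  # truncated at 1, exact at 1: log(1/2) - log(1/2) = 0
  expect_equal(loglik_univariate(1L, 1L, 1L, unif01), 0)
  # zero probability flagged as -Inf, not an error
  ll <- loglik_univariate(3L, 1L, 0L, unif01)
  expect_identical(as.numeric(ll), -Inf)
  expect_equal(attr(ll, "zero_probability_records"), 1L)
})

test_that("bivariate likelihood reduces to marginal sums when A is degenerate", {
  set.seed(21)
  dB <- rand_dist(6); dC <- rand_dist(6)
  m <- one_factor_model(dd_pointmass(0L), dB, dC)
  obs <- toy_ltrc()
  ll2 <- loglik_bivariate(obs, m)
  ll_marg <- loglik_univariate(obs$x_star, obs$delta_x, obs$t_x, dB) +
    loglik_univariate(obs$y_star, obs$delta_y, obs$t_y, dC)
  expect_equal(ll2, ll_marg, tolerance = 1e-10)
})

test_that("bivariate likelihood handles the four indicator patterns", {
  set.seed(22)
  dA <- rand_dist(3); dB <- rand_dist(3); dC <- rand_dist(3)
  m <- one_factor_model(dA, dB, dC)
  enum <- enumerate_latent(dA, dB, dC)
  # fully exact record with no truncation: log joint pmf
  expect_equal(loglik_bivariate(ltrc_data(2L, 1L, 0L, 2L, 1L, 0L), m),
               log(sum(enum$w[enum$x == 2 & enum$y == 2])),
               tolerance = 1e-12)
  # doubly censored record under a point-mass model above both: log 1
  mp <- one_factor_model(discrete_dist(c(0, 0, 0, 1)), dd_pointmass(0L),
                         dd_pointmass(0L))
  expect_equal(loglik_bivariate(ltrc_data(1L, 0L, 0L, 1L, 0L, 0L), mp), 0)
})

test_that("reader validates the schema and drops impossible rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(x = c(4, 2), delta_x = c(1, 1), t_x = c(1, 3),
                   y = c(5, 4), delta_y = c(0, 1), t_y = c(2, 1))
  write.csv(df, f, row.names = FALSE)
  expect_warning(obs <- read_ltrc(f), "truncation condition")
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$x_star, 4L)

  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[, -3], f2, row.names = FALSE)
  expect_error(read_ltrc(f2), "t_x")
})
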