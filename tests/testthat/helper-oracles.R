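# Brute-force oracles used across the suite.  They enumerate the full
# latent space of tiny models and never touch the package's convolution
# or E-step code paths.

rand_dist <- function(k, offset = 0L) {
  discrete_dist(stats::runif(k) + 0.05, offset = offset, normalize = TRUE)
}

# all latent configurations of a one-factor model with truncation,
# with their joint weights and derived quantities
enumerate_latent <- function(dA, dB, dC, dTX = NULL, dEps = NULL) {
  sup <- function(d) {
    s <- dd_support(d)
    s[1]:s[2]
  }
  g <- expand.grid(a = sup(dA), b = sup(dB), c = sup(dC))
  g$w <- dd_pmf(dA, g$a) * dd_pmf(dB, g$b) * dd_pmf(dC, g$c)
  if (!is.null(dTX)) {
    g <- merge(g, expand.grid(t = sup(dTX), e = sup(dEps)))
    g$w <- g$w * dd_pmf(dTX, g$t) * dd_pmf(dEps, g$e)
  }
  g$x <- g$a + g$b
  g$y <- g$a + g$c
  if (!is.null(dTX)) g$observed <- g$t <= g$x & g$t + g$e <= g$y
  g
}

# conditional pmf of one latent column given an event mask, on `levels`
oracle_conditional <- function(enum, mask, column, levels) {
  w <- tapply(enum$w[mask], factor(enum[[column]][mask], levels = levels),
              sum)
  w[is.na(w)] <- 0
  as.numeric(w / sum(w))
}

# event mask for an observed record (x, y, dX, dY)
record_mask <- function(enum, x, y, dX, dY) {
  mx <- if (dX == 1) enum$x == x else enum$x > x
  my <- if (dY == 1) enum$y == y else enum$y > y
  mx & my
}

# a small LTRC dataset with a bit of everything (hand-checkable sizes)
toy_ltrc <- function() {
  ltrc_data(x_star = c(2L, 3L, 3L, 4L), delta_x = c(1L, 0L, 1L, 1L),
            t_x = c(0L, 1L, 0L, 2L),
            y_star = c(3L, 2L, 4L, 3L), delta_y = c(1L, 1L, 0L, 1L),
            t_y = c(1L, 0L, 1L, 2L))
}
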