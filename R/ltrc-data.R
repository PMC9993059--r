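#' Paired LTRC observations
#'
#' Container for bivariate left-truncated right-censored records.  Each
#' record is the sextuple `(x_star, delta_x, t_x, y_star, delta_y, t_y)`:
#' the observed (possibly censored) lifetimes of the two members of a pair,
#' their censoring indicators (1 = exact, 0 = right-censored) and their
#' left-truncation values.  A record can only have been observed if
#' `t_x <= x_star` and `t_y <= y_star`; rows violating this are rejected.
#'
#' @param x_star,y_star integer observed values.
#' @param delta_x,delta_y censoring indicators in `{0, 1}`.
#' @param t_x,t_y integer truncation values.
#' @return an object of class `ltrc_data` (a validated data frame).
#' @export
ltrc_data <- function(x_star, delta_x, t_x, y_star, delta_y, t_y) {
  df <- data.frame(x_star = as.integer(x_star), delta_x = as.integer(delta_x),
                   t_x = as.integer(t_x), y_star = as.integer(y_star),
                   delta_y = as.integer(delta_y), t_y = as.integer(t_y))
  validate_ltrc(df)
}

validate_ltrc <- function(df, on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  need <- c("x_star", "delta_x", "t_x", "y_star", "delta_y", "t_y")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[need]
  for (cl in need) df[[cl]] <- as.integer(df[[cl]])
  if (anyNA(df)) stop("LTRC records contain non-integer or missing cells")
  if (!all(df$delta_x %in% 0:1 & df$delta_y %in% 0:1))
    stop("censoring indicators must be 0 or 1")
  if (any(df$x_star < 0 | df$y_star < 0 | df$t_x < 0 | df$t_y < 0))
    stop("lifetimes and truncation values must be non-negative")
  bad <- df$t_x > df$x_star | df$t_y > df$y_star
  if (any(bad)) {
    msg <- sprintf("%d record(s) violate the truncation condition t <= x*",
                   sum(bad))
    if (on_invalid == "error") stop(msg)
    warning(msg, "; dropped")
    df <- df[!bad, , drop = FALSE]
  }
  structure(df, class = c("ltrc_data", "data.frame"))
}

#' Read paired LTRC records from delimited text
#'
#' Expects a header with columns `x,delta_x,t_x,y,delta_y,t_y` (or the
#' `x_star`/`y_star` aliases); the delimiter is sniffed from the extension
#' (`.tsv` means tab, anything else comma).  Rows violating `t <= x*` are
#' dropped with a warning naming how many.
#'
#' @param path file path.
#' @param sep field delimiter; default inferred from the extension.
#' @return an `ltrc_data` object.
#' @export
read_ltrc <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  nm <- names(df)
  nm[nm == "x"] <- "x_star"
  nm[nm == "y"] <- "y_star"
  names(df) <- nm
  validate_ltrc(df, on_invalid = "drop")
}

#' @export
print.ltrc_data <- function(x, ...) {
  cat(sprintf(
    "ltrc_data: %d pairs; censored X %.1f%%, Y %.1f%%; max x* %d, max y* %d\n",
    nrow(x), 100 * mean(x$delta_x == 0), 100 * mean(x$delta_y == 0),
    max(x$x_star), max(x$y_star)))
  invisible(x)
}

#' Counting statistics of a univariate LTRC sample
#'
#' For each grid point `j` computes the number of exact observations
#' `m_j = #\{x_i = j, delta_i = 1\}`, the censored count
#' `r_j = #\{x_i = j, delta_i = 0\}`, the at-risk count
#' `s_j = #\{t_i <= j <= x_i\}` and the cumulative truncation count
#' `l_j = #\{t_i <= j\}`.  These are the sufficient statistics of the LTRC
#' product-limit estimator and of the reinforced-urn conjugate update.
#'
#' @param values integer observed values `x*`.
#' @param indicators censoring indicators in `{0, 1}`.
#' @param truncations integer truncation values `t` (default all 0).
#' @param grid_max upper grid bound; default `max(values)` (0 grid for an
#'   empty sample).
#' @return an object of class `count_vectors`: list with integer vectors
#'   `m`, `r_cens`, `s`, `l` indexed by `j = 0..grid_max`, plus `n` and
#'   `grid_max`.
#' @export
count_events <- function(values, indicators, truncations = NULL,
                         grid_max = NULL) {
  n <- length(values)
  if (is.null(truncations)) truncations <- integer(n)
  if (length(indicators) != n || length(truncations) != n)
    stop("values, indicators and truncations must have equal length")
  values <- as.integer(values); truncations <- as.integer(truncations)
  if (any(truncations > values))
    stop("record with value below its truncation cannot be observed")
  if (!all(indicators %in% 0:1)) stop("indicators must be 0 or 1")
  if (is.null(grid_max)) grid_max <- if (n) max(values) else 0L
  grid_max <- as.integer(grid_max)
  if (n && grid_max < max(values)) stop("grid_max below the largest value")
  j <- 0:grid_max
  m <- r_cens <- s <- l <- integer(grid_max + 1L)
  if (n) {
    tab_exact <- tabulate(values[indicators == 1] + 1L, grid_max + 1L)
    tab_cens  <- tabulate(values[indicators == 0] + 1L, grid_max + 1L)
    m <- tab_exact; r_cens <- tab_cens
    # s_j via entry/exit differencing: +1 at t_i, -1 at x_i + 1
    ent <- tabulate(truncations + 1L, grid_max + 2L)
    ext <- tabulate(values + 2L, grid_max + 2L)
    s <- cumsum(ent - ext)[seq_len(grid_max + 1L)]
    l <- cumsum(tabulate(truncations + 1L, grid_max + 1L))
  }
  structure(list(m = m, r_cens = r_cens, s = s, l = l,
                 n = n, grid_max = grid_max),
            class = "count_vectors")
}

#' LTRC product-limit (Kaplan-Meier / Lynden-Bell) estimator
#'
#' `S(x) = prod_{j = 0..x} (1 - m_j / s_j)`, with the convention that a
#' grid point with `s_j = 0` contributes factor 1 (no information at `j`).
#' Without truncation this is the Kaplan-Meier estimator; without censoring
#' it is Lynden-Bell's estimator.  When the estimate is defective (survival
#' mass left after the last exact observation, as happens with censoring)
#' the remainder is carried by one extra grid point at `grid_max + 1`, so
#' the product-limit survival values on `[0, grid_max]` are untouched and
#' the returned distribution is still proper.
#'
#' @param counts a `count_vectors` object.
#' @return a `discrete_dist` on `[0, grid_max]` (or `[0, grid_max + 1]` for
#'   a defective estimate).
#' @export
km_product_limit <- function(counts) {
  stopifnot(inherits(counts, "count_vectors"))
  haz <- ifelse(counts$s > 0, counts$m / counts$s, 0)
  surv <- cumprod(1 - haz)
  pmf <- -diff(c(1, surv))
  tail_mass <- surv[length(surv)]
  if (tail_mass > 0) pmf <- c(pmf, tail_mass)
  discrete_dist(pmf, offset = 0L, normalize = TRUE)
}

#' Univariate LTRC log-likelihood
#'
#' `sum_i [(1 - delta_i) log P(X > x*_i) + delta_i log P(X = x*_i)
#'  - log P(X >= t_i)]`.  Returns `-Inf` (with an attribute listing the
#' offending records) when a required probability is zero, so that
#' optimizers and stopping rules can proceed rather than error.
#'
#' @param values,indicators,truncations the univariate LTRC triplets.
#' @param dist a `discrete_dist` for `X`.
#' @return scalar log-likelihood, possibly `-Inf`.
#' @export
loglik_univariate <- function(values, indicators, truncations, dist) {
  p_exact <- dd_pmf(dist, values)
  p_above <- dd_survival(dist, values)
  p_entry <- dd_survival(dist, truncations - 1L)   # P(X >= t) = P(X > t-1)
  term <- ifelse(indicators == 1, log(p_exact), log(p_above)) - log(p_entry)
  if (any(!is.finite(term))) {
    out <- -Inf
    attr(out, "zero_probability_records") <- which(!is.finite(term))
    return(out)
  }
  sum(term)
}

#' Bivariate incomplete LTRC log-likelihood
#'
#' The observed-data log-likelihood of paired LTRC records under a
#' one-factor model:
#' `sum_i [log P*(x*_i, y*_i | dX_i, dY_i) - log P(X >= tX_i, Y >= tY_i)]`,
#' where `P*` is the joint pmf, a mixed tail, or the double tail according
#' to the censoring-indicator pattern.  Returns `-Inf` with a diagnostic
#' attribute when a required probability is zero.  This is the quantity
#' whose relative change drives the ER stopping rule.
#'
#' @param obs an `ltrc_data` object.
#' @param model a `one_factor_model`.
#' @return scalar log-likelihood, possibly `-Inf`.
#' @export
loglik_bivariate <- function(obs, model) {
  stopifnot(inherits(obs, "ltrc_data"), inherits(model, "one_factor_model"))
  pstar <- numeric(nrow(obs))
  pat <- paste0(obs$delta_x, obs$delta_y)
  for (pp in unique(pat)) {
    i <- pat == pp
    pstar[i] <- switch(pp,
      "11" = joint_pmf(model, obs$x_star[i], obs$y_star[i]),
      "01" = joint_tail(model, obs$x_star[i], obs$y_star[i], "gt_eq"),
      "10" = joint_tail(model, obs$x_star[i], obs$y_star[i], "eq_gt"),
      "00" = joint_tail(model, obs$x_star[i], obs$y_star[i], "gt_gt"))
  }
  p_entry <- joint_tail(model, obs$t_x, obs$t_y, "geq_geq")
  term <- log(pstar) - log(p_entry)
  if (any(!is.finite(term))) {
    out <- -Inf
    attr(out, "zero_probability_records") <- which(!is.finite(term))
    return(out)
  }
  sum(term)
}
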