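# Independent oracles kept deliberately naive: definitional formulas solved
# by explicit normal equations / enumeration, never sharing code with the
# package implementation.

# Brute-force local weighted polynomial regression at a single query point:
# q = ceiling(span * n) nearest points, tricube (or uniform) weights, normal
# equations solved directly.
oracle_local_fit <- function(u, y, x0, span, degree, weights = "tricube") {
  n <- length(u)
  q <- ceiling(span * n)
  d <- abs(u - x0)
  dmax <- sort(d)[q]
  idx <- which(d <= dmax)
  w <- if (weights == "uniform" || dmax == 0) rep(1, length(idx))
       else (1 - (d[idx] / dmax)^3)^3
  X <- outer(u[idx] - x0, 0:degree, `^`)
  A <- crossprod(X, w * X)
  b <- crossprod(X, w * y[idx])
  drop(solve(A, b))[1L]
}

# Definitional Spearman: rank both vectors (midranks), then textbook Pearson.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Closed-form simple OLS from the normal equations.
oracle_ols <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Expected utility of a 5L profile under a probabilistic crosswalk by full
# enumeration of the 243-entry 3L utility vector.
oracle_expected_utility <- function(weight_row, vs) {
  u3 <- vapply(names(weight_row),
               function(s) apply_value_set(parse_profile(s, "3L"), vs),
               numeric(1))
  sum(weight_row * u3)
}
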