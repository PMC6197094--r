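# independent oracles used against the package's fitting and integration
# routines; these deliberately avoid lm()/uniroot() so the two routes share
# no code

# straight-line least squares via the normal equations
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(crossprod(X), crossprod(X, y))
  c(intercept = beta[1L], slope = beta[2L])
}

# degree-d polynomial least squares via the normal equations
poly_oracle <- function(x, y, degree = 3L) {
  X <- outer(x, 0:degree, `^`)
  drop(solve(crossprod(X), crossprod(X, y)))  # (c0, c1, ..., cd)
}

# brute-force Riemann sum of clipped degree hours at 1-minute resolution
riemann_adh <- function(series, D0, start_h, end_h, dt = 1 / 60) {
  grid <- seq(start_h, end_h, by = dt)
  tt <- series$time_h; vv <- series$temp_C
  temp_at <- function(x) {
    if (identical(attr(series, "interpolation"), "linear"))
      approx(tt, vv, xout = x)$y
    else vv[findInterval(x, tt, rightmost.closed = TRUE)]
  }
  mids <- (head(grid, -1) + grid[-1]) / 2
  sum(pmax(temp_at(mids) - D0, 0)) * dt
}

eval_cubic_oracle <- function(c3, c2, c1, c0, x) c3 * x^3 + c2 * x^2 + c1 * x + c0

# noiseless measurements sampled from a cubic growth curve
noiseless_growth_data <- function(curve, by = 4) {
  tt <- seq(0, curve$valid_max, by = by)
  data.frame(time_h = tt,
             length_mm = eval_cubic_oracle(curve$coefficients[1], curve$coefficients[2],
                                           curve$coefficients[3], curve$coefficients[4], tt))
}

expect_rel_close <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
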