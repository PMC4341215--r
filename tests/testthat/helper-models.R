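# Shared fixtures and independent oracles.

study_rates <- function(bp = 1, F = 2, k4 = 0.1, k5 = 0.16, k6 = 0.06) {
  rate_constants(F = F, k3 = bp * k4, k4 = k4, k5 = k5, k6 = k6)
}

# Independent numerical oracle: generic ODE integration of the compartment
# system with deSolve (never the package's eigen/expm path).
ode_oracle <- function(initial, rates, times, variant = "DPM-NS",
                       probe = "targeted", washout_active = TRUE) {
  A <- build_generator(rates, variant, probe, washout_active)
  f <- function(t, y, parms) list(as.vector(A %*% y))
  t0 <- if (times[1L] > 0) c(0, times) else times
  out <- deSolve::ode(y = initial, times = t0, func = f, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  out <- out[match(times, out[, 1L]), -1L, drop = FALSE]
  unname(as.matrix(out))
}

# Closed-form ridge solution the Kaczmarz solver must agree with.
ridge_oracle <- function(B, y, lambda) {
  solve(crossprod(B) + diag(lambda, ncol(B)), crossprod(B, y))
}

# Curves where the ratiometric estimator is exact by construction:
# targeted = (1 + bp) * untargeted at every point.
proportional_measurement <- function(bp, n = 11L) {
  tt <- seq(0, 5, length.out = n)
  u <- 150 * exp(-0.4 * tt)
  dual_probe_measurement(
    "prop", "synthetic",
    targeted = concentration_curve("targeted", tt, (1 + bp) * u),
    untargeted = concentration_curve("untargeted", tt, u))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
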