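# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: the ODE oracle integrates the raw
# right-hand sides with deSolve, derivatives come from central finite
# differences, and the clipped-normal mean is the textbook closed form.

# numerically integrate dP/dt = (r - c) P, dB/dt = c P from (P0, 0)
ode_oracle <- function(r, c, t_end, P0, times = c(0, t_end)) {
  rhs <- function(t, y, parms) {
    list(c((r - c) * y[1], c * y[1]))
  }
  sol <- deSolve::ode(y = c(P = P0, B = 0), times = times, func = rhs,
                      parms = NULL, rtol = 1e-10, atol = 1e-8)
  list(P = sol[nrow(sol), "P"], B = sol[nrow(sol), "B"])
}

# central finite difference of f at x
central_diff <- function(f, x, h = 1e-6) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# mean of a normal(mu, sigma) clipped to [lo, hi]
clipped_normal_mean <- function(mu, sigma, lo = -Inf, hi = Inf) {
  if (sigma == 0) return(min(max(mu, lo), hi))
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  lo_term <- if (is.finite(lo)) lo * stats::pnorm(a) else 0
  hi_term <- if (is.finite(hi)) hi * (1 - stats::pnorm(b)) else 0
  mid <- mu * (stats::pnorm(b) - stats::pnorm(a)) -
    sigma * (stats::dnorm(b) - stats::dnorm(a))
  lo_term + hi_term + mid
}

# brute-force argmax of per-founder fitness over [0, r]
brute_force_c_star <- function(r, t_end, k_p, k_b, n = 1e5) {
  cs <- seq(0, r, length.out = n)
  cs[which.max(per_founder_fitness(cs, r, t_end, k_p, k_b))]
}
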