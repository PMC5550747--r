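test_that("closed-form planktonic solution matches its defining cases", {
  # static plankton at c = r
  p <- within_patch_params(r = 0.08, c = 0.08, t_end = 40)
  expect_identical(planktonic_at(p, 40), 5e6)
  expect_identical(planktonic_at(p, 0), 5e6)
  # pure Malthusian growth at c = 0
  p2 <- within_patch_params(r = 0.1, c = 0, t_end = 10, P0 = 1000)
  expect_equal(planktonic_at(p2, 10), 1000 * exp(1))
  expect_error(planktonic_at(p2, -1), "non-negative")
})

test_that("parameter constructor enforces the domain invariants", {
  expect_error(within_patch_params(r = 0.08, c = -0.01, t_end = 40))
  expect_error(within_patch_params(r = 0.08, c = 0.04, t_end = 40, P0 = 0))
  expect_error(within_patch_params(r = 0.08, c = 0.04, t_end = 40, d = 0.1),
               "simplified")
  full <- within_patch_params(r = 0.08, c = 0.04, t_end = 40, d = 0.1,
                              g = 100, growth_form = "linear")
  expect_error(planktonic_at(full, 10), "closed-form")
})

test_that("biofilm closed form handles c = 0, c = r, and c > r", {
  expect_equal(biofilm_at(within_patch_params(0.08, 0, 40), 40), 0)
  # removable singularity at c = r: B = c P0 t
  p <- within_patch_params(r = 0.08, c = 0.08, t_end = 40)
  expect_equal(biofilm_at(p, 40), 0.08 * 5e6 * 40)
  # generic interior value against the closed form and the ODE oracle
  p2 <- within_patch_params(r = 0.08, c = 0.04, t_end = 40)
  expect_equal(biofilm_at(p2, 40), 5e6 * (exp(1.6) - 1), tolerance = 1e-12)
  orc <- ode_oracle(0.08, 0.04, 40, 5e6)
  expect_equal(biofilm_at(p2, 40), unname(orc$B), tolerance = 1e-8)
  # c beyond r: plankton declines, biofilm stays non-negative
  p3 <- within_patch_params(r = 0.05, c = 0.2, t_end = 30)
  expect_lt(planktonic_at(p3, 30), p3$P0)
  expect_gt(biofilm_at(p3, 30), 0)
  orc3 <- ode_oracle(0.05, 0.2, 30, 5e6)
  expect_equal(biofilm_at(p3, 30), unname(orc3$B), tolerance = 1e-8)
})

test_that("closed forms satisfy the governing equations on random draws", {
  set.seed(42)
  for (i in 1:20) {
    r <- runif(1, 0.01, 0.15)
    cc <- runif(1, 0, r * 1.2)
    P0 <- 10^runif(1, 2, 7)
    tt <- runif(1, 5, 60)
    p <- within_patch_params(r = r, c = cc, t_end = tt, P0 = P0)
    dP <- central_diff(function(s) planktonic_at(p, s), tt, h = 1e-4)
    dB <- central_diff(function(s) biofilm_at(p, s), tt, h = 1e-4)
    P <- planktonic_at(p, tt)
    expect_equal(dP, (r - cc) * P, tolerance = 1e-5)
    expect_equal(dB, cc * P, tolerance = 1e-5)
  }
})

test_that("trajectories are consistent, monotone in c, and show the
           early/late biofilm crossover", {
  p <- within_patch_params(r = 0.08, c = 0.03, t_end = 40)
  tr <- solve_trajectory(p, times = c(0, 10, 40))
  expect_equal(tr$P, planktonic_at(p, c(0, 10, 40)))
  expect_equal(tr$B, biofilm_at(p, c(0, 10, 40)))
  expect_error(solve_trajectory(p, times = c(10, 5)), "increasing")
  # at fixed time, P declines monotonically in c while B > 0 for c > 0
  crs <- seq(0.1, 0.99, length.out = 15)
  P40 <- sapply(crs, function(cr)
    planktonic_at(within_patch_params(0.08, cr * 0.08, 40), 40))
  B40 <- sapply(crs, function(cr)
    biofilm_at(within_patch_params(0.08, cr * 0.08, 40), 40))
  expect_true(all(diff(P40) < 0))
  expect_true(all(B40 > 0))
  # crossing: the fastest colonizer leads early, a slower one wins late
  b_hi <- function(s) biofilm_at(within_patch_params(0.08, 0.99 * 0.08, 40), s)
  b_lo <- function(s) biofilm_at(within_patch_params(0.08, 0.3 * 0.08, 40), s)
  expect_gt(b_hi(5), b_lo(5))
  expect_lt(b_hi(40), b_lo(40))
})

test_that("full-model integration reduces to the closed forms and obeys
           the dispersal/growth extensions", {
  p <- within_patch_params(r = 0.08, c = 0.04, t_end = 40)
  full <- integrate_full_model(p)
  closed <- solve_trajectory(p, times = full$time)
  expect_equal(full$P, closed$P, tolerance = 1e-6)
  expect_equal(full$B, closed$B, tolerance = 1e-6)
  # intrinsic linear biofilm growth adds cells relative to the reduced model
  for (r in c(0.02, 0.12)) {
    base <- within_patch_params(r = r, c = 0.5 * r, t_end = 50)
    lin <- within_patch_params(r = r, c = 0.5 * r, t_end = 50,
                               d = 0.01, g = 40000, growth_form = "linear")
    B_base <- integrate_full_model(base, times = c(0, 50))$B[2]
    B_lin <- integrate_full_model(lin, times = c(0, 50))$B[2]
    expect_gt(B_lin, B_base)
  }
  # quadratic form must start cleanly from B = 0
  quad <- within_patch_params(r = 0.08, c = 0.04, t_end = 50,
                              d = 0.01, g = 1000, growth_form = "quadratic")
  trq <- integrate_full_model(quad, times = c(0, 50))
  expect_true(all(is.finite(trq$B)) && trq$B[2] > 0)
})

test_that("pure dispersal drains the biofilm into the plankton as the
           linear-system solution dictates", {
  # with c = 0, g = 0: B(t) = B0 e^{-dt}, and P picks up the dispersers
  r <- 0.05; d <- 0.5; P0 <- 1000; B0 <- 5000; tt <- 20
  p <- within_patch_params(r = r, c = 0, t_end = tt, P0 = P0, B0 = B0,
                           d = d, growth_form = "linear", g = 0)
  tr <- integrate_full_model(p, times = c(0, tt))
  B_exact <- B0 * exp(-d * tt)
  P_exact <- (P0 + d * B0 / (r + d)) * exp(r * tt) -
    d * B0 / (r + d) * exp(-d * tt)
  expect_equal(tr$B[2], B_exact, tolerance = 1e-6)
  expect_equal(tr$P[2], P_exact, tolerance = 1e-6)
  expect_gt(tr$P[2], P0 * exp(r * tt))  # inflated by dispersed cells
})

test_that("ranking of final biofilm across growth rates is preserved
           between the reduced and linear-growth models", {
  rs <- seq(0.02, 0.12, by = 0.02)
  b_none <- sapply(rs, function(r) {
    p <- within_patch_params(r = r, c = 0.5 * r, t_end = 50)
    integrate_full_model(p, times = c(0, 50))$B[2]
  })
  b_lin <- sapply(rs, function(r) {
    p <- within_patch_params(r = r, c = 0.5 * r, t_end = 50,
                             d = 0.01, g = 40000, growth_form = "linear")
    integrate_full_model(p, times = c(0, 50))$B[2]
  })
  expect_identical(order(b_none), order(b_lin))
})

test_that("limiting slope of B in c changes sign at patch quality rt = 2", {
  expect_equal(biofilm_slope_limit(1, 0.05, 40), 0)
  expect_equal(biofilm_slope_limit(1, 0.1, 40), -40)
  expect_gt(biofilm_slope_limit(1, 0.03, 40), 0)
  # matches the finite-difference slope of B(c) just below c = r
  for (pars in list(c(r = 0.1, t = 40), c(r = 0.03, t = 40),
                    c(r = 0.08, t = 30))) {
    r <- pars[["r"]]; tt <- pars[["t"]]
    fd <- central_diff(function(cc)
      biofilm_at(within_patch_params(r, cc, tt, P0 = 1), tt),
      r * (1 - 1e-6), h = r * 1e-8)
    expect_equal(fd, biofilm_slope_limit(1, r, tt), tolerance = 1e-3)
  }
})

test_that("total population derivative is zero at t = 0, negative after,
           and matches finite differences", {
  set.seed(7)
  for (i in 1:10) {
    P0 <- 10^runif(1, 1, 6)
    r <- runif(1, 0.01, 0.12)
    cc <- runif(1, 0, r * 0.95)
    expect_identical(total_size_derivative(P0, r, cc, 0), 0)
    tt <- runif(1, 1, 50)
    expect_lt(total_size_derivative(P0, r, cc, tt), 0)
  }
  # value check against a finite difference of P + B in c
  fd <- central_diff(function(cc) {
    p <- within_patch_params(0.05, cc, 10, P0 = 1000)
    planktonic_at(p, 10) + biofilm_at(p, 10)
  }, 0.02)
  expect_equal(total_size_derivative(1000, 0.05, 0.02, 10), fd,
               tolerance = 1e-6)
  # series and generic branches agree across their hand-over point
  c_below <- 0.05 - 0.99e-4 / 40   # series side of |x| = 1e-4
  c_above <- 0.05 - 1.01e-4 / 40   # generic side
  expect_equal(total_size_derivative(1, 0.05, c_below, 40),
               total_size_derivative(1, 0.05, c_above, 40),
               tolerance = 1e-5)
})

test_that("biofilm-maximizing colonization sits at the c = r boundary for
           poor patches and moves interior for rich ones", {
  # r t = 1.6 < 2: boundary optimum
  expect_equal(biofilm_maximizing_colonization(0.04, 40), 0.04)
  # r t > 2: interior optimum, and richer patches favour lower c/r
  c06 <- biofilm_maximizing_colonization(0.06, 40) / 0.06
  c12 <- biofilm_maximizing_colonization(0.12, 40) / 0.12
  expect_lt(c12, c06)
  expect_lt(c12, 1)
  # independent of the inoculum
  expect_equal(biofilm_maximizing_colonization(0.1, 40, P0 = 1),
               biofilm_maximizing_colonization(0.1, 40, P0 = 5e6))
  # hump condition on random parameters, against a dense grid oracle
  set.seed(11)
  for (i in 1:15) {
    r <- runif(1, 0.02, 0.15)
    tt <- runif(1, 10, 60)
    cstar <- biofilm_maximizing_colonization(r, tt)
    cs <- seq(0, r, length.out = 1e4)
    grid_best <- cs[which.max(sapply(cs, function(cc)
      biofilm_at(within_patch_params(r, cc, tt, P0 = 1), tt)))]
    expect_lt(abs(cstar - grid_best), 2 * r / 1e4)
    if (r * tt <= 2) expect_equal(cstar, r) else expect_lt(cstar, r)
  }
})
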