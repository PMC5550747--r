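# Within-patch coupled biofilm-plankton dynamics.
#
# Simplified model: dP/dt = (r - c) P, dB/dt = c P, with closed forms
#   P(t) = P0 exp((r - c) t)
#   B(t) = c/(r - c) [P(t) - P0]
# and the removable singularity at c = r handled by its analytic limit
# B(t) = c P0 t. The full model adds intrinsic biofilm growth G(B) and
# dispersal d back into the plankton and is integrated numerically.

# relative guard band for the c = r limit branch
.EQ_TOL <- 1e-12

# expm1(x)/x, continuous through x = 0
.expm1_ratio <- function(x) {
  out <- rep(1, length(x))
  nz <- x != 0
  out[nz] <- expm1(x[nz]) / x[nz]
  out
}

.at_growth_boundary <- function(r, c) abs(r - c) < .EQ_TOL * pmax(r, 1)

#' Parameters for one patch growth episode
#'
#' Bundles all rates and initial conditions for a single within-patch
#' growth episode of the coupled biofilm-plankton model. The simplified
#' model (`growth_form = "none"`, `d = 0`, `B0 = 0`) admits closed-form
#' solutions; other settings require numerical integration via
#' [integrate_full_model()].
#'
#' @param r Planktonic exponential growth rate (per unit time, >= 0).
#' @param c Colonization rate from plankton to biofilm (per unit time,
#'   >= 0). Values above `r` are permitted: the plankton then declines as
#'   switching outpaces growth.
#' @param t_end Duration of the growth episode (time units, >= 0).
#' @param P0 Planktonic inoculum (cells, > 0).
#' @param B0 Biofilm inoculum (cells, >= 0; 0 in the simplified model).
#' @param d Dispersal rate from biofilm back to plankton (per unit time,
#'   >= 0; 0 in the simplified model).
#' @param g Intrinsic biofilm growth coefficient: cells/time for the
#'   linear form, cells^(1/2)/time for the quadratic form.
#' @param growth_form Biofilm intrinsic growth law: `"none"` (simplified
#'   model), `"linear"` (dB/dt gains +g), or `"quadratic"` (+g sqrt(B)).
#'
#' @return An object of class `"within_patch_params"`.
#' @examples
#' p <- within_patch_params(r = 0.08, c = 0.04, t_end = 40)
#' planktonic_at(p, 40)
#' biofilm_at(p, 40)
#' @export
within_patch_params <- function(r, c, t_end, P0 = 5e6, B0 = 0, d = 0, g = 0,
                                growth_form = c("none", "linear", "quadratic")) {
  growth_form <- match.arg(growth_form)
  stopifnot(is.numeric(r), length(r) == 1L, r >= 0,
            is.numeric(c), length(c) == 1L, c >= 0,
            is.numeric(t_end), length(t_end) == 1L, t_end >= 0,
            is.numeric(P0), length(P0) == 1L, P0 > 0,
            is.numeric(B0), length(B0) == 1L, B0 >= 0,
            is.numeric(d), length(d) == 1L, d >= 0,
            is.numeric(g), length(g) == 1L, g >= 0)
  if (growth_form == "none" && (d != 0 || g != 0))
    stop("growth_form = \"none\" requires d = 0 and g = 0 (simplified model)")
  structure(list(r = r, c = c, t_end = t_end, P0 = P0, B0 = B0,
                 d = d, g = g, growth_form = growth_form),
            class = "within_patch_params")
}

#' @export
print.within_patch_params <- function(x, ...) {
  cat("Within-patch parameters\n")
  cat(sprintf("  r = %g, c = %g (c/r = %s), t_end = %g\n", x$r, x$c,
              if (x$r > 0) format(x$c / x$r, digits = 4) else "NA", x$t_end))
  cat(sprintf("  P0 = %g, B0 = %g, d = %g, g = %g, growth form: %s\n",
              x$P0, x$B0, x$d, x$g, x$growth_form))
  invisible(x)
}

.check_simplified <- function(params) {
  if (params$growth_form != "none" || params$d != 0 || params$B0 != 0)
    stop("closed-form solution requires the simplified model: ",
         "growth_form = \"none\", d = 0, B0 = 0")
}

#' Planktonic population at a time point (closed form)
#'
#' Evaluates P(t) = P0 exp((r - c) t) for the simplified model. Exact at
#' c = r, where the planktonic population is static at P0.
#'
#' @param params A [within_patch_params()] object satisfying the
#'   simplified-model invariants.
#' @param time Non-negative time point(s); vectorized.
#' @return Planktonic cell count(s), same length as `time`.
#' @export
planktonic_at <- function(params, time) {
  .check_simplified(params)
  if (any(time < 0)) stop("time must be non-negative")
  params$P0 * exp((params$r - params$c) * time)
}

#' Biofilm population at a time point (closed form)
#'
#' Evaluates B(t) = c/(r - c) [P(t) - P0] for the simplified model,
#' computed in the numerically stable form c P0 t expm1(x)/x with
#' x = (r - c) t, which passes continuously through the removable
#' singularity at c = r (limit c P0 t). Valid for all c >= 0, including
#' c > r; the result is non-negative throughout.
#'
#' @inheritParams planktonic_at
#' @return Biofilm cell count(s), same length as `time`.
#' @export
biofilm_at <- function(params, time) {
  .check_simplified(params)
  if (any(time < 0)) stop("time must be non-negative")
  x <- (params$r - params$c) * time
  params$c * params$P0 * time * .expm1_ratio(x)
}

#' Closed-form trajectory on a time grid
#'
#' Element-wise application of [planktonic_at()] and [biofilm_at()] over
#' a sorted non-negative time grid.
#'
#' @inheritParams planktonic_at
#' @param times Strictly increasing, non-negative time grid. Defaults to
#'   101 points on [0, t_end].
#' @return A `patch_trajectory`: a data frame with columns `time`, `P`,
#'   `B` and the parameters stored in `attr(, "params")`.
#' @export
solve_trajectory <- function(params, times = seq(0, params$t_end, length.out = 101L)) {
  if (any(times < 0)) stop("times must be non-negative")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  out <- data.frame(time = times,
                    P = planktonic_at(params, times),
                    B = biofilm_at(params, times))
  structure(out, params = params,
            class = c("patch_trajectory", "data.frame"))
}

#' @export
print.patch_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Patch trajectory: %d time points on [%g, %g]\n",
              nrow(x), min(x$time), max(x$time)))
  if (!is.null(p))
    cat(sprintf("  r = %g, c = %g, P0 = %g, growth form: %s\n",
                p$r, p$c, p$P0, p$growth_form))
  cat(sprintf("  final P = %.6g, final B = %.6g\n",
              x$P[nrow(x)], x$B[nrow(x)]))
  invisible(x)
}

#' @export
plot.patch_trajectory <- function(x, log = "y", ...) {
  ylim <- range(c(x$P, x$B)[c(x$P, x$B) > 0])
  graphics::plot(x$time, pmax(x$P, .Machine$double.xmin), type = "l",
                 col = "steelblue", lwd = 2, log = log, ylim = ylim,
                 xlab = "time", ylab = "cells", ...)
  graphics::lines(x$time, pmax(x$B, .Machine$double.xmin),
                  col = "darkorange", lwd = 2)
  graphics::legend("topleft", c("planktonic", "biofilm"),
                   col = c("steelblue", "darkorange"), lwd = 2, bty = "n")
  invisible(x)
}

#' Numerical integration of the full within-patch model
#'
#' Integrates
#'   dP/dt = (r - c) P + d B
#'   dB/dt = G(B) + c P - d B
#' where G(B) is 0, g, or g sqrt(B) for growth forms none, linear and
#' quadratic. Dispersal is assumed to return biofilm cells to the
#' plankton (the +dB term in dP/dt). With `growth_form = "none"` and
#' d = 0 the result agrees with the closed forms to integration
#' tolerance. Uses [deSolve::ode()] (lsoda, stiff-capable) with relative
#' tolerance 1e-8 and absolute tolerance 1e-6 cells.
#'
#' @param params A [within_patch_params()] object (any growth form).
#' @param times Strictly increasing, non-negative time grid starting at 0.
#' @return A `patch_trajectory` data frame (`time`, `P`, `B`).
#' @export
integrate_full_model <- function(params,
                                 times = seq(0, params$t_end, length.out = 101L)) {
  if (any(times < 0)) stop("times must be non-negative")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (times[1] != 0) times <- c(0, times)
  gfun <- switch(params$growth_form,
                 none = function(B) 0,
                 linear = function(B) params$g,
                 quadratic = function(B) params$g * sqrt(max(B, 0)))
  rhs <- function(t, y, parms) {
    P <- y[1]; B <- y[2]
    dP <- (params$r - params$c) * P + params$d * B
    dB <- gfun(B) + params$c * P - params$d * B
    list(c(dP, dB))
  }
  sol <- deSolve::ode(y = c(P = params$P0, B = params$B0), times = times,
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-6)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed at t = ", max(sol[, "time"]),
         " (istate = ", attr(sol, "istate")[1], ")")
  P <- sol[, "P"]; B <- sol[, "B"]
  if (any(P < -1e-4) || any(B < -1e-4)) {
    bad <- which(P < -1e-4 | B < -1e-4)[1]
    stop(sprintf("negative state at t = %g: P = %g, B = %g",
                 sol[bad, "time"], P[bad], B[bad]))
  }
  out <- data.frame(time = sol[, "time"], P = pmax(P, 0), B = pmax(B, 0))
  structure(out, params = params,
            class = c("patch_trajectory", "data.frame"))
}

#' Limiting slope of biofilm in colonization rate at c = r
#'
#' The slope of final biofilm count with respect to the colonization
#' rate, in the limit c -> r:
#'   lim_{c -> r} dB/dc = -(1/2) P0 t (r t - 2).
#' Negative exactly when the patch-quality product r t exceeds 2, which
#' is the condition for an interior (humped) maximum of B in c.
#'
#' @param P0 Planktonic inoculum (> 0).
#' @param r Planktonic growth rate (>= 0).
#' @param t_end Growth duration (>= 0).
#' @return The limiting slope, in cells per unit rate.
#' @export
biofilm_slope_limit <- function(P0, r, t_end) {
  stopifnot(P0 > 0, r >= 0, t_end >= 0)
  -0.5 * P0 * t_end * (r * t_end - 2)
}

#' Derivative of total population size in the colonization rate
#'
#' Evaluates
#'   d(P + B)/dc = -r P0 (1 + ((r - c) t - 1) exp((r - c) t)) / (r - c)^2,
#' the marginal cost of colonization to total patch population. Equals 0
#' at t_end = 0 and is strictly negative for t_end > 0. Near c = r the
#' expression is evaluated by its series in x = (r - c) t,
#'   -r P0 t^2 (1/2 + x/3 + x^2/8 + x^3/30 + ...),
#' to avoid 0/0 cancellation.
#'
#' @param P0 Planktonic inoculum (> 0).
#' @param r Planktonic growth rate (>= 0).
#' @param c Colonization rate (>= 0); vectorized.
#' @param t_end Growth duration (>= 0).
#' @return Derivative value(s), cells per unit rate.
#' @export
total_size_derivative <- function(P0, r, c, t_end) {
  stopifnot(P0 > 0, r >= 0, all(c >= 0), t_end >= 0)
  x <- (r - c) * t_end
  out <- numeric(length(x))
  near <- abs(x) < 1e-4
  if (any(near)) {
    xn <- x[near]
    out[near] <- -r * P0 * t_end^2 *
      (1 / 2 + xn / 3 + xn^2 / 8 + xn^3 / 30)
  }
  if (any(!near)) {
    xf <- x[!near]
    cf <- c[!near]
    out[!near] <- -r * P0 * (1 + (xf - 1) * exp(xf)) / (r - cf)^2
  }
  out
}

#' Colonization rate maximizing final biofilm
#'
#' Argmax over c in [0, r] of the final biofilm count B(t_end). When the
#' patch-quality product r t_end <= 2 the maximum sits at the boundary
#' c = r (all-in colonization); when r t_end > 2 the "growth engine"
#' effect moves the optimum to an interior c < r. The optimum is
#' independent of P0 because B is linear in the inoculum.
#'
#' Search strategy: a coarse grid scan (512 points) followed by bounded
#' scalar refinement with [stats::optimize()]; ties within 1e-9 relative
#' are resolved toward larger c, so a flat ridge returns the boundary.
#'
#' @param r Planktonic growth rate (> 0).
#' @param t_end Growth duration (> 0).
#' @param P0 Planktonic inoculum; does not affect the optimum.
#' @param n_grid Grid points for the pre-scan.
#' @return The optimal colonization rate (scalar, in [0, r]).
#' @export
biofilm_maximizing_colonization <- function(r, t_end, P0 = 1, n_grid = 512L) {
  stopifnot(r > 0, t_end > 0, P0 > 0)
  bfun <- function(cc) {
    x <- (r - cc) * t_end
    cc * P0 * t_end * .expm1_ratio(x)
  }
  cs <- seq(0, r, length.out = n_grid)
  vals <- bfun(cs)
  i <- which.max(vals)
  lo <- cs[max(1L, i - 1L)]
  hi <- cs[min(n_grid, i + 1L)]
  opt <- stats::optimize(bfun, c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5 * max(r, 1))
  c_star <- opt$maximum
  w_star <- opt$objective
  # ties toward larger c: prefer the boundary when the surface is flat
  if (bfun(r) >= w_star * (1 - 1e-9)) c_star <- r
  c_star
}
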