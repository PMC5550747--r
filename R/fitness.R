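# Per-founder fitness over colonization rate, its boundary gradients,
# and the three-regime allocation landscape in (k_p, k_b) space.
#
# W(c, r, t) = k_p e^{(r-c)t} + k_b [e^{(r-c)t} - 1] c/(r - c)
# is the expected number of next-patch founders per current founder
# (an R0): the planktonic survivors weighted k_p plus the accumulated
# biofilm weighted k_b, per inoculated cell. At c = r the biofilm term
# has the limit k_b r t, so W = k_p + k_b r t.

#' Per-founder fitness of a colonization strategy
#'
#' Expected founders of the next patch per current founder, for a growth
#' episode at planktonic growth rate `r`, duration `t_end`, colonization
#' rate `c`, with per-cell transmission probabilities `k_p` (planktonic)
#' and `k_b` (biofilm). Equals (k_p P(t) + k_b B(t)) / P0 from the
#' within-patch closed forms; evaluated directly in its stable
#' per-founder form, continuous through c = r where it equals
#' k_p + k_b r t.
#'
#' @param c Colonization rate(s) (>= 0); vectorized.
#' @param r Planktonic growth rate (>= 0).
#' @param t_end Growth duration (>= 0).
#' @param k_p,k_b Transmission weights in [0, 1]: the per-cell
#'   probability that a planktonic (biofilm) cell founds the next patch.
#' @return Fitness value(s) W >= 0, same length as `c`.
#' @examples
#' per_founder_fitness(c = 0.03, r = 0.06, t_end = 40, k_p = 0.1, k_b = 0.6)
#' @export
per_founder_fitness <- function(c, r, t_end, k_p, k_b) {
  stopifnot(all(c >= 0), r >= 0, t_end >= 0,
            k_p >= 0, k_p <= 1, k_b >= 0, k_b <= 1)
  x <- (r - c) * t_end
  k_p * exp(x) + k_b * c * t_end * .expm1_ratio(x)
}

# dW/dc, analytic:
#   dW/dc = -k_p t e^{ut} + k_b [ r (e^{ut} - 1)/u^2 - c t e^{ut}/u ],
# u = r - c. Near u = 0 the bracket is evaluated by its series
#   t - r t^2/2 + u (t^2 - r t^3/3) + O(u^2).
fitness_gradient <- function(c, r, t_end, k_p, k_b) {
  u <- r - c
  t <- t_end
  out <- numeric(length(c))
  near <- abs(u) < 1e-7 * max(r, 1)
  if (any(near)) {
    un <- u[near]
    out[near] <- -k_p * t * exp(un * t) +
      k_b * (t - r * t^2 / 2 + un * (t^2 - r * t^3 / 3))
  }
  if (any(!near)) {
    uf <- u[!near]; cf <- c[!near]
    e <- exp(uf * t)
    out[!near] <- -k_p * t * e + k_b * (r * expm1(uf * t) / uf^2 - cf * t * e / uf)
  }
  out
}

#' Fitness gradient in the zero-growth limit
#'
#' In the limit of no planktonic growth (r = 0) the allocation decision
#' is a zero-sum game and the fitness gradient reduces to
#'   dW/dc |_{r=0} = t e^{-c t} (k_b - k_p),
#' whose sign is the sign of k_b - k_p: whichever cell type transmits
#' better takes the whole population.
#'
#' @inheritParams per_founder_fitness
#' @return Gradient value(s), same length as `c`.
#' @export
fitness_gradient_zero_growth <- function(c, t_end, k_p, k_b) {
  stopifnot(all(c >= 0), t_end >= 0)
  t_end * exp(-c * t_end) * (k_b - k_p)
}

#' Optimal colonization rate for a patchy life cycle
#'
#' Global maximum of the per-founder fitness W over the strategy space
#' c in [0, r], boundaries included (the c = r boundary is evaluated by
#' its analytic limit). Search is a 1024-point grid pre-scan followed by
#' bounded scalar refinement; W(c) is observed unimodal on [0, r] in all
#' probed regimes, and the pre-scan protects the refinement against any
#' undetected multimodality. A flat fitness surface (k_p = k_b = 0)
#' resolves toward larger c.
#'
#' @inheritParams per_founder_fitness
#' @param r Planktonic growth rate (> 0).
#' @param t_end Growth duration (> 0).
#' @param n_grid Grid points for the pre-scan.
#' @param boundary_tol Relative tolerance (in units of r) within which
#'   the optimum is snapped to a boundary and labeled accordingly.
#' @return An object of class `"allocation_optimum"`: a list with
#'   `c_star` (optimal rate), `c_star_rel` (c*/r), `regime` (one of
#'   `"pure_plankton"`, `"mixed"`, `"pure_biofilm"`), and
#'   `W_at_optimum`.
#' @examples
#' optimal_colonization(r = 0.06, t_end = 40, k_p = 0.1, k_b = 0.6)
#' @export
optimal_colonization <- function(r, t_end, k_p, k_b, n_grid = 1024L,
                                 boundary_tol = 1e-6) {
  stopifnot(r > 0, t_end > 0, k_p >= 0, k_p <= 1, k_b >= 0, k_b <= 1)
  wfun <- function(cc) per_founder_fitness(cc, r, t_end, k_p, k_b)
  cs <- seq(0, r, length.out = n_grid)
  vals <- wfun(cs)
  i <- which.max(vals)
  lo <- cs[max(1L, i - 1L)]
  hi <- cs[min(n_grid, i + 1L)]
  opt <- stats::optimize(wfun, c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5 * max(r, 1))
  c_star <- opt$maximum
  w_star <- opt$objective
  # boundaries are evaluated exactly; take them when not worse
  w0 <- wfun(0); wr <- wfun(r)
  if (wr >= w_star * (1 - 1e-9) && wr >= w0) {
    c_star <- r; w_star <- wr
  } else if (w0 > w_star) {
    c_star <- 0; w_star <- w0
  }
  rel <- c_star / r
  regime <- if (rel <= boundary_tol) "pure_plankton"
            else if (rel >= 1 - boundary_tol) "pure_biofilm"
            else "mixed"
  if (regime == "pure_plankton") { c_star <- 0; rel <- 0 }
  if (regime == "pure_biofilm") { c_star <- r; rel <- 1 }
  structure(list(c_star = c_star, c_star_rel = rel, regime = regime,
                 W_at_optimum = w_star,
                 r = r, t_end = t_end, k_p = k_p, k_b = k_b),
            class = "allocation_optimum")
}

#' @export
print.allocation_optimum <- function(x, ...) {
  cat("Optimal colonization strategy\n")
  cat(sprintf("  r = %g, t = %g, k_p = %g, k_b = %g\n",
              x$r, x$t_end, x$k_p, x$k_b))
  cat(sprintf("  c* = %.6g  (c*/r = %.4f)  regime: %s\n",
              x$c_star, x$c_star_rel, x$regime))
  cat(sprintf("  W(c*) = %.6g\n", x$W_at_optimum))
  invisible(x)
}

#' Classify the optimal allocation regime
#'
#' Labels the fitness maximum over c in [0, r] as `"pure_plankton"`
#' (c* = 0), `"mixed"` (0 < c* < r) or `"pure_biofilm"` (c* = r), using
#' the closed-form boundary gradients
#'   dW/dc |_{c=0} = -k_p t e^{rt} + k_b (e^{rt} - 1)/r
#'   dW/dc |_{c=r} = t (k_b (1 - r t / 2) - k_p)
#' where decisive (gradient up at 0 and down at r implies an interior
#' maximum), with a grid + refinement optimization fallback for the
#' remaining cases. Note the c = r gradient changes sign at r t = 2, the
#' same patch-quality threshold that governs the biofilm hump.
#'
#' @inheritParams optimal_colonization
#' @return A character scalar regime label.
#' @export
classify_regime <- function(r, t_end, k_p, k_b, boundary_tol = 1e-6) {
  stopifnot(r > 0, t_end > 0)
  if (k_p == 0 && k_b == 0)  # flat surface: ties resolve toward larger c
    return("pure_biofilm")
  g0 <- -k_p * t_end * exp(r * t_end) + k_b * expm1(r * t_end) / r
  gr <- t_end * (k_b * (1 - r * t_end / 2) - k_p)
  if (g0 > 0 && gr < 0) return("mixed")
  optimal_colonization(r, t_end, k_p, k_b, n_grid = 257L,
                       boundary_tol = boundary_tol)$regime
}

#' Regime boundaries in transmission-weight space
#'
#' Locates, for fixed (r, t_end), the two level sets in the unit square
#' of (k_p, k_b) where the optimal-allocation regime changes: the
#' "white" boundary where c* departs from 0 (pure plankton to mixed) and
#' the "black" boundary where c* reaches r (mixed to pure biofilm). For
#' each k_p on a grid the boundary k_b is found by bisection along the
#' k_b axis; a boundary absent from the unit square yields an empty
#' curve (this happens for the pure-biofilm boundary once r t_end > 2,
#' when even k_p = 0 favors an interior optimum).
#'
#' @inheritParams optimal_colonization
#' @param k_grid Number of k_p grid points (>= 2) spanning [0, 1].
#' @param tol Bisection tolerance in k_b units.
#' @return A list of class `"regime_boundaries"` with data frames
#'   `white` and `black` (columns `k_p`, `k_b`; possibly zero rows).
#' @export
regime_boundaries <- function(r, t_end, k_grid = 101L, tol = 1e-4) {
  stopifnot(r > 0, t_end > 0, k_grid >= 2L)
  kps <- seq(0, 1, length.out = k_grid)
  rank_of <- c(pure_plankton = 0, mixed = 1, pure_biofilm = 2)
  # regime rank is non-decreasing in k_b at fixed k_p; the flat
  # degenerate corner k_p = k_b = 0 is ranked 0 here so its arbitrary
  # tie-break cannot fabricate a boundary point at the origin
  find_crossing <- function(kp, target_rank) {
    f <- function(kb) {
      if (kp == 0 && kb == 0) return(0)
      rank_of[[classify_regime(r, t_end, kp, kb)]]
    }
    lo <- 0; hi <- 1
    if (f(hi) < target_rank) return(NA_real_)
    if (f(lo) >= target_rank) return(0)
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (f(mid) >= target_rank) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  white <- vapply(kps, find_crossing, numeric(1), target_rank = 1)
  black <- vapply(kps, find_crossing, numeric(1), target_rank = 2)
  # k_p = 0 with k_b = 0 is the flat degenerate corner; the white
  # boundary there is the axis itself
  mk <- function(kb) {
    keep <- !is.na(kb)
    data.frame(k_p = kps[keep], k_b = kb[keep])
  }
  structure(list(white = mk(white), black = mk(black),
                 r = r, t_end = t_end),
            class = "regime_boundaries")
}

#' @export
print.regime_boundaries <- function(x, ...) {
  cat(sprintf("Regime boundaries at r = %g, t = %g\n", x$r, x$t_end))
  cat(sprintf("  pure-plankton/mixed (white): %d points\n", nrow(x$white)))
  cat(sprintf("  mixed/pure-biofilm (black):  %d points%s\n", nrow(x$black),
              if (nrow(x$black) == 0) " (absent from unit square)" else ""))
  invisible(x)
}

#' Optimal-allocation landscape over transmission weights
#'
#' Dense evaluation of the relative optimal colonization rate c*/r over
#' a (k_p, k_b) grid, for one or more (r, t_end) panels. Exploits the
#' linearity of W in (k_p, k_b): the fitness of every weight pair on a
#' shared colonization grid is a single matrix product, so the argmax
#' per cell is found at grid resolution and regime labels come from the
#' closed-form boundary gradients.
#'
#' @param r_values Vector of planktonic growth rates (> 0), one panel each.
#' @param t_values Vector of growth durations (> 0), recycled against
#'   `r_values`.
#' @param k_res Grid resolution per k axis.
#' @param n_c Colonization-grid resolution (sets the granularity of the
#'   reported c*/r values, about 1/n_c).
#' @return An object of class `"fitness_landscape"`: a list of panels,
#'   each with `r`, `t_end`, `k_p`, `k_b`, matrix `c_star_rel`
#'   (k_p by k_b) and matrix `regime` of labels.
#' @examples
#' ls <- landscape_grid(r_values = 0.06, t_values = 40, k_res = 21)
#' range(ls$panels[[1]]$c_star_rel)
#' @export
landscape_grid <- function(r_values, t_values, k_res = 101L, n_c = 1025L) {
  stopifnot(all(r_values > 0), all(t_values > 0))
  n_panel <- max(length(r_values), length(t_values))
  r_values <- rep_len(r_values, n_panel)
  t_values <- rep_len(t_values, n_panel)
  ks <- seq(0, 1, length.out = k_res)
  panels <- vector("list", n_panel)
  for (p in seq_len(n_panel)) {
    r <- r_values[p]; t_end <- t_values[p]
    cs <- seq(0, r, length.out = n_c)
    x <- (r - cs) * t_end
    a <- exp(x)                      # planktonic component per k_p
    h <- cs * t_end * .expm1_ratio(x)  # biofilm component per k_b
    KP <- rep(ks, times = k_res)     # cell order: k_p fastest
    KB <- rep(ks, each = k_res)
    W <- cbind(KP, KB) %*% rbind(a, h)   # (k_res^2) x n_c
    idx <- max.col(W, ties.method = "last")
    rel <- matrix(cs[idx] / r, nrow = k_res, ncol = k_res,
                  dimnames = list(k_p = NULL, k_b = NULL))
    g0 <- -KP * t_end * exp(r * t_end) + KB * expm1(r * t_end) / r
    gr <- t_end * (KB * (1 - r * t_end / 2) - KP)
    lab <- ifelse(g0 <= 0, "pure_plankton",
                  ifelse(gr >= 0, "pure_biofilm", "mixed"))
    lab[KP == 0 & KB == 0] <- "pure_biofilm"  # flat corner, ties to larger c
    regime <- matrix(lab, nrow = k_res, ncol = k_res)
    panels[[p]] <- list(r = r, t_end = t_end, k_p = ks, k_b = ks,
                        c_star_rel = rel, regime = regime)
  }
  structure(list(panels = panels), class = "fitness_landscape")
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat(sprintf("Fitness landscape: %d panel(s)\n", length(x$panels)))
  for (p in x$panels) {
    frac <- mean(p$regime == "mixed")
    cat(sprintf("  r = %g, t = %g: %d x %d grid, mixed-regime fraction %.3f\n",
                p$r, p$t_end, length(p$k_p), length(p$k_b), frac))
  }
  invisible(x)
}

#' @export
plot.fitness_landscape <- function(x, ...) {
  n <- length(x$panels)
  nc <- ceiling(sqrt(n)); nr <- ceiling(n / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (p in x$panels) {
    graphics::image(p$k_p, p$k_b, p$c_star_rel, zlim = c(0, 1),
                    col = grDevices::hcl.colors(64, "viridis"),
                    xlab = expression(k[p]), ylab = expression(k[b]),
                    main = sprintf("r = %g, t = %g", p$r, p$t_end), ...)
  }
  invisible(x)
}
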