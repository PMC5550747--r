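# Frontier-limited biofilm growth on a lattice.
#
# A deliberately minimal geometric simulator: cells occupy sites of a
# square/cubic lattice and only cells within a fixed depth of the
# exposed front can divide (a hard active-layer rule abstracting
# nutrient penetration; there is no solute field). Division is
# synchronous in epochs of one division time; an active cell places its
# daughter in a uniformly chosen empty neighbour site, or, when it has
# none, pushes the chain of cells along a lattice direction so the
# daughter surfaces at the first empty site within the active layer.
# The quantity of interest is the order of polynomial growth of the
# cumulative cell count: a D-dimensional body growing at its frontier
# accumulates cells like t^D, dropping an order every time a spatial
# dimension reaches confluence, while a body whose cells are all active
# doubles every epoch.

#' Configuration for a lattice growth simulation
#'
#' @param dimensionality Spatial dimension of the biofilm body: 1, 2 or 3.
#' @param geometry `"radial"` (growth from a central seed) or
#'   `"substratum"` (growth on a flat surface of dimension D - 1; the
#'   surface is a hard wall, seeds sit on it).
#' @param active_depth Depth of the dividing layer, in cell diameters
#'   (lattice distance from the exposed front; >= 1).
#' @param domain_extent Finite bound per axis in cell diameters, a
#'   vector of length `dimensionality` (NA entries are unbounded and
#'   sized automatically from the run length). For substratum geometry
#'   the last axis is the growth (height) direction.
#' @param division_time Time units per division epoch for active cells.
#' @param n_inoculum Number of seed cells (placed centrally for radial
#'   geometry, at random distinct surface sites for substratum).
#' @param inoculum_radius Radial geometry only: instead of scattered
#'   seeds, start from a filled von Neumann ball of this radius around
#'   the centre (0 disables). A compact seed skips the ramified startup
#'   transient of a lone cell, so growth is frontier-limited from the
#'   first epoch and window slope estimates reflect the asymptotic
#'   polynomial order.
#' @return An object of class `"geometry_config"`.
#' @examples
#' geometry_config(2, "substratum", domain_extent = c(40, NA))
#' @export
geometry_config <- function(dimensionality, geometry = c("radial", "substratum"),
                            active_depth = 3, domain_extent = NULL,
                            division_time = 1, n_inoculum = 1L,
                            inoculum_radius = 0L) {
  geometry <- match.arg(geometry)
  stopifnot(dimensionality %in% 1:3, active_depth >= 1,
            division_time > 0, n_inoculum >= 1, inoculum_radius >= 0)
  if (inoculum_radius > 0 && geometry != "radial")
    stop("inoculum_radius applies to radial geometry only")
  if (is.null(domain_extent)) domain_extent <- rep(NA_real_, dimensionality)
  stopifnot(length(domain_extent) == dimensionality)
  if (geometry == "substratum" && dimensionality == 1)
    stop("substratum geometry needs dimensionality >= 2 (a D-1 surface)")
  structure(list(dimensionality = as.integer(dimensionality),
                 geometry = geometry,
                 active_depth = as.integer(active_depth),
                 domain_extent = domain_extent,
                 division_time = division_time,
                 n_inoculum = as.integer(n_inoculum),
                 inoculum_radius = as.integer(inoculum_radius)),
            class = "geometry_config")
}

#' @export
print.geometry_config <- function(x, ...) {
  cat(sprintf("Lattice growth config: %dD %s, active depth %d\n",
              x$dimensionality, x$geometry, x$active_depth))
  cat(sprintf("  extent: %s, division time %g, inoculum %d\n",
              paste(ifelse(is.na(x$domain_extent), "unbounded",
                           x$domain_extent), collapse = " x "),
              x$division_time, x$n_inoculum))
  invisible(x)
}

# state codes
.ST_EMPTY <- 0L
.ST_CELL <- 1L
.ST_WALL <- 2L

#' Simulate frontier-limited lattice growth
#'
#' Runs the active-layer lattice model to time `t_end` and returns the
#' cumulative cell count and active-cell count per division epoch. The
#' simulation stops early, flagged via `attr(, "saturated")`, if no
#' division is possible (domain full).
#'
#' Uses R's global random number generator; call [set.seed()] first for
#' reproducibility.
#'
#' @param config A [geometry_config()] object.
#' @param t_end Simulated time (>= one division epoch).
#' @return An object of class `"growth_curve"`: a data frame with
#'   columns `time`, `N`, `active`, with the configuration in
#'   `attr(, "config")`.
#' @examples
#' set.seed(1)
#' cfg <- geometry_config(2, "radial", active_depth = 1)
#' simulate_frontier_growth(cfg, t_end = 10)
#' @export
simulate_frontier_growth <- function(config, t_end) {
  stopifnot(inherits(config, "geometry_config"), t_end >= config$division_time)
  D <- config$dimensionality
  depth <- config$active_depth
  n_epochs <- floor(t_end / config$division_time)
  reach <- n_epochs * depth + 2L

  # lattice extents, +2 for a wall border on every axis
  ext <- integer(D)
  for (k in seq_len(D)) {
    ext[k] <- if (is.na(config$domain_extent[k])) {
      if (config$geometry == "radial" || k == D) {
        if (config$geometry == "radial") 2L * reach + 3L else reach + 2L
      } else reach + 2L
    } else as.integer(config$domain_extent[k]) + 2L
  }
  n_sites <- prod(ext)
  if (n_sites > 5e7) stop("lattice too large (", n_sites, " sites); ",
                          "reduce t_end or domain_extent")
  state <- rep(.ST_EMPTY, n_sites)
  strides <- cumprod(c(1L, ext[-D]))
  coord_of <- function(idx) {  # 1-based coords from linear index
    idx0 <- idx - 1L
    sapply(seq_len(D), function(k) (idx0 %/% strides[k]) %% ext[k] + 1L)
  }
  index_of <- function(coords) 1L + sum((coords - 1L) * strides)

  # wall border: any site with a coordinate on the boundary
  for (k in seq_len(D)) {
    idx0 <- seq_len(n_sites) - 1L
    ck <- (idx0 %/% strides[k]) %% ext[k] + 1L
    state[ck == 1L | ck == ext[k]] <- .ST_WALL
  }
  shifts <- as.integer(c(strides, -strides))

  # inoculum placement
  if (config$geometry == "radial") {
    centre <- pmax((ext + 1L) %/% 2L, 2L)
    if (config$inoculum_radius > 0L) {
      # filled von Neumann ball around the centre
      rr <- config$inoculum_radius
      offs <- as.matrix(do.call(expand.grid, rep(list(-rr:rr), D)))
      offs <- offs[rowSums(abs(offs)) <= rr, , drop = FALSE]
      seeds <- apply(offs, 1L, function(o) index_of(centre + o))
    } else {
      seeds <- index_of(centre)
      extra <- config$n_inoculum - 1L
      if (extra > 0) {  # scatter the rest uniformly over interior sites
        interior <- setdiff(which(state == .ST_EMPTY), seeds)
        seeds <- c(seeds, interior[sample.int(length(interior), extra)])
      }
    }
  } else {
    # substratum: last axis is height; seeds on the layer just above the
    # bottom wall, random distinct lateral positions
    lateral <- lapply(seq_len(D - 1L), function(k) 2:(ext[k] - 1L))
    surface <- as.matrix(expand.grid(lateral))
    if (nrow(surface) < config$n_inoculum)
      stop("substratum too small for the inoculum")
    pick <- surface[sample.int(nrow(surface), config$n_inoculum), , drop = FALSE]
    seeds <- apply(cbind(pick, 2L), 1L, index_of)
  }
  state[seeds] <- .ST_CELL

  # a cell at depth k needs a push of at most k sites to surface its
  # daughter; capping the walk at the active depth keeps front cells
  # dividing strictly into adjacent empty sites
  n_dirs <- 2L * D
  max_walk <- depth
  times <- numeric(n_epochs + 1L)
  N <- numeric(n_epochs + 1L)
  active_n <- numeric(n_epochs + 1L)
  N[1] <- length(seeds)
  saturated <- FALSE
  last_epoch <- n_epochs

  for (ep in seq_len(n_epochs)) {
    cells <- which(state == .ST_CELL)
    # front: occupied sites with at least one empty neighbour
    has_empty <- rep(FALSE, length(cells))
    for (s in shifts) has_empty <- has_empty | state[cells + s] == .ST_EMPTY
    front <- cells[has_empty]
    # active = occupied sites within `depth` lattice steps of the front
    if (depth == 1L || length(front) == 0L) {
      active <- front
    } else {
      marked <- rep(FALSE, n_sites)
      marked[front] <- TRUE
      layer <- front
      active <- front
      for (k in seq_len(depth - 1L)) {
        nb <- unique(as.vector(outer(layer, shifts, `+`)))
        layer <- nb[state[nb] == .ST_CELL & !marked[nb]]
        if (length(layer) == 0L) break
        marked[layer] <- TRUE
        active <- c(active, layer)
      }
    }
    active_n[ep] <- length(active)
    if (length(active) == 0L) { saturated <- TRUE; last_epoch <- ep - 1L; break }

    divided <- FALSE
    for (cell in active[sample.int(length(active))]) {  # randomized order
      for (d in sample.int(n_dirs)) {
        s <- shifts[d]
        pos <- cell
        placed <- FALSE
        for (step in seq_len(max_walk)) {
          pos <- pos + s
          st <- state[pos]
          if (st == .ST_EMPTY) {  # chain push: daughter surfaces here
            state[pos] <- .ST_CELL
            placed <- TRUE
            break
          }
          if (st == .ST_WALL) break
        }
        if (placed) { divided <- TRUE; break }
      }
    }
    times[ep + 1L] <- ep * config$division_time
    N[ep + 1L] <- sum(state == .ST_CELL)
    if (!divided) { saturated <- TRUE; last_epoch <- ep; break }
  }
  keep <- seq_len(last_epoch + 1L)
  times <- seq(0, by = config$division_time, length.out = last_epoch + 1L)
  out <- data.frame(time = times, N = N[keep], active = active_n[keep])
  structure(out, config = config, saturated = saturated,
            class = c("growth_curve", "data.frame"))
}

#' @export
print.growth_curve <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Growth curve: %dD %s lattice, %d epochs, final N = %d%s\n",
              cfg$dimensionality, cfg$geometry, nrow(x) - 1L,
              as.integer(x$N[nrow(x)]),
              if (isTRUE(attr(x, "saturated"))) " (saturated)" else ""))
  invisible(x)
}

#' @export
plot.growth_curve <- function(x, log = "xy", ...) {
  d <- x[x$time > 0 & x$N > 0, ]
  graphics::plot(d$time, d$N, type = "b", pch = 16, cex = 0.6, log = log,
                 xlab = "time", ylab = "accumulated cells", ...)
  invisible(x)
}

#' Detect confluence from the active-cell count
#'
#' First epoch at which the active-cell count plateaus (relative change
#' from the previous epoch within `tol`), signalling that a spatial
#' dimension has filled. Returns NA if no plateau occurs.
#'
#' @param curve A [simulate_frontier_growth()] result.
#' @param tol Relative plateau tolerance (default 5%).
#' @return Time of the first plateau epoch, or NA.
#' @export
detect_confluence <- function(curve, tol = 0.05) {
  a <- curve$active
  for (i in 3:length(a)) {
    if (a[i - 1] > 0 && abs(a[i] - a[i - 1]) <= tol * a[i - 1])
      return(curve$time[i])
  }
  NA_real_
}

#' Estimate the polynomial order of a growth curve
#'
#' Least-squares slope of log N versus log t within a time window: for
#' N(t) proportional to t^k the slope estimates k. Exponential growth
#' has no polynomial order; it is reported as non-convergence, detected
#' by slopes drifting upward across three sub-windows by more than
#' twice the estimate's standard error.
#'
#' @param curve A [simulate_frontier_growth()] result, or any data frame
#'   with `time` and `N` columns.
#' @param window Time interval `c(lo, hi)`; defaults to the
#'   post-confluence range when [detect_confluence()] finds one, else
#'   all positive times.
#' @param min_points Minimum samples with N > 0 required in the window.
#' @return An object of class `"growth_order"`: list with `order`, `se`,
#'   `r_squared`, `converged`, `sub_slopes`, `window`, `n`.
#' @export
estimate_growth_order <- function(curve, window = NULL, min_points = 10L) {
  if (is.null(window)) {
    conf_t <- if (inherits(curve, "growth_curve")) detect_confluence(curve)
              else NA_real_
    window <- c(if (is.na(conf_t)) 0 else conf_t, max(curve$time))
  }
  d <- curve[curve$time > max(window[1], 0) & curve$time <= window[2] &
               curve$N > 0, , drop = FALSE]
  if (nrow(d) == 0L) stop("window contains no positive counts")
  if (nrow(d) < min_points)
    stop("window has ", nrow(d), " usable samples; need >= ", min_points)
  lt <- log(d$time); ln <- log(d$N)
  fit <- stats::lm(ln ~ lt)
  # exact power laws fit perfectly; the usual summary warning is moot
  sm <- suppressWarnings(summary(fit))
  slope <- sm$coefficients["lt", "Estimate"]
  se <- sm$coefficients["lt", "Std. Error"]
  # drift check over three contiguous sub-windows
  thirds <- cut(seq_len(nrow(d)), 3, labels = FALSE)
  sub <- vapply(1:3, function(i) {
    ii <- thirds == i
    if (sum(ii) < 3) return(NA_real_)
    stats::coef(stats::lm(ln[ii] ~ lt[ii]))[2]
  }, numeric(1))
  drifting <- !anyNA(sub) && all(diff(sub) > 0) &&
    (sub[3] - sub[1]) > 2 * max(se, 1e-8)
  structure(list(order = slope, se = se, r_squared = sm$r.squared,
                 converged = !drifting, sub_slopes = unname(sub),
                 window = window, n = nrow(d)),
            class = "growth_order")
}

#' @export
print.growth_order <- function(x, ...) {
  cat(sprintf("Growth order estimate: %.3f +/- %.3f (R^2 = %.4f, n = %d)%s\n",
              x$order, x$se, x$r_squared, x$n,
              if (!x$converged) " -- no stable order (upward drift)" else ""))
  invisible(x)
}

#' Growth-order decay through confluence
#'
#' Runs a bounded-domain simulation and estimates the growth order in
#' successive time windows. As the biofilm reaches confluence across
#' each finite dimension the polynomial order of accumulation drops by
#' one, so the window estimates should be non-increasing (within
#' standard error) after each confluence event.
#'
#' @param config A [geometry_config()] with at least one finite axis.
#' @param t_end Simulated time.
#' @param n_windows Number of successive estimation windows.
#' @param min_points Minimum samples per window.
#' @return A data frame of class `"confluence_check"`: one row per
#'   window with `t_lo`, `t_hi`, `order`, `se`, with the growth curve in
#'   `attr(, "curve")`.
#' @export
confluence_decay_check <- function(config, t_end, n_windows = 3L,
                                   min_points = 6L) {
  stopifnot(inherits(config, "geometry_config"))
  if (all(is.na(config$domain_extent)))
    stop("confluence check needs at least one finite axis")
  curve <- simulate_frontier_growth(config, t_end)
  tmax <- max(curve$time)
  edges <- seq(0, tmax, length.out = n_windows + 1L)
  rows <- lapply(seq_len(n_windows), function(i) {
    est <- estimate_growth_order(curve, window = c(edges[i], edges[i + 1L]),
                                 min_points = min_points)
    data.frame(window = i, t_lo = edges[i], t_hi = edges[i + 1L],
               order = est$order, se = est$se)
  })
  structure(do.call(rbind, rows), curve = curve,
            class = c("confluence_check", "data.frame"))
}
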