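# Serial-passaging bet-hedging simulation.
#
# A lineage alternates growth episodes (closed-form within-patch model)
# with transmission bottlenecks: of the P and B cells present at the end
# of a passage, fractions k_p and k_b respectively found the next
# passage, entering as planktonic cells. The per-passage fitness
# R0 = founders(this passage) / founders(previous passage) is recorded,
# and lineages are summarized by the variance, arithmetic mean and
# geometric mean of R0 across passages. Founder counts are continuous,
# but a lineage that falls below one founding cell is extinct: less
# than one cell cannot found a patch, and extinction is absorbing.

#' Simulate one passaged lineage
#'
#' Runs a single lineage through `n_passages` cycles of growth and
#' transmission under stochastic environments. Each passage draws an
#' environment (r, t, k_p, k_b) from `treatment`, applies the
#' colonization rate (by default `c_rel` times the drawn r), grows the
#' founders as an all-planktonic inoculum via the closed forms, and
#' transmits k_p P + k_b B cells as the next passage's founders.
#' Founder counts are continuous and carried across passages without
#' resetting; a lineage whose founders fall below `extinction_threshold`
#' (one cell by default) is extinct and its remaining R0 values are 0.
#'
#' Because the within-patch model and the transmission step are linear
#' in the inoculum, each passage's R0 depends only on the drawn
#' environment and the colonization strategy, never on the founder
#' count.
#'
#' @param c_rel Colonization rate: relative to the drawn growth rate
#'   (`c_mode = "relative"`, default, absolute c = c_rel * r) or an
#'   absolute rate (`c_mode = "absolute"`).
#' @param treatment An [make_treatment()] environment distribution.
#' @param n_passages Number of growth/transmission cycles.
#' @param founders0 Initial planktonic founder count.
#' @param c_mode See `c_rel`.
#' @param extinction_threshold Founder count below which the lineage is
#'   extinct (absorbing; remaining R0 are 0). Default 1 cell; set 0 to
#'   disable and keep the dynamics exactly scale-free.
#' @return An object of class `"lineage_trajectory"`: a data frame with
#'   one row per passage (columns `passage`, `r`, `t`, `k_p`, `k_b`,
#'   `founders_in`, `P_end`, `B_end`, `transmitted`, `R0`).
#' @examples
#' set.seed(7)
#' run_lineage(c_rel = 0.1, treatment = make_treatment("high"))
#' @export
run_lineage <- function(c_rel, treatment, n_passages = 10L,
                        founders0 = 5000,
                        c_mode = c("relative", "absolute"),
                        extinction_threshold = 1) {
  c_mode <- match.arg(c_mode)
  stopifnot(c_rel >= 0, n_passages >= 1, founders0 > 0,
            inherits(treatment, "environment_distribution"),
            extinction_threshold >= 0, founders0 > extinction_threshold)
  env <- draw_environment(treatment, n = n_passages)
  founders <- founders0
  rec <- vector("list", n_passages)
  for (i in seq_len(n_passages)) {
    e <- env[i, ]
    if (founders < extinction_threshold || founders < 1e-300) {
      rec[[i]] <- data.frame(passage = i, r = e$r, t = e$t,
                             k_p = e$k_p, k_b = e$k_b,
                             founders_in = 0, P_end = 0, B_end = 0,
                             transmitted = 0, R0 = 0)
      founders <- 0
      next
    }
    c_abs <- if (c_mode == "relative") c_rel * e$r else c_rel
    x <- (e$r - c_abs) * e$t
    P_end <- founders * exp(x)
    B_end <- c_abs * founders * e$t * .expm1_ratio(x)
    transmitted <- e$k_p * P_end + e$k_b * B_end
    rec[[i]] <- data.frame(passage = i, r = e$r, t = e$t,
                           k_p = e$k_p, k_b = e$k_b,
                           founders_in = founders, P_end = P_end,
                           B_end = B_end, transmitted = transmitted,
                           R0 = transmitted / founders)
    founders <- transmitted
  }
  structure(do.call(rbind, rec),
            c_rel = c_rel, c_mode = c_mode, founders0 = founders0,
            treatment = treatment,
            class = c("lineage_trajectory", "data.frame"))
}

#' @export
print.lineage_trajectory <- function(x, ...) {
  s <- summarize_lineage(x)
  cat(sprintf("Passaged lineage: %d passages, c_rel = %g (%s)\n",
              nrow(x), attr(x, "c_rel"), attr(x, "c_mode")))
  cat(sprintf("  R0: mean %.4g, var %.4g, geometric mean %.4g\n",
              s[["mean_R0"]], s[["var_R0"]], s[["gmean_R0"]]))
  invisible(x)
}

#' Summarize a lineage's per-passage fitness
#'
#' Sample variance (n - 1 denominator), arithmetic mean and geometric
#' mean of the R0 sequence. The geometric mean is exp(mean(log R0)),
#' defined as 0 whenever any passage has R0 = 0: extinction is
#' absorbing.
#'
#' @param traj A [run_lineage()] result (or any data frame with an `R0`
#'   column).
#' @return A named numeric vector `var_R0`, `mean_R0`, `gmean_R0`.
#' @export
summarize_lineage <- function(traj) {
  R0 <- traj$R0
  stopifnot(length(R0) >= 1, all(R0 >= 0))
  gmean <- if (any(R0 == 0)) 0 else exp(mean(log(R0)))
  c(var_R0 = if (length(R0) > 1) stats::var(R0) else 0,
    mean_R0 = mean(R0), gmean_R0 = gmean)
}

#' Run the full passaging experiment
#'
#' Replicated passaging simulations across a grid of colonization
#' strategies and variance treatments: `n_replicates` independent
#' lineages per (c_rel, treatment) cell, each summarized by its
#' variance, mean and geometric-mean R0, then aggregated across
#' replicates with normal-approximation confidence intervals.
#'
#' @param c_rel_grid Colonization strategies (relative rates by
#'   default). The reference design covers absolute colonization rates
#'   (0, 0.2] at the mean growth rate 0.06, i.e. relative rates up to
#'   10/3 -- a window that straddles the fixed-environment optimum
#'   c*/r = 0.49 and extends deep into the biofilm-heavy regime.
#' @param treatments Character vector of treatment levels.
#' @param n_replicates Lineages per cell.
#' @param n_passages Passages per lineage.
#' @param founders0 Initial founder count.
#' @param convention Variance convention passed to [make_treatment()].
#' @param seed Optional integer seed (sets the global RNG).
#' @param conf Confidence level for replicate-level intervals.
#' @param c_mode,extinction_threshold Passed to [run_lineage()].
#' @return An object of class `"passaging_experiment"`: list with
#'   `replicates` (per-lineage summaries) and `summary` (per-cell mean
#'   and CI of each statistic).
#' @examples
#' ex <- run_experiment(c_rel_grid = c(0.05, 0.15), treatments = "high",
#'                      n_replicates = 5, seed = 1)
#' ex$summary
#' @export
run_experiment <- function(c_rel_grid = seq(0.01, 0.2, by = 0.01) / 0.06,
                           treatments = c("low", "mid", "high"),
                           n_replicates = 100L, n_passages = 10L,
                           founders0 = 5000, convention = "cv",
                           seed = NULL, conf = 0.95,
                           c_mode = "relative", extinction_threshold = 1) {
  stopifnot(all(c_rel_grid >= 0), n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  cells <- expand.grid(treatment = treatments, c_rel = c_rel_grid,
                       replicate = seq_len(n_replicates),
                       stringsAsFactors = FALSE)
  dists <- lapply(unique(treatments), make_treatment, convention = convention)
  names(dists) <- unique(treatments)
  stats_mat <- t(vapply(seq_len(nrow(cells)), function(i) {
    summarize_lineage(run_lineage(cells$c_rel[i], dists[[cells$treatment[i]]],
                                  n_passages = n_passages,
                                  founders0 = founders0, c_mode = c_mode,
                                  extinction_threshold = extinction_threshold))
  }, numeric(3)))
  replicates <- cbind(cells, as.data.frame(stats_mat))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  agg <- function(stat) {
    m <- stats::aggregate(replicates[[stat]],
                          by = replicates[c("treatment", "c_rel")], mean)
    s <- stats::aggregate(replicates[[stat]],
                          by = replicates[c("treatment", "c_rel")],
                          function(v) stats::sd(v) / sqrt(length(v)))
    data.frame(treatment = m$treatment, c_rel = m$c_rel, statistic = stat,
               mean = m$x, ci_lo = m$x - z * s$x, ci_hi = m$x + z * s$x)
  }
  summary_df <- rbind(agg("var_R0"), agg("mean_R0"), agg("gmean_R0"))
  summary_df <- summary_df[order(summary_df$statistic, summary_df$treatment,
                                 summary_df$c_rel), ]
  rownames(summary_df) <- NULL
  structure(list(replicates = replicates, summary = summary_df,
                 n_passages = n_passages, founders0 = founders0,
                 convention = convention, c_mode = c_mode),
            class = "passaging_experiment")
}

#' @export
print.passaging_experiment <- function(x, ...) {
  cat(sprintf(paste0("Passaging experiment: %d treatment(s) x %d strategies",
                     " x %d replicates x %d passages\n"),
              length(unique(x$replicates$treatment)),
              length(unique(x$replicates$c_rel)),
              max(x$replicates$replicate), x$n_passages))
  invisible(x)
}

#' @export
summary.passaging_experiment <- function(object, ...) {
  object$summary
}

#' @export
plot.passaging_experiment <- function(x, ...) {
  stats <- c(var_R0 = "variance in R0", mean_R0 = "average R0",
             gmean_R0 = "geometric mean R0")
  trts <- unique(x$summary$treatment)
  cols <- stats::setNames(grDevices::hcl.colors(max(3, length(trts)), "Dark 3"),
                          trts)
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (s in names(stats)) {
    d <- x$summary[x$summary$statistic == s, ]
    pos <- d$mean > 0
    graphics::plot(NA, xlim = range(d$c_rel),
                   ylim = range(d$mean[pos]), log = "y",
                   xlab = "relative colonization rate",
                   ylab = stats[[s]])
    for (tr in trts) {
      dd <- d[d$treatment == tr & d$mean > 0, ]
      graphics::lines(dd$c_rel, dd$mean, col = cols[[tr]], lwd = 2)
      graphics::points(dd$c_rel, dd$mean, col = cols[[tr]], pch = 16,
                       cex = 0.6)
    }
    graphics::legend("bottomleft", legend = trts, col = cols[trts],
                     lwd = 2, bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Linear-versus-quadratic response-curve selection
#'
#' Fits ordinary least squares regressions of a summary statistic on the
#' colonization rate, linear (y ~ c) and quadratic (y ~ c + c^2), and
#' selects the model with the lower AIC (full Gaussian log-likelihood
#' convention, shared between the candidates, via [stats::AIC()]).
#'
#' @param c_rel Colonization rates (>= 4 distinct values).
#' @param y Response statistic at each rate.
#' @return An object of class `"response_curve_fit"`: list with `linear`
#'   and `quadratic` `lm` fits, their AICs, and `chosen`
#'   (`"linear"` or `"quadratic"`).
#' @examples
#' fit_response_curves(c(0.05, 0.1, 0.15, 0.2), c(1, 2, 2.9, 4.1))
#' @export
fit_response_curves <- function(c_rel, y) {
  stopifnot(length(c_rel) == length(y))
  if (length(unique(c_rel)) < 4)
    stop("need at least 4 distinct colonization rates")
  if (stats::sd(y) == 0)
    stop("degenerate response: y is constant")
  d <- data.frame(c_rel = c_rel, y = y)
  lin <- stats::lm(y ~ c_rel, data = d)
  quad <- stats::lm(y ~ c_rel + I(c_rel^2), data = d)
  aics <- c(linear = stats::AIC(lin), quadratic = stats::AIC(quad))
  structure(list(linear = lin, quadratic = quad, aic = aics,
                 chosen = names(aics)[which.min(aics)]),
            class = "response_curve_fit")
}

#' @export
print.response_curve_fit <- function(x, ...) {
  cat(sprintf("Response curve: %s selected (AIC linear %.2f, quadratic %.2f)\n",
              x$chosen, x$aic[["linear"]], x$aic[["quadratic"]]))
  print(stats::coef(x[[x$chosen]]))
  invisible(x)
}

#' @export
coef.response_curve_fit <- function(object, ...) {
  stats::coef(object[[object$chosen]])
}
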