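test_that("per-founder fitness honours its boundary identities", {
  # no colonization: only the exponentially grown plankton transmits
  expect_equal(per_founder_fitness(0, 0.06, 40, 0.1, 0.6), 0.1 * exp(2.4))
  # zero growth duration: W is the planktonic transmission weight
  expect_identical(per_founder_fitness(0.03, 0.06, 0, 0.1, 0.6), 0.1)
  # c = r limit: W = k_p + k_b r t
  expect_equal(per_founder_fitness(0.06, 0.06, 40, 0.1, 0.6), 1.54)
  # continuity at the limit branch
  w_eps <- per_founder_fitness(0.06 * (1 - 1e-8), 0.06, 40, 0.1, 0.6)
  expect_equal(w_eps, 1.54, tolerance = 1e-8)
})

test_that("per-founder fitness equals the absolute fitness per inoculated
           cell from the within-patch model", {
  set.seed(3)
  for (i in 1:15) {
    r <- runif(1, 0.01, 0.12)
    cc <- runif(1, 0, r)
    tt <- runif(1, 5, 60)
    kp <- runif(1); kb <- runif(1)
    P0 <- 10^runif(1, 2, 7)
    p <- within_patch_params(r, cc, tt, P0 = P0)
    w_abs <- (kp * planktonic_at(p, tt) + kb * biofilm_at(p, tt)) / P0
    expect_equal(per_founder_fitness(cc, r, tt, kp, kb), w_abs,
                 tolerance = 1e-12)
  }
})

test_that("zero-growth fitness gradient is the closed form with the sign
           of the transmission difference", {
  expect_equal(fitness_gradient_zero_growth(0.3, 25, 0.4, 0.4), 0)
  expect_gt(fitness_gradient_zero_growth(0.1, 10, 0.1, 0.6), 0)
  expect_lt(fitness_gradient_zero_growth(0.1, 10, 0.6, 0.1), 0)
  expect_equal(fitness_gradient_zero_growth(0.05, 10, 0.1, 0.6),
               10 * exp(-0.5) * 0.5)
  # matches the full gradient as r -> 0
  fd <- central_diff(function(cc)
    per_founder_fitness(cc, 1e-10, 10, 0.1, 0.6), 0.05)
  expect_equal(fitness_gradient_zero_growth(0.05, 10, 0.1, 0.6), fd,
               tolerance = 1e-4)
})

test_that("optimal colonization reproduces the reference mixed optimum and
           the boundary regimes", {
  opt <- optimal_colonization(r = 0.06, t_end = 40, k_p = 0.1, k_b = 0.6)
  expect_equal(opt$regime, "mixed")
  # two-decimal agreement with the reference value 0.49
  expect_lt(abs(opt$c_star_rel - 0.49), 0.01)
  # and exact agreement with an independent brute-force argmax
  expect_lt(abs(opt$c_star - brute_force_c_star(0.06, 40, 0.1, 0.6)),
            2 * 0.06 / 1e5)
  expect_equal(opt$W_at_optimum,
               per_founder_fitness(opt$c_star, 0.06, 40, 0.1, 0.6))
  # biofilm worthless: all-plankton
  expect_equal(optimal_colonization(0.06, 40, 0.3, 0)$regime, "pure_plankton")
  # vanishing growth with biofilm favoured: all-biofilm (zero-sum game)
  o0 <- optimal_colonization(1e-9, 40, 0.1, 0.6)
  expect_equal(o0$regime, "pure_biofilm")
  expect_equal(o0$c_star, 1e-9)
})

test_that("zero-growth limit never yields an interior optimum", {
  set.seed(5)
  for (i in 1:10) {
    kp <- runif(1); kb <- runif(1)
    if (abs(kb - kp) < 0.05) next
    o <- optimal_colonization(1e-9, runif(1, 5, 60), kp, kb)
    expect_true(o$regime %in% c("pure_plankton", "pure_biofilm"))
    expect_equal(o$regime,
                 if (kb > kp) "pure_biofilm" else "pure_plankton")
  }
})

test_that("optimizer matches a dense brute-force grid on random landscapes", {
  set.seed(8)
  for (i in 1:40) {
    r <- runif(1, 0.01, 0.15)
    tt <- runif(1, 5, 70)
    kp <- runif(1); kb <- runif(1)
    o <- optimal_colonization(r, tt, kp, kb)
    bf <- brute_force_c_star(r, tt, kp, kb, n = 1e5)
    expect_lt(abs(o$c_star - bf), 2 * r / 1e5)
  }
})

test_that("regime classification agrees with the optimizer and links the
           biofilm hump to the pure-biofilm threshold", {
  expect_equal(classify_regime(0.05, 30, 1, 0), "pure_plankton")
  expect_equal(classify_regime(0.12, 40, 0, 1), "mixed")
  set.seed(13)
  for (i in 1:60) {
    r <- runif(1, 0.01, 0.15)
    tt <- runif(1, 5, 70)
    kp <- runif(1); kb <- runif(1)
    expect_equal(classify_regime(r, tt, kp, kb),
                 optimal_colonization(r, tt, kp, kb)$regime,
                 info = sprintf("r=%g t=%g kp=%g kb=%g", r, tt, kp, kb))
  }
  # with k_p = 0 the fitness is proportional to the biofilm count, so the
  # optimum is interior exactly when the biofilm hump exists (r t > 2)
  expect_equal(classify_regime(0.04, 40, 0, 1), "pure_biofilm")  # rt = 1.6
  expect_equal(classify_regime(0.08, 40, 0, 1), "mixed")         # rt = 3.2
  o <- optimal_colonization(0.08, 40, 0, 1)
  expect_equal(o$c_star, biofilm_maximizing_colonization(0.08, 40),
               tolerance = 1e-6)
})

test_that("regime boundaries bracket the classification and vanish where
           published-style panels say they should", {
  rb_low <- regime_boundaries(0.02, 40, k_grid = 21)
  expect_gt(nrow(rb_low$white), 10)
  expect_gt(nrow(rb_low$black), 10)
  # near-zero-sum: the two thresholds are close (thin mixed band)
  merged <- merge(rb_low$white, rb_low$black, by = "k_p",
                  suffixes = c("_w", "_b"))
  expect_lt(mean(abs(merged$k_b_b - merged$k_b_w)), 0.15)
  # rich patches: the pure-biofilm threshold leaves the unit square
  rb_hi <- regime_boundaries(0.12, 40, k_grid = 21)
  expect_identical(nrow(rb_hi$black), 0L)
  # points either side of the white boundary classify differently
  for (i in unique(pmin(c(5, 10, 15), nrow(rb_low$white)))) {
    kp <- rb_low$white$k_p[i]; kb <- rb_low$white$k_b[i]
    if (kb < 0.01 || kb > 0.99) next
    expect_equal(classify_regime(0.02, 40, kp, kb - 5e-3), "pure_plankton")
    expect_false(classify_regime(0.02, 40, kp, kb + 5e-3) == "pure_plankton")
  }
})

test_that("the allocation landscape grows its mixed region with patch
           quality and stays within [0, 1]", {
  ls_r <- landscape_grid(c(0.02, 0.12), 40, k_res = 41)
  rel <- lapply(ls_r$panels, `[[`, "c_star_rel")
  expect_true(all(sapply(rel, function(m) all(m >= 0 & m <= 1))))
  mixed_area <- sapply(ls_r$panels, function(p) mean(p$regime == "mixed"))
  expect_gt(mixed_area[2], mixed_area[1])
  # permissive growth periods widen the mixed region relative to the
  # near-zero-sum short-period panel; at long r*t the pure-plankton/
  # mixed threshold line steepens (slope ~ r t), so the band eventually
  # thins again rather than growing without bound
  ls_t <- landscape_grid(0.08, c(10, 40, 70), k_res = 41)
  area_t <- sapply(ls_t$panels, function(p) mean(p$regime == "mixed"))
  expect_gt(area_t[2], area_t[1])
  expect_gt(area_t[3], area_t[1])
  # grid labels agree with the scalar classifier on sampled cells
  p <- ls_r$panels[[2]]
  set.seed(2)
  for (i in sample(length(p$k_p), 8)) for (j in sample(length(p$k_b), 2)) {
    if (p$k_p[i] == 0 && p$k_b[j] == 0) next
    expect_equal(p$regime[i, j],
                 classify_regime(p$r, p$t_end, p$k_p[i], p$k_b[j]))
  }
})
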