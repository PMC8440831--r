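test_that("pooled deviations have the documented group sizes", {
  m1 <- generate_spine_model(geometry_params(), seed = 51)$model
  m2 <- generate_spine_model(geometry_params(), seed = 52)$model
  m3 <- generate_spine_model(geometry_params(), seed = 53)$model
  subjects <- lapply(list(m1, m2, m3), function(m)
    emulate_operators(m, operator_variability_spec(), 3, seed = 60))
  baselines <- lapply(subjects, average_models)
  pool <- pool_deviations(subjects, baselines)
  key <- paste(pool$component, pool$parameter, pool$direction)
  sizes <- table(key)
  ## 3 subjects x 3 operators: 28 markers each for marker-position-x
  expect_equal(unname(sizes["marker position x"]), 28 * 3 * 3)
  expect_equal(unname(sizes["body orientation y"]), 18 * 3 * 3)
  expect_equal(unname(sizes["joint position z"]), 17 * 3 * 3)
  expect_equal(length(sizes), 15)
  ## positions are mean-centred by the arithmetic-mean baseline per slot
  mk <- pool[pool$component == "marker" & pool$subject == 1, ]
  sums <- tapply(mk$value, paste(mk$element, mk$direction), sum)
  expect_lt(max(abs(sums)), 1e-9)
})

test_that("identical operators give an all-zero pool and zero summaries", {
  m <- fix_model()$model
  pool <- pool_deviations(list(list(m, m, m)), list(m))
  expect_lt(max(abs(pool$value)), 1e-12)
  sm <- summarize_deviations(pool)
  expect_equal(max(sm$by_group$max_abs), 0, tolerance = 1e-12)
  expect_equal(unname(sm$marker_3d["max"]), 0, tolerance = 1e-12)
})

test_that("deviation summary handles a single-sample group correctly", {
  m <- fix_model()$model
  pool <- pool_deviations(list(list(m, m)), list(m))
  pool$value[1] <- 2  # plant one deviation
  sub <- structure(pool[1, , drop = FALSE],
                   class = c("deviation_pool", "data.frame"))
  sm <- summarize_deviations(sub)
  expect_equal(sm$by_group$median_abs, 2)
  expect_equal(sm$by_group$max_abs, 2)
})

test_that("KDE sampling reproduces the source moments", {
  fx <- fix_operators()
  m <- fx$baseline
  ## N(0,1) source deviations planted into the pool
  withr::with_seed(41, src <- rnorm(nrow(fx$pool)))
  pool_fake <- fx$pool
  pool_fake$value <- src
  d1 <- fit_kde(pool_fake)
  withr::with_seed(4, {
    draws <- replicate(40, draw_perturbation(d1, m))
  })
  ## marker block: compare against the moments of its own source samples
  mk <- pool_fake$value[pool_fake$component == "marker"]
  x <- as.vector(draws[1:84, ])  # 3360 draws
  expect_lt(abs(mean(x) - mean(mk)), 0.1)
  expect_lt(abs(sd(x) - sd(mk)), 0.15)
})

test_that("degenerate single-valued groups draw within the bandwidth floor", {
  m <- fix_model()$model
  pool <- pool_deviations(list(list(m, m, m)), list(m))  # all zeros
  dists <- fit_kde(pool, bw_floor = 1e-6)
  withr::with_seed(5, d <- draw_perturbation(dists, m))
  expect_lt(max(abs(d)), 1e-5)
})

test_that("group samplers are isolated: zeroing one group leaves others alone", {
  m <- fix_model()$model
  spec <- operator_variability_spec(
    marker_position = c(0, 0, 0),
    body_position = c(1, 1, 1), body_orientation = c(1, 1, 1),
    joint_position = c(1, 1, 1), joint_orientation = c(1, 1, 1))
  dists <- perturbation_distributions(spec)
  withr::with_seed(6, d <- draw_perturbation(dists, m))
  layout <- parameter_layout(m)
  expect_true(all(d[layout$component == "marker"] == 0))
  expect_true(all(d[layout$component != "marker"] != 0))
})

test_that("fit_kde refuses underfilled groups with a helpful message", {
  m <- fix_model()$model
  pool <- pool_deviations(list(list(m, m)), list(m))
  expect_error(fit_kde(pool, min_samples = 100), "supply spreads directly")
})

test_that("check_convergence matches a literal brute-force recomputation", {
  ## constant history converges at the minimum checkable n
  h <- matrix(1, 60, 2)
  expect_equal(check_convergence(h, min_iter = 20), 20L)
  expect_equal(oracle_convergence(h, min_iter = 20), 20L)
  ## a step change inside the final window defers convergence
  h2 <- matrix(c(rep(1, 50), rep(50, 10)), ncol = 1)
  expect_true(is.na(check_convergence(h2, min_iter = 20)) ||
                check_convergence(h2, min_iter = 20) < 50)
  expect_equal(check_convergence(h2, min_iter = 20),
               oracle_convergence(h2, min_iter = 20))
  ## i.i.d. noise histories: implementation equals the oracle
  set.seed(23)
  for (rep in 1:8) {
    h3 <- matrix(rnorm(120, mean = sample(c(0, 2, 10), 1)), ncol = 1)
    expect_identical(check_convergence(h3, min_iter = 30),
                     oracle_convergence(h3, min_iter = 30))
  }
  ## short history: none
  expect_true(is.na(check_convergence(matrix(1, 5, 1), min_iter = 100)))
})

test_that("confidence bands follow the order statistics", {
  ## identical curves give zero-width bands equal to the curve
  curve <- sin(seq(0, pi, length.out = 30))
  curves <- array(rep(curve, each = 25), c(25, 1, 30))
  b <- confidence_bands(curves)
  expect_equal(as.numeric(b$low), curve, tolerance = 1e-12)
  expect_equal(as.numeric(b$width), rep(0, 30), tolerance = 1e-12)
  ## c * constant with c ~ U(0,1): band approx [0.05, 0.95] * constant
  set.seed(24)
  cs <- runif(1000)
  curves2 <- array(rep(cs, times = 20) * 8,
                   c(1000, 1, 20))
  b2 <- confidence_bands(curves2)
  expect_lt(abs(mean(b2$low) - 0.05 * 8), 0.15)
  expect_lt(abs(mean(b2$high) - 0.95 * 8), 0.15)
  ## coverage: at least 90% of curves inside the band pointwise (+/- 1)
  inside <- colSums(curves2[, 1, ] >= matrix(b2$low, 1000, 20, byrow = TRUE) &
                      curves2[, 1, ] <= matrix(b2$high, 1000, 20, byrow = TRUE))
  expect_true(all(inside >= 0.9 * 1000 - 2))
})

test_that("t_sigma_max picks the frame of maximal variance with earliest ties", {
  ## constant variance over time: earliest frame wins
  set.seed(25)
  vals <- rnorm(40)
  curves <- array(rep(vals, times = 51 * 10), c(40, 51, 10))
  ts <- t_sigma_max_stats(curves)
  expect_true(all(ts$t_index == 1))
  ## inflated noise at frame 6 of DOF 3
  curves2 <- array(rnorm(40 * 51 * 10, sd = 0.1), c(40, 51, 10))
  curves2[, 3, 6] <- rnorm(40, sd = 25)
  ts2 <- t_sigma_max_stats(curves2)
  expect_equal(ts2$t_index[3], 6)
  ## symmetric two-curve set: median 0, min -d, max +d
  d <- 2.5
  curves3 <- array(0, c(6, 51, 4))
  curves3[1:3, , ] <- d
  curves3[4:6, , ] <- -d
  ts3 <- t_sigma_max_stats(curves3)
  expect_true(all(ts3$median == 0))
  expect_true(all(ts3$min == -d))
  expect_true(all(ts3$max == d))
})

test_that("sensitivity factors: perfect dependence, null bound, flags", {
  set.seed(26)
  n <- 2000
  draws <- matrix(rnorm(n * 294), n, 294)
  ## parameter 12 drawn one-sided so its max-|deviation| response is linear
  ## in the draw itself
  draws[, 12] <- abs(rnorm(n))
  curves <- array(rnorm(n * 51 * 5, sd = 1), c(n, 51, 5))
  for (f in 1:5) curves[, 7, f] <- 2 * draws[, 12]
  sf <- sensitivity_factors(draws, curves)
  expect_equal(unname(sf$r[12, 7]), 1, tolerance = 1e-9)
  ## independent draws: |r| < 0.1 for at least 99% of cells
  r_null <- sf$r[-12, -7]
  expect_gt(mean(abs(r_null) < 0.1), 0.99)
  ## zero-variance draw column is flagged and reported as 0
  draws2 <- draws; draws2[, 5] <- 3
  sf2 <- sensitivity_factors(draws2, curves)
  expect_true(all(sf2$flags[5, ]))
  expect_true(all(sf2$r[5, ] == 0))
})

test_that("zero-variance distributions give a degenerate, reproducible simulation", {
  m <- fix_model()$model
  spec0 <- operator_variability_spec(
    marker_position = c(0, 0, 0), body_position = c(0, 0, 0),
    body_orientation = c(0, 0, 0), joint_position = c(0, 0, 0),
    joint_orientation = c(0, 0, 0))
  dists <- perturbation_distributions(spec0)
  tr <- generate_flexion_trial(m, motion_spec(n_frames = 10, noise_sd = 0),
                               seed = 3)
  settings <- mc_settings(max_iter = 30, min_iter = 10, seed = 9,
                          n_norm_frames = 20)
  res <- run_monte_carlo(m, dists, tr$trial, settings)
  ## every relative curve is identically zero, bands have zero width
  expect_lt(max(abs(res$curves)), 1e-9)
  expect_lt(max(res$bands$width), 1e-9)
  ## converges at the minimum allowed n
  expect_equal(res$converged_n, 10L)
  expect_equal(res$n, 10L)
  ## all sensitivities flagged zero
  expect_true(all(res$sensitivity$flags))
  expect_true(all(res$sensitivity$r == 0))
})

test_that("identical seeds reproduce the simulation bit for bit", {
  fx <- fix_operators()
  dists <- fit_kde(fx$pool)
  tr <- generate_flexion_trial(fx$baseline,
                               motion_spec(n_frames = 8, noise_sd = 0),
                               seed = 13)
  settings <- mc_settings(max_iter = 6, min_iter = 5, seed = 77,
                          n_norm_frames = 15)
  r1 <- run_monte_carlo(fx$baseline, dists, tr$trial, settings)
  r2 <- run_monte_carlo(fx$baseline, dists, tr$trial, settings)
  expect_identical(r1$draws, r2$draws)
  expect_identical(r1$curves, r2$curves)
  expect_identical(r1$bands, r2$bands)
  expect_identical(r1$sensitivity$r, r2$sensitivity$r)
  ## a different seed gives different draws
  settings2 <- mc_settings(max_iter = 6, min_iter = 5, seed = 78,
                           n_norm_frames = 15)
  r3 <- run_monte_carlo(fx$baseline, dists, tr$trial, settings2)
  expect_false(identical(r1$draws, r3$draws))
})

test_that("doubling joint-orientation spreads does not shrink the bands", {
  m <- fix_model()$model
  tr <- generate_flexion_trial(m, motion_spec(n_frames = 8, noise_sd = 0),
                               seed = 19)
  base_spec <- operator_variability_spec()
  spec2 <- base_spec
  spec2$joint_orientation <- 2 * spec2$joint_orientation
  settings <- mc_settings(max_iter = 25, min_iter = 25, seed = 31,
                          n_norm_frames = 15)
  r1 <- run_monte_carlo(m, perturbation_distributions(base_spec), tr$trial,
                        settings)
  r2 <- run_monte_carlo(m, perturbation_distributions(spec2), tr$trial,
                        settings)
  expect_gte(mean(r2$bands$width), mean(r1$bands$width))
})
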