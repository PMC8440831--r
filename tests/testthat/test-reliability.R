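test_that("identical columns with subject spread give ICC = 1", {
  x <- cbind(c(10, 20, 30, 40), c(10, 20, 30, 40))
  res <- icc_2_1(x)
  expect_equal(res$icc, 1, tolerance = 1e-12)
})

test_that("ICC(2,1) equals the brute-force ANOVA oracle", {
  x <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), ncol = 2, byrow = TRUE)
  expect_equal(icc_2_1(x)$icc, oracle_icc21(x), tolerance = 1e-12)
  ## property: random tables, 4-10 subjects x 2-3 columns
  set.seed(14)
  for (rep in 1:60) {
    n <- sample(4:10, 1); k <- sample(2:3, 1)
    tab <- matrix(rnorm(n * k, 20, 6), n, k)
    expect_equal(icc_2_1(tab)$icc, oracle_icc21(tab), tolerance = 1e-10)
  }
})

test_that("a systematic offset between columns drives agreement toward zero", {
  set.seed(15)
  base <- rnorm(6, 50, 0.5)           # tiny between-subject spread
  x <- cbind(base, base + 40)          # large constant offset
  res <- icc_2_1(x)
  expect_lt(res$icc, 0.05)
  expect_equal(unname(res$icc), unname(oracle_icc21(x)), tolerance = 1e-10)
})

test_that("ICC is invariant to shifting all cells and to positive rescaling", {
  set.seed(16)
  x <- matrix(rnorm(12, 30, 8), 6, 2)
  r0 <- icc_2_1(x)$icc
  expect_equal(icc_2_1(x + 17.3)$icc, r0, tolerance = 1e-10)
  expect_equal(icc_2_1(x * 3.7)$icc, r0, tolerance = 1e-10)
})

test_that("degenerate all-equal tables are signalled", {
  expect_error(icc_2_1(matrix(5, 4, 2)), "undefined")
})

test_that("SEM formula reproduces the published worked values", {
  ## printed SD/ICC pairs -> printed SEM at one decimal
  expect_equal(round(sem(5.5, 0.86), 1), 2.1)
  expect_equal(round(sem(6.2, 0.12), 1), 5.8)
  expect_equal(sem(4.2, 1), 0)
  expect_error(sem(3, 1.2), "<= 1")
  expect_error(sem(-1, 0.5), ">= 0")
})

test_that("SDD = SEM x 1.96 x sqrt(2) and reproduces worked values", {
  expect_equal(round(sdd(sem(5.5, 0.86)), 1), 5.7)
  expect_equal(sdd(0), 0)
  expect_equal(round(sdd(sem(1.82, 0.970)), 1), 0.9)
  expect_equal(sdd(2), 2 * 1.96 * sqrt(2))
})

test_that("SEM is monotone in ICC and SDD is linear in SEM", {
  iccs <- seq(0, 1, by = 0.1)
  sems <- sem(5, iccs)
  expect_true(all(diff(sems) < 0))
  x <- runif(5, 0, 10)
  expect_equal(sdd(2 * x), 2 * sdd(x))
})

test_that("ICC classification uses the conventional bands", {
  expect_identical(classify_icc(0.86), "excellent")
  expect_identical(classify_icc(0.12), "poor")
  expect_identical(classify_icc(0.55), "fair to good")
  ## boundaries belong to the middle band as printed
  expect_identical(classify_icc(0.40), "fair to good")
  expect_identical(classify_icc(0.75), "fair to good")
  expect_identical(classify_icc(c(0.2, 0.5, 0.9)),
                   c("poor", "fair to good", "excellent"))
})

test_that("reliability_summary mirrors the published table columns", {
  set.seed(17)
  tabs <- list(LL = matrix(rnorm(10, 20, 5), 5, 2),
               TK = matrix(rnorm(10, 20, 5), 5, 2))
  out <- reliability_summary(tabs)
  expect_setequal(names(out), c("parameter", "icc", "ci_low", "ci_high", "p",
                                "sd", "sem", "sdd", "classification",
                                "mean_rom", "min_rom", "max_rom"))
  expect_equal(out$sdd, out$sem * 1.96 * sqrt(2))
  expect_true(all(out$icc <= 1))
  ## CI brackets the estimate where defined
  ok <- !is.na(out$ci_low)
  expect_true(all(out$ci_low[ok] <= out$icc[ok] &
                    out$icc[ok] <= out$ci_high[ok]))
})

test_that("the two SD conventions agree for two columns up to their definitions", {
  set.seed(18)
  x <- matrix(rnorm(14, 25, 4), 7, 2)
  s_pair <- reliability_sd(x, "pairwise")
  s_mean <- reliability_sd(x, "from_mean")
  expect_gt(s_pair, 0)
  expect_gt(s_mean, 0)
  ## for k = 2 the deviation from the row mean is half the difference
  expect_equal(sd(abs(x[, 1] - x[, 2])), s_pair)
})
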