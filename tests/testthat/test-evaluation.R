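test_that("percentageError is the signed relative error in percent", {
  expect_equal(percentageError(90, 100), -10)
  expect_equal(percentageError(100, 100), 0)
  expect_equal(percentageError(c(110, 330), c(100, 300)), c(10, 10))
  expect_error(percentageError(90, 0), "positive")
  expect_error(percentageError(90, -5), "positive")
})

test_that("summarizeErrors reports MPE/MAPE with sample SDs", {
  s <- summarizeErrors(c(-10, 10))
  expect_equal(s$mpe_pct, 0)
  expect_equal(s$mape_pct, 10)
  expect_equal(s$sd_pe_pct, sd(c(-10, 10)))

  one <- summarizeErrors(-28)
  expect_equal(one$mpe_pct, -28)
  expect_true(is.na(one$sd_pe_pct))
  expect_equal(one$n, 1)

  # four stratum means of a strongly underestimating method
  grp <- summarizeErrors(c(-30.6, -28.7, -27.7, -26.9))
  expect_equal(grp$mpe_pct, -28.475)
  expect_equal(grp$mape_pct, 28.475)
  expect_error(summarizeErrors(numeric(0)), "no errors")
})

test_that("MAPE dominates |MPE| and pooling is size-weighted", {
  set.seed(30)
  for (i in 1:6) {
    e <- rnorm(sample(2:40, 1), sd = 15)
    s <- summarizeErrors(e)
    expect_gte(s$mape_pct, abs(s$mpe_pct))
    expect_gte(s$mape_pct, 0)
  }
  g1 <- rnorm(8, -20, 5); g2 <- rnorm(3, 4, 2); g3 <- rnorm(12, 1, 8)
  pooled <- summarizeErrors(c(g1, g2, g3))
  weighted <- (8 * mean(g1) + 3 * mean(g2) + 12 * mean(g3)) / 23
  expect_equal(pooled$mpe_pct, weighted)
})

test_that("agreement reproduces the hand-computed 4-pair fixture", {
  actual <- c(100, 200, 300, 400)
  est <- c(90, 210, 290, 420)        # differences -10, +10, -10, +20
  a <- agreement(actual, est)
  expect_equal(a$mean_diff_mL, 2.5)
  expect_equal(a$sd_diff_mL, 15)
  expect_equal(a$loa_lower_mL, 2.5 - 1.96 * 15)   # -26.9
  expect_equal(a$loa_upper_mL, 2.5 + 1.96 * 15)   # +31.9
  expect_equal(a$loa_upper_mL - a$loa_lower_mL, 2 * 1.96 * a$sd_diff_mL)
  expect_equal(a$cv_pct, 15 / 250 * 100)
  expect_equal(a$n, 4)
})

test_that("agreement handles perfect, offset and proportional estimates", {
  x <- c(120, 260, 390, 505, 700)
  perfect <- agreement(x, x)
  expect_equal(perfect$pearson_r, 1)
  expect_equal(perfect$mean_diff_mL, 0)
  expect_equal(perfect$loa_lower_mL, 0)
  expect_equal(perfect$loa_upper_mL, 0)
  expect_gt(perfect$t_p, 0.9)
  expect_gt(perfect$wilcoxon_p, 0.9)

  off <- agreement(x, x + 30)
  expect_equal(off$pearson_r, 1)
  expect_equal(off$mean_diff_mL, 30)
  expect_equal(off$sd_diff_mL, 0)

  prop <- agreement(x, 2 * x)
  expect_equal(prop$pearson_r, 1)
  expect_equal(prop$r_squared, 1)
  expect_equal(prop$mean_diff_mL, mean(x))

  expect_error(agreement(rep(100, 4), c(90, 110, 100, 95)), "constant")
  expect_error(agreement(100, 90), "at least 2")
})

test_that("paired tests are non-significant on symmetric differences", {
  x <- c(150, 250, 350, 450, 550, 650)
  d <- c(-30, -20, -10, 10, 20, 30)
  a <- agreement(x, x + d)
  expect_gt(a$t_p, 0.9)
  expect_gt(a$wilcoxon_p, 0.9)
})

test_that("the Wilcoxon variants agree in direction and handle zeros", {
  x <- c(100, 200, 300, 400, 500, 600)
  d <- c(0, 0, 15, 25, 40, 60)
  drop <- agreement(x, x + d)$wilcoxon_p
  pratt <- agreement(x, x + d, zeroes = "pratt")$wilcoxon_p
  expect_lt(drop, 0.2)
  expect_true(pratt > 0 && pratt <= 1)
  # large-n path (normal approximation with continuity correction)
  set.seed(77)
  big <- rnorm(40, 5, 2)
  p <- agreement(seq(100, 490, 10), seq(100, 490, 10) + big)$wilcoxon_p
  expect_lt(p, 1e-6)
})

test_that("groupByVolume partitions (0, Inf) with right-closed bounds", {
  g <- groupByVolume(c(150, 200, 200.1, 400, 550, 600, 601, 1400))
  expect_equal(as.character(g),
               c("0-200", "0-200", "200-400", "200-400", "400-600",
                 "400-600", ">600", ">600"))
  expect_equal(levels(g), c("0-200", "200-400", "400-600", ">600"))
  expect_false(anyNA(g))
  expect_error(groupByVolume(100, cutpoints = c(400, 200)), "increasing")
  expect_error(groupByVolume(c(-5, 100)), "positive")
})

test_that("evaluateCohort assembles pooled and per-group reports", {
  set.seed(8)
  actual <- runif(24, 120, 900)
  cohort <- data.frame(
    actual_volume_mL = actual,
    est_traditional_mL = actual * 0.72 + rnorm(24, 0, 20),
    est_reconstruction_n4_mL = actual + rnorm(24, 0, 12))
  rep <- evaluateCohort(cohort)
  expect_equal(rep$n, 24)
  expect_named(rep$methods,
               c("est_traditional_mL", "est_reconstruction_n4_mL"))
  tra <- rep$methods$est_traditional_mL$pooled
  expect_lt(tra$errors$mpe_pct, -20)
  expect_gt(tra$agreement$pearson_r, 0.9)
  n4 <- rep$methods$est_reconstruction_n4_mL$pooled
  expect_lt(abs(n4$errors$mpe_pct), 5)
  # group sizes sum to the cohort size
  expect_equal(sum(unlist(rep$groups)), 24)
  # per-group error summaries pool back to the overall mean, size-weighted
  gsum <- rep$methods$est_traditional_mL$by_group
  sizes <- vapply(gsum, function(g) g$errors$n, numeric(1))
  means <- vapply(gsum, function(g) g$errors$mpe_pct, numeric(1))
  expect_equal(sum(sizes * means) / sum(sizes), tra$errors$mpe_pct)
})
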