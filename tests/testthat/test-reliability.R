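test_that("cronbach_alpha matches hand-computed values", {
  # perfectly parallel items: every subject repeats one value across items
  m <- matrix(rep(c(1, 2, 4, 0, 3), 7), ncol = 7)
  expect_equal(cronbach_alpha(m), 1.0)
  # 3 subjects x 2 items, hand oracle: vars 4 and 1, total 9 -> 2(1 - 5/9)
  m2 <- cbind(c(0, 2, 4), c(1, 2, 3))
  expect_equal(cronbach_alpha(m2), 8 / 9)
  # independently shuffled items carry no shared signal
  set.seed(21)
  m3 <- replicate(7, sample(0:4, 200, replace = TRUE))
  expect_lt(abs(cronbach_alpha(m3)), 0.3)
})

test_that("cronbach_alpha rejects degenerate input", {
  expect_error(cronbach_alpha(matrix(2, 4, 7)), "variance")
  expect_error(cronbach_alpha(matrix(1:7, 1, 7)), "subjects")
  expect_error(cronbach_alpha(matrix(1:5, 5, 1)), "items")
})

test_that("cronbach_alpha is invariant to shifts and common scaling", {
  set.seed(31)
  m <- matrix(rnorm(60, 10, 2), ncol = 6) + rnorm(10)
  a <- cronbach_alpha(m)
  expect_equal(cronbach_alpha(m + 7), a)
  expect_equal(cronbach_alpha(m * 3.5), a)
})

test_that("icc_two_way agrees with the brute-force ANOVA oracle", {
  # perfect agreement
  m <- cbind(c(1, 3, 5, 9), c(1, 3, 5, 9))
  expect_equal(icc_two_way(m)$icc, 1.0)
  # fixed rater offset: the ANOVA-table oracle value, computed from first
  # principles, is the reference
  m2 <- cbind(c(1, 3, 5, 7), c(2, 4, 6, 8))
  expect_equal(icc_two_way(m2)$icc, icc21_brute(m2), tolerance = 1e-12)
  # absolute-agreement symmetry under column swap
  expect_equal(icc_two_way(m2[, 2:1])$icc, icc_two_way(m2)$icc)
  # random tables: equality to 1e-10 and range [-1, 1]
  set.seed(41)
  for (i in 1:100) {
    n <- sample(4:12, 1); k <- sample(2:4, 1)
    tab <- matrix(rnorm(n * k, sample(0:20, 1), runif(1, 0.5, 4)), n, k)
    res <- icc_two_way(tab)
    expect_equal(res$icc, icc21_brute(tab), tolerance = 1e-10)
    expect_gte(res$icc, -1)
    expect_lte(res$icc, 1)
  }
})

test_that("icc_two_way mean squares match base-R aov", {
  set.seed(51)
  n <- 8; k <- 2
  tab <- matrix(rnorm(n * k, 10, 3), n, k)
  d <- data.frame(y = as.vector(tab),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][, "Mean Sq"]
  res <- icc_two_way(tab)
  expect_equal(res$msr, ms[1], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(res$msc, ms[2], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(res$mse, ms[3], tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("icc confidence interval brackets the estimate", {
  set.seed(61)
  for (i in 1:20) {
    tab <- matrix(rnorm(20, 10, 3), 10, 2) + rnorm(10, 0, 3)
    res <- icc_two_way(tab)
    expect_lte(res$ci[["lower"]], res$icc)
    expect_gte(res$ci[["upper"]], res$icc)
  }
})

test_that("icc_two_way rejects incomplete or tiny tables", {
  m <- cbind(c(1, 2, NA), c(1, 2, 3))
  expect_error(icc_two_way(m), "missing")
  expect_error(icc_two_way(cbind(1:2, 2:3)), "subjects")
})

test_that("friedman_test matches hand ranks and stats::friedman.test", {
  # identical columns: no differences at all
  m <- matrix(rep(c(3, 5, 1), 3), ncol = 3)
  res <- friedman_test(m)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # strictly increasing rows: ranks 1,2,3 in every block -> chi2 = 6
  m2 <- rbind(c(1, 2, 3), c(4, 6, 8), c(0, 5, 9))
  expect_equal(friedman_test(m2)$statistic, 6)
  # agreement with the base implementation, including ties
  set.seed(71)
  for (i in 1:20) {
    m3 <- matrix(sample(0:6, 8 * 4, replace = TRUE), 8, 4)
    if (any(apply(m3, 1, function(r) length(unique(r))) == 1)) next
    ref <- stats::friedman.test(m3)
    res3 <- friedman_test(m3)
    expect_equal(res3$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res3$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("friedman statistic is invariant to rank-preserving transforms", {
  set.seed(81)
  m <- matrix(rnorm(24), 6, 4)
  a <- friedman_test(m)$statistic
  expect_equal(friedman_test(exp(m))$statistic, a)
  expect_equal(friedman_test(m^3 + 100)$statistic, a)
})

test_that("sham scores pool across timepoints in simulated experiments", {
  p <- sapply(1:10, function(s) sham_pooling_check(cached_experiment(s))$p_value)
  expect_gte(sum(p > 0.05), 9)
})

test_that("reliability_block returns coherent septic-assessment results", {
  rel <- reliability_block(cached_experiment(1))
  expect_lte(rel$cronbach_alpha, 1)
  expect_gte(rel$icc, -1)
  expect_lte(rel$icc, 1)
  expect_lte(rel$icc_ci95[["lower"]], rel$icc)
  expect_gte(rel$icc_ci95[["upper"]], rel$icc)
  expect_identical(rel$n_raters, 2L)
  expect_equal(rel$timepoints_used, c(2, 12, 14, 16, 18, 20, 24))
})
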