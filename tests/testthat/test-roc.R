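test_that("roc_curve handles the degenerate anchor cases", {
  expect_equal(suppressWarnings(roc_curve(rep(28, 5), rep(0, 5)))$auc, 1.0)
  x <- c(0, 3, 7, 12, 28)
  expect_equal(roc_curve(x, x)$auc, 0.5)
  expect_error(roc_curve(numeric(0), 1:3), "non-empty")
  expect_error(roc_curve(c(1, 30), c(0, 1)), "0..28")
})

test_that("trapezoid AUC equals the tie-corrected Mann-Whitney statistic", {
  set.seed(91)
  for (i in 1:100) {
    pos <- sample(0:28, 50, replace = TRUE)
    neg <- sample(0:28, 50, replace = TRUE)
    roc <- roc_curve(pos, neg)
    expect_equal(roc$auc, auc_by_pairwise_count(pos, neg), tolerance = 1e-12)
  }
})

test_that("ROC curve is a proper step function and AUC matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(101)
  pos <- pmin(28, rpois(80, 9))
  neg <- pmin(28, rpois(120, 2))
  roc <- roc_curve(pos, neg)
  expect_true(all(diff(roc$sens) <= 0))
  expect_true(all(diff(roc$spec) >= 0))
  expect_equal(roc$sens[1], 1); expect_equal(roc$spec[1], 0)
  expect_equal(roc$sens[30], 0); expect_equal(roc$spec[30], 1)
  ref <- pROC::roc(response = c(rep(1, length(pos)), rep(0, length(neg))),
                   predictor = c(pos, neg), quiet = TRUE, direction = "<")
  expect_equal(roc$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("AUC is invariant under strictly increasing score transforms", {
  # a monotone relabelling of the score scale cannot change rank order
  set.seed(111)
  pos <- sample(0:14, 40, replace = TRUE)
  neg <- sample(0:14, 40, replace = TRUE)
  mono <- sort(sample(0:28, 15))
  expect_equal(roc_curve(mono[pos + 1], mono[neg + 1])$auc,
               roc_curve(pos, neg)$auc, tolerance = 1e-12)
})

test_that("Hanley-McNeil interval behaves as the formula dictates", {
  ci <- auc_ci_hanley(0.5, 40, 40)
  expect_equal(ci[["upper"]] - 0.5, 0.5 - ci[["lower"]], tolerance = 1e-12)
  # width shrinks like sqrt(10) when both classes grow 10-fold
  w1 <- unname(diff(auc_ci_hanley(0.8, 50, 50)))
  w10 <- unname(diff(auc_ci_hanley(0.8, 500, 500)))
  expect_equal(w1 / w10, sqrt(10), tolerance = 0.01)
  expect_warning(auc_ci_hanley(1, 10, 10), "degenerate")
  expect_error(auc_ci_hanley(0.8, 1, 50), ">= 2")
})

test_that("Hanley-McNeil interval agrees with a bootstrap oracle", {
  set.seed(121)
  pos <- pmin(28, rpois(150, 8))
  neg <- pmin(28, rpois(150, 3))
  roc <- roc_curve(pos, neg)
  boot <- replicate(2000, {
    auc_by_pairwise_count(sample(pos, replace = TRUE),
                          sample(neg, replace = TRUE))
  })
  perc <- unname(stats::quantile(boot, c(0.025, 0.975)))
  expect_equal(roc$auc_ci95[["lower"]], perc[1], tolerance = 0.02)
  expect_equal(roc$auc_ci95[["upper"]], perc[2], tolerance = 0.02)
})

test_that("youden_cutoff maximizes J with ties broken downward", {
  # perfect separation at score 10
  roc <- suppressWarnings(roc_curve(c(10, 12, 20), c(0, 2, 9)))
  yj <- youden_cutoff(roc)
  expect_equal(yj$cutoff, 10)
  expect_equal(yj$youden_j, 1)
  # equal-J ties return the lower threshold: two point masses
  roc2 <- suppressWarnings(roc_curve(rep(c(5, 9), 5), rep(c(1, 3), 5)))
  j2 <- roc2$sens + roc2$spec - 1
  best <- youden_cutoff(roc2)
  expect_equal(best$youden_j, max(j2))
  expect_equal(best$cutoff, min(roc2$thresholds[j2 == max(j2)]))
  # brute force over all 30 thresholds on random instances
  set.seed(131)
  for (i in 1:100) {
    pos <- sample(0:28, 30, replace = TRUE)
    neg <- sample(0:28, 30, replace = TRUE)
    roc3 <- suppressWarnings(roc_curve(pos, neg))
    jj <- vapply(0:29, function(c) mean(pos >= c) + mean(neg < c) - 1,
                 numeric(1))
    got <- youden_cutoff(roc3)
    expect_equal(got$youden_j, max(jj), tolerance = 1e-12)
    expect_equal(got$cutoff, (0:29)[which.max(jj)])
  }
})

test_that("clopper_pearson matches closed forms, binom.test and inversion", {
  expect_equal(clopper_pearson(20, 20)[["lower"]], 0.025^(1 / 20),
               tolerance = 1e-12)
  expect_equal(clopper_pearson(20, 20)[["upper"]], 1)
  expect_equal(clopper_pearson(0, 20)[["lower"]], 0)
  expect_equal(clopper_pearson(0, 20)[["upper"]], 1 - 0.025^(1 / 20),
               tolerance = 1e-12)
  cp57 <- clopper_pearson(57, 100)
  expect_equal(unname(cp57), c(0.4667, 0.6685), tolerance = 1e-3)
  for (xx in c(0, 3, 12, 25)) {
    ref <- stats::binom.test(xx, 25)$conf.int
    got <- clopper_pearson(xx, 25)
    expect_equal(got[["lower"]], ref[1], tolerance = 1e-9)
    expect_equal(got[["upper"]], ref[2], tolerance = 1e-9)
    inv <- cp_by_tail_inversion(xx, 25)
    expect_equal(got[["lower"]], inv[["lower"]], tolerance = 1e-9)
    expect_equal(got[["upper"]], inv[["upper"]], tolerance = 1e-9)
  }
})

test_that("clopper_pearson achieves nominal coverage", {
  set.seed(141)
  p <- 0.3; n <- 25
  draws <- stats::rbinom(10000, n, p)
  lowers <- stats::qbeta(0.025, draws, n - draws + 1)
  lowers[draws == 0] <- 0
  uppers <- stats::qbeta(0.975, draws + 1, n - draws)
  uppers[draws == n] <- 1
  expect_gte(mean(lowers <= p & p <= uppers), 0.95)
})

test_that("operating_point reports exact intervals and handles zero cells", {
  op <- operating_point(c(5, 9, 2, 7), c(0, 1, 1, 2), 3)
  expect_equal(op$sens$estimate, 3 / 4)
  expect_equal(op$spec$estimate, 1)
  expect_equal(op$youden_j, op$sens$estimate + op$spec$estimate - 1)
  expect_equal(op$sens$ci, clopper_pearson(3, 4))
  # nothing classified positive: PPV undefined
  op2 <- operating_point(c(0, 1), c(0, 1), 28)
  expect_true(is.na(op2$ppv$estimate))
  expect_true(all(is.na(op2$ppv$ci)))
})

test_that("build_roc_inputs pools assessments and enforces class presence", {
  ex <- cached_experiment(1)
  inp <- build_roc_inputs(ex)
  mice <- ex$mice
  dead <- mice$mouse_id[mice$group != "sham" & mice$outcome != "survived"]
  a1 <- ex$assessments[ex$assessments$rater_id == "R1", ]
  expect_length(inp$scores_pos, sum(a1$mouse_id %in% dead))
  # every surviving sham mouse contributes one assessment per scheduled time
  expect_length(inp$scores_neg,
                sum(mice$group == "sham") * length(monitoring_schedule(24)))
  expect_equal(inp$n_excluded_septic_survivors,
               sum(mice$group != "sham" & mice$outcome == "survived"))

  sham_only <- list(mice = mice[mice$group == "sham", ],
                    assessments = ex$assessments)
  expect_error(build_roc_inputs(sham_only), "septic")
  all_alive <- list(mice = transform(mice, outcome = "survived"),
                    assessments = ex$assessments)
  expect_error(build_roc_inputs(all_alive), "positive class")
})
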