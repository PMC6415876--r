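test_that("OLS reproduces exact lines and matches the normal equations", {
  x <- c(10, 20, 30, 40, 50)
  tab <- measurement_table(paste0("s", 1:5), 2 * x / 2 + 1, x / 2)
  # y = 2x + 1 with x = reference
  tab$device <- 2 * tab$reference + 1
  fit <- ols_regression(tab)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope_ci, c(2, 2), tolerance = 1e-8)

  for (seed in 1:20) {
    tb <- random_table(6, seed)
    f <- ols_regression(tb)
    o <- oracle_ols(tb$reference, tb$device)
    expect_equal(f$slope, o$slope, tolerance = 1e-10)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
  }

  const <- measurement_table(c("a", "b", "c"), c(1, 2, 3), c(5, 5, 5))
  expect_error(ols_regression(const), class = "spermfx_degenerate_predictor_error")
})

test_that("Passing-Bablok agrees exactly with the brute-force enumeration oracle", {
  ident <- measurement_table(paste0("s", 1:10), seq(5, 95, 10), seq(5, 95, 10))
  fit <- passing_bablok(ident)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)

  for (seed in 1:100) {
    n <- 4 + seed %% 7   # n in 4..10
    tb <- random_table(n, seed + 1000)
    f <- passing_bablok(tb)
    o <- oracle_pb(tb$reference, tb$device)
    expect_identical(f$slope, o$slope)
    expect_identical(f$intercept, o$intercept)
    expect_equal(f$K, o$K)
  }
})

test_that("exchanging the methods inverts the Passing-Bablok slope", {
  with_seed_local(99, {
    x <- runif(40, 10, 90) + rnorm(40, 0, 0.001)  # tie-free
    y <- 5 + 1.3 * x + rnorm(40, 0, 2)
    tb <- measurement_table(paste0("s", 1:40), clamp_vec(y), clamp_vec(x))
    fwd <- passing_bablok(tb)
    rev_tab <- measurement_table(tb$sample_id, tb$reference, tb$device)
    bwd <- passing_bablok(rev_tab)
    expect_equal(bwd$slope, 1 / fwd$slope, tolerance = 0.05)
  })
})

test_that("the slope CI covers the generating slope at roughly nominal rate", {
  hits <- 0L
  for (seed in 1:100) {
    tb <- gen_paired_table(paired_data_spec(
      n = 102, true_slope = 1, true_intercept = -1,
      noise_sd_device = 3, noise_sd_reference = 3, seed = seed))$table
    ci <- passing_bablok(tb)$slope_ci
    if (ci[1] <= 1 && 1 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("Bland-Altman bias, SD and limits of agreement", {
  same <- measurement_table(c("a", "b", "c"), c(10, 20, 30), c(10, 20, 30))
  ba0 <- bland_altman(same)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$sd_diff, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))

  shift <- measurement_table(c("a", "b", "c"), c(13, 23, 33), c(10, 20, 30))
  ba3 <- bland_altman(shift)
  expect_equal(ba3$bias, 3)
  expect_equal(ba3$sd_diff, 0)

  for (seed in 1:25) {
    tb <- random_table(10 + seed, seed + 300)
    ba <- bland_altman(tb)
    expect_identical(ba$loa_low, ba$bias - 1.96 * ba$sd_diff)
    expect_identical(ba$loa_high, ba$bias + 1.96 * ba$sd_diff)
    d <- tb$device - tb$reference
    expect_equal(ba$bias, mean(d))
    expect_equal(ba$sd_diff, sd(d))
  }
})

test_that("threshold classification tallies the confusion matrix", {
  tb <- measurement_table(c("a", "b"), c(70, 90), c(75, 85))
  cm <- confusion_at_threshold(tb, 80)
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]),
               c(tp = 1, fp = 0, fn = 0, tn = 1))

  allpos <- measurement_table(c("a", "b", "c"), c(10, 20, 30), c(15, 25, 35))
  cm2 <- confusion_at_threshold(allpos, 80)
  expect_equal(cm2$tp, 3)
  expect_equal(cm2$fp + cm2$fn + cm2$tn, 0)
})

test_that("Clopper-Pearson intervals match closed forms and tail inversion", {
  # k = n: lower bound is (alpha/2)^(1/n)
  for (n in c(5, 18, 40)) {
    ci <- clopper_pearson(n, n)
    expect_equal(ci[1], 0.025^(1 / n), tolerance = 1e-10)
    expect_identical(ci[2], 1)
  }
  expect_identical(clopper_pearson(0, 12)[1], 0)

  for (case in list(c(3, 10), c(9, 13), c(18, 18), c(0, 7), c(27, 31))) {
    expect_equal(clopper_pearson(case[1], case[2]),
                 oracle_cp(case[1], case[2]), tolerance = 1e-8)
    bt <- binom.test(case[1], case[2])$conf.int
    expect_equal(clopper_pearson(case[1], case[2]), as.numeric(bt),
                 tolerance = 1e-8)
  }
})

test_that("diagnostic metrics carry exact CIs and tolerate empty margins", {
  cm <- confusion_matrix(tp = 18, fp = 4, fn = 0, tn = 9)
  dm <- diagnostic_metrics(cm)
  expect_equal(dm$sensitivity, 100)
  expect_equal(round(dm$sensitivity_ci, 2), c(81.47, 100))
  expect_equal(round(dm$specificity, 2), 69.23)
  expect_equal(round(dm$specificity_ci, 2), c(38.57, 90.91))
  expect_equal(round(dm$accuracy, 2), 87.10)
  expect_equal(round(dm$accuracy_ci, 2), c(70.17, 96.37))

  zero_sens <- confusion_matrix(tp = 0, fp = 0, fn = 5, tn = 5)
  dm2 <- diagnostic_metrics(zero_sens)
  expect_equal(dm2$sensitivity, 0)
  expect_identical(dm2$sensitivity_ci[1], 0)

  no_pos <- confusion_matrix(tp = 0, fp = 2, fn = 0, tn = 8)
  expect_warning(dm3 <- diagnostic_metrics(no_pos), "sensitivity undefined")
  expect_true(is.na(dm3$sensitivity))
  expect_false(is.na(dm3$specificity))
})

test_that("AUC equals the pair-counting oracle, including ties", {
  sep <- measurement_table(paste0("s", 1:8),
                           c(10, 20, 30, 40, 90, 92, 94, 96),
                           c(50, 60, 70, 75, 85, 90, 95, 99))
  expect_equal(roc_auc(sep)$auc, 1)

  flat <- measurement_table(paste0("s", 1:6), rep(50, 6),
                            c(70, 75, 78, 85, 90, 95))
  expect_equal(roc_auc(flat)$auc, 0.5)

  for (seed in 1:100) {
    n <- 6 + seed %% 7  # 6..12
    tb <- with_seed_local(seed + 2000, {
      x <- sample(seq(60, 100, 5), n, replace = TRUE)
      y <- sample(seq(0, 100, 10), n, replace = TRUE)   # coarse: many ties
      measurement_table(paste0("s", 1:n), y, x)
    })
    truth <- tb$reference < 80
    if (all(truth) || !any(truth)) {
      expect_error(roc_auc(tb), class = "spermfx_undefined_auc_error")
    } else {
      expect_equal(roc_auc(tb)$auc, oracle_auc(100 - tb$device, truth))
    }
  }
})

test_that("DeLong CI agrees with the reference ROC implementation", {
  skip_if_not_installed("pROC")
  for (seed in c(11, 22, 33)) {
    tb <- random_table(40, seed + 4000)
    truth <- tb$reference < 80
    if (all(truth) || !any(truth)) next
    ours <- roc_auc(tb)
    ref <- pROC::roc(response = truth, predictor = 100 - tb$device,
                     levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
    expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    expect_equal(ours$auc_ci, ref_ci[c(1, 3)], tolerance = 1e-9)
  }
})

test_that("the cusum test keeps lines and flags curvature", {
  line <- measurement_table(paste0("s", 1:20), seq(2, 97, 5), seq(2, 97, 5))
  expect_gte(passing_bablok(line)$cusum_p, 0.99)

  x <- 1:50
  curved <- measurement_table(paste0("s", x), pmin((x / 5)^2, 100), pmin(x, 100))
  expect_lt(passing_bablok(curved)$cusum_p, 0.05)
})

test_that("compare_methods bundles every requested analysis into one report", {
  tb <- gen_paired_table(paired_data_spec(n = 60, true_intercept = -1,
                                          value_range = c(40, 100), seed = 8))$table
  rep <- compare_methods(tb, threshold = 80)
  expect_s3_class(rep$ols, "regression_fit")
  expect_s3_class(rep$pb, "passing_bablok_fit")
  expect_s3_class(rep$ba, "bland_altman_result")
  expect_s3_class(rep$diag, "diagnostic_metrics")
  expect_equal(rep$report$results$ba_bias, rep$ba$bias)
  only_ba <- compare_methods(tb, analyses = "ba")
  expect_null(only_ba$ols)
  expect_s3_class(only_ba$ba, "bland_altman_result")
})
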