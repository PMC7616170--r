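test_that("AUC matches exhaustive pair enumeration", {
  expect_equal(empirical_roc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(empirical_roc(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc, 0.75)
  set.seed(31)
  for (i in 1:30) {
    n <- sample(4:20, 1)
    v <- sample(1:8, n, replace = TRUE)  # plenty of ties
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    roc <- empirical_roc(v, y)
    expect_equal(roc$auc, auc_brute_force(v, y))
    # every operating point satisfies the J identity exactly
    expect_equal(roc$curve$j,
                 roc$curve$sensitivity + roc$curve$specificity - 1)
    expect_equal(roc$j_statistic, roc$sensitivity + roc$specificity - 1)
  }
})

test_that("ROC is invariant under strictly monotone metric transforms", {
  set.seed(17)
  v <- stats::rlnorm(40, 3, 0.5)
  y <- stats::rbinom(40, 1, stats::plogis(scale(log(v))))
  r1 <- empirical_roc(v, y)
  r2 <- empirical_roc(log(v), y)
  expect_equal(r1$auc, r2$auc)
  expect_equal(r1$sensitivity, r2$sensitivity)
  expect_equal(r1$specificity, r2$specificity)
  expect_equal(r1$j_statistic, r2$j_statistic)
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(23)
  v <- stats::rnorm(60)
  y <- stats::rbinom(60, 1, stats::plogis(v))
  ours <- empirical_roc(v, y)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(y, v, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs)
})

test_that("lower-predicts-positive direction mirrors the analysis", {
  v <- c(1, 2, 3, 4)
  y <- c(1, 1, 0, 0)
  r <- empirical_roc(v, y, direction = "lower_predicts_positive")
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
})

test_that("Youden selection breaks ties toward sensitivity, then lower cutoff", {
  curve <- data.frame(
    cutoff = c(1, 2, 3, 4),
    sensitivity = c(1.0, 0.9, 0.6, 0.2),
    specificity = c(0.1, 0.6, 0.9, 0.9),
    j = c(0.1, 0.5, 0.5, 0.1)
  )
  roc <- structure(list(auc = 0.8, direction = "higher_predicts_positive",
                        curve = curve, cutoff = NA, sensitivity = NA,
                        specificity = NA, j_statistic = NA,
                        n_pos = 10, n_neg = 10, p_value = NA),
                   class = "roc_result")
  best <- youden_optimal(roc)
  expect_equal(best$cutoff, 2)       # J tied at 0.5; sens 0.9 beats 0.6
  curve2 <- curve
  curve2$sensitivity[3] <- 0.9
  curve2$specificity[3] <- 0.6
  roc$curve <- curve2
  expect_equal(youden_optimal(roc)$cutoff, 2)  # full tie -> lower cutoff
})

test_that("a constant metric yields J = 0 at a degenerate cutoff", {
  r <- empirical_roc(rep(2.5, 10), c(rep(0, 5), rep(1, 5)))
  expect_equal(r$auc, 0.5)
  expect_equal(r$j_statistic, 0)
})

test_that("single-class labels and missing values are rejected", {
  expect_error(empirical_roc(1:4, c(1, 1, 1, 1)), "both outcome classes")
  expect_error(empirical_roc(c(1, NA, 3), c(0, 1, 1)), "missing")
  expect_error(empirical_roc(1:3, c(0, 1, 2)), "binary")
})

test_that("Pearson correlation matches the product-moment definition", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1)
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y)$r, hand)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "n >= 3")
})

test_that("paired differences carry exact t-based intervals", {
  same <- paired_difference(c(3, 5, 9), c(3, 5, 9))
  expect_equal(same$mean_diff, 0)
  expect_true(same$ci95[1] <= 0 && same$ci95[2] >= 0)

  pd <- paired_difference(c(2, 4, 6), c(1, 2, 3))  # diffs 1, 2, 3
  expect_equal(pd$mean_diff, 2)
  half <- stats::qt(0.975, 2) * stats::sd(c(1, 2, 3)) / sqrt(3)
  expect_equal(pd$ci95, c(2 - half, 2 + half))
  expect_true(pd$ci95[1] <= pd$mean_diff && pd$mean_diff <= pd$ci95[2])

  wide <- paired_difference(c(2, 4, 6), c(1, 2, 3), m_comparisons = 3)
  expect_gt(wide$ci95[2] - wide$ci95[1], pd$ci95[2] - pd$ci95[1])
  expect_error(paired_difference(1:3, 1:4), "equal length")
})

test_that("the ROC table gates operating points at AUC > 0.7 strictly", {
  co <- generate_cohort(80, effect = cohort_effect(), seed = 14)
  # append a pure-noise metric under each config id
  for (cfg in c("psi45_55", "psi40_60", "psi35_65", "psi30_70")) {
    co[[paste0("noise_metric_", cfg)]] <-
      stats::runif(nrow(co)) + seq_len(nrow(co)) * 1e-9
  }
  t3 <- table3_report(co, metrics = c("surface_healthy_he_cm2",
                                      "noise_metric"))
  expect_identical(nrow(t3), 8L)
  noise_rows <- t3[t3$metric == "noise_metric", ]
  expect_true(all(is.na(noise_rows$cutoff)))
  strong_rows <- t3[t3$metric == "surface_healthy_he_cm2" & t3$auc > 0.7, ]
  expect_true(all(!is.na(strong_rows$j_statistic)))
  expect_equal(strong_rows$j_statistic,
               strong_rows$sensitivity + strong_rows$specificity - 1)

  # AUC exactly at the gate stays blank (strict inequality)
  vals <- c(5, 5, 5, 2, 0, 1, 4)
  labs <- c(1, 1, 1, 1, 1, 0, 0)
  expect_equal(empirical_roc(vals, labs)$auc, 0.7)
  co2 <- data.frame(patient_id = sprintf("Q%d", 1:7),
                    m_psi40_60 = vals, recurrence = labs)
  t32 <- table3_report(co2, metrics = "m",
                       configs = list(threshold_config(40, 60)))
  expect_equal(t32$auc, 0.7)
  expect_true(is.na(t32$cutoff))
})
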