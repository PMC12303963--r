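test_that("the correlation estimator is exact on a hand-computed example", {
  # five points; r computed from the definitional sums
  x <- c(1, 2, 4, 5, 8)
  y <- c(2, 1, 5, 4, 9)
  n <- 5
  r_hand <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  metrics <- data.frame(image_id = paste0("i", 1:5), m = x)
  scores <- matrix(y, 5, 1, dimnames = list(paste0("i", 1:5), "Factor1"))
  ct <- correlate_metrics_factors(metrics, scores)
  expect_equal(ct$r, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
  expect_equal(ct$p, 2 * pt(-abs(t_hand), df = 3), tolerance = 1e-12)
})

test_that("identical columns correlate perfectly and get double stars", {
  v <- c(0.2, 1.4, -0.5, 2.2, 0.9, -1.3)
  metrics <- data.frame(image_id = paste0("i", 1:6), m = v)
  scores <- matrix(v, 6, 1, dimnames = list(paste0("i", 1:6), "Factor1"))
  ct <- correlate_metrics_factors(metrics, scores)
  expect_equal(ct$r, 1)
  expect_lt(ct$p, 1e-10)
  expect_equal(ct$flag, "**")
})

test_that("planted correlations are recovered and nulls stay unflagged", {
  cross <- matrix(0, 18, 6)
  cross[match("brown_D", default_metric_names()), 1] <- 0.45
  jt <- gen_joint_dataset(10000, joint_target_corr(cross), seed = 61)
  ct <- correlate_metrics_factors(jt$metrics, jt$scores)
  planted <- ct[ct$metric == "brown_D" & ct$factor == "Factor1", ]
  expect_equal(planted$r, 0.45, tolerance = 0.03)
  null_cells <- ct[ct$metric == "yellow_H", ]
  expect_lt(max(abs(null_cells$r)), 0.05)
})

test_that("significance flags follow the p thresholds", {
  withr::local_seed(62)
  jt <- gen_joint_dataset(200, seed = 62)
  ct <- correlate_metrics_factors(jt$metrics, jt$scores, adjust = TRUE)
  expect_true(all(ct$flag[ct$p < 0.01] == "**"))
  expect_true(all(ct$flag[ct$p >= 0.01 & ct$p < 0.05] == "*"))
  expect_true(all(ct$flag[ct$p >= 0.05] == ""))
  expect_true(all(ct$p_bh >= ct$p - 1e-12))
})

test_that("constant metric columns yield NA cells with a warning", {
  metrics <- data.frame(image_id = paste0("i", 1:6), flat = rep(2, 6),
                        ok = c(1, 3, 2, 5, 4, 6))
  scores <- matrix(rnorm(6), 6, 1, dimnames = list(paste0("i", 1:6), "Factor1"))
  expect_warning(ct <- correlate_metrics_factors(metrics, scores), "constant")
  expect_true(is.na(ct$r[ct$metric == "flat"]))
  expect_false(is.na(ct$r[ct$metric == "ok"]))
})

test_that("wide formatting mirrors the journal table layout", {
  withr::local_seed(63)
  jt <- gen_joint_dataset(42, seed = 63)
  ct <- correlate_metrics_factors(jt$metrics, jt$scores)
  wide <- format_correlation_table(ct)
  expect_equal(nrow(wide), 18)
  expect_equal(names(wide), c("metric", paste0("Factor", 1:6)))
  expect_match(wide$Factor1[1], "^-?0\\.\\d{3}\\**$")
})
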