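test_that("configuration rejects invalid values", {
  expect_error(background_config(n_background_iter = 0), class = "prism_error_bad_value")
  expect_error(background_config(gc_tolerance = 0), class = "prism_error_bad_value")
  expect_error(background_config(accessibility_tolerance = -1), class = "prism_error_bad_value")
})

test_that("a single admissible candidate is chosen with certainty", {
  peaks <- peak_table(rep("chr1", 3), c(0L, 1000L, 2000L), c(500L, 1500L, 2500L),
                      peak_id = c("feat", "near", "far"),
                      gc = c(0.50, 0.49, 0.60),
                      mean_accessibility = c(0.3, 0.3, 0.3))
  fs <- feature_set(which(peaks$peak_id == "feat"), "f", 3)
  cfg <- background_config(accessibility_tolerance = 0.05, seed = 3)
  for (it in 1:5) {
    bg <- sample_background_set(peaks, fs, cfg, iteration = it)
    expect_identical(peaks$peak_id[bg$peak_indices], "near")
  }
})

test_that("background sets are size-matched, disjoint, tolerance-respecting and seeded", {
  u <- calibration_universe()
  cfg <- background_config(seed = 77)
  fs <- draw_matchable_feature(u, 150, 1, cfg)
  bg1 <- sample_background_set(u$peaks, fs, cfg, iteration = 1)
  bg1_again <- sample_background_set(u$peaks, fs, cfg, iteration = 1)
  bg2 <- sample_background_set(u$peaks, fs, cfg, iteration = 2)

  expect_identical(bg1$peak_indices, bg1_again$peak_indices)   # determinism
  expect_false(identical(bg1$peak_indices, bg2$peak_indices))  # fresh draw per iteration
  expect_length(bg1$peak_indices, length(fs$peak_indices))
  expect_length(intersect(bg1$peak_indices, fs$peak_indices), 0)
  expect_false(anyDuplicated(bg1$peak_indices) > 0)

  # peak-for-peak GC window and set-level accessibility window
  expect_true(all(abs(u$peaks$gc[bg1$peak_indices] - u$peaks$gc[fs$peak_indices])
                  <= cfg$gc_tolerance + 1e-12))
  target <- mean(u$peaks$mean_accessibility[fs$peak_indices])
  expect_true(all(abs(u$peaks$mean_accessibility[bg1$peak_indices] - target)
                  <= cfg$accessibility_tolerance + 1e-12))
})

test_that("impossible matching raises the typed error naming the peak", {
  peaks <- peak_table(rep("chr1", 4), (0:3) * 1000L, (0:3) * 1000L + 500L,
                      peak_id = paste0("p", 1:4),
                      gc = c(0.5, 0.9, 0.9, 0.9),
                      mean_accessibility = rep(0.3, 4))
  fs <- feature_set(1L, "f", 4)
  expect_error(sample_background_set(peaks, fs, background_config(accessibility_tolerance = 1)),
               class = "prism_error_unmatchable_peak")
  expect_error(sample_background_set(peaks, fs, background_config(accessibility_tolerance = 1)),
               "p1")
})

test_that("bias-corrected variation is the raw-to-background-mean ratio", {
  u <- calibration_universe()
  cfg <- background_config(n_background_iter = 8, seed = 5)
  fs <- draw_matchable_feature(u, 120, 2, cfg)
  bcv <- bias_corrected_variation(u$binary, fs, u$peaks, cfg)
  expect_length(bcv$background_raws, 8)
  expect_equal(bcv$bias_corrected, bcv$raw / mean(bcv$background_raws), tolerance = 1e-15)
  expect_equal(bcv$raw, raw_variability(u$binary, fs)$value, tolerance = 1e-12)
})

test_that("an all-identical-cell matrix gives a degenerate background error", {
  X <- Matrix::Matrix(matrix(rep(c(1, 0), each = 10), nrow = 5, ncol = 4, byrow = TRUE) * 0 + 1,
                      sparse = TRUE)  # 5 cells, 4 peaks, all ones
  peaks <- peak_table(rep("chr1", 4), (0:3) * 1000L, (0:3) * 1000L + 500L,
                      gc = 0.5, mean_accessibility = 1)
  colnames(X) <- peaks$peak_id
  fs <- feature_set(1:2, "f", 4)
  expect_error(
    bias_corrected_variation(X, fs, peaks, background_config(accessibility_tolerance = 1)),
    class = "prism_error_degenerate_background"
  )
})

test_that("final variation is internally consistent and bit-reproducible", {
  u <- calibration_universe()
  cfg <- background_config(n_background_iter = 6, n_negative_control = 10, seed = 9)
  fs <- draw_matchable_feature(u, 150, 3, cfg)
  r1 <- final_variation(u$binary, fs, u$peaks, cfg)
  r2 <- final_variation(u$binary, fs, u$peaks, cfg)
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(r1$control_bias_corrected, r2$control_bias_corrected)

  expect_equal(r1$bias_corrected, r1$raw / r1$background_mean, tolerance = 1e-15)
  expect_equal(r1$final, r1$bias_corrected / mean(r1$control_bias_corrected), tolerance = 1e-15)
  expect_equal(r1$z_score,
               (r1$bias_corrected - mean(r1$control_bias_corrected)) / sd(r1$control_bias_corrected),
               tolerance = 1e-12)
  expect_equal(r1$p_value,
               (1 + sum(r1$control_bias_corrected >= r1$bias_corrected)) / (10 + 1),
               tolerance = 1e-15)
  expect_true(r1$p_value >= 0 && r1$p_value <= 1)
})

test_that("a single negative control leaves the Z-score missing but not the p-value", {
  u <- calibration_universe()
  cfg <- background_config(n_background_iter = 4, n_negative_control = 1, seed = 13)
  fs <- draw_matchable_feature(u, 100, 4, cfg)
  r <- final_variation(u$binary, fs, u$peaks, cfg)
  expect_true(is.na(r$z_score))
  expect_true(r$p_value %in% c(1 / 2, 1))
})

test_that("strong injected heterogeneity is detected above all controls", {
  # dense accessibility so the disjoint-support effect is far outside the
  # negative-control spread; h = 1 is the strongest attainable effect
  probs <- withr::with_seed(11, pmin(0.5, pmax(0.05, rnorm(2000, 0.45, 0.008))))
  u <- generate_null_universe(fixture_spec(acc_probs = probs, seed = 11))
  cfg <- background_config(seed = 14)
  fs <- draw_matchable_feature(u, 200, 12, cfg)
  u2 <- inject_block_heterogeneity(u, fs$peak_indices, h = 1, seed = 13)
  r <- final_variation(u2$binary, fs, u2$peaks, cfg)
  expect_gt(r$final, 1)
  expect_equal(r$p_value, 1 / 31, tolerance = 1e-15)  # above all 30 controls
  expect_lte(r$p_value, 0.05)
  expect_gt(r$z_score, 3)
})
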