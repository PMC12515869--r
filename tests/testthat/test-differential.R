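mk6 <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- c("c1", "c2", "c3", "m1", "m2", "m3")
  intensity_table(m, rep(c("control", "case"), each = 3))
}

test_that("fold change is the ratio of group means over present values", {
  tab <- mk6(f1 = c(1, 1, 1, 2, 2, 2),
             f2 = c(2, 2, 2, 2, 2, 2),
             f3 = c(1, 1, 1, 1.6, 1.6, 1.6),
             f4 = c(1, NA, NA, 2, 2, 2))
  fc <- compute_fold_change(tab)
  expect_equal(fc$fc, c(2, 1, 1.6, 2))
  expect_equal(fc$log2fc[1], 1)
  expect_equal(fc$testable, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("the assumption gate selects Student's vs Welch's test", {
  set.seed(31)
  student_hits <- welch_hits <- 0L
  reps <- 200L
  for (i in seq_len(reps)) {
    a <- 2^rnorm(50); b <- 2^rnorm(50)
    if (select_test(a, b)$decision == "student") student_hits <- student_hits + 1L
    a2 <- 2^rnorm(50); b2 <- 2^rnorm(50, sd = 10)  # 100x variance on log2
    if (select_test(a2, b2)$decision == "welch") welch_hits <- welch_hits + 1L
  }
  ## the gate passes when 2 Shapiro + 1 Levene all fail to reject: ~0.95^3
  expect_gte(student_hits / reps, 0.78)
  expect_gte(welch_hits / reps, 0.95)

  expect_equal(select_test(c(2, 2, 2), c(2, 2, 2))$decision, "untestable")
  expect_equal(test_feature(c(2, 2, 2), c(2, 2, 2), "untestable"), 1)
})

test_that("t-tests behave at the null and separation limits", {
  x <- c(1.0, 1.3, 0.8)
  expect_gte(test_feature(x, x, "student"), 0.99)

  eps <- 1e-6
  p_tiny <- test_feature(c(1, 1, 1) * (1 + eps * c(-1, 0, 1)),
                         c(4, 4, 4) * (1 + eps * c(-1, 0, 1)), "student")
  expect_lt(p_tiny, 1e-10)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_length(adjust_bh(numeric(0)), 0)

  set.seed(41)
  for (i in 1:1000) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("significance calls follow the fold-change and p thresholds", {
  expect_equal(call_significant(1.6, 0.01), "up")
  expect_equal(call_significant(1.4, 0.001), "ns")
  expect_equal(call_significant(0.5, 0.03), "down")
  expect_equal(call_significant(2.0, 0.2), "ns")
  expect_equal(call_significant(c(1.6, 0.6), c(0.01, 0.01)), c("up", "down"))
})

test_that("swapping group labels inverts fold changes and calls", {
  set.seed(51)
  m <- matrix(rlnorm(60, sdlog = 0.5), 10,
              dimnames = list(sprintf("f%d", 1:10),
                              c("c1", "c2", "c3", "m1", "m2", "m3")))
  m[1, ] <- m[1, ] * c(1, 1, 1, 4, 4, 4)   # a clear up feature
  fwd <- run_differential(intensity_table(m, rep(c("control", "case"), each = 3)))
  rev <- run_differential(intensity_table(m, rep(c("case", "control"), each = 3)))
  expect_equal(rev$fc, 1 / fwd$fc, tolerance = 1e-12)
  expect_equal(rev$p, fwd$p, tolerance = 1e-9)
  swap <- c(up = "down", down = "up", ns = "ns")
  expect_equal(rev$call, unname(swap[fwd$call]))

  # monotonicity: inflating case values cannot decrease fc
  m2 <- m
  m2[, 4:6] <- m2[, 4:6] * 1.7
  fc2 <- compute_fold_change(intensity_table(m2, rep(c("control", "case"),
                                                     each = 3)))
  expect_true(all(fc2$fc >= fwd$fc - 1e-12))
})

test_that("near-noiseless spiked data is recovered exactly", {
  des <- synthetic_design(noise_sd = 0.01, sample_scale_sd = 0,
                          missing_rate = 0, spike_frac_sites = 0.2,
                          true_site_fc = 2, spike_frac_proteins = 0,
                          frac_modified_proteins = 1, seed = 8)
  sim <- run_synth(des, n_proteins = 60)
  res <- run_differential(sim$quant$sites)
  truth <- sim$tabs$truth[match(res$feature, sim$tabs$truth$feature), ]
  expect_true(all(res$call[truth$true_fc > 1] == "up"))
  expect_true(all(res$call[truth$true_fc < 1] == "down"))
  expect_true(all(res$call[truth$true_fc == 1] == "ns"))
})

test_that("untestable features are reported, not dropped", {
  tab <- mk6(f1 = c(1, NA, NA, 2, 2, 2),
             f2 = c(1, 2, 1, 2, 1, 2))
  res <- run_differential(tab)
  expect_equal(res$test_used[res$feature == "f1"], "untestable")
  expect_equal(res$call[res$feature == "f1"], "ns")
  expect_true(is.na(res$p[res$feature == "f1"]))
  s <- summarize_differential(res)
  expect_equal(unname(s["n_features"]),
               unname(s["n_up"] + s["n_down"] + s["n_ns"]))
})
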