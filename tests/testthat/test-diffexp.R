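test_that("matched-pairs estimator averages per-pair effects and drops incomplete pairs", {
  # constant case
  p <- data.frame(pair_id = 1:6, vehicle = rep(5, 6), agonist = rep(4, 6))
  eff <- matched_pairs_effect(p)
  expect_equal(eff$ddcq_hat, -1)
  expect_equal(eff$log2_fc, 1)
  expect_equal(fold_change(eff$ddcq_hat), 2)
  expect_equal(eff$sd_pairs, 0)
  # dropped pair
  p2 <- data.frame(pair_id = 1:4, vehicle = c(5, 5, 5, NA),
                   agonist = c(4, 4.5, 3.5, 4))
  eff2 <- matched_pairs_effect(p2)
  expect_equal(eff2$ddcq_hat, -1)
  expect_equal(eff2$n_pairs_used, 3L)
  expect_equal(eff2$n_pairs_dropped, 1L)
  # fewer than two complete pairs: not estimable, no error
  p3 <- data.frame(pair_id = 1:3, vehicle = c(5, NA, NA), agonist = c(4, 4, NA))
  expect_true(is.na(matched_pairs_effect(p3)$ddcq_hat))
})

test_that("matched-pairs estimate equals the pair-fixed-effects regression coefficient", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    v <- rnorm(n, 5); a <- rnorm(n, 4.5)
    if (rep %% 3 == 0) v[1] <- NA
    p <- data.frame(pair_id = seq_len(n), vehicle = v, agonist = a)
    eff <- matched_pairs_effect(p)
    expect_equal(eff$ddcq_hat, pair_fe_coef(v, a, seq_len(n)), tolerance = 1e-10)
  }
})

test_that("Skillings-Mack equals Friedman on complete designs", {
  set.seed(21)
  for (rep in 1:15) {
    t <- sample(2:4, 1)
    n <- sample(3:8, 1)
    m <- matrix(rnorm(n * t), n, t)
    fr <- friedman.test(m)
    sm <- skillings_mack(as.vector(m), block = rep(seq_len(n), t),
                         treatment = rep(letters[seq_len(t)], each = n))
    expect_equal(unname(sm$statistic), unname(fr$statistic), tolerance = 1e-10)
    expect_equal(unname(sm$parameter), unname(fr$parameter))
    expect_equal(sm$p.value, fr$p.value, tolerance = 1e-10)
  }
})

test_that("complete two-treatment SM equals the direction-count statistic", {
  set.seed(22)
  for (n in 3:8) {
    v <- rnorm(n); a <- rnorm(n)
    sm <- skillings_mack(c(v, a), block = rep(seq_len(n), 2),
                         treatment = rep(c("v", "a"), each = n))
    expect_equal(unname(sm$statistic), direction_count_stat(v, a),
                 tolerance = 1e-10)
  }
})

test_that("concordant two-treatment designs give the closed-form chi-square values", {
  mk <- function(n) skillings_mack(rep(c(1, 0), n), rep(seq_len(n), each = 2),
                                   rep(c("vehicle", "agonist"), n))
  sm6 <- mk(6)
  expect_equal(unname(sm6$statistic), 6)
  expect_equal(round(sm6$p.value, 4), 0.0143)
  sm5 <- mk(5)
  expect_equal(unname(sm5$statistic), 5)
  expect_equal(round(sm5$p.value, 4), 0.0253)
  # perfectly balanced directions: statistic 0, p 1
  bal <- skillings_mack(c(rep(c(1, 0), 3), rep(c(0, 1), 3)),
                        rep(1:6, each = 2), rep(c("v", "a"), 6))
  expect_equal(unname(bal$statistic), 0)
  expect_equal(bal$p.value, 1)
})

test_that("SM handles incomplete blocks, monotone invariance and edge cases", {
  set.seed(23)
  v <- rnorm(6); a <- v - 1
  val <- c(v, a); blk <- rep(1:6, 2); trt <- rep(c("v", "a"), each = 6)
  val[c(2, 9)] <- NA   # one-sided losses leave those blocks unusable
  sm <- skillings_mack(val, blk, trt)
  expect_equal(sm$n_blocks, 4L)
  # strictly monotone transformation leaves the statistic unchanged
  sm2 <- skillings_mack(exp(val), blk, trt)
  expect_equal(sm$statistic, sm2$statistic)
  expect_true(sm$statistic >= 0)
  # no usable blocks: p missing, no exception
  smna <- skillings_mack(c(1, NA, NA, 2), c(1, 1, 2, 2), rep(c("v", "a"), 2))
  expect_true(is.na(smna$p.value))
  # disconnected three-treatment design errors with the components
  expect_error(
    skillings_mack(c(1, 2, 3, 4), c("b1", "b1", "b2", "b2"),
                   c("t1", "t2", "t3", "t4")),
    "disconnected")
})

test_that("p decreases monotonically in the statistic at fixed df", {
  stats <- c(0.5, 2, 4, 6, 9)
  p <- pchisq(stats, df = 1, lower.tail = FALSE)
  expect_true(all(diff(p) < 0))
})

test_that("Monte-Carlo SM p-value matches the exact sign-flip null", {
  v <- rep(1, 6); a <- rep(0, 6)
  val <- c(rbind(v, a)); blk <- rep(1:6, each = 2)
  trt <- rep(c("vehicle", "agonist"), 6)
  p1 <- skillings_mack_mc(val, blk, trt, n_draws = 4000, seed = 99)$p.value
  # exact two-sided sign-flip null: 2 * (1/2)^6 = 0.03125
  expect_lt(abs(p1 - 0.03125), 0.012)
  # reproducible bit-exactly under a fixed seed
  p2 <- skillings_mack_mc(val, blk, trt, n_draws = 4000, seed = 99)$p.value
  expect_identical(p1, p2)
  # zero statistic: all permutations are >= 0, p = 1
  bal <- skillings_mack_mc(c(rep(c(1, 0), 3), rep(c(0, 1), 3)),
                           rep(1:6, each = 2), rep(c("v", "a"), 6),
                           n_draws = 500, seed = 1)
  expect_equal(bal$p.value, 1)
})

test_that("alternative tests behave on degenerate and concordant data", {
  # constant zero differences: permutation and signed-rank p = 1
  p0 <- data.frame(pair_id = 1:6, vehicle = rep(3, 6), agonist = rep(3, 6))
  pv0 <- alternative_tests(p0, seed = 1)
  expect_equal(unname(pv0["perm_signflip"]), 1)
  expect_equal(unname(pv0["signed_rank"]), 1)
  # six all-negative differences: exact sign-flip p = 2/64
  p1 <- data.frame(pair_id = 1:6, vehicle = 5 + (1:6) / 10,
                   agonist = 4 + (1:6) / 11)
  pv1 <- alternative_tests(p1, seed = 1)
  expect_equal(unname(pv1["perm_signflip"]), 2 / 64)
  # insufficient pairs: paired tests NA, unpaired unaffected
  p2 <- data.frame(pair_id = 1:4, vehicle = c(5, 5.5, NA, NA),
                   agonist = c(NA, NA, 4, 4.4))
  pv2 <- alternative_tests(p2, seed = 1)
  expect_true(is.na(pv2["perm_signflip"]))
  expect_false(is.na(pv2["welch_t"]))
})

test_that("Welch's t holds its nominal level on null normal data", {
  set.seed(77)
  rej <- mean(replicate(2000, {
    t.test(rnorm(6), rnorm(6), var.equal = FALSE)$p.value < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("estimate_effects ties the pieces together per assay", {
  sheet <- make_sheet(n_pairs = 6)
  set.seed(5)
  m <- rbind(up = c(rnorm(6, 5, 0.1), rnorm(6, 4, 0.1)),
             null = rnorm(12, 5, 0.1))
  colnames(m) <- c(sheet$sample_id[sheet$condition == "vehicle_control"],
                   sheet$sample_id[sheet$condition == "agonist"])
  eff <- estimate_effects(m, sheet,
                          methods = c("skillings_mack", "perm_signflip",
                                      "signed_rank", "welch_t",
                                      "mann_whitney", "unpaired_perm"),
                          n_draws = 500, seed = 3)
  expect_equal(eff$log2_fc, -eff$ddcq_hat)
  pcols <- grep("^p_", names(eff), value = TRUE)
  expect_length(pcols, 6L)
  expect_true(all(eff[, pcols] >= 0 & eff[, pcols] <= 1, na.rm = TRUE))
  expect_lt(eff$p_skillings_mack[eff$assay_id == "up"], 0.05)
  expect_gt(eff$p_skillings_mack[eff$assay_id == "null"], 0.05)
})
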