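test_that("noise-free simulation reproduces the planted effect exactly", {
  cfg <- sim_config(n_assays = 20, baseline_cq_mean = 26, baseline_cq_sd = 1,
                    frac_media_only = 0, frac_cell_derived = 0,
                    frac_mc_shared = 0, resid_sd = 0, pair_sd = 0,
                    dropout_slope = 0, qc_fail_rate = 0,
                    effect_assays = c("mir-0003" = -1.0), seed = 2)
  sim <- simulate_experiment(cfg)
  m <- pivot_to_matrix(sim$wells, sim$sheet)
  vc <- sim$sheet$sample_id[sim$sheet$condition == "vehicle_control"]
  ag <- sim$sheet$sample_id[sim$sheet$condition == "agonist"]
  expect_equal(unname(m["mir-0003", ag] - m["mir-0003", vc]), rep(-1, 6))
  expect_equal(unname(m["mir-0001", ag] - m["mir-0001", vc]), rep(0, 6))
})

test_that("media-only fraction is realized exactly by construction", {
  cfg <- sim_config(n_assays = 100, frac_media_only = 0.1, seed = 4)
  sim <- simulate_experiment(cfg)
  m <- pivot_to_matrix(sim$wells, sim$sheet)
  vcag <- sim$sheet$sample_id[sim$sheet$condition != "media_control"]
  never_in_cells <- rownames(m)[rowSums(!is.na(m[, vcag])) == 0]
  expect_equal(sum(sim$truth$media_only), 10L)
  expect_true(all(sim$truth$assay_id[sim$truth$media_only] %in% never_in_cells))
})

test_that("one seed gives bit-identical output", {
  cfg <- sim_config(n_assays = 50, seed = 9)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_experiment(sim_config(n_assays = 50, seed = 10))
  expect_false(identical(s1$wells$cq, s3$wells$cq))
})

test_that("unknown effect assays are a configuration error", {
  expect_error(simulate_experiment(
    sim_config(n_assays = 10, effect_assays = c("nope" = 1))), "nope")
})

test_that("realized pairwise differences average to the planted effect", {
  # Monte-Carlo oracle: across seeded replicates the mean per-pair difference
  # of the effect assay approaches the planted ddCq within 3 standard errors.
  planted <- -0.8
  diffs <- vapply(1:200, function(s) {
    cfg <- sim_config(n_assays = 4, baseline_cq_mean = 26, baseline_cq_sd = 0.5,
                      frac_media_only = 0, frac_cell_derived = 0,
                      frac_mc_shared = 0, resid_sd = 0.3, pair_sd = 0.4,
                      dropout_slope = 0, qc_fail_rate = 0,
                      effect_assays = c("mir-0002" = planted), seed = s)
    sim <- simulate_experiment(cfg)
    m <- pivot_to_matrix(sim$wells, sim$sheet)
    vc <- sim$sheet$sample_id[sim$sheet$condition == "vehicle_control"]
    ag <- sim$sheet$sample_id[sim$sheet$condition == "agonist"]
    mean(m["mir-0002", ag] - m["mir-0002", vc])
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - planted), 3 * se)
})

test_that("QC failures are delivered to the QC filter, not removed upstream", {
  cfg <- sim_config(n_assays = 200, baseline_cq_mean = 26, baseline_cq_sd = 0.5,
                    frac_media_only = 0, frac_cell_derived = 0,
                    frac_mc_shared = 0, dropout_slope = 0,
                    qc_fail_rate = 0.1, seed = 6)
  sim <- simulate_experiment(cfg)
  w <- sim$wells
  failing <- !is.na(w$cq) & (w$amp_score < 1 | w$cq_conf < 0.8)
  expect_gt(sum(failing), 0)
  # the generator keeps their Cq; apply_well_qc removes them
  expect_true(all(!is.na(w$cq[failing])))
  wq <- apply_well_qc(w, qc_thresholds())
  expect_true(all(is.na(wq$cq[failing])))
  rate <- sum(failing) / sum(!is.na(w$cq))
  expect_lt(abs(rate - 0.1), 0.02)
})

test_that("recovery metrics equal a hand-counted confusion matrix", {
  truth <- data.frame(assay_id = sprintf("a%02d", 1:10),
                      planted_ddcq = c(1, -1, 2, 0, 0, 0, 0, 0, 0, 0),
                      media_only = FALSE)
  # selected: two true positives, one false positive
  rec <- evaluate_recovery(c("a01", "a03", "a05"), truth)
  expect_equal(rec$tp, 2L); expect_equal(rec$fp, 1L)
  expect_equal(rec$fn, 1L); expect_equal(rec$tn, 6L)
  expect_equal(rec$sensitivity, 2 / 3)
  expect_equal(rec$specificity, 6 / 7)
  expect_equal(rec$fdp, 1 / 3)
  # perfect selection
  perfect <- evaluate_recovery(c("a01", "a02", "a03"), truth)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$fdp, 0)
  # empty selection with planted effects present
  none <- evaluate_recovery(character(), truth)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$fdp, 0)
  # assay set mismatch is a consistency error
  expect_error(evaluate_recovery("zz", truth), "zz")
})
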