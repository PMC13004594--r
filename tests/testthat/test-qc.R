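test_that("well QC applies strict thresholds and keeps boundary wells", {
  w <- data.frame(sample_id = "S1", assay_id = sprintf("a%d", 1:5), card = "A",
                  cq = c(35.0, 34.0, 28, 28, 28),
                  amp_score = c(1.2, 1.2, 1.0, 0.99, 1.2),
                  cq_conf = c(0.95, 0.95, 0.80, 0.95, 0.79))
  out <- apply_well_qc(w, qc_thresholds())
  expect_equal(is.na(out$cq), c(TRUE, FALSE, FALSE, TRUE, TRUE))
  counts <- attr(out, "qc_counts")
  expect_equal(unname(counts[c("rejected_cq_max", "rejected_amp_score",
                               "rejected_cq_conf")]), c(1L, 1L, 1L))
  # idempotent: a second application changes nothing
  out2 <- apply_well_qc(out, qc_thresholds())
  expect_identical(out2$cq, out$cq)
  # non-Cq fields untouched
  expect_identical(out$amp_score, w$amp_score)
})

test_that("expression-rate rule distinguishes both-groups from either-group", {
  sheet <- make_sheet(n_pairs = 6)
  m <- matrix(25, 3, 12,
              dimnames = list(c("full", "five_of_six", "four_of_six"),
                              sheet$sample_id))
  ag <- sheet$sample_id[sheet$condition == "agonist"]
  m["five_of_six", ag[1]] <- NA                 # 6/6 vehicle, 5/6 agonist
  m["four_of_six", ag[1:2]] <- NA               # 6/6 vehicle, 4/6 agonist
  both <- expression_rate_filter(m, sheet, qc_thresholds())
  expect_setequal(both, c("full", "five_of_six"))
  either <- expression_rate_filter(
    m, sheet, qc_thresholds(expr_rule = "either_group"))
  expect_setequal(either, c("full", "five_of_six", "four_of_six"))
  # fully detected matrix: everything accepted
  m2 <- matrix(25, 2, 12, dimnames = list(c("x", "y"), sheet$sample_id))
  expect_setequal(expression_rate_filter(m2, sheet, qc_thresholds()), c("x", "y"))
  # a group with zero samples is a configuration error
  expect_error(expression_rate_filter(m, sheet[sheet$condition != "agonist", ],
                                      qc_thresholds()), "agonist")
})

test_that("media-control exclusion implements the 10-fold and media-only rules", {
  sheet <- make_sheet(n_pairs = 2, n_media = 2)
  samples <- sheet$sample_id
  mc <- samples[sheet$condition == "media_control"]
  vcag <- samples[sheet$condition != "media_control"]
  m <- matrix(NA_real_, 4, 6,
              dimnames = list(c("kept_delta4", "dropped_delta1",
                                "media_only", "absent_mc"), samples))
  m["kept_delta4", mc] <- 30.0; m["kept_delta4", vcag] <- 26.0
  m["dropped_delta1", mc] <- 27.0; m["dropped_delta1", vcag] <- 26.0
  m["media_only", mc] <- 30.0
  m["absent_mc", vcag] <- 28.0
  kept <- media_control_exclusion(m, sheet, qc_thresholds())
  expect_setequal(kept, c("kept_delta4", "absent_mc"))
  detail <- attr(kept, "detail")
  expect_equal(detail$reason[detail$assay_id == "media_only"], "media_only")
  expect_equal(detail$reason[detail$assay_id == "dropped_delta1"], "mc_delta")
})

test_that("media filter is skipped with a warning when no media controls exist", {
  sheet <- make_sheet(n_pairs = 2)
  m <- matrix(25, 2, 4, dimnames = list(c("a", "b"), sheet$sample_id))
  expect_warning(kept <- media_control_exclusion(m, sheet, qc_thresholds()),
                 "skipped")
  expect_setequal(kept, c("a", "b"))
})

test_that("tightening thresholds never grows the accepted set", {
  sheet <- make_sheet(n_pairs = 5, n_media = 4)
  set.seed(31)
  for (rep in 1:5) {
    m <- matrix(runif(20 * 14, 24, 36), 20, 14,
                dimnames = list(sprintf("a%02d", 1:20), sheet$sample_id))
    m[runif(length(m)) < 0.25] <- NA
    loose <- expression_rate_filter(m, sheet, qc_thresholds(expr_rate = 0.6))
    tight <- expression_rate_filter(m, sheet, qc_thresholds(expr_rate = 0.8))
    expect_true(all(tight %in% loose))
    k33 <- media_control_exclusion(m, sheet, qc_thresholds(mc_delta_min = 3.3))
    k50 <- media_control_exclusion(m, sheet, qc_thresholds(mc_delta_min = 5.0))
    expect_true(all(k50 %in% k33))
  }
})

test_that("on noise-free simulations the media filter removes exactly the media-only set", {
  cfg <- sim_config(n_assays = 60, baseline_cq_mean = 27, baseline_cq_sd = 1,
                    frac_media_only = 0.2, frac_cell_derived = 0.3,
                    frac_mc_shared = 0, resid_sd = 0, pair_sd = 0,
                    dropout_slope = 0, qc_fail_rate = 0, seed = 5)
  sim <- simulate_experiment(cfg)
  m <- pivot_to_matrix(sim$wells, sim$sheet)
  kept <- media_control_exclusion(m, sim$sheet, qc_thresholds())
  excluded <- setdiff(rownames(m), kept)
  expect_setequal(excluded, sim$truth$assay_id[sim$truth$media_only])
})
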