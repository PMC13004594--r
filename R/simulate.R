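#' Configuration for the synthetic TaqMan-array experiment generator
#'
#' The defaults mirror the design the analysis was built for: 754 miRNA
#' assays split over two array cards, 6 matched vehicle/agonist pairs, 6
#' media-control replicates, assay-level baseline Cq drawn near the detection
#' ceiling (most EV miRNAs are low-abundance), a media-control-only assay
#' subset, a serum-background subset shared between media and cells, a
#' cell-derived subset strongly enriched (several cycles lower) in the
#' cell-conditioned media, additive pair- and card-level offsets, censoring at
#' Cq 34, logistic dropout near the ceiling, and random QC failures realized
#' as failing amplification scores / Cq confidences so that the QC filter
#' (not the generator) removes them.
#'
#' @param n_assays Number of assays.
#' @param card_split Fraction of assays on card A.
#' @param n_pairs Number of matched vehicle/agonist pairs (>= 2).
#' @param n_media Number of media-control replicates.
#' @param baseline_cq_mean,baseline_cq_sd Normal distribution of assay-level
#'   baseline Cq in cell-conditioned media (cycles).
#' @param frac_media_only Fraction of assays detected only in media control.
#' @param frac_cell_derived Fraction of assays present in media control but at
#'   least `mc_shift_range[1]` cycles higher there (cell-derived signal that
#'   survives the media filter).
#' @param frac_mc_shared Fraction of serum-background assays present in both
#'   media and cells at similar levels (removed by the 3.3-cycle rule).
#'   Remaining assays are absent from media control.
#' @param effect_assays Planted treatment effects (cycles of delta-delta-Cq).
#'   Either a named numeric vector (`assay id -> effect`; unknown ids are an
#'   error) or an unnamed numeric vector, in which case the effects are
#'   planted on the lowest-baseline detectable non-media-only assays.
#' @param pair_sd SD of the pair-level additive offset (cycles); media
#'   controls get per-sample offsets with the same SD.
#' @param card_offset Additive Cq shift of card B (cycles).
#' @param resid_sd Within-well residual SD (cycles).
#' @param cq_censor Detection ceiling: wells with underlying Cq above this are
#'   missing.
#' @param dropout_slope Slope of the logistic detection-dropout probability
#'   `plogis(dropout_slope * (cq - cq_censor))`; 0 disables the mechanism.
#' @param qc_fail_rate Probability that an otherwise-detected well fails QC
#'   through a low amplification score or Cq confidence.
#' @param pair_dropout_rate Probability, per assay and pair, that one randomly
#'   chosen side of the pair is missing (one-sided missingness at random).
#' @param mc_shift_range Range of the uniform media-control Cq excess for
#'   cell-derived assays (cycles).
#' @param mc_shared_delta_sd SD of the media-vs-cells Cq difference for
#'   serum-background assays.
#' @param receptor Receptor label written to the sample sheet.
#' @param seed Integer RNG seed; identical configurations give bit-identical
#'   output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_assays = 754, card_split = 0.5, n_pairs = 6,
                       n_media = 6, baseline_cq_mean = 33.5, baseline_cq_sd = 3,
                       frac_media_only = 0.10, frac_cell_derived = 0.15,
                       frac_mc_shared = 0.50, effect_assays = NULL,
                       pair_sd = 0.5, card_offset = 0.3, resid_sd = 0.3,
                       cq_censor = 34, dropout_slope = 1, qc_fail_rate = 0.02,
                       pair_dropout_rate = 0, mc_shift_range = c(4, 8),
                       mc_shared_delta_sd = 1, receptor = "ADORA1", seed = 1) {
  cfg <- list(n_assays = as.integer(n_assays), card_split = card_split,
              n_pairs = as.integer(n_pairs), n_media = as.integer(n_media),
              baseline_cq_mean = baseline_cq_mean,
              baseline_cq_sd = baseline_cq_sd,
              frac_media_only = frac_media_only,
              frac_cell_derived = frac_cell_derived,
              frac_mc_shared = frac_mc_shared, effect_assays = effect_assays,
              pair_sd = pair_sd, card_offset = card_offset,
              resid_sd = resid_sd, cq_censor = cq_censor,
              dropout_slope = dropout_slope, qc_fail_rate = qc_fail_rate,
              pair_dropout_rate = pair_dropout_rate,
              mc_shift_range = mc_shift_range,
              mc_shared_delta_sd = mc_shared_delta_sd,
              receptor = receptor, seed = as.integer(seed))
  fr <- c(cfg$frac_media_only, cfg$frac_cell_derived, cfg$frac_mc_shared,
          cfg$card_split, cfg$qc_fail_rate, cfg$pair_dropout_rate)
  stopifnot(all(fr >= 0), all(fr <= 1),
            cfg$frac_media_only + cfg$frac_cell_derived + cfg$frac_mc_shared <= 1,
            cfg$n_pairs >= 2L, cfg$n_media >= 0L, cfg$resid_sd >= 0,
            cfg$pair_sd >= 0, cfg$cq_censor > 0)
  structure(cfg, class = "sim_config")
}

sim_assay_names <- function(n) sprintf("mir-%04d", seq_len(n))

#' Simulate a synthetic EV miRNA array experiment
#'
#' Generates well records, a sample sheet and a per-assay truth manifest from
#' a [sim_config()].  The underlying Cq of a well is
#' `baseline(assay) + condition effect + pair (or media-sample) offset +
#' card offset + residual`; agonist wells of effect assays are additionally
#' shifted by the planted delta-delta-Cq.  Wells above the censoring ceiling,
#' wells lost to logistic dropout, media-control wells of media-absent assays
#' and vehicle/agonist wells of media-only assays are reported with an
#' undetermined (missing) Cq.  QC failures keep their Cq but receive a
#' failing amplification score or Cq confidence, so they are removed by
#' [apply_well_qc()] rather than by the generator.
#'
#' The single RNG stream is consumed in a fixed documented order (baselines,
#' class assignment, media-control shifts, offsets, residuals, dropout, QC
#' failures, pair dropout), so one seed gives bit-identical output.
#'
#' @param config A [sim_config()].
#' @return List with `wells` (canonical well table), `sheet` (sample sheet)
#'   and `truth` (`data.frame`: `assay_id`, `planted_ddcq`, `media_only`,
#'   `cell_derived`, `mc_shared`, `baseline_cq`, `normalizer_ok`).
#' @examples
#' sim <- simulate_experiment(sim_config(n_assays = 40, seed = 7))
#' table(sim$sheet$condition)
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_assays
  assays <- sim_assay_names(n)
  card <- ifelse(seq_len(n) <= round(n * config$card_split), "A", "B")

  ## 1. assay baselines; 2. class assignment by random permutation
  baseline <- rnorm(n, config$baseline_cq_mean, config$baseline_cq_sd)
  perm <- sample.int(n)
  n_mo <- round(n * config$frac_media_only)
  n_cd <- round(n * config$frac_cell_derived)
  n_sh <- round(n * config$frac_mc_shared)
  class <- rep("absent_mc", n)
  class[perm[seq_len(n_mo)]] <- "media_only"
  class[perm[n_mo + seq_len(n_cd)]] <- "cell_derived"
  class[perm[n_mo + n_cd + seq_len(n_sh)]] <- "mc_shared"

  ## 3. media-control level shifts
  mc_shift <- numeric(n)
  mc_shift[class == "cell_derived"] <-
    runif(sum(class == "cell_derived"),
          config$mc_shift_range[1], config$mc_shift_range[2])
  mc_shift[class == "mc_shared"] <-
    rnorm(sum(class == "mc_shared"), 0, config$mc_shared_delta_sd)

  ## planted effects
  effect <- stats::setNames(rep(0, n), assays)
  ea <- config$effect_assays
  if (!is.null(ea) && length(ea)) {
    if (!is.null(names(ea)) && all(nzchar(names(ea)))) {
      unknown <- setdiff(names(ea), assays)
      if (length(unknown))
        stop("effect_assays references unknown assay(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      effect[names(ea)] <- ea
    } else {
      ## unnamed effects go on assays the filters are designed to keep:
      ## cell-derived or media-absent, and well below the detection ceiling
      eligible <- which(class %in% c("cell_derived", "absent_mc") &
                          baseline <= config$cq_censor - 3)
      if (length(eligible) < length(ea))
        stop("not enough detectable assays to plant ", length(ea),
             " effects", call. = FALSE)
      target <- eligible[order(baseline[eligible])][seq_along(ea)]
      effect[target] <- ea
    }
  }

  ## samples
  pair_ids <- sprintf("P%02d", seq_len(config$n_pairs))
  sheet <- rbind(
    if (config$n_media > 0)
      data.frame(sample_id = sprintf("MC%02d", seq_len(config$n_media)),
                 receptor = config$receptor, condition = "media_control",
                 pair_id = NA_character_)
    else NULL,
    data.frame(sample_id = paste0("VC_", pair_ids), receptor = config$receptor,
               condition = "vehicle_control", pair_id = pair_ids),
    data.frame(sample_id = paste0("AG_", pair_ids), receptor = config$receptor,
               condition = "agonist", pair_id = pair_ids))
  sheet$run_batch <- "sim"

  ## 4. pair- and media-sample-level offsets
  pair_off <- rnorm(config$n_pairs, 0, config$pair_sd)
  mc_off <- rnorm(config$n_media, 0, config$pair_sd)

  n_s <- nrow(sheet)
  cond <- sheet$condition
  pair_idx <- match(sheet$pair_id, pair_ids)
  samp_off <- ifelse(cond == "media_control",
                     mc_off[match(sheet$sample_id,
                                  sprintf("MC%02d", seq_len(config$n_media)))],
                     pair_off[pair_idx])

  ## underlying Cq, assays x samples; 5. residuals
  base_m <- matrix(baseline, n, n_s)
  base_m <- base_m + matrix(rep(samp_off, each = n), n, n_s)
  base_m <- base_m + config$card_offset * (card == "B")
  is_mc <- cond == "media_control"
  base_m[, is_mc] <- base_m[, is_mc] + mc_shift
  base_m[, cond == "agonist"] <- base_m[, cond == "agonist"] + effect
  cq <- base_m + matrix(rnorm(n * n_s, 0, config$resid_sd), n, n_s)

  ## structural absence
  cq[class == "media_only", !is_mc] <- NA_real_
  cq[class == "absent_mc", is_mc] <- NA_real_

  ## 6. censoring and logistic dropout
  cq[!is.na(cq) & cq > config$cq_censor] <- NA_real_
  if (config$dropout_slope > 0) {
    p_drop <- plogis(config$dropout_slope * (cq - config$cq_censor))
    drop <- !is.na(cq) & runif(n * n_s) < p_drop
    cq[drop] <- NA_real_
  }

  ## 7. QC failures and quality scores
  detected <- !is.na(cq)
  qc_fail <- detected & runif(n * n_s) < config$qc_fail_rate
  fail_via_amp <- runif(n * n_s) < 0.5
  amp <- matrix(runif(n * n_s, 1.05, 1.8), n, n_s)
  conf <- matrix(runif(n * n_s, 0.85, 1.0), n, n_s)
  amp[qc_fail & fail_via_amp] <- runif(sum(qc_fail & fail_via_amp), 0.2, 0.95)
  conf[qc_fail & !fail_via_amp] <- runif(sum(qc_fail & !fail_via_amp), 0.3, 0.75)
  amp[!detected] <- NA_real_
  conf[!detected] <- NA_real_

  ## 8. one-sided pair dropout
  if (config$pair_dropout_rate > 0) {
    vc_col <- match(paste0("VC_", pair_ids), sheet$sample_id)
    ag_col <- match(paste0("AG_", pair_ids), sheet$sample_id)
    for (p in seq_len(config$n_pairs)) {
      hit <- runif(n) < config$pair_dropout_rate
      side_ag <- runif(n) < 0.5
      cq[hit & side_ag, ag_col[p]] <- NA_real_
      cq[hit & !side_ag, vc_col[p]] <- NA_real_
    }
  }

  wells <- data.frame(
    sample_id = rep(sheet$sample_id, each = n),
    assay_id = rep(assays, n_s),
    card = rep(card, n_s),
    cq = as.vector(cq),
    amp_score = as.vector(amp),
    cq_conf = as.vector(conf),
    stringsAsFactors = FALSE)

  truth <- data.frame(assay_id = assays, planted_ddcq = unname(effect),
                      media_only = class == "media_only",
                      cell_derived = class == "cell_derived",
                      mc_shared = class == "mc_shared",
                      baseline_cq = baseline,
                      normalizer_ok = class == "absent_mc" &
                        baseline <= config$cq_censor - 4,
                      stringsAsFactors = FALSE)
  list(wells = wells, sheet = sheet, truth = truth)
}

#' Score a selection against the simulation ground truth
#'
#' Compares the selected assay set (rows of a [rank_and_select()] result with
#' `selected == TRUE`) against the assays with a non-zero planted
#' delta-delta-Cq.  Assays absent from the selection table (e.g. removed by
#' the filters) count as not selected.
#'
#' @param selection A selection `data.frame` (needs `assay_id`, `selected`)
#'   or a character vector of selected assay ids.
#' @param truth Truth manifest from [simulate_experiment()].
#' @return List with the confusion counts (`tp`, `fp`, `fn`, `tn`) and
#'   `sensitivity`, `specificity`, `fdp` (false discovery proportion; 0 when
#'   nothing is selected).
#' @export
evaluate_recovery <- function(selection, truth) {
  selected <- if (is.character(selection)) selection
  else selection$assay_id[isTRUE_vec(selection$selected)]
  unknown <- setdiff(selected, truth$assay_id)
  if (length(unknown))
    stop("selected assays absent from truth manifest: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  pos <- truth$assay_id[truth$planted_ddcq != 0]
  neg <- setdiff(truth$assay_id, pos)
  tp <- length(intersect(selected, pos))
  fp <- length(intersect(selected, neg))
  fn <- length(setdiff(pos, selected))
  tn <- length(setdiff(neg, selected))
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sensitivity = if (length(pos)) tp / length(pos) else NA_real_,
       specificity = if (length(neg)) tn / length(neg) else NA_real_,
       fdp = if (length(selected)) fp / length(selected) else 0)
}

isTRUE_vec <- function(x) !is.na(x) & x
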