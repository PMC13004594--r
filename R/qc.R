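#' Quality-control and filtering thresholds
#'
#' Bundles every tunable threshold of the well-level QC, the group
#' expression-rate acceptance rule and the media-control exclusion filter.
#' Defaults reproduce the array-analysis settings the pipeline was designed
#' around: wells with Cq above 34, Cq confidence below 0.8 or amplification
#' score below 1 are discarded; an assay must be detected in at least 80% of
#' samples in both treated groups; and an assay detected in the cell-free
#' media control is kept only when the vehicle control is at least 3.3 cycles
#' (10-fold) more abundant.
#'
#' @param cq_max Maximum acceptable Cq (cycles); wells with `cq > cq_max` are
#'   treated as missing (strict inequality).
#' @param cq_conf_min Minimum Cq confidence; wells with `cq_conf < cq_conf_min`
#'   are treated as missing (strict inequality).
#' @param amp_score_min Minimum amplification score, strict inequality.
#' @param expr_rate Required detection fraction per group, in (0, 1].
#' @param expr_rule `"both_groups"` (detection rate must reach `expr_rate` in
#'   vehicle control AND agonist) or `"either_group"` (one group suffices).
#' @param mc_delta_min Minimum mean-Cq excess of the media control over the
#'   vehicle control (cycles) for an assay detected in both to be kept;
#'   3.3 cycles corresponds to a 10-fold difference.
#' @param mc_presence_rate Detection fraction at or above which an assay
#'   counts as present in the media control.
#' @param mc_delta_mode `"directional"` (vehicle must be more abundant, the
#'   default, since the filter removes serum background) or `"absolute"`.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(cq_max = 34, cq_conf_min = 0.8, amp_score_min = 1,
                          expr_rate = 0.8,
                          expr_rule = c("both_groups", "either_group"),
                          mc_delta_min = 3.3, mc_presence_rate = 0.5,
                          mc_delta_mode = c("directional", "absolute")) {
  expr_rule <- match.arg(expr_rule)
  mc_delta_mode <- match.arg(mc_delta_mode)
  stopifnot(cq_max > 0, expr_rate > 0, expr_rate <= 1,
            mc_presence_rate > 0, mc_presence_rate <= 1, mc_delta_min >= 0)
  structure(list(cq_max = cq_max, cq_conf_min = cq_conf_min,
                 amp_score_min = amp_score_min, expr_rate = expr_rate,
                 expr_rule = expr_rule, mc_delta_min = mc_delta_min,
                 mc_presence_rate = mc_presence_rate,
                 mc_delta_mode = mc_delta_mode),
            class = "qc_thresholds")
}

#' Apply well-level quality control
#'
#' Sets `cq` to missing wherever `cq > cq_max`, `cq_conf < cq_conf_min` or
#' `amp_score < amp_score_min` (all strict, so boundary values are retained).
#' All other fields are untouched and already-missing wells pass through, which
#' makes the operation idempotent.  Per-rule rejection counts are attached as
#' attribute `"qc_counts"`.
#'
#' @param records Well-record `data.frame`.
#' @param thresholds A [qc_thresholds()] object.
#' @return `records` with failed wells' `cq` set to `NA`.
#' @examples
#' w <- data.frame(sample_id = "S1", assay_id = c("a", "b", "c"), card = "A",
#'                 cq = c(35, 34, 28), amp_score = c(1.2, 1.0, 0.4),
#'                 cq_conf = c(0.95, 0.8, 0.9))
#' apply_well_qc(w, qc_thresholds())$cq   # 35 fails cq, 0.4 fails amp score
#' @export
apply_well_qc <- function(records, thresholds = qc_thresholds()) {
  obs <- !is.na(records$cq)
  fail_cq   <- obs & records$cq > thresholds$cq_max
  fail_conf <- obs & !is.na(records$cq_conf) &
    records$cq_conf < thresholds$cq_conf_min
  fail_amp  <- obs & !is.na(records$amp_score) &
    records$amp_score < thresholds$amp_score_min
  fail <- fail_cq | fail_conf | fail_amp
  records$cq[fail] <- NA_real_
  attr(records, "qc_counts") <- c(
    wells_in = nrow(records), observed = sum(obs),
    rejected_cq_max = sum(fail_cq), rejected_cq_conf = sum(fail_conf),
    rejected_amp_score = sum(fail_amp), rejected_total = sum(fail))
  records
}

group_samples <- function(sheet, condition) {
  sheet$sample_id[sheet$condition == condition]
}

detection_rate <- function(mat, samples) {
  if (length(samples) == 0L) return(rep(NA_real_, nrow(mat)))
  rowMeans(!is.na(mat[, samples, drop = FALSE]))
}

#' Group expression-rate acceptance filter
#'
#' Accepts an assay when its detection fraction (share of non-missing Cq
#' values after well QC) reaches `expr_rate` in both the vehicle-control and
#' agonist groups (`expr_rule = "both_groups"`, the default) or in at least
#' one of them (`"either_group"`).  Comparison is `>=`, so 5 of 6 detected
#' (0.833) passes the default 0.8.
#'
#' @param mat QC-applied Cq matrix from [pivot_to_matrix()].
#' @param sheet Sample sheet defining the groups.
#' @param thresholds A [qc_thresholds()] object.
#' @return Sorted character vector of accepted assay ids, with per-group
#'   detection rates attached as attribute `"rates"`.
#' @export
expression_rate_filter <- function(mat, sheet, thresholds = qc_thresholds()) {
  vc <- group_samples(sheet, "vehicle_control")
  ag <- group_samples(sheet, "agonist")
  if (length(vc) == 0L || length(ag) == 0L)
    stop("expression-rate filter needs at least one vehicle_control and one ",
         "agonist sample", call. = FALSE)
  r_vc <- detection_rate(mat, vc)
  r_ag <- detection_rate(mat, ag)
  eps <- 1e-12
  ok <- if (thresholds$expr_rule == "both_groups")
    r_vc >= thresholds$expr_rate - eps & r_ag >= thresholds$expr_rate - eps
  else
    r_vc >= thresholds$expr_rate - eps | r_ag >= thresholds$expr_rate - eps
  accepted <- sort(rownames(mat)[ok])
  attr(accepted, "rates") <- data.frame(assay_id = rownames(mat),
                                        rate_vehicle = r_vc, rate_agonist = r_ag,
                                        row.names = NULL)
  accepted
}

#' Media-control exclusion filter
#'
#' Removes assays whose signal is attributable to the cell-free media control
#' (serum background) rather than to cell-derived vesicles:
#' \itemize{
#'   \item assays detected in the media control but in no vehicle-control or
#'     agonist sample ("media-only") are excluded;
#'   \item assays present in the media control (detection fraction at or above
#'     `mc_presence_rate`) and detected in the vehicle control are excluded
#'     unless `mean(MC Cq) - mean(VC Cq) >= mc_delta_min`, i.e. unless the
#'     vehicle control is at least 10-fold more abundant;
#'   \item assays with no media-control detection are retained unconditionally.
#' }
#' Group means use detected wells only.  With no media-control samples the
#' filter is skipped with a warning and every assay is retained.
#'
#' @inheritParams expression_rate_filter
#' @return Sorted character vector of retained assay ids with a per-assay
#'   `data.frame` of reasons attached as attribute `"detail"`.
#' @export
media_control_exclusion <- function(mat, sheet, thresholds = qc_thresholds()) {
  mc <- group_samples(sheet, "media_control")
  vc <- group_samples(sheet, "vehicle_control")
  ag <- group_samples(sheet, "agonist")
  if (length(mc) == 0L) {
    warning("no media_control samples: media-control exclusion skipped",
            call. = FALSE)
    out <- sort(rownames(mat))
    attr(out, "detail") <- data.frame(assay_id = out, reason = "no_media_control")
    return(out)
  }
  mc_rate <- detection_rate(mat, mc)
  mc_det <- mc_rate > 0
  vcag_det <- rowSums(!is.na(mat[, c(vc, ag), drop = FALSE]))
  vc_det <- rowSums(!is.na(mat[, vc, drop = FALSE]))
  mc_mean <- rowMeans(mat[, mc, drop = FALSE], na.rm = TRUE)
  vc_mean <- rowMeans(mat[, vc, drop = FALSE], na.rm = TRUE)
  delta <- mc_mean - vc_mean
  if (thresholds$mc_delta_mode == "absolute") delta <- abs(delta)
  eps <- 1e-12
  media_only <- mc_det & vcag_det == 0L
  present_mc <- mc_rate >= thresholds$mc_presence_rate - eps
  too_close <- present_mc & vc_det > 0L & !media_only &
    delta < thresholds$mc_delta_min - eps
  reason <- rep("retained", nrow(mat))
  reason[!mc_det] <- "absent_in_mc"
  reason[too_close] <- "mc_delta"
  reason[media_only] <- "media_only"
  retained <- sort(rownames(mat)[!(media_only | too_close)])
  attr(retained, "detail") <- data.frame(
    assay_id = rownames(mat), mc_rate = mc_rate, mc_mean = mc_mean,
    vc_mean = vc_mean, mc_vc_delta = mc_mean - vc_mean, reason = reason,
    row.names = NULL)
  retained
}

#' Assemble the assay-level QC report
#'
#' One row per assay with detection counts per group and the first filter (if
#' any) that rejected it: `expression_rate`, `media_only` or `mc_delta`.
#'
#' @inheritParams expression_rate_filter
#' @param accepted Result of [expression_rate_filter()].
#' @param retained Result of [media_control_exclusion()].
#' @return A `data.frame`; write it with [utils::write.csv()] if a file is
#'   needed.
#' @export
qc_report <- function(mat, sheet, accepted, retained) {
  mc <- group_samples(sheet, "media_control")
  vc <- group_samples(sheet, "vehicle_control")
  ag <- group_samples(sheet, "agonist")
  det <- function(s) rowSums(!is.na(mat[, s, drop = FALSE]))
  detail <- attr(retained, "detail")
  reason <- rep("pass", nrow(mat))
  names(reason) <- rownames(mat)
  if (!is.null(detail)) {
    mc_reason <- detail$reason[match(rownames(mat), detail$assay_id)]
    reason[mc_reason %in% c("media_only", "mc_delta")] <-
      mc_reason[mc_reason %in% c("media_only", "mc_delta")]
  }
  reason[!(rownames(mat) %in% accepted)] <- "expression_rate"
  data.frame(assay_id = rownames(mat),
             n_detected_mc = if (length(mc)) det(mc) else 0L,
             n_detected_vehicle = det(vc), n_detected_agonist = det(ag),
             rejection_reason = reason, row.names = NULL)
}
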