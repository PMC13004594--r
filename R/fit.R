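#' Fit the EV miRNA differential-expression model
#'
#' The one-stop estimator: runs well-level QC, the expression-rate and
#' media-control filters, normalizer selection, global-mean delta-Cq
#' normalization, the matched-pairs delta-delta-Cq estimator and the
#' Skillings-Mack test (plus any requested alternatives) and applies the
#' discovery thresholds.  Returns a classed object with `print`, `summary`,
#' `coef` and `plot` (volcano) methods.
#'
#' @param wells Well-record `data.frame` (see [read_well_table()]) or a list
#'   as returned by [simulate_experiment()], in which case `sheet` is taken
#'   from it.
#' @param sheet Sample sheet `data.frame`.
#' @param qc A [qc_thresholds()] object.
#' @param normalizers Optional explicit normalizer assay ids (character), used
#'   instead of the automatic selection.
#' @param methods p-value methods besides `skillings_mack`; see
#'   [estimate_effects()].
#' @param p_cut,fc_cut_log2,p_sig Selection thresholds, see
#'   [rank_and_select()].
#' @param n_draws,seed Monte-Carlo settings for permutation-based methods.
#' @return Object of class `ev_diffexp`: list with `effects`, `selection`,
#'   `normalizers`, `counts` (per-stage bookkeeping), `cq` (QC-applied
#'   matrix), `dcq`, `survivors`, `qc_report`, `sheet`, `thresholds`, `call`.
#' @examples
#' sim <- simulate_experiment(sim_config(n_assays = 60, seed = 3))
#' fit <- ev_diffexp(sim$wells, sim$sheet)
#' head(coef(fit))
#' @export
ev_diffexp <- function(wells, sheet = NULL, qc = qc_thresholds(),
                       normalizers = NULL, methods = "skillings_mack",
                       p_cut = 0.2, fc_cut_log2 = 0.585, p_sig = 0.05,
                       n_draws = 2000L, seed = NULL) {
  cl <- match.call()
  if (is.list(wells) && !is.data.frame(wells) && !is.null(wells$wells)) {
    if (is.null(sheet)) sheet <- wells$sheet
    wells <- wells$wells
  }
  if (is.null(sheet)) stop("a sample sheet is required", call. = FALSE)
  validate_sheet(sheet)

  wq <- apply_well_qc(wells, qc)
  qc_counts <- attr(wq, "qc_counts")
  mat <- pivot_to_matrix(wq, sheet)

  accepted <- expression_rate_filter(mat, sheet, qc)
  retained <- withCallingHandlers(
    media_control_exclusion(mat, sheet, qc),
    warning = function(w) invokeRestart("muffleWarning"))
  mc_skipped <- length(group_samples(sheet, "media_control")) == 0L
  survivors <- intersect(accepted, retained)

  norm <- if (is.null(normalizers)) select_normalizers(mat, sheet, qc)
          else manual_normalizers(mat, normalizers)
  vcag <- sheet$sample_id[sheet$condition != "media_control"]
  dcq <- compute_delta_cq(mat[, vcag, drop = FALSE], norm)

  effects <- estimate_effects(dcq, sheet, assays = survivors,
                              methods = methods, n_draws = n_draws,
                              seed = seed)
  selection <- rank_and_select(effects, p_cut = p_cut,
                               fc_cut_log2 = fc_cut_log2, p_sig = p_sig)
  counts <- list(
    wells = qc_counts,
    assays_total = nrow(mat),
    assays_expression_accepted = length(accepted),
    assays_mc_retained = length(retained),
    mc_filter_skipped = mc_skipped,
    assays_surviving = length(survivors),
    n_normalizers = length(norm$assays),
    pairs_total = sum(sheet$condition == "agonist"),
    assays_selected = sum(selection$selected),
    assays_not_estimable = sum(is.na(effects$ddcq_hat)))
  structure(list(call = cl, effects = effects, selection = selection,
                 normalizers = norm, counts = counts, cq = mat, dcq = dcq,
                 survivors = survivors,
                 qc_report = qc_report(mat, sheet, accepted, retained),
                 sheet = sheet, qc = qc,
                 thresholds = c(p_cut = p_cut, fc_cut_log2 = fc_cut_log2,
                                p_sig = p_sig)),
            class = "ev_diffexp")
}

#' @export
print.ev_diffexp <- function(x, ...) {
  cat("EV miRNA differential expression fit\n")
  cat(sprintf("  receptor(s): %s\n",
              paste(unique(x$sheet$receptor), collapse = ", ")))
  cat(sprintf("  %d assays -> %d after filters (%d expression-rate, %d media-control)\n",
              x$counts$assays_total, x$counts$assays_surviving,
              x$counts$assays_expression_accepted,
              x$counts$assays_mc_retained))
  cat(sprintf("  %d normalizer assays; %d matched pairs\n",
              x$counts$n_normalizers, x$counts$pairs_total))
  cat(sprintf("  %d assays selected at p < %.2g and |log2 FC| >= %.3g\n",
              x$counts$assays_selected, x$thresholds["p_cut"],
              x$thresholds["fc_cut_log2"]))
  invisible(x)
}

#' @export
summary.ev_diffexp <- function(object, n = 10L, ...) {
  structure(list(fit = object, n = n), class = "summary.ev_diffexp")
}

#' @export
print.summary.ev_diffexp <- function(x, ...) {
  print(x$fit)
  sel <- x$fit$selection
  cat("\nTop assays by |log2 FC|:\n")
  cols <- c("assay_id", "log2_fc", "p_primary", "selected")
  print(utils::head(sel[, cols], x$n), row.names = FALSE, digits = 3)
  if (any(sel$selected)) {
    cat("\nSelected signature:",
        paste(sel$assay_id[sel$selected], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract log2 fold changes from a fit
#'
#' @param object An `ev_diffexp` fit.
#' @param ... Ignored.
#' @return Named numeric vector of log2 fold changes (`-ddCq`), in effect-rank
#'   order.
#' @export
coef.ev_diffexp <- function(object, ...) {
  stats::setNames(object$selection$log2_fc, object$selection$assay_id)
}

#' Volcano plot of a fit
#'
#' Plots `-log10(p)` against the log2 fold change with the discovery
#' thresholds as dotted guides; selected assays are drawn filled and labelled.
#'
#' @param x An `ev_diffexp` fit.
#' @param label Label the selected assays?
#' @param ... Passed to [plot()].
#' @return Invisibly, the [volcano_table()] used.
#' @export
plot.ev_diffexp <- function(x, label = TRUE, ...) {
  v <- volcano_table(x$effects, p_cut = x$thresholds["p_cut"],
                     fc_cut_log2 = x$thresholds["fc_cut_log2"])
  plot(v$log2_fc, v$neg_log10_p, pch = ifelse(v$selected, 19, 1),
       xlab = expression(log[2] ~ "fold change"),
       ylab = expression(-log[10] ~ italic(p)), ...)
  abline(v = c(-1, 1) * x$thresholds["fc_cut_log2"], lty = 3)
  abline(h = -log10(x$thresholds["p_cut"]), lty = 3)
  if (label && any(v$selected))
    text(v$log2_fc[v$selected], v$neg_log10_p[v$selected],
         v$assay_id[v$selected], pos = 3, cex = 0.7)
  invisible(v)
}
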