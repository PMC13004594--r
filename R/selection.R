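#' Rank assays by effect magnitude and apply the discovery thresholds
#'
#' Assays are sorted by absolute log2 fold change, descending (ties broken by
#' ascending p-value, then assay id), and flagged against three thresholds:
#' the liberal discovery screen `p < p_cut` (default 0.2, strict, chosen for
#' discovery power rather than false-positive control), the effect-size rule
#' `|log2_fc| >= fc_cut_log2` (default 0.585, i.e. 1.5-fold), and nominal
#' significance `p < p_sig`.  The combined signature rule is
#' `selected = selected_p02 & selected_fc15`.  Assays with a missing primary
#' p-value receive rank positions but no selection flags and are listed in the
#' `"unselectable"` attribute.
#'
#' @param effects Effect table from [estimate_effects()] (needs `assay_id`,
#'   `log2_fc` and `p_skillings_mack`, or a `p_primary` column).
#' @param p_cut Discovery p-value cutoff (strict `<`).
#' @param fc_cut_log2 Absolute log2-fold-change cutoff (`>=`).
#' @param p_sig Nominal significance cutoff (strict `<`).
#' @return `data.frame` sorted by rank with columns `assay_id`, `log2_fc`,
#'   `p_primary`, `rank_by_effect`, `selected_p02`, `selected_fc15`,
#'   `significant_p05`, `selected`.
#' @export
rank_and_select <- function(effects, p_cut = 0.2, fc_cut_log2 = 0.585,
                            p_sig = 0.05) {
  if (nrow(effects) == 0L)
    return(data.frame(assay_id = character(), log2_fc = numeric(),
                      p_primary = numeric(), rank_by_effect = integer(),
                      selected_p02 = logical(), selected_fc15 = logical(),
                      significant_p05 = logical(), selected = logical()))
  p <- if ("p_primary" %in% names(effects)) effects$p_primary
       else effects$p_skillings_mack
  out <- data.frame(assay_id = effects$assay_id, log2_fc = effects$log2_fc,
                    p_primary = p)
  ord <- order(-abs(out$log2_fc), out$p_primary, out$assay_id, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  out$rank_by_effect <- seq_len(nrow(out))
  eps <- 1e-12
  has_p <- !is.na(out$p_primary)
  out$selected_p02 <- has_p & out$p_primary < p_cut
  out$selected_fc15 <- !is.na(out$log2_fc) &
    abs(out$log2_fc) >= fc_cut_log2 - eps
  out$significant_p05 <- has_p & out$p_primary < p_sig
  out$selected <- out$selected_p02 & out$selected_fc15
  out$selected_fc15[!has_p] <- FALSE
  out$selected[!has_p] <- FALSE
  rownames(out) <- NULL
  attr(out, "thresholds") <- c(p_cut = p_cut, fc_cut_log2 = fc_cut_log2,
                               p_sig = p_sig)
  attr(out, "unselectable") <- out$assay_id[!has_p]
  out
}

#' Row-wise z-transformation of a fold-change matrix
#'
#' Standardizes each row (assay) to mean 0 and SD 1 (sample SD, matching the
#' `(1, 2, 3) -> (-1, 0, 1)` convention); zero-variance rows map to all
#' zeros.  This is the transformation behind clustered fold-change heatmaps.
#'
#' @param m Numeric matrix with at least two columns.
#' @return Matrix of z-scores, same dimensions and dimnames.
#' @export
zscore_matrix <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L)
    stop("z-transformation needs at least two columns", call. = FALSE)
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

#' Deterministic hierarchical ordering for heatmaps
#'
#' Agglomerative clustering on Euclidean distances (average linkage by
#' default; the metric is the contract, the linkage a configurable choice).
#' Returns row and column leaf orders plus merge heights; duplicate rows merge
#' at height zero.  Leaf order is the deterministic [stats::hclust()] order,
#' which breaks ties by input position.
#'
#' @param z Numeric matrix (typically from [zscore_matrix()]) with at least
#'   two rows; all entries must be finite.
#' @param linkage Linkage method passed to [stats::hclust()].
#' @return List with `row_order`, `col_order` (integer permutations),
#'   `row_heights`, `col_heights` and the two `hclust` objects.
#' @export
hierarchical_order <- function(z, linkage = "average") {
  z <- as.matrix(z)
  if (nrow(z) < 2L) stop("need at least two rows to cluster", call. = FALSE)
  if (any(!is.finite(z))) {
    bad <- which(!is.finite(z), arr.ind = TRUE)
    stop("non-finite entries at (row, col): ",
         paste(apply(utils::head(bad, 5L), 1L, paste, collapse = ","),
               collapse = "; "), call. = FALSE)
  }
  hr <- hclust(dist(z, method = "euclidean"), method = linkage)
  hc <- if (ncol(z) >= 2L)
    hclust(dist(t(z), method = "euclidean"), method = linkage) else NULL
  list(row_order = hr$order,
       col_order = if (is.null(hc)) seq_len(ncol(z)) else hc$order,
       row_heights = hr$height,
       col_heights = if (is.null(hc)) numeric() else hc$height,
       row_hclust = hr, col_hclust = hc)
}

#' Volcano-plot table
#'
#' Emits per-assay `log2_fc` and `-log10(p)` with the selection flags, ready
#' for plotting; the threshold guide values are attached as attribute
#' `"thresholds"`.  Zero p-values are clamped to the smallest representable
#' positive double before taking logs, with a warning.
#'
#' @param effects Effect table (needs `assay_id`, `log2_fc` and a p column as
#'   in [rank_and_select()]).
#' @param p_cut,fc_cut_log2 Guide thresholds.
#' @return `data.frame` with `assay_id`, `log2_fc`, `neg_log10_p`,
#'   `selected_p02`, `selected_fc15`, `selected`.
#' @export
volcano_table <- function(effects, p_cut = 0.2, fc_cut_log2 = 0.585) {
  sel <- rank_and_select(effects, p_cut = p_cut, fc_cut_log2 = fc_cut_log2)
  if (nrow(sel) == 0L)
    return(structure(data.frame(assay_id = character(), log2_fc = numeric(),
                                neg_log10_p = numeric(),
                                selected_p02 = logical(),
                                selected_fc15 = logical(),
                                selected = logical()),
                     thresholds = c(p_cut = p_cut, fc_cut_log2 = fc_cut_log2)))
  p <- sel$p_primary
  if (any(!is.na(p) & p == 0)) {
    warning("p-value of 0 clamped before log transform", call. = FALSE)
    p[!is.na(p) & p == 0] <- .Machine$double.xmin
  }
  structure(data.frame(assay_id = sel$assay_id, log2_fc = sel$log2_fc,
                       neg_log10_p = -log10(p),
                       selected_p02 = sel$selected_p02,
                       selected_fc15 = sel$selected_fc15,
                       selected = sel$selected),
            thresholds = c(p_cut = p_cut, fc_cut_log2 = fc_cut_log2))
}
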