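#' Select endogenous-background normalizer miRNAs
#'
#' An assay qualifies as a normalizer when all of:
#' \enumerate{
#'   \item it is undetected, or detected in fewer than 50% (strictly) of the
#'     media-control samples (`mc_presence_rate`);
#'   \item it is detected in 100% of all vehicle-control and agonist samples;
#'   \item if its media-control detection rate is strictly between 0 and 50%,
#'     its mean media-control Cq differs from the mean vehicle-control Cq by
#'     more than `mc_delta_min` cycles (absolute difference).
#' }
#' The per-sample normalizer mean pools qualifying assays across both array
#' cards, giving a global-mean endogenous background per sample.  Media-control
#' samples typically detect few or no normalizer assays; their per-sample mean
#' is computed over whatever is observed and is `NaN` when nothing is.
#'
#' @param mat QC-applied Cq matrix including media-control columns.
#' @param sheet Sample sheet.
#' @param thresholds A [qc_thresholds()] object (`mc_presence_rate` and
#'   `mc_delta_min` are reused as the 50% and 3.3-cycle criteria).
#' @return An object of class `normalizer_set`: list with `assays`,
#'   `per_sample_mean` (named numeric over all samples) and `criteria_trace`
#'   (per-candidate `data.frame` with the first failing criterion or
#'   `"qualified"`).
#' @export
select_normalizers <- function(mat, sheet, thresholds = qc_thresholds()) {
  mc <- group_samples(sheet, "media_control")
  vc <- group_samples(sheet, "vehicle_control")
  ag <- group_samples(sheet, "agonist")
  if (length(vc) == 0L || length(ag) == 0L)
    stop("normalizer selection needs vehicle_control and agonist samples",
         call. = FALSE)
  mc_rate <- if (length(mc)) detection_rate(mat, mc) else rep(0, nrow(mat))
  vcag <- mat[, c(vc, ag), drop = FALSE]
  full_vcag <- rowSums(is.na(vcag)) == 0L
  mc_mean <- if (length(mc)) rowMeans(mat[, mc, drop = FALSE], na.rm = TRUE)
             else rep(NaN, nrow(mat))
  vc_mean <- rowMeans(mat[, vc, drop = FALSE], na.rm = TRUE)
  eps <- 1e-12
  crit1 <- mc_rate < thresholds$mc_presence_rate - eps
  crit3_applies <- mc_rate > 0 & crit1
  crit3 <- !crit3_applies |
    abs(mc_mean - vc_mean) > thresholds$mc_delta_min + eps
  status <- rep("qualified", nrow(mat))
  status[!crit3] <- "fails_mc_delta"
  status[!full_vcag] <- "fails_full_observation"
  status[!crit1] <- "fails_mc_rate"
  qualified <- crit1 & full_vcag & crit3
  if (!any(qualified))
    stop("no assay qualifies as a normalizer; supply an explicit normalizer ",
         "list via the 'normalizers' argument of compute_delta_cq()/",
         "ev_diffexp()", call. = FALSE)
  assays <- sort(rownames(mat)[qualified])
  per_sample_mean <- colMeans(mat[assays, , drop = FALSE], na.rm = TRUE)
  structure(list(assays = assays, per_sample_mean = per_sample_mean,
                 criteria_trace = data.frame(
                   assay_id = rownames(mat), mc_detection_rate = mc_rate,
                   fully_observed_vcag = full_vcag,
                   mc_vc_delta = mc_mean - vc_mean, status = status,
                   row.names = NULL)),
            class = "normalizer_set")
}

#' @export
print.normalizer_set <- function(x, ...) {
  cat("Endogenous normalizer set:", length(x$assays), "assays\n")
  cat("  per-sample mean Cq range:",
      paste(round(range(x$per_sample_mean, na.rm = TRUE), 2), collapse = " - "),
      "\n")
  invisible(x)
}

#' Build a normalizer set from an explicit assay list
#'
#' Escape hatch for datasets where no assay satisfies the automatic criteria.
#'
#' @param mat QC-applied Cq matrix.
#' @param assays Character vector of assay ids to use as normalizers.
#' @return A `normalizer_set`.
#' @export
manual_normalizers <- function(mat, assays) {
  missing <- setdiff(assays, rownames(mat))
  if (length(missing))
    stop("normalizer assays not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(list(assays = sort(assays),
                 per_sample_mean = colMeans(mat[assays, , drop = FALSE],
                                            na.rm = TRUE),
                 criteria_trace = data.frame(assay_id = sort(assays),
                                             status = "manual")),
            class = "normalizer_set")
}

#' Compute the delta-Cq matrix
#'
#' `dCq(assay, sample) = Cq(assay, sample) - normalizer mean of that sample`.
#' Missingness propagates: a cell is `NA` exactly where the source Cq is.
#'
#' @param mat Cq matrix restricted to the samples being normalized (usually
#'   vehicle-control and agonist columns).
#' @param normalizers A `normalizer_set` whose `per_sample_mean` covers every
#'   column of `mat`.
#' @return Matrix of dCq values (cycles) with attribute `"normalizers"`.
#' @examples
#' m <- matrix(c(28, 25, 26, 24), 2, 2,
#'             dimnames = list(c("a", "norm"), c("S1", "S2")))
#' ns <- manual_normalizers(m, "norm")
#' compute_delta_cq(m, ns)["a", ]   # 3 and 2 cycles above background
#' @export
compute_delta_cq <- function(mat, normalizers) {
  stopifnot(inherits(normalizers, "normalizer_set"))
  mu <- normalizers$per_sample_mean[colnames(mat)]
  bad <- colnames(mat)[is.na(mu) | is.nan(mu)]
  if (length(bad))
    stop("no normalizer mean available for sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  d <- sweep(mat, 2L, mu, "-")
  attr(d, "normalizers") <- normalizers$assays
  d
}

#' Fold change from a delta-delta-Cq value
#'
#' Relative quantification: `2^(-ddCq)`; the log2 fold change is `-ddCq`, so a
#' negative ddCq (fewer cycles after treatment, i.e. more template) means
#' up-regulation.
#'
#' @param ddcq Numeric vector of delta-delta-Cq values (cycles).
#' @return `2^(-ddcq)`.
#' @examples
#' fold_change(c(-0.585, 0, -log2(10)))  # 1.5, 1, 10
#' @export
fold_change <- function(ddcq) 2^(-ddcq)
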