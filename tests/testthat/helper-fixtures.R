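# Shared builders and independent oracles for the test suite.

toy_wells_path <- function() {
  system.file("extdata", "toy_wells.csv", package = "evmircq")
}
toy_sheet_path <- function() {
  system.file("extdata", "toy_sample_sheet.csv", package = "evmircq")
}

# Minimal well table builder: one row per (sample, assay) with clean QC scores.
make_wells <- function(cq, samples, assays, card = "A") {
  stopifnot(length(cq) == length(samples) * length(assays))
  data.frame(sample_id = rep(samples, each = length(assays)),
             assay_id = rep(assays, length(samples)),
             card = card, cq = cq, amp_score = 1.3, cq_conf = 0.95,
             stringsAsFactors = FALSE)
}

# Sample sheet for n pairs plus m media controls.
make_sheet <- function(n_pairs = 2, n_media = 0, receptor = "ADORA1") {
  p <- sprintf("P%d", seq_len(n_pairs))
  rbind(
    if (n_media > 0)
      data.frame(sample_id = sprintf("MC%d", seq_len(n_media)),
                 receptor = receptor, condition = "media_control",
                 pair_id = NA_character_)
    else NULL,
    data.frame(sample_id = paste0("VC_", p), receptor = receptor,
               condition = "vehicle_control", pair_id = p),
    data.frame(sample_id = paste0("AG_", p), receptor = receptor,
               condition = "agonist", pair_id = p))
}

# Independent oracle: treatment coefficient of a pair-fixed-effects least
# squares fit on complete pairs.
pair_fe_coef <- function(vehicle, agonist, pair) {
  keep <- !is.na(vehicle) & !is.na(agonist)
  df <- data.frame(y = c(vehicle[keep], agonist[keep]),
                   tr = rep(c(0, 1), each = sum(keep)),
                   pair = factor(rep(pair[keep], 2)))
  unname(coef(lm(y ~ tr + pair, data = df))["tr"])
}

# Independent oracle: naive O(n^3) average-linkage agglomeration returning
# sorted merge heights.
naive_average_linkage_heights <- function(x) {
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in seq((i + 1L), length(clusters))) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# Exact direction-count statistic for complete two-treatment block data:
# (S_plus - S_minus)^2 / n.
direction_count_stat <- function(vehicle, agonist) {
  s <- sign(agonist - vehicle)
  sum(s)^2 / length(s)
}
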