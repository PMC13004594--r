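#' Pair up delta-Cq observations for one receptor experiment
#'
#' For each assay, collects `(pair_id, dCq_vehicle, dCq_agonist)` triples from
#' a delta-Cq (or Cq) matrix and the sample sheet.  Either side of a pair may
#' be missing; downstream estimators decide how to handle incompleteness.
#'
#' @param mat Numeric matrix (assays x samples), typically from
#'   [compute_delta_cq()].
#' @param sheet Sample sheet.
#' @param assays Assays to extract (default: all rows of `mat`).
#' @return Named list (one element per assay) of `data.frame`s with columns
#'   `pair_id`, `vehicle`, `agonist`.
#' @export
paired_observations <- function(mat, sheet, assays = rownames(mat)) {
  vc <- sheet[sheet$condition == "vehicle_control", c("sample_id", "pair_id")]
  ag <- sheet[sheet$condition == "agonist", c("sample_id", "pair_id")]
  pairs <- merge(vc, ag, by = "pair_id", suffixes = c("_vc", "_ag"))
  pairs <- pairs[order(pairs$pair_id), ]
  lapply(stats::setNames(assays, assays), function(a) {
    data.frame(pair_id = pairs$pair_id,
               vehicle = mat[a, pairs$sample_id_vc],
               agonist = mat[a, pairs$sample_id_ag],
               row.names = NULL)
  })
}

#' Matched-pairs delta-delta-Cq estimator
#'
#' Per-pair effect `ddCq_i = dCq_agonist,i - dCq_vehicle,i`; the estimate is
#' the mean over complete pairs, which equals the treatment coefficient of a
#' within-pairs regression with pair fixed effects on the complete pairs.
#' Pairs with a missing side are dropped and counted.  With fewer than two
#' complete pairs the effect is reported as not estimable (`NA`) rather than
#' raising an error.
#'
#' Both dispersion readings of the estimate are returned: `sd_pairs`, the SD
#' of the per-pair effects, and `se = sd_pairs / sqrt(n)`, the standard error
#' of the mean effect.
#'
#' @param paired A `data.frame` with columns `pair_id`, `vehicle`, `agonist`
#'   (one element of [paired_observations()]).
#' @return List with `ddcq_hat`, `log2_fc` (`= -ddcq_hat`), `sd_pairs`, `se`,
#'   `n_pairs_used`, `n_pairs_dropped`, `per_pair_ddcq`.
#' @examples
#' p <- data.frame(pair_id = 1:4, vehicle = c(5, 5.2, 4.8, NA),
#'                 agonist = c(4, 4.7, 3.3, 4.1))
#' matched_pairs_effect(p)$ddcq_hat   # mean of -1.0, -0.5, -1.5 = -1.0
#' @export
matched_pairs_effect <- function(paired) {
  d <- paired$agonist - paired$vehicle
  names(d) <- paired$pair_id
  complete <- !is.na(d)
  n <- sum(complete)
  if (n < 2L)
    return(list(ddcq_hat = NA_real_, log2_fc = NA_real_, sd_pairs = NA_real_,
                se = NA_real_, n_pairs_used = n,
                n_pairs_dropped = sum(!complete), per_pair_ddcq = d[complete]))
  dd <- d[complete]
  est <- mean(dd)
  s <- sd(dd)
  list(ddcq_hat = est, log2_fc = -est, sd_pairs = s, se = s / sqrt(n),
       n_pairs_used = n, n_pairs_dropped = sum(!complete), per_pair_ddcq = dd)
}

## Shared core: ranks within usable blocks -> adjusted treatment scores A and
## the null covariance Sigma (diag: sum of co-occurrence counts; off-diagonal:
## minus pairwise co-occurrence counts).
sm_scores <- function(value, block, treatment, t_levels) {
  t <- length(t_levels)
  keep <- !is.na(value)
  value <- value[keep]; block <- block[keep]; treatment <- treatment[keep]
  A <- numeric(t); names(A) <- t_levels
  lambda <- matrix(0, t, t, dimnames = list(t_levels, t_levels))
  usable <- 0L
  for (b in unique(block)) {
    idx <- block == b
    k <- sum(idx)
    if (k < 2L) next
    usable <- usable + 1L
    r <- rank(value[idx], ties.method = "average")
    tr <- match(treatment[idx], t_levels)
    A[tr] <- A[tr] + sqrt(12 / (k + 1)) * (r - (k + 1) / 2)
    lambda[tr, tr] <- lambda[tr, tr] + 1
  }
  diag(lambda) <- 0
  Sigma <- -lambda
  diag(Sigma) <- rowSums(lambda)
  list(A = A, Sigma = Sigma, lambda = lambda, n_blocks = usable)
}

## Moore-Penrose inverse of a symmetric matrix via eigendecomposition;
## rank determined with a tolerance relative to the largest eigenvalue.
sym_ginv <- function(S, tol = 1e-8) {
  e <- eigen(S, symmetric = TRUE)
  pos <- e$values > tol * max(e$values, 0)
  rank <- sum(pos)
  inv <- if (rank == 0L) S * 0 else
    e$vectors[, pos, drop = FALSE] %*%
      (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
  list(inv = inv, rank = rank)
}

sm_connected <- function(lambda) {
  t <- nrow(lambda)
  seen <- rep(FALSE, t)
  queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(lambda[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  seen
}

#' Skillings-Mack rank test for incomplete block designs
#'
#' Generalizes the Friedman test to block designs where some treatments are
#' unobserved in some blocks (here: matched pairs with detection-limit
#' missingness).  Within each usable block (at least two observed treatments)
#' observations are ranked with midranks for ties; the adjusted treatment
#' score is
#' `A_j = sum_i sqrt(12/(k_i+1)) * (r_ij - (k_i+1)/2)`
#' over blocks `i` where treatment `j` is observed, with `k_i` observed
#' treatments in block `i`.  The statistic is `A' Sigma^- A` with `Sigma` the
#' null covariance of `A` and `Sigma^-` a generalized inverse (the covariance
#' is singular by construction since scores sum to zero); the degrees of
#' freedom are `rank(Sigma)`, which is `t - 1` for a connected design.  On
#' complete two-or-more-treatment data the statistic reduces to the Friedman
#' chi-square.  The p-value is the upper chi-square tail; for small designs
#' see [skillings_mack_mc()].
#'
#' @param value Numeric observations (`NA` = unobserved).
#' @param block Block (pair) labels, same length as `value`.
#' @param treatment Treatment labels, same length as `value`.
#' @param t_levels Optional explicit treatment level order.
#' @return An object of class `htest` with `statistic`, `parameter` (df) and
#'   `p.value` (`NA` with zero usable blocks).
#' @examples
#' # six concordant pairs: agonist below vehicle in every block
#' v <- c(rbind(1:6 * 0 + 1, 1:6 * 0))  # vehicle 1, agonist 0
#' skillings_mack(v, block = rep(1:6, each = 2),
#'                treatment = rep(c("vehicle", "agonist"), 6))
#' @export
skillings_mack <- function(value, block, treatment, t_levels = NULL) {
  if (is.null(t_levels)) t_levels <- sort(unique(as.character(treatment)))
  if (length(t_levels) < 2L) stop("need at least two treatments", call. = FALSE)
  sc <- sm_scores(value, as.character(block), as.character(treatment), t_levels)
  dn <- list(method = "Skillings-Mack test",
             data.name = paste(length(value), "observations in",
                               sc$n_blocks, "usable blocks"))
  if (sc$n_blocks == 0L)
    return(structure(c(dn, list(statistic = c("SM chi-squared" = NA_real_),
                                parameter = c(df = NA_real_),
                                p.value = NA_real_, n_blocks = 0L)),
                     class = "htest"))
  observed <- rowSums(sc$lambda) > 0
  if (sum(observed) >= 2L) {
    comp <- sm_connected(sc$lambda[observed, observed, drop = FALSE])
    if (!all(comp))
      stop("design is disconnected: treatment groups {",
           paste(names(sc$A)[observed][comp], collapse = ","), "} and {",
           paste(names(sc$A)[observed][!comp], collapse = ","),
           "} share no block", call. = FALSE)
  }
  gi <- sym_ginv(sc$Sigma)
  stat <- max(0, drop(t(sc$A) %*% gi$inv %*% sc$A))
  df <- gi$rank
  structure(c(dn, list(statistic = c("SM chi-squared" = stat),
                       parameter = c(df = df),
                       p.value = pchisq(stat, df, lower.tail = FALSE),
                       n_blocks = sc$n_blocks)),
            class = "htest")
}

#' Monte-Carlo p-value for the Skillings-Mack statistic
#'
#' Small-sample refinement of the chi-square approximation: observed values
#' are permuted among the observed treatments independently within each block
#' (for two treatments this is the sign-flip null), the statistic is
#' recomputed, and the p-value uses the add-one correction
#' `p = (1 + #(perm >= obs)) / (1 + n_draws)`.
#'
#' @inheritParams skillings_mack
#' @param n_draws Number of permutation draws (at least 1000 recommended).
#' @param seed Integer seed for reproducibility.
#' @return An `htest` with the observed statistic and the Monte-Carlo
#'   `p.value`.
#' @export
skillings_mack_mc <- function(value, block, treatment, t_levels = NULL,
                              n_draws = 2000L, seed = NULL) {
  if (is.null(t_levels)) t_levels <- sort(unique(as.character(treatment)))
  obs <- skillings_mack(value, block, treatment, t_levels)
  if (is.na(obs$p.value)) return(obs)
  if (!is.null(seed)) set.seed(seed)
  block <- as.character(block); treatment <- as.character(treatment)
  keep <- !is.na(value)
  v <- value[keep]; b <- block[keep]; tr <- treatment[keep]
  blocks <- split(seq_along(v), b)
  stat_obs <- unname(obs$statistic)
  count <- 0L
  for (i in seq_len(n_draws)) {
    vp <- v
    for (idx in blocks)
      if (length(idx) > 1L) vp[idx] <- vp[sample(idx)]
    sp <- sm_scores(vp, b, tr, t_levels)
    gi <- sym_ginv(sp$Sigma)
    if (drop(t(sp$A) %*% gi$inv %*% sp$A) >= stat_obs - 1e-12)
      count <- count + 1L
  }
  obs$p.value <- (1 + count) / (1 + n_draws)
  obs$method <- "Skillings-Mack test (Monte-Carlo p)"
  obs
}

## Exact (n <= max_exact) or Monte-Carlo sign-flip permutation test on paired
## differences; two-sided on |mean|.
signflip_p <- function(d, n_draws = 2000L, max_exact = 12L) {
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2L) return(NA_real_)
  if (all(d == 0)) return(1)
  obs <- abs(mean(d))
  if (n <= max_exact) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    perm <- abs(signs %*% d) / n
    mean(perm >= obs - 1e-12)
  } else {
    signs <- matrix(sample(c(-1, 1), n_draws * n, replace = TRUE), n_draws, n)
    perm <- abs(signs %*% d) / n
    (1 + sum(perm >= obs - 1e-12)) / (1 + n_draws)
  }
}

## Monte-Carlo unpaired label-permutation test on the difference of group
## means; two-sided.
unpaired_perm_p <- function(x, y, n_draws = 2000L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  pool <- c(x, y)
  if (sd(pool) == 0) return(1)
  obs <- abs(mean(y) - mean(x))
  n1 <- length(x)
  count <- 0L
  for (i in seq_len(n_draws)) {
    idx <- sample(length(pool), n1)
    if (abs(mean(pool[-idx]) - mean(pool[idx])) >= obs - 1e-12)
      count <- count + 1L
  }
  (1 + count) / (1 + n_draws)
}

#' Alternative significance tests for the sensitivity grid
#'
#' Computes, for one assay, the p-values of the paired and unpaired
#' alternatives to the Skillings-Mack test so that conclusions can be probed
#' across estimator/test combinations:
#' \describe{
#'   \item{perm_signflip}{sign-flip permutation on per-pair differences;
#'     exact enumeration when the number of complete pairs is at most
#'     `max_exact` (worst case 4096 evaluations), Monte-Carlo otherwise.}
#'   \item{signed_rank}{Wilcoxon signed-rank on per-pair differences (exact
#'     small-sample null when there are no ties or zeros).}
#'   \item{welch_t}{Welch's two-sample t on unpaired group values.}
#'   \item{mann_whitney}{Wilcoxon rank-sum on unpaired group values.}
#'   \item{unpaired_perm}{Monte-Carlo label permutation of the difference in
#'     group means.}
#' }
#' All tests are two-sided.  A method with insufficient data yields `NA`
#' without affecting the others.
#'
#' @param paired `data.frame` with `pair_id`, `vehicle`, `agonist` columns.
#' @param n_draws Monte-Carlo draws for permutation tests.
#' @param seed Integer seed (applied once before the Monte-Carlo tests).
#' @param max_exact Largest pair count for exact sign-flip enumeration.
#' @return Named numeric vector of p-values.
#' @export
alternative_tests <- function(paired, n_draws = 2000L, seed = NULL,
                              max_exact = 12L) {
  if (!is.null(seed)) set.seed(seed)
  d <- paired$agonist - paired$vehicle
  dc <- d[!is.na(d)]
  x <- paired$vehicle[!is.na(paired$vehicle)]
  y <- paired$agonist[!is.na(paired$agonist)]
  p_sr <- if (length(dc) < 2L) NA_real_
  else if (all(dc == 0)) 1
  else suppressWarnings(wilcox.test(dc)$p.value)
  p_t <- if (length(x) < 2L || length(y) < 2L || (sd(x) == 0 && sd(y) == 0))
    NA_real_
  else suppressWarnings(t.test(y, x, var.equal = FALSE)$p.value)
  p_mw <- if (length(x) < 2L || length(y) < 2L) NA_real_
  else suppressWarnings(wilcox.test(y, x)$p.value)
  c(perm_signflip = signflip_p(d, n_draws, max_exact),
    signed_rank = p_sr, welch_t = p_t, mann_whitney = p_mw,
    unpaired_perm = unpaired_perm_p(x, y, n_draws))
}

#' Per-assay effect estimates and p-values
#'
#' Runs the matched-pairs delta-delta-Cq estimator and the requested tests on
#' every assay of a delta-Cq matrix.  The Skillings-Mack test uses the
#' vehicle/agonist pair structure as blocks; pairs with a missing side carry
#' no rank information and are dropped from the test (and from the paired
#' estimator), which is exactly the incomplete-block situation the test is
#' built for once designs are larger than two treatments per block.
#'
#' @param dcq Delta-Cq (or Cq) matrix restricted to vehicle/agonist samples.
#' @param sheet Sample sheet.
#' @param assays Assays to analyze (default all rows).
#' @param methods Character vector of p-value methods; `"skillings_mack"`
#'   always runs, optional extras are `"skillings_mack_mc"` and the
#'   [alternative_tests()] grid (`"perm_signflip"`, `"signed_rank"`,
#'   `"welch_t"`, `"mann_whitney"`, `"unpaired_perm"`).
#' @param n_draws Monte-Carlo draws where needed.
#' @param seed Integer seed; per-assay streams are derived from it so results
#'   do not depend on assay evaluation order.
#' @return `data.frame` with one row per assay: `assay_id`, `ddcq_hat`,
#'   `log2_fc`, `sd_log2_fc` (per-pair SD), `se_log2_fc`, `n_pairs`,
#'   `p_skillings_mack` and one `p_<method>` column per extra method.
#' @export
estimate_effects <- function(dcq, sheet, assays = rownames(dcq),
                             methods = "skillings_mack",
                             n_draws = 2000L, seed = NULL) {
  obs <- paired_observations(dcq, sheet, assays)
  extra <- setdiff(methods, "skillings_mack")
  known <- c("skillings_mack_mc", "perm_signflip", "signed_rank", "welch_t",
             "mann_whitney", "unpaired_perm")
  if (length(bad <- setdiff(extra, known)))
    stop("unknown method(s): ", paste(bad, collapse = ", "), call. = FALSE)
  rows <- lapply(seq_along(obs), function(i) {
    p <- obs[[i]]
    eff <- matched_pairs_effect(p)
    long <- data.frame(
      value = c(p$vehicle, p$agonist),
      block = rep(p$pair_id, 2L),
      treatment = rep(c("vehicle", "agonist"), each = nrow(p)))
    sm <- skillings_mack(long$value, long$block, long$treatment,
                         t_levels = c("vehicle", "agonist"))
    out <- data.frame(assay_id = names(obs)[i], ddcq_hat = eff$ddcq_hat,
                      log2_fc = eff$log2_fc, sd_log2_fc = eff$sd_pairs,
                      se_log2_fc = eff$se, n_pairs = eff$n_pairs_used,
                      p_skillings_mack = sm$p.value)
    aseed <- if (is.null(seed)) NULL else (seed + i) %% .Machine$integer.max
    if ("skillings_mack_mc" %in% extra)
      out$p_skillings_mack_mc <- skillings_mack_mc(
        long$value, long$block, long$treatment,
        t_levels = c("vehicle", "agonist"),
        n_draws = n_draws, seed = aseed)$p.value
    alt <- intersect(known[-1L], extra)
    if (length(alt)) {
      pv <- alternative_tests(p, n_draws = n_draws, seed = aseed)
      for (m in alt) out[[paste0("p_", m)]] <- unname(pv[m])
    }
    out
  })
  do.call(rbind, rows)
}
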