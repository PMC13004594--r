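#' Column dialect for delimited well tables and sample sheets
#'
#' TaqMan array exports differ between instrument software versions, so the
#' readers map vendor column names onto a fixed canonical schema through a
#' dialect object rather than hard-coding one header layout.
#'
#' @param columns Named list mapping canonical column names to one or more
#'   accepted header aliases.  Canonical well-table columns are `sample_id`,
#'   `assay_id`, `card`, `cq`, `amp_score`, `cq_conf`; canonical sample-sheet
#'   columns are `sample_id`, `receptor`, `condition`, `pair_id`, `run_batch`.
#'   Entries given here are merged over the built-in aliases.
#' @param na_cq Character vector of sentinel strings denoting an undetermined
#'   Cq.  All are normalized to `NA`.
#' @param sep Field separator.  `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @param dec Decimal mark, `"."` or `","`.
#' @return An object of class `cq_dialect`.
#' @examples
#' d <- cq_dialect(columns = list(cq = "Crt"), na_cq = c("", "Undetermined"))
#' @export
cq_dialect <- function(columns = list(), na_cq = c("", "Undetermined", "NA"),
                       sep = NULL, dec = ".") {
  stopifnot(is.list(columns), dec %in% c(".", ","))
  base <- list(
    sample_id = c("sample_id", "sample", "Sample Name", "sample.name"),
    assay_id  = c("assay_id", "assay", "miRNA", "Target Name", "target.name", "detector"),
    card      = c("card", "Card", "array"),
    cq        = c("cq", "Cq", "Ct", "CT", "Crt"),
    amp_score = c("amp_score", "AmpScore", "Amp Score", "amp.score", "ampscore"),
    cq_conf   = c("cq_conf", "CqConf", "Cq Conf", "cq.conf", "cqconf"),
    receptor  = c("receptor", "Receptor", "experiment"),
    condition = c("condition", "Condition", "group"),
    pair_id   = c("pair_id", "pair", "block", "Pair"),
    run_batch = c("run_batch", "batch", "run")
  )
  for (nm in names(columns)) base[[nm]] <- unique(c(columns[[nm]], base[[nm]]))
  structure(list(columns = base, na_cq = na_cq, sep = sep, dec = dec),
            class = "cq_dialect")
}

## Read a delimited file as all-character data.frame, auto-detecting the
## separator when the dialect does not fix one.
read_delim_raw <- function(path, dialect) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- dialect$sep
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
              lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  }
  read.table(path, header = TRUE, sep = sep, dec = dialect$dec,
             colClasses = "character", check.names = FALSE,
             stringsAsFactors = FALSE, quote = "\"", comment.char = "",
             strip.white = TRUE)
}

## Map vendor headers to the canonical schema; errors name the missing column.
map_columns <- function(df, dialect, required, optional = character()) {
  out <- list()
  for (cn in c(required, optional)) {
    hit <- intersect(dialect$columns[[cn]], names(df))
    if (length(hit) == 0L) {
      if (cn %in% required)
        stop("required column '", cn, "' not found (accepted aliases: ",
             paste(dialect$columns[[cn]], collapse = ", "), ")", call. = FALSE)
      next
    }
    out[[cn]] <- df[[hit[1L]]]
  }
  as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
}

num_or_na <- function(x, na_strings, dec = ".") {
  x[x %in% na_strings | is.na(x)] <- NA_character_
  if (dec == ",") x <- gsub(",", ".", x, fixed = TRUE)
  suppressWarnings(as.numeric(x))
}

#' Read a qPCR well table
#'
#' Reads a delimited well-level export (one row per reaction well) into the
#' canonical schema: `sample_id`, `assay_id`, `card`, `cq`, `amp_score`,
#' `cq_conf`.  Undetermined-Cq sentinels become `NA`; row order is preserved.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param dialect A [cq_dialect()] describing column aliases and sentinels.
#' @return A `data.frame` of well records, one per input row.
#' @examples
#' f <- system.file("extdata", "toy_wells.csv", package = "evmircq")
#' head(read_well_table(f))
#' @export
read_well_table <- function(path, dialect = cq_dialect()) {
  raw <- read_delim_raw(path, dialect)
  df <- map_columns(raw, dialect,
                    required = c("sample_id", "assay_id", "card", "cq",
                                 "amp_score", "cq_conf"))
  df$cq <- num_or_na(df$cq, dialect$na_cq, dialect$dec)
  df$amp_score <- num_or_na(df$amp_score, dialect$na_cq, dialect$dec)
  df$cq_conf <- num_or_na(df$cq_conf, dialect$na_cq, dialect$dec)
  validate_wells(df)
  df
}

validate_wells <- function(df) {
  bad_card <- setdiff(unique(df$card), c("A", "B"))
  if (length(bad_card))
    stop("card must be 'A' or 'B'; found: ", paste(bad_card, collapse = ", "),
         call. = FALSE)
  if (any(!is.na(df$cq) & (!is.finite(df$cq) | df$cq <= 0)))
    stop("non-missing cq values must be finite and > 0", call. = FALSE)
  if (any(!is.na(df$cq_conf) & (df$cq_conf < 0 | df$cq_conf > 1)))
    stop("cq_conf must lie in [0, 1]", call. = FALSE)
  key <- paste(df$sample_id, df$assay_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (sample, assay) rows: ",
         paste(gsub("\r", " / ", utils::head(dup, 5L)), collapse = "; "),
         call. = FALSE)
  }
  invisible(df)
}

#' Write a well table in the canonical schema
#'
#' Missing Cq values are written as `"Undetermined"` so that a written table
#' read back with [read_well_table()] reproduces the input.
#'
#' @param wells Well-record `data.frame`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_well_table <- function(wells, path) {
  out <- wells[, c("sample_id", "assay_id", "card", "cq", "amp_score", "cq_conf")]
  out$cq <- ifelse(is.na(out$cq), "Undetermined", format(out$cq, digits = 15L))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' The sample sheet assigns every sample a receptor experiment, a condition
#' (`media_control`, `vehicle_control` or `agonist`) and, for the two treated
#' conditions, a pair identifier linking each vehicle replicate to its matched
#' agonist replicate.
#'
#' @inheritParams read_well_table
#' @return A `data.frame` with columns `sample_id`, `receptor`, `condition`,
#'   `pair_id` and (if present) `run_batch`.
#' @export
read_sample_sheet <- function(path, dialect = cq_dialect()) {
  raw <- read_delim_raw(path, dialect)
  df <- map_columns(raw, dialect,
                    required = c("sample_id", "receptor", "condition"),
                    optional = c("pair_id", "run_batch"))
  if (is.null(df$pair_id)) df$pair_id <- NA_character_
  df$pair_id[df$pair_id %in% c("", "NA")] <- NA_character_
  validate_sheet(df)
  df
}

validate_sheet <- function(sheet) {
  ok <- c("media_control", "vehicle_control", "agonist")
  bad <- setdiff(unique(sheet$condition), ok)
  if (length(bad))
    stop("unknown condition(s): ", paste(bad, collapse = ", "),
         "; expected ", paste(ok, collapse = "/"), call. = FALSE)
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  if (any(!is.na(sheet$pair_id[sheet$condition == "media_control"])))
    stop("media_control samples must not carry a pair_id", call. = FALSE)
  for (cond in c("vehicle_control", "agonist")) {
    p <- sheet$pair_id[sheet$condition == cond]
    if (any(is.na(p)))
      stop(cond, " samples must carry a pair_id", call. = FALSE)
    if (anyDuplicated(p))
      stop("pair_id occurs more than once within condition ", cond, call. = FALSE)
  }
  invisible(sheet)
}

#' Pivot well records to an assays-by-samples Cq matrix
#'
#' Cells with no record, or with a missing/undetermined Cq, are `NA`.  Assay
#' (row) order is lexicographic; sample (column) order follows the sample
#' sheet, so the result is invariant to the input row order.
#'
#' @param records Well-record `data.frame` (raw or QC-filtered).
#' @param sheet Sample sheet `data.frame`; every sample in `records` must
#'   appear here.
#' @return Numeric matrix of Cq values with assay rownames and sample colnames.
#' @export
pivot_to_matrix <- function(records, sheet) {
  extra <- setdiff(unique(records$sample_id), sheet$sample_id)
  if (length(extra))
    stop("samples present in records but absent from sample sheet: ",
         paste(extra, collapse = ", "), call. = FALSE)
  assays <- sort(unique(records$assay_id))
  samples <- sheet$sample_id
  m <- matrix(NA_real_, nrow = length(assays), ncol = length(samples),
              dimnames = list(assays, samples))
  if (nrow(records))
    m[cbind(match(records$assay_id, assays),
            match(records$sample_id, samples))] <- records$cq
  m
}

#' Write the per-assay results table
#'
#' Joins effect estimates and selection flags into one delimited file with a
#' stable column order: `assay_id`, `log2_fc`, `sd_log2_fc`, `se_log2_fc`,
#' `n_pairs`, `p_skillings_mack`, any further p-value columns, then
#' `selected_p02`, `selected_fc15`, `selected`.
#'
#' @param effects Effect-estimate `data.frame` from [estimate_effects()].
#' @param selections Selection `data.frame` from [rank_and_select()].
#' @param path Output CSV path.
#' @return Invisibly, the written `data.frame`.
#' @export
write_results <- function(effects, selections, path) {
  tab <- merge(effects, selections[, c("assay_id", "rank_by_effect",
                                       "selected_p02", "selected_fc15",
                                       "significant_p05", "selected")],
               by = "assay_id", all.x = TRUE, sort = TRUE)
  pcols <- grep("^p_", names(tab), value = TRUE)
  pcols <- c(intersect("p_skillings_mack", pcols), setdiff(pcols, "p_skillings_mack"))
  lead <- c("assay_id", "ddcq_hat", "log2_fc", "sd_log2_fc", "se_log2_fc", "n_pairs")
  ord <- c(intersect(lead, names(tab)), pcols,
           setdiff(names(tab), c(lead, pcols)))
  tab <- tab[order(tab$assay_id), ord, drop = FALSE]
  ok <- tryCatch({ write.csv(tab, path, row.names = FALSE); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write results to '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(tab)
}
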