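## Allowed configuration keys per block; unknown keys are rejected so typos
## fail loudly instead of silently running with defaults.
config_schema <- list(
  paths = c("well_table", "sample_sheet", "out_dir"),
  simulate = c("n_assays", "card_split", "n_pairs", "n_media",
               "baseline_cq_mean", "baseline_cq_sd", "frac_media_only",
               "frac_cell_derived", "frac_mc_shared", "effect_assays",
               "pair_sd", "card_offset", "resid_sd", "cq_censor",
               "dropout_slope", "qc_fail_rate", "pair_dropout_rate",
               "mc_shift_range", "mc_shared_delta_sd", "receptor", "seed"),
  qc = c("cq_max", "cq_conf_min", "amp_score_min", "expr_rate", "expr_rule",
         "mc_delta_min", "mc_presence_rate", "mc_delta_mode"),
  normalization = c("normalizers"),
  stats = c("methods", "n_draws", "seed"),
  selection = c("p_cut", "fc_cut_log2", "p_sig"))

#' Validate a pipeline configuration
#'
#' @param config Named list (e.g. from [yaml::read_yaml()]) with any of the
#'   blocks `paths`, `simulate`, `qc`, `normalization`, `stats`, `selection`.
#'   Unknown blocks or keys raise an error.
#' @return The validated config, invisibly.
#' @export
validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  bad <- setdiff(names(config), names(config_schema))
  if (length(bad))
    stop("unknown config block(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (blk in names(config)) {
    bad <- setdiff(names(config[[blk]]), config_schema[[blk]])
    if (length(bad))
      stop("unknown key(s) in '", blk, "': ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  has_files <- !is.null(config$paths$well_table) &&
    !is.null(config$paths$sample_sheet)
  if (!has_files && is.null(config$simulate))
    stop("config needs either paths$well_table + paths$sample_sheet or a ",
         "simulate block", call. = FALSE)
  invisible(config)
}

#' Run the full analysis pipeline from a configuration
#'
#' Sequences read (or simulate) -> well QC -> expression/media filters ->
#' normalizer selection -> delta-Cq -> effects and p-values -> selection ->
#' reports, writing all artifacts into `paths$out_dir` and returning a
#' machine-readable run manifest (also written as `manifest.json`) that
#' records the configuration, seed and the counts at every stage.
#'
#' @param config Configuration list or path to a YAML file; see
#'   [validate_config()].
#' @param stage Run up to this stage: `"simulate"` (write simulated inputs
#'   only), `"qc"`, `"normalize"`, `"diffexp"` or `"select"`/`"all"` (full
#'   run, default).
#' @param quiet Suppress per-stage progress messages?
#' @return The manifest list, invisibly.  Components include `counts` (from
#'   [ev_diffexp()]), `outputs` (paths written) and `config`.
#' @export
run_pipeline <- function(config, stage = c("all", "select", "diffexp",
                                           "normalize", "qc", "simulate"),
                         quiet = FALSE) {
  stage <- match.arg(stage)
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  validate_config(config)
  say <- function(...) if (!quiet) message("[evmircq] ", sprintf(...))
  out_dir <- config$paths$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  t0 <- proc.time()[["elapsed"]]

  truth <- NULL
  if (!is.null(config$simulate)) {
    scfg <- do.call(sim_config, config$simulate)
    say("simulating experiment (%d assays, seed %d)", scfg$n_assays, scfg$seed)
    sim <- simulate_experiment(scfg)
    wells <- sim$wells; sheet <- sim$sheet; truth <- sim$truth
    outputs["well_table"] <- file.path(out_dir, "simulated_wells.csv")
    write_well_table(wells, outputs["well_table"])
    outputs["sample_sheet"] <- file.path(out_dir, "simulated_sample_sheet.csv")
    write.csv(sheet, outputs["sample_sheet"], row.names = FALSE)
    outputs["truth"] <- file.path(out_dir, "truth_manifest.csv")
    write.csv(truth, outputs["truth"], row.names = FALSE)
  } else {
    say("reading %s", config$paths$well_table)
    wells <- read_well_table(config$paths$well_table)
    sheet <- read_sample_sheet(config$paths$sample_sheet)
  }

  manifest <- list(package = "evmircq",
                   version = as.character(packageVersion("evmircq")),
                   stage = stage, config = config)
  if (stage == "simulate") {
    manifest$outputs <- as.list(outputs)
    manifest$elapsed_s <- proc.time()[["elapsed"]] - t0
    return(write_manifest(manifest, out_dir))
  }

  qc <- do.call(qc_thresholds, config$qc %||% list())
  stats_cfg <- config$stats %||% list()
  sel_cfg <- config$selection %||% list()
  say("fitting (QC, filters, normalization, effects, selection)")
  fit <- ev_diffexp(wells, sheet, qc = qc,
                    normalizers = config$normalization$normalizers,
                    methods = stats_cfg$methods %||% "skillings_mack",
                    n_draws = stats_cfg$n_draws %||% 2000L,
                    seed = stats_cfg$seed,
                    p_cut = sel_cfg$p_cut %||% 0.2,
                    fc_cut_log2 = sel_cfg$fc_cut_log2 %||% 0.585,
                    p_sig = sel_cfg$p_sig %||% 0.05)

  outputs["qc_report"] <- file.path(out_dir, "qc_report.csv")
  write.csv(fit$qc_report, outputs["qc_report"], row.names = FALSE)
  if (stage != "qc") {
    outputs["normalizer_report"] <- file.path(out_dir, "normalizer_report.csv")
    write.csv(fit$normalizers$criteria_trace, outputs["normalizer_report"],
              row.names = FALSE)
  }
  if (stage %in% c("diffexp", "select", "all")) {
    outputs["results"] <- file.path(out_dir, "results.csv")
    write_results(fit$effects, fit$selection, outputs["results"])
  }
  if (stage %in% c("select", "all")) {
    outputs["selection"] <- file.path(out_dir, "selection.csv")
    write.csv(fit$selection, outputs["selection"], row.names = FALSE)
    outputs["volcano"] <- file.path(out_dir, "volcano.csv")
    write.csv(volcano_table(fit$effects,
                            p_cut = fit$thresholds["p_cut"],
                            fc_cut_log2 = fit$thresholds["fc_cut_log2"]),
              outputs["volcano"], row.names = FALSE)
    zm <- pipeline_zmatrix(fit)
    if (!is.null(zm)) {
      outputs["zmatrix"] <- file.path(out_dir, "zmatrix.csv")
      write.csv(zm, outputs["zmatrix"], row.names = FALSE)
    }
    if (!is.null(truth)) {
      rec <- evaluate_recovery(fit$selection, truth)
      manifest$recovery <- rec
      say("recovery: sensitivity %.2f, FDP %.2f", rec$sensitivity, rec$fdp)
    }
  }
  manifest$counts <- fit$counts
  manifest$normalizer_assays <- fit$normalizers$assays
  manifest$outputs <- as.list(outputs)
  manifest$elapsed_s <- proc.time()[["elapsed"]] - t0
  say("done: %d assays selected", fit$counts$assays_selected)
  write_manifest(manifest, out_dir)
}

## z-transformed per-pair ddCq of the selected assays, rows in clustered
## order; NULL when fewer than two selected assays or two complete pairs.
pipeline_zmatrix <- function(fit) {
  sel <- fit$selection$assay_id[fit$selection$selected]
  if (length(sel) < 2L) return(NULL)
  obs <- paired_observations(fit$dcq, fit$sheet, sel)
  dd <- do.call(rbind, lapply(obs, function(p) p$agonist - p$vehicle))
  colnames(dd) <- obs[[1L]]$pair_id
  keep_col <- colSums(is.na(dd)) == 0L
  dd <- dd[, keep_col, drop = FALSE]
  if (ncol(dd) < 2L) return(NULL)
  z <- zscore_matrix(-dd)  # -ddCq = log2 FC orientation
  ord <- hierarchical_order(z)
  z <- z[ord$row_order, , drop = FALSE]
  data.frame(assay_id = rownames(z), z, check.names = FALSE, row.names = NULL)
}

write_manifest <- function(manifest, out_dir) {
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, force = TRUE)
  manifest$outputs$manifest <- path
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cli_usage <- function() {
  paste0(
    "usage: evqpcr <subcommand> [--config FILE] [--seed N] [--out DIR]\n",
    "subcommands: simulate | qc | normalize | diffexp | select | run-all\n",
    "       evqpcr --version | --help\n")
}

#' Command-line entry point
#'
#' Thin argv-level wrapper over [run_pipeline()] used by the `evqpcr` script
#' in `inst/scripts/`.  Subcommands `simulate`, `qc`, `normalize`, `diffexp`,
#' `select` and `run-all` run the pipeline up to the corresponding stage;
#' `--seed` overrides the simulation and statistics seeds and `--out` the
#' output directory.
#'
#' @param argv Character vector of command-line arguments (without the
#'   program name).
#' @return Integer exit status: 0 on success, 1 on a runtime failure, 2 on a
#'   usage error.
#' @export
cli_entry <- function(argv = character()) {
  if (length(argv) == 0L || argv[1L] %in% c("--help", "-h", "help")) {
    cat(cli_usage())
    return(if (length(argv)) 0L else 2L)
  }
  if (argv[1L] == "--version") {
    cat("evqpcr (evmircq) ", as.character(packageVersion("evmircq")), "\n",
        sep = "")
    return(0L)
  }
  sub <- argv[1L]
  stages <- c("simulate" = "simulate", "qc" = "qc", "normalize" = "normalize",
              "diffexp" = "diffexp", "select" = "select", "run-all" = "all")
  if (!sub %in% names(stages)) {
    message("unknown subcommand: ", sub, "\n", cli_usage())
    return(2L)
  }
  opts <- list(config = NULL, seed = NULL, out = NULL)
  args <- argv[-1L]
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    kv <- strsplit(a, "=", fixed = TRUE)[[1L]]
    key <- sub("^--", "", kv[1L])
    if (!grepl("^--", a) || !key %in% names(opts)) {
      message("unknown flag: ", a, "\n", cli_usage())
      return(2L)
    }
    if (length(kv) == 2L) { opts[[key]] <- kv[2L] }
    else {
      if (i == length(args)) { message("flag needs a value: ", a); return(2L) }
      opts[[key]] <- args[i + 1L]; i <- i + 1L
    }
    i <- i + 1L
  }
  config <- if (!is.null(opts$config)) {
    if (!file.exists(opts$config)) {
      message("config file not found: ", opts$config)
      return(2L)
    }
    yaml::read_yaml(opts$config)
  } else list(simulate = list())
  if (!is.null(opts$seed)) {
    seed <- as.integer(opts$seed)
    if (is.na(seed)) { message("--seed must be an integer"); return(2L) }
    if (!is.null(config$simulate)) config$simulate$seed <- seed
    config$stats$seed <- seed
  }
  if (!is.null(opts$out)) config$paths$out_dir <- opts$out
  status <- tryCatch({
    run_pipeline(config, stage = stages[[sub]])
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}
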