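# Command-line pipeline tying the stages together:
# simulate -> correlate -> recommend -> pool -> callpeaks -> evaluate.
#
# The installed entry point is exec/poolctrl (a thin Rscript over
# poolctrl_main()); every subcommand delegates to the module functions and
# writes a YAML manifest capturing the effective configuration, input
# digests and seeds, so a run can be reproduced exactly from its manifest.

pc_usage <- function() {
  paste(
    "usage: poolctrl <command> [options]",
    "",
    "commands:",
    "  simulate   --preset NAME --seed INT --out DIR [--depth N] [--force]",
    "  correlate  --reads A,B,... --chrom-sizes FILE [--chips A,B,...]",
    "             [--peaks FILE] [--bin-width 200] [--fragment-length 150]",
    "             [--threshold 0.7] --out PREFIX",
    "  recommend  --report FILE [--threshold 0.7]",
    "  pool       --reads A,B,... --fraction F --seed INT --out FILE",
    "  callpeaks  --chip FILE --control FILE --chrom-sizes FILE",
    "             [--fdr 0.05] [--fragment-length 150] --out FILE",
    "  evaluate   --manifest FILE",
    "",
    "exit codes: 0 success (recommend: pool), 3 recommend: sequence deeper,",
    "            2 usage error",
    sep = "\n")
}

parse_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      pc_stop("poolctrl_usage", "unexpected argument '%s'", a)
    key <- sub("^--", "", a)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      out[[key]] <- TRUE
      i <- i + 1L
    }
  }
  out
}

opt <- function(opts, key, default = NULL, required = FALSE) {
  v <- opts[[key]]
  if (is.null(v)) {
    if (required)
      pc_stop("poolctrl_usage", "missing required option --%s", key)
    return(default)
  }
  v
}

file_digests <- function(paths) {
  paths <- unlist(paths, use.names = FALSE)
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

write_manifest <- function(path, stage, config, inputs = character(0),
                           outputs = character(0)) {
  yaml::write_yaml(list(tool = "poolctrl",
                        version = as.character(utils::packageVersion("poolctrl")),
                        stage = stage,
                        config = config,
                        input_digests = file_digests(inputs),
                        outputs = as.list(unlist(outputs))),
                   path)
  invisible(path)
}

pc_log <- function(stage, fmt, ...) {
  message(sprintf("[poolctrl:%s] %s", stage, sprintf(fmt, ...)))
}

cmd_simulate <- function(opts) {
  preset <- opt(opts, "preset", required = TRUE)
  seed <- as.integer(opt(opts, "seed", 1L))
  out <- opt(opts, "out", required = TRUE)
  config <- scenario_config()
  depth <- opt(opts, "depth")
  if (!is.null(depth)) {
    config$control_depths <- config$chip_depths <- as.numeric(depth)
  }
  scen <- generate_scenario(preset, seed = seed, out_dir = out,
                            config = config,
                            force = isTRUE(opt(opts, "force", FALSE)))
  pc_log("simulate", "preset=%s seed=%d -> %s (%d controls, %d chips)",
         preset, seed, out, length(scen$controls), length(scen$chips))
  0L
}

cmd_correlate <- function(opts) {
  read_paths <- strsplit(opt(opts, "reads", required = TRUE), ",")[[1L]]
  bw <- as.integer(opt(opts, "bin-width", 200L))
  fl <- as.integer(opt(opts, "fragment-length", 150L))
  thr <- as.numeric(opt(opts, "threshold", 0.7))
  layout <- read_chrom_sizes(opt(opts, "chrom-sizes", required = TRUE), bw)
  out <- opt(opts, "out", required = TRUE)
  controls <- lapply(read_paths, load_reads)
  ctrl_bins <- lapply(controls, bin_counts, layout = layout,
                      fragment_length = fl)
  peaks_path <- opt(opts, "peaks")
  master <- if (!is.null(peaks_path)) {
    build_master_list(list(import_peaks(peaks_path)))
  } else {
    # auto mode: candidate enrichment regions from an initial comparison of
    # each ChIP with the pool of all controls
    chip_paths <- strsplit(opt(opts, "chips", required = TRUE), ",")[[1L]]
    pooled <- bin_counts(pool_reads(controls), layout, fl)
    sets <- lapply(chip_paths, function(cp) {
      call_peaks(bin_counts(load_reads(cp), layout, fl), pooled)
    })
    build_master_list(sets)
  }
  report <- pairwise_report(ctrl_bins, master, fixed_threshold = thr)
  write_report_tsv(report, paste0(out, "_report.tsv"))
  write_newick(hcluster(report), paste0(out, "_dendrogram.nwk"))
  write_manifest(paste0(out, "_manifest.yaml"), "correlate",
                 list(bin_width = bw, fragment_length = fl, threshold = thr,
                      master_regions = nrow(master$regions)),
                 inputs = read_paths,
                 outputs = paste0(out, c("_report.tsv", "_dendrogram.nwk")))
  pc_log("correlate", "%d samples, %d pairs, threshold=%.2f -> %s_report.tsv",
         length(controls), nrow(report$pairs), thr, out)
  0L
}

cmd_recommend <- function(opts) {
  thr <- as.numeric(opt(opts, "threshold", 0.7))
  report <- read_report_tsv(opt(opts, "report", required = TRUE),
                            threshold = thr)
  rec <- recommend(report)
  print(rec)
  if (rec$decision == "pool") 0L else 3L
}

cmd_pool <- function(opts) {
  read_paths <- strsplit(opt(opts, "reads", required = TRUE), ",")[[1L]]
  fraction <- as.numeric(opt(opts, "fraction", 1))
  seed <- as.integer(opt(opts, "seed", 1L))
  out <- opt(opts, "out", required = TRUE)
  controls <- lapply(read_paths, load_reads)
  pooled <- if (fraction < 1) {
    make_pooled_design(controls, fraction, seed)
  } else {
    pool_reads(controls)
  }
  write_reads(pooled, out, "tagAlign")
  pc_log("pool", "%d samples, fraction=%g, seed=%d -> %s (%d reads)",
         length(controls), fraction, seed, out, pooled$depth)
  0L
}

cmd_callpeaks <- function(opts) {
  bw <- as.integer(opt(opts, "bin-width", 200L))
  fl <- as.integer(opt(opts, "fragment-length", 150L))
  layout <- read_chrom_sizes(opt(opts, "chrom-sizes", required = TRUE), bw)
  chip <- bin_counts(load_reads(opt(opts, "chip", required = TRUE)),
                     layout, fl)
  control <- bin_counts(load_reads(opt(opts, "control", required = TRUE)),
                        layout, fl)
  peaks <- call_peaks(chip, control,
                      fdr = as.numeric(opt(opts, "fdr", 0.05)))
  out <- opt(opts, "out", required = TRUE)
  write_bed(peaks, out)
  pc_log("callpeaks", "%d peaks -> %s", n_regions(peaks), out)
  0L
}

cmd_evaluate <- function(opts) {
  manifest <- yaml::read_yaml(opt(opts, "manifest", required = TRUE))
  gold <- import_peaks(manifest$gold)
  k_grid <- if (is.null(manifest$k_grid)) seq(5, 100, by = 5)
            else as.numeric(manifest$k_grid)
  out <- if (is.null(manifest$out)) "evaluation" else manifest$out
  rows <- lapply(manifest$candidates, function(cand) {
    set <- import_peaks(if (is.list(cand)) cand$path else cand)
    label <- if (is.list(cand) && !is.null(cand$label)) cand$label
             else basename(if (is.list(cand)) cand$path else cand)
    curve <- overlap_sensitivity(set, gold, k_grid)
    data.frame(candidate = label, k = k_grid,
               sensitivity = curve$sensitivity,
               ppv = suppressWarnings(ppv(set, gold)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, paste0(out, "_curves.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pc_log("evaluate", "%d candidate sets vs %s -> %s_curves.tsv",
         length(manifest$candidates), manifest$gold, out)
  0L
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `correlate`, `recommend`, `pool`, `callpeaks`
#' and `evaluate` subcommands; see `exec/poolctrl` for the installed script.
#' The `recommend` exit code encodes the decision (0 = pool, 3 = sequence
#' deeper) so the tool composes in shell pipelines.
#'
#' @param args character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly.
#' @export
poolctrl_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1L] %in% c("--help", "-h", "help")) {
    cat(pc_usage(), "\n")
    return(invisible(0L))
  }
  cmd <- args[1L]
  handler <- switch(cmd,
                    simulate = cmd_simulate,
                    correlate = cmd_correlate,
                    recommend = cmd_recommend,
                    pool = cmd_pool,
                    callpeaks = cmd_callpeaks,
                    evaluate = cmd_evaluate,
                    NULL)
  if (is.null(handler)) {
    message(sprintf("unknown command '%s'\n%s", cmd, pc_usage()))
    return(invisible(2L))
  }
  status <- tryCatch({
    opts <- parse_args(args[-1L])
    if (isTRUE(opts[["help"]])) {
      cat(pc_usage(), "\n")
      0L
    } else {
      handler(opts)
    }
  }, poolctrl_usage = function(e) {
    message(conditionMessage(e), "\n", pc_usage())
    2L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
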