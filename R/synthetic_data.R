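# Read-level synthetic ChIP-seq scenarios with a tunable between-sample
# background correlation.
#
# Bin-level background rates are log-normal with a Gaussian-copula mixture of
# a shared and a sample-specific component weighted so that the pairwise
# correlation of log-rates between any two samples equals rho exactly -- the
# single interpretable dial that places a scenario in the empirical high or
# low correlation class.  ChIP samples add planted fold-enrichment regions
# on top of their matching control's background; reads are multinomial over
# bins with uniform positions within a bin and fair-coin strands, so every
# downstream module operates on the same read-level objects as real data.

#' Scenario configuration for the synthetic generator
#'
#' Defaults describe a desk-scale study: one 10-Mb chromosome in 200-bp bins
#' (50,000 bins), two control/ChIP replicate pairs at one million reads per
#' sample, log-normal background rates with `sd_log = 1`, and 150 planted
#' 1-kb enrichment regions at fold 8-16.
#'
#' @param layout `GenomeLayout`; default one 10-Mb chromosome, 200-bp bins.
#' @param n_replicates number of control/ChIP pairs (default 2).
#' @param control_depths reads per control sample (recycled; default 1e6).
#' @param chip_depths reads per ChIP sample (recycled; default 1e6).
#' @param rho target pairwise correlation of log background rates between
#'   samples, in `[0, 1]`.
#' @param mean_log,sd_log log-normal parameters of the bin background rates.
#' @param n_regions number of planted enrichment regions (default 150).
#' @param region_width width of each planted region in bp (default 1000).
#' @param fold_range fold-enrichment range, drawn uniformly per region
#'   (default `c(8, 16)`).
#' @param treatment_frac fraction of bins whose background rate is perturbed
#'   between treatment conditions (default 0).
#' @param treatment_sd log-sd of the treatment perturbation (default 0.7).
#' @param lab_bias_amplitude amplitude of the smooth multiplicative lab bias
#'   applied to flagged samples (default 0 = no bias).
#' @param seed integer seed.
#' @return A `ScenarioConfig` list.
#' @export
scenario_config <- function(layout = genome_layout("chrS", 1e7, 200L),
                            n_replicates = 2L,
                            control_depths = 1e6,
                            chip_depths = 1e6,
                            rho = 0.95,
                            mean_log = 0, sd_log = 1,
                            n_regions = 150L, region_width = 1000L,
                            fold_range = c(8, 16),
                            treatment_frac = 0, treatment_sd = 0.7,
                            lab_bias_amplitude = 0,
                            seed = 1L) {
  if (rho < 0 || rho > 1)
    pc_stop("poolctrl_bad_arg", "rho must be in [0, 1]")
  if (any(control_depths < 1) || any(chip_depths < 1))
    pc_stop("poolctrl_bad_arg", "depths must be >= 1")
  structure(list(layout = layout,
                 n_replicates = as.integer(n_replicates),
                 control_depths = rep_len(control_depths, n_replicates),
                 chip_depths = rep_len(chip_depths, n_replicates),
                 rho = rho, mean_log = mean_log, sd_log = sd_log,
                 n_regions = as.integer(n_regions),
                 region_width = as.integer(region_width),
                 fold_range = fold_range,
                 treatment_frac = treatment_frac,
                 treatment_sd = treatment_sd,
                 lab_bias_amplitude = lab_bias_amplitude,
                 seed = as.integer(seed)),
            class = "ScenarioConfig")
}

#' Draw correlated per-sample background rate vectors
#'
#' Sample `i`'s log-rate is
#' `mean_log + sd_log * (sqrt(rho) * Z_s + sqrt(1 - rho) * Z_i)` with
#' standard-normal `Z_s` shared across samples and `Z_i` sample-specific, so
#' the pairwise correlation of log-rates between any two samples equals
#' `rho` exactly.  An optional smooth positional lab bias multiplies the
#' rates of flagged samples by `exp(amplitude * sin(2 pi pos / period))`,
#' emulating a laboratory batch effect that decorrelates otherwise similar
#' samples.
#'
#' @param config a `ScenarioConfig`.
#' @param n_samples number of rate vectors to draw (default
#'   `config$n_replicates`).
#' @param lab_biased logical vector flagging samples receiving the lab bias.
#' @param seed overrides `config$seed` when given.
#' @return Numeric matrix, bins x samples, of positive rates.
#' @export
draw_background <- function(config, n_samples = config$n_replicates,
                            lab_biased = rep(FALSE, n_samples),
                            seed = config$seed) {
  stopifnot(inherits(config, "ScenarioConfig"))
  nb <- sum(n_bins(config$layout))
  rho <- config$rho
  with_seed(seed, {
    zs <- stats::rnorm(nb)
    logr <- vapply(seq_len(n_samples), function(i) {
      zi <- stats::rnorm(nb)
      config$mean_log +
        config$sd_log * (sqrt(rho) * zs + sqrt(1 - rho) * zi)
    }, numeric(nb))
    rates <- exp(logr)
    if (any(lab_biased) && config$lab_bias_amplitude != 0) {
      pos <- seq_len(nb) / nb
      bias <- exp(config$lab_bias_amplitude * sin(2 * pi * pos * 5))
      rates[, lab_biased] <- rates[, lab_biased] * bias
    }
    rates
  })
}

#' Perturb background rates between treatment conditions
#'
#' A fixed random subset of `treatment_frac` of the bins gets a
#' condition-specific multiplicative log-normal perturbation, emulating
#' chromatin differences between treatments of the same cell type.
#'
#' @param rates bins x samples rate matrix.
#' @param condition integer condition id per sample; condition 1 is the
#'   reference and is left untouched.
#' @param config a `ScenarioConfig` (uses `treatment_frac`, `treatment_sd`).
#' @param seed integer seed.
#' @return The perturbed rate matrix.
#' @export
apply_treatment_effect <- function(rates, condition, config,
                                   seed = config$seed) {
  stopifnot(length(condition) == ncol(rates))
  if (config$treatment_frac <= 0) return(rates)
  nb <- nrow(rates)
  with_seed(derive_seed(seed, "treatment"), {
    bins <- sample.int(nb, round(config$treatment_frac * nb))
    for (cond in setdiff(unique(condition), 1L)) {
      shift <- exp(stats::rnorm(length(bins), 0, config$treatment_sd))
      cols <- which(condition == cond)
      rates[bins, cols] <- rates[bins, cols] * shift
    }
    rates
  })
}

#' Plant fold-enrichment regions into ChIP rate vectors
#'
#' Selects `n_regions` disjoint regions of `region_width` bp and multiplies
#' the ChIP rates inside each by a fold drawn uniformly from `fold_range`.
#' Control rates are untouched; the same regions and folds apply to every
#' ChIP sample (replicates of one factor).
#'
#' @param control_rates bins x samples background rate matrix.
#' @param config a `ScenarioConfig`.
#' @param seed integer seed.
#' @return List: `chip_rates` (bins x samples), `truth` data frame with
#'   columns (chrom, start, end, fold) of the planted regions, sorted and
#'   disjoint.
#' @export
plant_enrichment <- function(control_rates, config, seed = config$seed) {
  stopifnot(inherits(config, "ScenarioConfig"))
  layout <- config$layout
  w <- layout$bin_width
  nb_per <- n_bins(layout)
  chip_rates <- control_rates
  if (config$n_regions == 0L) {
    return(list(chip_rates = chip_rates,
                truth = data.frame(chrom = character(), start = integer(),
                                   end = integer(), fold = numeric(),
                                   stringsAsFactors = FALSE)))
  }
  wb <- max(1L, as.integer(round(config$region_width / w)))
  # slot the genome into strides of (region + 2-bin spacer); sampling slots
  # guarantees disjoint regions
  stride <- wb + 2L
  # place all regions on the first (largest) chromosome arrangement:
  # distribute proportionally over chromosomes
  total_slots <- sum(pmax(0L, (nb_per - 1L) %/% stride))
  if (total_slots < config$n_regions)
    pc_stop("poolctrl_bad_arg",
            "genome too small for %d disjoint regions of %d bp",
            config$n_regions, config$region_width)
  offs <- c(0L, cumsum(nb_per))
  slot_chrom <- rep(seq_along(nb_per), pmax(0L, (nb_per - 1L) %/% stride))
  slot_index <- unlist(lapply(pmax(0L, (nb_per - 1L) %/% stride), seq_len))
  truth <- with_seed(derive_seed(seed, "plant"), {
    pick <- sort(sample.int(total_slots, config$n_regions))
    folds <- stats::runif(config$n_regions, config$fold_range[1L],
                          config$fold_range[2L])
    data.frame(chrom = layout$chrom_names[slot_chrom[pick]],
               bin_start = (slot_index[pick] - 1L) * stride + 1L,
               chrom_i = slot_chrom[pick],
               fold = folds, stringsAsFactors = FALSE)
  })
  for (j in seq_len(nrow(truth))) {
    b0 <- truth$bin_start[j]
    gbins <- offs[truth$chrom_i[j]] + b0:(b0 + wb - 1L)
    chip_rates[gbins, ] <- chip_rates[gbins, ] * truth$fold[j]
  }
  len <- layout$chrom_lengths[truth$chrom]
  truth$start <- (truth$bin_start - 1L) * w
  truth$end <- pmin(as.integer(truth$bin_start - 1L + wb) * w, len)
  truth <- truth[order(truth$chrom_i, truth$start),
                 c("chrom", "start", "end", "fold")]
  rownames(truth) <- NULL
  list(chip_rates = chip_rates, truth = truth)
}

#' Sample a read-level dataset from bin rates
#'
#' Reads per bin are multinomial with probabilities proportional to the
#' rates; read 5' positions are uniform within the bin and strands are fair
#' coins.  The output has exactly `depth` reads.
#'
#' @param rates positive rate vector over the genome-order bins of `layout`.
#' @param depth number of reads.
#' @param layout a `GenomeLayout`.
#' @param seed integer seed.
#' @param source_label provenance label.
#' @return A `ReadSet`.
#' @export
sample_reads <- function(rates, depth, layout, seed, source_label = "synth") {
  stopifnot(inherits(layout, "GenomeLayout"))
  nb_per <- n_bins(layout)
  if (length(rates) != sum(nb_per))
    pc_stop("poolctrl_bad_arg", "rates length does not match layout bins")
  depth <- as.integer(depth)
  if (depth == 0L)
    return(read_set(source_label = source_label))
  with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1L, depth, rates))
    bin <- rep.int(seq_along(counts), counts)
    offs <- c(0L, cumsum(nb_per))
    chrom_i <- findInterval(bin - 1L, offs[-length(offs)], rightmost.closed = FALSE)
    chrom_i <- pmin(chrom_i, length(nb_per))
    local_bin <- bin - offs[chrom_i]
    w <- layout$bin_width
    len <- as.numeric(layout$chrom_lengths[chrom_i])
    bin_start <- (local_bin - 1L) * w
    bin_w <- pmin(w, len - bin_start)
    pos5 <- bin_start + floor(stats::runif(depth) * bin_w)
    strand <- c("+", "-")[1L + (stats::runif(depth) < 0.5)]
    read_set(layout$chrom_names[chrom_i], as.integer(pos5), strand,
             source_label = source_label)
  })
}

scenario_presets <- function() {
  list(
    mbrg_high = list(rho = 0.95, n_replicates = 2L),
    mbrg_low = list(rho = 0.3, n_replicates = 2L),
    mbrg_unequal_depth = list(rho = 0.95, n_replicates = 2L,
                              control_depths = c(1e6, 3e6)),
    mtg = list(rho = 0.9, n_replicates = 4L, treatment_frac = 0.05,
               condition = c(1L, 1L, 2L, 3L)),
    mcg_high = list(rho = 0.9, n_replicates = 2L),
    mcg_low = list(rho = 0.05, n_replicates = 2L),
    lab_effect = list(rho = 0.9, n_replicates = 2L,
                      lab_bias_amplitude = 0.6,
                      lab_biased = c(FALSE, TRUE)))
}

#' Generate a complete synthetic scenario
#'
#' Presets mirror the three sample classes (multiple biological replicates,
#' treatments, cell lines) plus an unequal-depth replicate setting and a lab
#' batch effect:
#'
#' * `mbrg_high` -- biological replicates, shared background (`rho = 0.95`,
#'   comfortably inside the high class).
#' * `mbrg_low` -- replicates with weakly shared background (`rho = 0.3`,
#'   below the 0.6-0.8 decision band).
#' * `mbrg_unequal_depth` -- as `mbrg_high` with control depth ratio 1:3.
#' * `mtg` -- four controls across three treatments, `rho = 0.9`, 5% of bins
#'   perturbed between conditions.
#' * `mcg_high` / `mcg_low` -- different cell lines with similar
#'   (`rho = 0.9`) or essentially independent (`rho = 0.05`) backgrounds.
#' * `lab_effect` -- `rho = 0.9` but the second control carries a smooth
#'   multiplicative lab bias.
#'
#' @param preset one of the names above.
#' @param seed integer seed (overrides the config default).
#' @param out_dir optional directory; when given, gzipped tagAlign files,
#'   a `chrom.sizes` file, a truth-table TSV and a YAML manifest are written.
#'   An existing nonempty directory is refused unless `force = TRUE`.
#' @param config base `ScenarioConfig`; preset fields override it.
#' @param force overwrite a nonempty `out_dir`.
#' @return A `Scenario`: `config`, `layout`, `controls` and `chips` (lists of
#'   `ReadSet`s), `truth` (planted regions), `rates` (bins x samples control
#'   rates), `chip_rates`, `condition`, and output `paths` when written.
#' @export
generate_scenario <- function(preset = names(scenario_presets()),
                              seed = 1L, out_dir = NULL,
                              config = scenario_config(), force = FALSE) {
  preset <- match.arg(preset)
  p <- scenario_presets()[[preset]]
  config$seed <- as.integer(seed)
  for (nm in intersect(names(p), names(config))) config[[nm]] <- p[[nm]]
  config$control_depths <- rep_len(config$control_depths, config$n_replicates)
  config$chip_depths <- rep_len(config$chip_depths, config$n_replicates)
  n <- config$n_replicates
  condition <- if (!is.null(p$condition)) p$condition else rep(1L, n)
  lab_biased <- if (!is.null(p$lab_biased)) p$lab_biased else rep(FALSE, n)
  rates <- draw_background(config, n_samples = n, lab_biased = lab_biased,
                           seed = derive_seed(seed, "bg"))
  rates <- apply_treatment_effect(rates, condition, config, seed = seed)
  planted <- plant_enrichment(rates, config, seed = seed)
  controls <- lapply(seq_len(n), function(i) {
    sample_reads(rates[, i], config$control_depths[i], config$layout,
                 derive_seed(seed, "control", i),
                 source_label = sprintf("control_%d", i))
  })
  chips <- lapply(seq_len(n), function(i) {
    sample_reads(planted$chip_rates[, i], config$chip_depths[i],
                 config$layout, derive_seed(seed, "chip", i),
                 source_label = sprintf("chip_%d", i))
  })
  scen <- structure(list(preset = preset, config = config,
                         layout = config$layout,
                         controls = controls, chips = chips,
                         truth = planted$truth, rates = rates,
                         chip_rates = planted$chip_rates,
                         condition = condition, lab_biased = lab_biased,
                         seed = as.integer(seed), paths = NULL),
                    class = "Scenario")
  if (!is.null(out_dir)) scen$paths <- write_scenario(scen, out_dir, force)
  scen
}

#' @export
print.Scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s' (seed %d): %d control/ChIP pairs, rho = %g, %d planted regions\n",
              x$preset, x$seed, x$config$n_replicates, x$config$rho,
              nrow(x$truth)))
  invisible(x)
}

write_scenario <- function(scen, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !force)
    pc_stop("poolctrl_io",
            "output directory %s exists and is not empty (use force = TRUE)",
            out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  layout <- scen$layout
  paths <- list(chrom_sizes = file.path(out_dir, "chrom.sizes"),
                truth = file.path(out_dir, "truth_regions.tsv"),
                manifest = file.path(out_dir, "manifest.yaml"))
  writeLines(paste(layout$chrom_names, layout$chrom_lengths, sep = "\t"),
             paths$chrom_sizes)
  utils::write.table(scen$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$controls <- vapply(seq_along(scen$controls), function(i) {
    f <- file.path(out_dir, sprintf("control_%d.tagAlign.gz", i))
    write_reads(scen$controls[[i]], f, "tagAlign")
    f
  }, character(1L))
  paths$chips <- vapply(seq_along(scen$chips), function(i) {
    f <- file.path(out_dir, sprintf("chip_%d.tagAlign.gz", i))
    write_reads(scen$chips[[i]], f, "tagAlign")
    f
  }, character(1L))
  cfg <- scen$config
  yaml::write_yaml(list(
    preset = scen$preset, seed = scen$seed,
    rho = cfg$rho, n_replicates = cfg$n_replicates,
    control_depths = cfg$control_depths, chip_depths = cfg$chip_depths,
    bin_width = layout$bin_width,
    chrom_lengths = as.list(layout$chrom_lengths),
    n_regions = cfg$n_regions, region_width = cfg$region_width,
    fold_range = cfg$fold_range,
    treatment_frac = cfg$treatment_frac,
    lab_bias_amplitude = cfg$lab_bias_amplitude,
    files = lapply(paths, as.vector)), paths$manifest)
  paths
}

#' Planted truth regions as a gold-standard RegionSet
#'
#' Ranks the planted regions by fold (a stand-in score), e.g. for recall /
#' precision checks of the baseline caller against simulation truth.
#'
#' @param scen a `Scenario`.
#' @return A ranked `RegionSet`.
#' @export
truth_region_set <- function(scen) {
  stopifnot(inherits(scen, "Scenario"))
  df <- scen$truth
  df$score <- df$fold
  new_region_set(rank_regions(df[, c("chrom", "start", "end", "score")],
                              scen$layout$chrom_names), "truth")
}
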