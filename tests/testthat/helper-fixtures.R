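# Shared fixture builders and independent brute-force oracles.

# Canonical multiset key of a ReadSet: order-independent comparison.
read_key <- function(rs) {
  sort(paste(rs$reads$chrom, rs$reads$pos5, rs$reads$strand, sep = ":"))
}

tiny_layout <- function(nbins = 10L, bin_width = 200L, chroms = "chr1") {
  genome_layout(chroms, rep(nbins * bin_width, length(chroms)), bin_width)
}

# BinCounts built directly from a count vector (bypasses reads; for caller
# fixtures where exact counts matter).
counts_fixture <- function(counts, layout, fragment_length = 150L) {
  nb <- poolctrl::n_bins(layout)
  stopifnot(length(counts) == sum(nb))
  split_counts <- split(as.integer(counts),
                        rep(seq_along(nb), nb))
  names(split_counts) <- layout$chrom_names
  structure(list(layout = layout, counts = split_counts,
                 fragment_length = as.integer(fragment_length),
                 assign = "midpoint", total = sum(counts), skipped = 0L),
            class = "BinCounts")
}

# RegionSet from parallel vectors, ranked by the given scores.
region_fixture <- function(chrom, start, end, score) {
  df <- data.frame(chrom = chrom, start = as.integer(start),
                   end = as.integer(end), score = as.numeric(score),
                   stringsAsFactors = FALSE)
  ord <- order(-df$score, df$chrom, df$start)
  df <- df[ord, ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  structure(list(regions = df, caller_label = "fixture"), class = "RegionSet")
}

# Random disjoint ranked region set on one chromosome.
random_region_set <- function(n, seed, width = 150L, spacing = 400L) {
  set.seed(seed)
  starts <- sort(sample.int(60L, n)) * spacing
  region_fixture("chr1", starts, starts + width, stats::runif(n))
}

# Minimal CorrelationReport from a vector of pairwise correlations, via the
# public TSV round trip.
report_from_r <- function(r, threshold = 0.7) {
  n_pairs <- length(r)
  df <- data.frame(a = sprintf("s%03d_a", seq_len(n_pairs)),
                   b = sprintf("s%03d_b", seq_len(n_pairs)),
                   group = "MBRG", r = r, class = "low", flagged = FALSE)
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  on.exit(unlink(f))
  read_report_tsv(f, threshold = threshold)
}

# --- independent brute-force oracles -------------------------------------

# Two-pass sum-formula Pearson correlation.
bf_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  (n * sxy - sx * sy) /
    (sqrt(n * sxx - sx^2) * sqrt(n * syy - sy^2))
}

bf_norm_euclidean <- function(x, y) {
  p <- x / sum(x); q <- y / sum(y)
  sqrt(sum((p - q)^2))
}

bf_overlaps <- function(a, b) {
  # >= 1 bp overlap of 0-based half-open intervals on the same chromosome
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

bf_ppv <- function(cand, gold) {
  cd <- cand$regions; gd <- gold$regions
  hits <- vapply(seq_len(nrow(cd)), function(i) {
    any(vapply(seq_len(nrow(gd)), function(j) {
      bf_overlaps(cd[i, ], gd[j, ])
    }, logical(1L)))
  }, logical(1L))
  mean(hits)
}

bf_sensitivity <- function(cand, gold, k_grid) {
  cd <- cand$regions[order(cand$regions$rank), ]
  gd <- gold$regions[order(gold$regions$rank), ]
  vapply(k_grid, function(k) {
    nc <- ceiling(k / 100 * nrow(cd))
    ng <- ceiling(k / 100 * nrow(gd))
    ct <- cd[seq_len(nc), , drop = FALSE]
    gt <- gd[seq_len(ng), , drop = FALSE]
    mean(vapply(seq_len(nrow(gt)), function(j) {
      any(vapply(seq_len(nrow(ct)), function(i) {
        bf_overlaps(gt[j, ], ct[i, ])
      }, logical(1L)))
    }, logical(1L)))
  }, numeric(1L))
}

# Small, fast scenario for end-to-end tests: 2-Mb genome (10,000 bins).
small_scenario <- function(preset, seed, depth = 2e5, n_regions = 40L,
                           ...) {
  generate_scenario(preset, seed = seed,
                    config = scenario_config(
                      layout = genome_layout("chrS", 2e6, 200L),
                      control_depths = depth, chip_depths = depth,
                      n_regions = n_regions, ...))
}
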