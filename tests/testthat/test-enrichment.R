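# Baseline two-sample caller, peak import, master lists, restriction.

test_that("identical chip and control yield no peaks on a flat fixture", {
  layout <- genome_layout("chr1", 200000L, 200L)  # 1,000 bins
  flat <- counts_fixture(rep(5L, 1000L), layout)
  peaks <- call_peaks(flat, flat, fdr = 0.05)
  expect_equal(n_regions(peaks), 0L)
  # brute-force check: the per-bin conditional binomial p-value at equal
  # totals is P(Bin(11, 1/2) >= 5) for every bin, far above any BH cut
  p_bin <- pbinom(4, 11, 0.5, lower.tail = FALSE)
  expect_true(min(p.adjust(rep(p_bin, 1000), "BH")) > 0.05)
})

test_that("a single strongly enriched bin is recovered as exactly one region", {
  layout <- genome_layout("chr1", 200000L, 200L)
  chip <- rep(5L, 1000L); ctrl <- rep(5L, 1000L)
  chip[437L] <- 100L; ctrl[437L] <- 1L
  # keep totals equal so the depth ratio is 1: spread the 99-read surplus
  # over the first 99 control bins
  ctrl[1:99] <- ctrl[1:99] + 1L
  peaks <- call_peaks(counts_fixture(chip, layout),
                      counts_fixture(ctrl, layout), fdr = 0.05)
  expect_equal(n_regions(peaks), 1L)
  expect_equal(peaks$regions$start, 436L * 200L)
  expect_equal(peaks$regions$end, 437L * 200L)
})

test_that("degenerate inputs are handled: empty chip, zero control, mismatched layouts", {
  layout <- genome_layout("chr1", 200000L, 200L)
  flat <- counts_fixture(rep(5L, 1000L), layout)
  empty <- counts_fixture(rep(0L, 1000L), layout)
  expect_equal(n_regions(call_peaks(empty, flat)), 0L)
  expect_error(call_peaks(flat, empty), class = "poolctrl_zero_control")
  other <- counts_fixture(rep(5L, 500L), genome_layout("chr1", 100000L, 200L))
  expect_error(call_peaks(flat, other), "layout")
})

test_that("BH selection at a smaller fdr is nested within a larger fdr", {
  set.seed(11)
  layout <- genome_layout("chr1", 400000L, 200L)
  ctrl <- rpois(2000L, 10)
  chip <- rpois(2000L, 10 * exp(rnorm(2000L, 0, 0.3)))
  cb <- counts_fixture(chip, layout); qb <- counts_fixture(ctrl, layout)
  strict <- as_granges(call_peaks(cb, qb, fdr = 0.01, min_gap_bins = 0L))
  loose <- as_granges(call_peaks(cb, qb, fdr = 0.10, min_gap_bins = 0L))
  # every strict region is covered by the loose call
  if (length(strict) > 0) {
    uncovered <- GenomicRanges::setdiff(strict, loose)
    expect_equal(sum(GenomicRanges::width(uncovered)), 0L)
  } else succeed()
})

test_that("caller recovers planted enrichment with high recall and precision", {
  # >= 30 expected background reads/bin, fold >= 8
  recalls <- precisions <- numeric(0)
  for (seed in 1:3) {
    scen <- generate_scenario("mbrg_high", seed = seed,
      config = scenario_config(layout = genome_layout("chrS", 2e6, 200L),
                               control_depths = 3e5, chip_depths = 3e5,
                               n_regions = 40L))
    chip <- bin_counts(scen$chips[[1]], scen$layout)
    ctrl <- bin_counts(scen$controls[[1]], scen$layout)
    peaks <- call_peaks(chip, ctrl, fdr = 0.05)
    truth <- truth_region_set(scen)
    recalls <- c(recalls, ppv(truth, peaks))     # planted regions recovered
    precisions <- c(precisions, ppv(peaks, truth))
  }
  expect_gte(mean(recalls), 0.95)
  expect_gte(mean(precisions), 0.9)
})

test_that("peak recall is monotone non-decreasing in joint sequencing depth", {
  scen <- small_scenario("mbrg_high", seed = 5, depth = 4e5)
  truth <- truth_region_set(scen)
  recall_at <- function(f, seed) {
    chip <- bin_counts(subsample_reads(scen$chips[[1]], f, seed), scen$layout)
    ctrl <- bin_counts(subsample_reads(scen$controls[[1]], f, seed + 1L),
                       scen$layout)
    ppv(truth, call_peaks(chip, ctrl))
  }
  mean_recall <- vapply(c(0.05, 0.25, 1.0), function(f) {
    mean(vapply(1:3, function(s) recall_at(f, 100L * s), numeric(1L)))
  }, numeric(1L))
  expect_true(all(diff(mean_recall) >= -1e-9))
})

test_that("imported peaks merge overlaps keeping the maximum score", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tp1\t5",
               "chr1\t50\t150\tp2\t9",
               "chr2\t0\t80\tp3\t2"), f)
  set <- import_peaks(f)
  expect_equal(n_regions(set), 2L)
  top <- set$regions[set$regions$rank == 1L, ]
  expect_equal(top$score, 9)
  expect_equal(c(top$start, top$end), c(0L, 150L))
  # missing score column is a named error
  g <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100", g)
  expect_error(import_peaks(g), "column 5")
})

test_that("master lists merge overlapping and book-ended intervals", {
  a <- region_fixture("chr1", 0L, 100L, 1)
  b <- region_fixture("chr1", 50L, 150L, 2)
  m <- build_master_list(list(a, b))
  expect_equal(m$regions$start, 0L)
  expect_equal(m$regions$end, 150L)
  # book-ended intervals merge; disjoint inputs pass through
  c2 <- region_fixture("chr1", c(150L, 400L), c(200L, 500L), c(1, 2))
  m2 <- build_master_list(list(b, c2))
  expect_equal(nrow(m2$regions), 2L)
  expect_equal(m2$regions$end[1], 200L)
  single <- build_master_list(list(c2))
  expect_equal(nrow(single$regions), 2L)
  expect_null(single$regions$score)
})

test_that("count restriction selects the same bins for every sample", {
  layout <- tiny_layout(nbins = 10L)
  master <- structure(list(regions = data.frame(
    chrom = "chr1", start = 600L, end = 1200L)), class = "MasterList")
  # master covers bins 4-6 exactly
  x <- counts_fixture(1:10, layout)
  expect_equal(restrict_counts(x, master), c(4, 5, 6))
  # a region straddling a bin boundary pulls in both bins
  straddle <- structure(list(regions = data.frame(
    chrom = "chr1", start = 150L, end = 250L)), class = "MasterList")
  expect_equal(restrict_counts(x, straddle), c(1, 2))
  # same index set regardless of the counts
  y <- counts_fixture(rep(7L, 10L), layout)
  expect_equal(master_bin_indices(layout, master),
               master_bin_indices(layout, master))
  expect_length(restrict_counts(y, master), 3L)
  empty <- structure(list(regions = data.frame(
    chrom = character(), start = integer(), end = integer())),
    class = "MasterList")
  expect_warning(v <- restrict_counts(x, empty), "no bins")
  expect_length(v, 0L)
})
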