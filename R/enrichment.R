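# Ranked ChIP-enriched region lists and master lists.
#
# The built-in caller is a deliberately simple two-sample model: scaled
# control counts define a Poisson background expectation per bin, upper-tail
# p-values are corrected by Benjamini-Hochberg, and significant bins are
# merged into regions ranked by -log10 of their best bin p-value.  It
# preserves the one property the pooling framework needs -- a ranked peak
# list whose quality depends on control depth -- while externally produced
# peak lists (e.g. MOSAiCS or SPP output) plug in via import_peaks().

new_region_set <- function(df, caller_label) {
  rownames(df) <- NULL
  structure(list(regions = df, caller_label = caller_label),
            class = "RegionSet")
}

#' Number of regions in a RegionSet
#' @param set a `RegionSet`.
#' @return Integer count.
#' @export
n_regions <- function(set) nrow(set$regions)

#' @export
print.RegionSet <- function(x, ...) {
  cat(sprintf("RegionSet (%s): %d ranked regions\n",
              x$caller_label, n_regions(x)))
  invisible(x)
}

#' RegionSet / MasterList intervals as a GRanges
#' @param x a `RegionSet` or `MasterList`.
#' @return A `GRanges` (1-based) carrying `score` and `rank` metadata when
#'   present.
#' @export
as_granges <- function(x) {
  df <- x$regions
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  if (!is.null(df$score)) S4Vectors::mcols(gr)$score <- df$score
  if (!is.null(df$rank)) S4Vectors::mcols(gr)$rank <- df$rank
  gr
}

rank_regions <- function(df, chrom_order = NULL) {
  if (nrow(df) == 0L) {
    df$rank <- integer(0)
    return(df)
  }
  co <- if (is.null(chrom_order)) sort(unique(df$chrom)) else chrom_order
  ord <- order(-df$score, match(df$chrom, co), df$start)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Call ChIP-enriched regions from binned ChIP and control counts
#'
#' Per bin with ChIP count `x` and control count `y`, enrichment is tested
#' with the exact conditional binomial test for the ratio of two Poisson
#' rates: under the null the ChIP count given the bin total is
#' `Binomial(x + y + pseudocount, t / (1 + t))` with
#' `t = chip$total / control$total`, and the p-value is the upper tail at
#' `x`.  Conditioning accounts for the sampling noise of the control itself
#' (a scaled-control Poisson expectation does not, and is anti-conservative
#' at realistic control depths).  Benjamini-Hochberg at `fdr` selects bins;
#' selected bins
#' separated by at most `min_gap_bins` non-selected bins are merged into one
#' region whose score is `-log10` of the minimum constituent bin p-value.
#' Regions are ranked by score descending, ties broken by chromosome order
#' then start.
#'
#' @param chip,control `BinCounts` on the same layout and fragment length.
#' @param fdr Benjamini-Hochberg false discovery rate (default 0.05).
#' @param pseudocount integer added to each bin's control count (default 1),
#'   so a zero-control bin still has a finite background.
#' @param min_gap_bins merge selected bins separated by at most this many
#'   non-selected bins (default 1).
#' @return A ranked `RegionSet` with `caller_label = "baseline"`.
#' @export
call_peaks <- function(chip, control, fdr = 0.05, pseudocount = 1,
                       min_gap_bins = 1L) {
  stopifnot(inherits(chip, "BinCounts"), inherits(control, "BinCounts"))
  if (!same_layout(chip$layout, control$layout))
    pc_stop("poolctrl_bad_arg", "chip and control layouts differ")
  if (chip$fragment_length != control$fragment_length)
    pc_stop("poolctrl_bad_arg", "chip and control fragment lengths differ")
  if (control$total == 0)
    pc_stop("poolctrl_zero_control",
            "control has zero assigned reads; supply a deeper control or use a pseudocount-only background explicitly")
  if (pseudocount <= 0)
    pc_stop("poolctrl_bad_arg", "pseudocount must be > 0")
  layout <- chip$layout
  empty <- new_region_set(
    data.frame(chrom = character(), start = integer(), end = integer(),
               score = numeric(), rank = integer(), stringsAsFactors = FALSE),
    "baseline")
  if (chip$total == 0) return(empty)
  x <- flatten_counts(chip)
  y <- flatten_counts(control)
  t_ratio <- chip$total / control$total
  q <- t_ratio / (1 + t_ratio)
  p <- stats::pbinom(x - 1L, x + y + round(pseudocount), q,
                     lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = "BH")
  sel <- padj <= fdr
  if (!any(sel)) return(empty)
  nb <- n_bins(layout)
  offs <- c(0L, cumsum(nb))
  w <- layout$bin_width
  out <- list()
  for (i in seq_along(layout$chrom_names)) {
    chrom <- layout$chrom_names[i]
    idx <- which(sel[(offs[i] + 1L):offs[i + 1L]])
    if (length(idx) == 0L) next
    grp <- cumsum(c(1L, as.integer(diff(idx) > min_gap_bins + 1L)))
    len <- layout$chrom_lengths[[chrom]]
    pv <- p[offs[i] + idx]
    out[[chrom]] <- do.call(rbind, lapply(split(seq_along(idx), grp), function(j) {
      b1 <- idx[j[1L]]
      b2 <- idx[j[length(j)]]
      data.frame(chrom = chrom,
                 start = (b1 - 1L) * w,
                 end = min(b2 * w, len),
                 score = -log10(max(min(pv[j]), 1e-300)),
                 stringsAsFactors = FALSE)
    }))
  }
  df <- do.call(rbind, out)
  new_region_set(rank_regions(df, layout$chrom_names), "baseline")
}

#' Import an externally produced peak list from a BED file
#'
#' Overlapping intervals are merged keeping the maximum score, then regions
#' are ranked by score descending.
#'
#' @param path BED file (0-based half-open), at least `score_column` columns.
#' @param score_column 1-based index of the score column (default 5, the BED
#'   score field).
#' @return A ranked `RegionSet` with `caller_label = "imported"`.
#' @export
import_peaks <- function(path, score_column = 5L) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < score_column)
    pc_stop("poolctrl_parse",
            "peak file %s has %d columns; score column %d not present",
            path, ncol(tab), score_column)
  sc <- suppressWarnings(as.numeric(tab[[score_column]]))
  if (anyNA(sc))
    pc_stop("poolctrl_parse", "non-numeric score in column %d of %s",
            score_column, path)
  gr <- GenomicRanges::GRanges(tab[[1L]],
                               IRanges::IRanges(tab[[2L]] + 1L, tab[[3L]]))
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L, with.revmap = TRUE)
  score <- vapply(S4Vectors::mcols(red)$revmap, function(i) max(sc[i]),
                  numeric(1L))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                   start = GenomicRanges::start(red) - 1L,
                   end = GenomicRanges::end(red),
                   score = score, stringsAsFactors = FALSE)
  new_region_set(rank_regions(df), "imported")
}

#' Build a master list of ChIP-enriched regions
#'
#' The master list is the union of the intervals of all input peak sets with
#' overlapping or book-ended intervals merged; it defines which genome bins
#' enter the control-similarity calculation.
#'
#' @param sets nonempty list of `RegionSet`s.
#' @return A `MasterList`: pairwise-disjoint unscored intervals sorted by
#'   coordinate.
#' @export
build_master_list <- function(sets) {
  if (!is.list(sets) || length(sets) == 0L)
    pc_stop("poolctrl_bad_arg", "sets must be a nonempty list of RegionSet")
  grs <- lapply(sets, as_granges)
  # reduce() merges overlapping and book-ended intervals and returns them
  # sorted by coordinate within each chromosome
  red <- GenomicRanges::reduce(do.call(c, lapply(grs, function(g) {
    S4Vectors::mcols(g) <- NULL
    g
  })))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                   start = GenomicRanges::start(red) - 1L,
                   end = GenomicRanges::end(red), stringsAsFactors = FALSE)
  structure(list(regions = df), class = "MasterList")
}

#' @export
print.MasterList <- function(x, ...) {
  cat(sprintf("MasterList: %d disjoint regions, %g bp\n", nrow(x$regions),
              sum(x$regions$end - x$regions$start)))
  invisible(x)
}

#' Indices of layout bins overlapping a master list
#'
#' A bin qualifies with >= 1 bp overlap, so the selected index set depends
#' only on the layout and master list -- every sample sharing the layout gets
#' the same bins, keeping count vectors aligned across samples.
#'
#' @param layout a `GenomeLayout`.
#' @param master a `MasterList`.
#' @return Integer indices into the genome-order flattened bin vector.
#' @export
master_bin_indices <- function(layout, master) {
  stopifnot(inherits(layout, "GenomeLayout"), inherits(master, "MasterList"))
  nb <- n_bins(layout)
  offs <- c(0L, cumsum(nb))
  idx <- integer(0)
  for (i in seq_along(layout$chrom_names)) {
    chrom <- layout$chrom_names[i]
    mr <- master$regions[master$regions$chrom == chrom, , drop = FALSE]
    if (nrow(mr) == 0L) next
    hits <- IRanges::countOverlaps(chrom_bins_iranges(layout, chrom),
                                   IRanges::IRanges(mr$start + 1L, mr$end))
    idx <- c(idx, offs[i] + which(hits > 0L))
  }
  idx
}

#' Restrict bin counts to master-list bins
#'
#' @param bins a `BinCounts`.
#' @param master a `MasterList`.
#' @return Numeric vector of the counts of every bin overlapping a master
#'   region by >= 1 bp, concatenated in genome order.  An empty master list
#'   yields an empty vector with a warning.
#' @export
restrict_counts <- function(bins, master) {
  stopifnot(inherits(bins, "BinCounts"))
  idx <- master_bin_indices(bins$layout, master)
  if (length(idx) == 0L) {
    warning("master list selects no bins; returning an empty vector")
    return(numeric(0))
  }
  flatten_counts(bins)[idx]
}

#' Write a RegionSet or MasterList as BED
#'
#' Region sets are written as BED5 (name = rank); master lists as BED3.
#'
#' @param x a `RegionSet` or `MasterList`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- x$regions
  lines <- if (inherits(x, "RegionSet") && nrow(df) > 0L) {
    paste(df$chrom, df$start, df$end, paste0("peak_", df$rank),
          signif(df$score, 6L), sep = "\t")
  } else if (nrow(df) > 0L) {
    paste(df$chrom, df$start, df$end, sep = "\t")
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}
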