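# Mapped-read I/O, genome binning, subsampling and pooling.
#
# Reads are uniquely mapped single-end tags represented by their chromosome,
# 0-based 5' coordinate and strand.  All interval arithmetic in this file is
# 0-based half-open; the 5' end of a minus-strand alignment [start, end) is
# end - 1.

#' Genome layout: chromosomes tiled by fixed-width bins
#'
#' @param chrom_names character vector of chromosome identifiers.
#' @param chrom_lengths integer vector of chromosome lengths in bp.
#' @param bin_width bin width in bp (default 200, the standard ChIP-seq
#'   bin size).
#' @return A `GenomeLayout` object.  Bins are contiguous, non-overlapping and
#'   tile each chromosome; chromosome `i` has `ceiling(length / bin_width)`
#'   bins.
#' @export
genome_layout <- function(chrom_names, chrom_lengths, bin_width = 200L) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.integer(chrom_lengths)
  bin_width <- as.integer(bin_width)
  if (length(chrom_names) == 0L || length(chrom_names) != length(chrom_lengths))
    pc_stop("poolctrl_bad_layout", "chrom_names and chrom_lengths must be equal-length, nonempty")
  if (anyDuplicated(chrom_names))
    pc_stop("poolctrl_bad_layout", "duplicated chromosome names")
  if (any(chrom_lengths <= 0L) || bin_width <= 0L)
    pc_stop("poolctrl_bad_layout", "chromosome lengths and bin_width must be > 0")
  structure(list(chrom_names = chrom_names,
                 chrom_lengths = stats::setNames(chrom_lengths, chrom_names),
                 bin_width = bin_width),
            class = "GenomeLayout")
}

#' Read a UCSC chrom.sizes file into a GenomeLayout
#'
#' @param path two-column whitespace-separated file: chromosome, length.
#' @param bin_width bin width in bp.
#' @return A `GenomeLayout`.
#' @export
read_chrom_sizes <- function(path, bin_width = 200L) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "size"))
  genome_layout(tab$chrom, tab$size, bin_width)
}

#' Number of bins per chromosome of a layout
#' @param layout a `GenomeLayout`.
#' @return Named integer vector.
#' @export
n_bins <- function(layout) {
  stopifnot(inherits(layout, "GenomeLayout"))
  as.integer(ceiling(layout$chrom_lengths / layout$bin_width)) |>
    stats::setNames(layout$chrom_names)
}

# Bins of one chromosome as a 1-based IRanges (bin b covers
# [(b-1)*w, min(b*w, len)) in 0-based half-open coordinates).
chrom_bins_iranges <- function(layout, chrom) {
  w <- layout$bin_width
  len <- layout$chrom_lengths[[chrom]]
  nb <- as.integer(ceiling(len / w))
  starts <- (seq_len(nb) - 1L) * w + 1L
  ends <- pmin(seq_len(nb) * w, len)
  IRanges::IRanges(start = starts, end = ends)
}

#' Construct a ReadSet
#'
#' A `ReadSet` is a multiset of uniquely mapped single-end reads, the unit of
#' subsampling and pooling.  `depth` always equals the number of reads.
#'
#' @param chrom character vector of chromosome ids.
#' @param pos5 integer vector of 0-based 5' coordinates.
#' @param strand character vector, `"+"` or `"-"`.
#' @param source_label free-text provenance.
#' @return A `ReadSet`.
#' @export
read_set <- function(chrom = character(), pos5 = integer(),
                     strand = character(), source_label = "") {
  n <- length(pos5)
  if (length(chrom) != n || length(strand) != n)
    pc_stop("poolctrl_bad_reads", "chrom, pos5, strand must have equal length")
  if (n > 0L && !all(strand %in% c("+", "-")))
    pc_stop("poolctrl_bad_reads", "strand must be '+' or '-'")
  structure(list(reads = data.frame(chrom = as.character(chrom),
                                    pos5 = as.integer(pos5),
                                    strand = as.character(strand),
                                    stringsAsFactors = FALSE),
                 depth = n,
                 source_label = as.character(source_label)[1L]),
            class = "ReadSet")
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet '%s': %d reads on %d chromosome(s)\n",
              x$source_label, x$depth, length(unique(x$reads$chrom))))
  invisible(x)
}

#' Load mapped reads from a tagAlign or BED6 file
#'
#' Both formats are 6-column, 0-based half-open.  Plus-strand reads get
#' `pos5 = start`; minus-strand reads get `pos5 = end - 1`.  Gzipped files
#' (`.gz`) are read transparently.
#'
#' @param path file path.
#' @param fmt `"tagAlign"` or `"bed6"` (identical column geometry; kept
#'   separate for provenance).
#' @return A `ReadSet` with `depth` equal to the number of records; an empty
#'   file yields an empty `ReadSet`.
#' @export
load_reads <- function(path, fmt = c("tagAlign", "bed6")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path))
    pc_stop("poolctrl_io", "file not found: %s", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(read_set(source_label = basename(path)))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 6L))
    pc_stop("poolctrl_parse",
            "malformed line %d in %s: expected 6 fields, got %d",
            which(nf != 6L)[1L], path, nf[nf != 6L][1L])
  m <- matrix(unlist(fields, use.names = FALSE), ncol = 6L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad))
    pc_stop("poolctrl_parse", "malformed line %d in %s: bad coordinates",
            bad[1L], path)
  strand <- m[, 6L]
  bads <- which(!strand %in% c("+", "-"))
  if (length(bads))
    pc_stop("poolctrl_parse", "malformed line %d in %s: strand '%s'",
            bads[1L], path, strand[bads[1L]])
  pos5 <- ifelse(strand == "+", start, end - 1L)
  read_set(m[, 1L], pos5, strand, source_label = basename(path))
}

#' Write a ReadSet as tagAlign or BED6
#'
#' Records are written with a nominal read length so that a round trip through
#' [load_reads()] reproduces the read multiset exactly (the 5' coordinate and
#' strand are the invariants; the 3' coordinate is nominal).
#'
#' @param rs a `ReadSet`.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param fmt `"tagAlign"` or `"bed6"`.
#' @param read_length nominal read length in bp (default 36).
#' @return `path`, invisibly.
#' @export
write_reads <- function(rs, path, fmt = c("tagAlign", "bed6"),
                        read_length = 36L) {
  fmt <- match.arg(fmt)
  stopifnot(inherits(rs, "ReadSet"), read_length >= 1L)
  r <- rs$reads
  plus <- r$strand == "+"
  start <- ifelse(plus, r$pos5, pmax(0L, r$pos5 + 1L - as.integer(read_length)))
  end <- ifelse(plus, r$pos5 + as.integer(read_length), r$pos5 + 1L)
  name <- if (fmt == "tagAlign") "N" else "read"
  score <- if (fmt == "tagAlign") 1000L else 0L
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  if (nrow(r) > 0L) {
    writeLines(paste(r$chrom, start, end, name, score, r$strand, sep = "\t"),
               con)
  }
  invisible(path)
}

#' Count fragment-extended reads in genome bins
#'
#' Each read is extended from its 5' end in the strand direction to
#' `fragment_length` bases.  Under the default `"midpoint"` rule the fragment
#' is assigned to exactly the bin containing its midpoint (clamped to the
#' chromosome), so the counts conserve reads: `sum(counts) + skipped = depth`.
#' The alternative `"overlap"` rule adds one count to every bin the fragment
#' overlaps and does not conserve reads.
#'
#' @param rs a `ReadSet`.
#' @param layout a `GenomeLayout`.
#' @param fragment_length average fragment length in bp used for extension
#'   (default 150).
#' @param assign `"midpoint"` (default) or `"overlap"`.
#' @return A `BinCounts` object: per-chromosome integer count vectors plus
#'   `total` (reads assigned) and `skipped` (reads on chromosomes absent from
#'   the layout).
#' @export
bin_counts <- function(rs, layout, fragment_length = 150L,
                       assign = c("midpoint", "overlap")) {
  assign <- match.arg(assign)
  stopifnot(inherits(rs, "ReadSet"), inherits(layout, "GenomeLayout"))
  fragment_length <- as.integer(fragment_length)
  if (fragment_length < 1L)
    pc_stop("poolctrl_bad_arg", "fragment_length must be >= 1")
  w <- layout$bin_width
  nb <- n_bins(layout)
  counts <- lapply(nb, integer)
  r <- rs$reads
  known <- r$chrom %in% layout$chrom_names
  skipped <- sum(!known)
  r <- r[known, , drop = FALSE]
  # fragment [fs, fe) in 0-based half-open coordinates
  plus <- r$strand == "+"
  fs <- ifelse(plus, r$pos5, r$pos5 + 1L - fragment_length)
  fe <- fs + fragment_length
  for (chrom in unique(r$chrom)) {
    sel <- r$chrom == chrom
    len <- layout$chrom_lengths[[chrom]]
    if (assign == "midpoint") {
      mid <- (fs[sel] + fe[sel]) %/% 2L
      mid <- pmin(pmax(mid, 0L), len - 1L)
      b <- mid %/% w + 1L
      counts[[chrom]] <- tabulate(b, nbins = nb[[chrom]])
    } else {
      cs <- pmax(fs[sel], 0L)
      ce <- pmin(fe[sel], len)
      frag <- IRanges::IRanges(start = cs + 1L, end = pmax(ce, cs + 1L))
      counts[[chrom]] <-
        IRanges::countOverlaps(chrom_bins_iranges(layout, chrom), frag)
    }
  }
  structure(list(layout = layout,
                 counts = counts,
                 fragment_length = fragment_length,
                 assign = assign,
                 total = if (assign == "midpoint") nrow(r)
                         else sum(vapply(counts, sum, numeric(1L))),
                 skipped = skipped),
            class = "BinCounts")
}

#' @export
print.BinCounts <- function(x, ...) {
  cat(sprintf("BinCounts: %d bins x %d bp, %g reads assigned (%d skipped)\n",
              sum(n_bins(x$layout)), x$layout$bin_width, x$total, x$skipped))
  invisible(x)
}

#' Flatten per-chromosome bin counts into one genome-order vector
#' @param bc a `BinCounts`.
#' @return Numeric vector of all bin counts in layout chromosome order.
#' @export
flatten_counts <- function(bc) {
  unlist(bc$counts[bc$layout$chrom_names], use.names = FALSE)
}

same_layout <- function(a, b) {
  identical(a$chrom_names, b$chrom_names) &&
    identical(as.integer(a$chrom_lengths), as.integer(b$chrom_lengths)) &&
    a$bin_width == b$bin_width
}

#' Randomly subsample a ReadSet without replacement
#'
#' Draws exactly `round(fraction * depth)` reads (round half to even, so
#' repeat counts are deterministic) uniformly without replacement.  The same
#' seed always reproduces the same subsample.
#'
#' @param rs a nonempty `ReadSet`.
#' @param fraction proportion in (0, 1].
#' @param seed integer seed for this draw.
#' @return A `ReadSet` that is a sub-multiset of `rs`.
#' @export
subsample_reads <- function(rs, fraction, seed) {
  stopifnot(inherits(rs, "ReadSet"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    pc_stop("poolctrl_bad_arg", "fraction must be in (0, 1]")
  if (rs$depth == 0L)
    pc_stop("poolctrl_bad_arg", "cannot subsample an empty ReadSet")
  n_keep <- as.integer(round_half_even(fraction * rs$depth))
  subsample_n(rs, n_keep, seed)
}

#' Subsample a ReadSet to an exact read count
#'
#' @param rs a `ReadSet`.
#' @param n number of reads to draw without replacement (`0 <= n <= depth`).
#' @param seed integer seed.
#' @return A `ReadSet` of exactly `n` reads.
#' @export
subsample_n <- function(rs, n, seed) {
  stopifnot(inherits(rs, "ReadSet"))
  n <- as.integer(n)
  if (n < 0L || n > rs$depth)
    pc_stop("poolctrl_bad_arg", "n must be in [0, depth]")
  idx <- sort(with_seed(seed, sample.int(rs$depth, n)))
  out <- rs$reads[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(reads = out, depth = n,
                 source_label = sprintf("%s[%d/%d@%d]", rs$source_label, n,
                                        rs$depth, as.integer(seed))),
            class = "ReadSet")
}

#' Pool reads of several samples in silico
#'
#' Pooling simply combines the reads of the parts: the output multiset is the
#' multiset union, and `depth` is the sum of the part depths.  The order of
#' parts does not affect the multiset.
#'
#' @param parts nonempty list of `ReadSet`s.
#' @param source_label label for the pooled set.
#' @return A pooled `ReadSet`.
#' @export
pool_reads <- function(parts, source_label = "pooled") {
  if (!is.list(parts) || length(parts) == 0L ||
      !all(vapply(parts, inherits, logical(1L), "ReadSet")))
    pc_stop("poolctrl_bad_arg", "parts must be a nonempty list of ReadSet")
  reads <- do.call(rbind, lapply(parts, `[[`, "reads"))
  rownames(reads) <- NULL
  structure(list(reads = reads, depth = nrow(reads),
                 source_label = source_label),
            class = "ReadSet")
}
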