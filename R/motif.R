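# PWM motif scanning of peak sequences with exact score p-values.
#
# Scores are log2 odds of the motif model against a zero-order background.
# The score threshold for a given p-value is computed exactly by dynamic
# programming over the discretized score distribution (bin width 1e-3 bits),
# i.e. by convolving the per-position score distributions under the
# background model -- no Monte-Carlo or Gaussian approximation.

PWM_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix from counts or probabilities
#'
#' @param mat 4 x W numeric matrix (rows A, C, G, T).  Counts are converted
#'   to probabilities column-wise with `pseudocount` added to every cell.
#' @param id motif identifier.
#' @param background nucleotide background probabilities (A, C, G, T);
#'   default uniform.
#' @param pseudocount added to counts before normalization (default 1e-4).
#' @return A `PWM` object with per-position probabilities summing to 1.
#' @export
pwm <- function(mat, id = "motif", background = rep(0.25, 4),
                pseudocount = 1e-4) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L)
    pc_stop("poolctrl_bad_arg", "PWM must have 4 rows (A, C, G, T)")
  if (any(mat < 0))
    pc_stop("poolctrl_bad_arg", "PWM entries must be nonnegative")
  if (abs(sum(background) - 1) > 1e-9 || any(background <= 0))
    pc_stop("poolctrl_bad_arg", "background must be positive and sum to 1")
  probs <- apply(mat + pseudocount, 2L, function(col) col / sum(col))
  rownames(probs) <- PWM_BASES
  structure(list(id = id, matrix = probs,
                 background = stats::setNames(background, PWM_BASES)),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM '%s': width %d, consensus %s\n", x$id, ncol(x$matrix),
              paste(PWM_BASES[apply(x$matrix, 2L, which.max)],
                    collapse = "")))
  invisible(x)
}

#' Read a JASPAR-style count matrix
#'
#' Accepts the raw JASPAR format: an optional `>ID name` header followed by
#' four rows, each optionally prefixed with the base letter and with counts
#' optionally wrapped in brackets, e.g. `A [ 3 21 25 ... ]`.
#'
#' @param path file path.
#' @param ... passed to [pwm()].
#' @return A `PWM`.
#' @export
read_jaspar <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  id <- "motif"
  if (length(lines) && startsWith(lines[1L], ">")) {
    id <- strsplit(sub("^>", "", lines[1L]), "[ \t]+")[[1L]][1L]
    lines <- lines[-1L]
  }
  if (length(lines) < 4L)
    pc_stop("poolctrl_parse", "JASPAR matrix needs 4 count rows")
  rows <- lapply(lines[1:4], function(l) {
    l <- gsub("^[ACGTacgt][ \t:]*", "", l)
    l <- gsub("[][]", " ", l)
    as.numeric(strsplit(trimws(l), "[ \t]+")[[1L]])
  })
  w <- unique(lengths(rows))
  if (length(w) != 1L)
    pc_stop("poolctrl_parse", "JASPAR rows have unequal widths")
  pwm(do.call(rbind, rows), id = id, ...)
}

# Integer (milli-bit) log-odds score matrix of a PWM.
pwm_int_scores <- function(p, bin_bits = 1e-3) {
  round(log2(p$matrix / p$background) / bin_bits)
}

#' Exact score distribution threshold for a PWM p-value
#'
#' Computes the distribution of the log-odds score of a random background
#' sequence by dynamic programming over the discretized scores and returns
#' the smallest score whose upper-tail probability is at most `p_threshold`,
#' together with the attained tail probability.
#'
#' @param p a `PWM`.
#' @param p_threshold p-value threshold (default 0.01).
#' @param bin_bits discretization bin width in bits (default 1e-3).
#' @return List with `score` (threshold in bits), `score_int` (in bins) and
#'   `attained_p` (exact tail probability at the threshold).
#' @export
motif_score_threshold <- function(p, p_threshold = 0.01, bin_bits = 1e-3) {
  stopifnot(inherits(p, "PWM"))
  if (p_threshold <= 0 || p_threshold > 1)
    pc_stop("poolctrl_bad_arg", "p_threshold must be in (0, 1]")
  s <- pwm_int_scores(p, bin_bits)
  lo <- sum(apply(s, 2L, min))
  hi <- sum(apply(s, 2L, max))
  # dist[i] = P(partial score == lo_partial + i - 1) under the background
  dist <- 1
  off <- 0L
  for (j in seq_len(ncol(s))) {
    cmin <- min(s[, j])
    new <- numeric(length(dist) + max(s[, j]) - cmin)
    for (b in 1:4) {
      sh <- s[b, j] - cmin
      new[(1L + sh):(length(dist) + sh)] <-
        new[(1L + sh):(length(dist) + sh)] + dist * p$background[b]
    }
    dist <- new
    off <- off + cmin
  }
  tail_p <- rev(cumsum(rev(dist)))
  scores_int <- off + seq_along(dist) - 1L
  ok <- which(tail_p <= p_threshold)
  if (length(ok) == 0L) {
    # even the maximal score is more probable than p_threshold
    idx <- length(scores_int)
  } else {
    idx <- ok[1L]
  }
  list(score = scores_int[idx] * bin_bits,
       score_int = scores_int[idx],
       attained_p = tail_p[idx])
}

seq_to_idx <- function(s) {
  match(strsplit(toupper(s), "")[[1L]], PWM_BASES)
}

# Max integer log-odds score over all windows of one strand; NA windows
# (containing non-ACGT) are skipped.  Returns -Inf when no valid window.
max_window_score <- function(idx, s_int) {
  w <- ncol(s_int)
  L <- length(idx)
  if (L < w) return(-Inf)
  n_win <- L - w + 1L
  tot <- numeric(n_win)
  for (j in seq_len(w)) {
    v <- s_int[, j][idx[j:(j + n_win - 1L)]]
    tot <- tot + v
  }
  if (all(is.na(tot))) -Inf else max(tot, na.rm = TRUE)
}

#' Scan peak sequences for PWM occurrences at an exact p-value threshold
#'
#' Scores every position of every peak on both strands with the PWM log-odds
#' score and flags peaks containing at least one position scoring at or
#' above the threshold corresponding to `p_threshold` under the background
#' model (see [motif_score_threshold()]).
#'
#' @param peaks a nonempty `RegionSet` with coordinates within the genome.
#' @param genome a `Biostrings::DNAStringSet` (names = chromosomes) or a
#'   FASTA file path.
#' @param p a `PWM`.
#' @param p_threshold score p-value threshold (default 0.01).
#' @param max_n_frac peaks whose sequence exceeds this fraction of `N` bases
#'   are excluded from the denominator (default 0.5) and reported.
#' @return A `MotifScan`: per-peak logical `hit`, the `occurrence_rate`
#'   (fraction of scanned peaks with >= 1 hit), the score threshold used and
#'   the indices of excluded peaks.
#' @export
scan_motif <- function(peaks, genome, p, p_threshold = 0.01,
                       max_n_frac = 0.5) {
  stopifnot(inherits(peaks, "RegionSet"), inherits(p, "PWM"))
  if (n_regions(peaks) == 0L)
    pc_stop("poolctrl_bad_arg", "empty peak set")
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("[ \t].*$", "", names(genome))
  df <- peaks$regions
  missing <- setdiff(unique(df$chrom), names(genome))
  if (length(missing))
    pc_stop("poolctrl_bad_arg", "chromosome(s) absent from genome: %s",
            paste(missing, collapse = ", "))
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  if (any(df$end > lens[df$chrom]))
    pc_stop("poolctrl_bad_arg", "peak extends beyond its chromosome")
  thr <- motif_score_threshold(p, p_threshold)
  s_int <- pwm_int_scores(p)
  s_int_rc <- s_int[4:1, rev(seq_len(ncol(s_int))), drop = FALSE]
  seqs <- as.character(Biostrings::subseq(genome[df$chrom],
                                          start = df$start + 1L,
                                          end = df$end))
  hit <- logical(nrow(df))
  excluded <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    idx <- seq_to_idx(seqs[i])
    if (mean(is.na(idx)) > max_n_frac) {
      excluded[i] <- TRUE
      next
    }
    best <- max(max_window_score(idx, s_int), max_window_score(idx, s_int_rc))
    hit[i] <- is.finite(best) && best >= thr$score_int
  }
  scanned <- !excluded
  structure(list(hit = hit, excluded = which(excluded),
                 occurrence_rate = mean(hit[scanned]),
                 n_scanned = sum(scanned),
                 threshold_score_bits = thr$score,
                 attained_p = thr$attained_p,
                 pwm_id = p$id),
            class = "MotifScan")
}

#' @export
print.MotifScan <- function(x, ...) {
  cat(sprintf("MotifScan [%s]: %d/%d peaks with >= 1 occurrence (rate %.3f), threshold %.3f bits (p = %.4g)\n",
              x$pwm_id, sum(x$hit), x$n_scanned, x$occurrence_rate,
              x$threshold_score_bits, x$attained_p))
  invisible(x)
}
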