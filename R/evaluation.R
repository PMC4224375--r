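# Peak-set comparison against gold standards: top-k% rank-overlap
# sensitivity curves, positive predictive value and experiment summaries.

# countOverlaps over a shared seqlevel universe (avoids spurious warnings
# when candidate and gold live on different chromosomes).
count_hits <- function(query, subject, min_overlap) {
  lv <- union(GenomicRanges::seqnames(GenomicRanges::seqinfo(query)),
              GenomicRanges::seqnames(GenomicRanges::seqinfo(subject)))
  GenomeInfoDb::seqlevels(query) <- lv
  GenomeInfoDb::seqlevels(subject) <- lv
  GenomicRanges::countOverlaps(query, subject, minoverlap = min_overlap)
}

#' Top-k% rank-overlap sensitivity curve
#'
#' For each `k` in the grid, both peak sets are truncated to their top
#' `ceiling(k% * N)` peaks by rank, and the sensitivity is the fraction of
#' truncated gold peaks overlapped (>= `min_overlap` bp) by at least one
#' truncated candidate peak.  The symmetric truncation measures whether the
#' candidate identifies peaks in the same rank order as the gold standard;
#' `mode = "candidate_only"` instead keeps the full gold set as denominator.
#'
#' @param candidate,gold ranked `RegionSet`s; `gold` must be nonempty.
#' @param k_grid percentages (default `seq(5, 100, by = 5)`).
#' @param mode `"symmetric"` (default) truncates both sets;
#'   `"candidate_only"` truncates only the candidate.
#' @param min_overlap minimum overlap in bp to count a hit (default 1).
#' @return An `OverlapCurve`: `k_grid`, `sensitivity` per k (in `[0, 1]`),
#'   `n_repeats = 1`.
#' @export
overlap_sensitivity <- function(candidate, gold, k_grid = seq(5, 100, by = 5),
                                mode = c("symmetric", "candidate_only"),
                                min_overlap = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(candidate, "RegionSet"), inherits(gold, "RegionSet"))
  if (n_regions(gold) == 0L)
    pc_stop("poolctrl_bad_arg", "gold standard peak set is empty")
  if (any(k_grid <= 0 | k_grid > 100))
    pc_stop("poolctrl_bad_arg", "k_grid values must be in (0, 100]")
  if (n_regions(candidate) == 0L) {
    return(structure(list(k_grid = k_grid,
                          sensitivity = rep(0, length(k_grid)),
                          n_repeats = 1L), class = "OverlapCurve"))
  }
  cg <- as_granges(candidate)
  gg <- as_granges(gold)
  cg <- cg[order(S4Vectors::mcols(cg)$rank)]
  gg <- gg[order(S4Vectors::mcols(gg)$rank)]
  sens <- vapply(k_grid, function(k) {
    # candidate_only keeps the full gold set as the denominator
    ng <- if (mode == "symmetric") ceiling(k / 100 * length(gg))
          else length(gg)
    nc <- ceiling(k / 100 * length(cg))
    gt <- gg[seq_len(ng)]
    ct <- cg[seq_len(min(nc, length(cg)))]
    mean(count_hits(gt, ct, min_overlap) > 0L)
  }, numeric(1L))
  structure(list(k_grid = k_grid, sensitivity = sens, n_repeats = 1L),
            class = "OverlapCurve")
}

#' Positive predictive value of a candidate peak set
#'
#' @param candidate,gold `RegionSet`s; `gold` must be nonempty.
#' @param min_overlap minimum overlap in bp (default 1).
#' @return Fraction of candidate peaks overlapping at least one gold peak;
#'   `NA` with a warning when the candidate set is empty.
#' @export
ppv <- function(candidate, gold, min_overlap = 1L) {
  stopifnot(inherits(candidate, "RegionSet"), inherits(gold, "RegionSet"))
  if (n_regions(gold) == 0L)
    pc_stop("poolctrl_bad_arg", "gold standard peak set is empty")
  if (n_regions(candidate) == 0L) {
    warning("empty candidate peak set; PPV undefined")
    return(NA_real_)
  }
  mean(count_hits(as_granges(candidate), as_granges(gold), min_overlap) > 0L)
}

#' Average overlap curves across ChIP samples and repeats
#'
#' @param curves nonempty list of `OverlapCurve`s on identical k grids.
#' @return An `OverlapCurve` with pointwise `mean` and sample `sd` and
#'   `n_repeats = length(curves)`.
#' @export
average_curves <- function(curves) {
  if (!is.list(curves) || length(curves) == 0L)
    pc_stop("poolctrl_bad_arg", "curves must be a nonempty list")
  grids <- lapply(curves, `[[`, "k_grid")
  if (!all(vapply(grids, identical, logical(1L), grids[[1L]])))
    pc_stop("poolctrl_bad_arg", "curves are defined on different k grids")
  m <- vapply(curves, `[[`, numeric(length(grids[[1L]])), "sensitivity")
  m <- matrix(m, nrow = length(grids[[1L]]))
  structure(list(k_grid = grids[[1L]],
                 sensitivity = rowMeans(m),
                 mean = rowMeans(m),
                 sd = apply(m, 1L, stats::sd),
                 n_repeats = length(curves)),
            class = "OverlapCurve")
}

#' @export
print.OverlapCurve <- function(x, ...) {
  cat(sprintf("OverlapCurve over %d k values (n = %d): sensitivity %.3f at k=%g ... %.3f at k=%g\n",
              length(x$k_grid), x$n_repeats,
              x$sensitivity[1L], x$k_grid[1L],
              x$sensitivity[length(x$k_grid)], x$k_grid[length(x$k_grid)]))
  invisible(x)
}

#' Plot one or more overlap sensitivity curves
#'
#' Simple base-graphics line chart of sensitivity against the top-k% cutoff.
#'
#' @param x an `OverlapCurve` or list of them.
#' @param labels legend labels when `x` is a list.
#' @param ... passed to [graphics::matplot()].
#' @export
plot_overlap_curves <- function(x, labels = NULL, ...) {
  curves <- if (inherits(x, "OverlapCurve")) list(x) else x
  k <- curves[[1L]]$k_grid
  m <- vapply(curves, `[[`, numeric(length(k)), "sensitivity")
  graphics::matplot(k, matrix(m, nrow = length(k)), type = "b", pch = 19,
                    lty = 1, xlab = "top k% of peaks",
                    ylab = "overlap sensitivity", ylim = c(0, 1), ...)
  if (!is.null(labels))
    graphics::legend("bottomright", legend = labels,
                     col = seq_along(curves), lty = 1, pch = 19)
  invisible(NULL)
}

#' Summarize a pooling experiment into tidy tables
#'
#' Computes, for every experiment record, the top-k% sensitivity curve and
#' the PPV against the matching ChIP sample's gold standard, then aggregates
#' mean and sample sd over (ChIP sample x repeat).
#'
#' @param result an `ExperimentResult` from [run_experiment()].
#' @param k_grid percentages (default `seq(5, 100, by = 5)`).
#' @param mode passed to [overlap_sensitivity()].
#' @return A list of two data frames: `sensitivity` with columns (design,
#'   fraction, k, mean, sd, n) and `ppv` with columns (design, fraction,
#'   mean, sd, n).
#' @export
summarize_experiment <- function(result, k_grid = seq(5, 100, by = 5),
                                 mode = "symmetric") {
  stopifnot(inherits(result, "ExperimentResult"))
  rows <- lapply(result$records, function(rec) {
    gold <- result$gs[[rec$chip]]
    curve <- overlap_sensitivity(rec$peaks, gold, k_grid, mode = mode)
    data.frame(design = rec$design, fraction = rec$fraction, rep = rec$rep,
               chip = rec$chip, k = k_grid, sensitivity = curve$sensitivity,
               ppv = suppressWarnings(ppv(rec$peaks, gold)),
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  sens <- do.call(rbind, lapply(
    split(long, list(long$design, long$fraction, long$k), drop = TRUE),
    function(d) data.frame(design = d$design[1L], fraction = d$fraction[1L],
                           k = d$k[1L], mean = mean(d$sensitivity),
                           sd = stats::sd(d$sensitivity), n = nrow(d),
                           stringsAsFactors = FALSE)))
  one_per_rec <- long[!duplicated(paste(long$design, long$fraction, long$rep,
                                        long$chip)), ]
  ppv_tab <- do.call(rbind, lapply(
    split(one_per_rec, list(one_per_rec$design, one_per_rec$fraction),
          drop = TRUE),
    function(d) data.frame(design = d$design[1L], fraction = d$fraction[1L],
                           mean = mean(d$ppv, na.rm = TRUE),
                           sd = stats::sd(d$ppv), n = nrow(d),
                           stringsAsFactors = FALSE)))
  sens <- sens[order(sens$design, sens$fraction, sens$k), ]
  ppv_tab <- ppv_tab[order(ppv_tab$design, ppv_tab$fraction), ]
  rownames(sens) <- rownames(ppv_tab) <- NULL
  list(sensitivity = sens, ppv = ppv_tab)
}
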