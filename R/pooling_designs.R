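# Matched-cost pooling designs and repeated, seeded end-to-end experiments.
#
# Design M ("matching"): each biological replicate keeps its own control,
# subsampled to a fraction of the full matching input.  Design P ("pooled"):
# the same subsamples are combined in silico into one deeper control shared
# by all replicates.  Both designs consume exactly the same reads, so a
# comparison between them is a comparison at equal sequencing cost.

#' Design specification for a matched-cost experiment
#'
#' @param kind `"M"` (per-replicate matching controls) or `"P"` (one pooled
#'   control).
#' @param per_replicate_fraction proportion of each full control retained.
#' @param replicate_depths full depths of the replicate controls.
#' @param seed base seed.
#' @return A `DesignSpec`.
#' @export
design_spec <- function(kind = c("M", "P"), per_replicate_fraction,
                        replicate_depths, seed = 1L) {
  kind <- match.arg(kind)
  if (per_replicate_fraction <= 0 || per_replicate_fraction > 1)
    pc_stop("poolctrl_bad_arg", "per_replicate_fraction must be in (0, 1]")
  structure(list(kind = kind,
                 per_replicate_fraction = per_replicate_fraction,
                 replicate_depths = as.numeric(replicate_depths),
                 seed = as.integer(seed)),
            class = "DesignSpec")
}

#' Total control reads consumed by a design
#' @param spec a `DesignSpec`.
#' @return Numeric read count: the sum over replicates of
#'   `round(fraction * depth)`.  Identical for Designs M and P at the same
#'   fraction (the cost identity).
#' @export
design_cost <- function(spec) {
  stopifnot(inherits(spec, "DesignSpec"))
  sum(round_half_even(spec$per_replicate_fraction * spec$replicate_depths))
}

#' Fold reduction in sequencing cost between two designs
#'
#' The ratio of total control reads consumed by the full design to those
#' consumed by the reduced design; with equal replicate depths this is `1/f`.
#' Subsampling each of two equally deep replicates to 5% therefore reduces
#' the overall control sequencing cost 20-fold.
#'
#' @param full_design a `DesignSpec`, typically at fraction 1.
#' @param reduced_design a `DesignSpec` at the reduced fraction.
#' @return The fold ratio.
#' @export
design_cost_ratio <- function(full_design, reduced_design) {
  design_cost(full_design) / design_cost(reduced_design)
}

#' Build Design M: per-replicate subsampled matching controls
#'
#' Each control is independently subsampled to `fraction` of its depth with
#' a seed derived from `(seed, replicate index, "M")`, so the draw for each
#' replicate is independent but reproducible.
#'
#' @param controls list of full-depth control `ReadSet`s, one per replicate.
#' @param fraction proportion in (0, 1]; the conventional grid is
#'   `c(0.005, 0.05, 0.25, 0.5)`.
#' @param seed base seed.
#' @return List of subsampled `ReadSet`s, one per replicate.
#' @export
make_matching_design <- function(controls, fraction, seed) {
  if (!is.list(controls) || length(controls) == 0L)
    pc_stop("poolctrl_bad_arg", "controls must be a nonempty list of ReadSet")
  lapply(seq_along(controls), function(i) {
    subsample_reads(controls[[i]], fraction, derive_seed(seed, "M", i))
  })
}

#' Build Design P: one pooled control from the Design-M subsamples
#'
#' Pools exactly the reads Design M would use (same seed derivation), so the
#' two designs have identical cost; the pooled depth is the sum of the
#' per-replicate subsample depths.  Pooling two 5% subsamples of equally deep
#' replicates yields a control at 10% of one full matching input, mapping the
#' subsample grid 0.5%/5%/25%/50% onto pooled depths 1%/10%/50%/100%.
#'
#' @inheritParams make_matching_design
#' @return A pooled `ReadSet`.
#' @export
make_pooled_design <- function(controls, fraction, seed) {
  parts <- make_matching_design(controls, fraction, seed)
  pool_reads(parts, source_label = sprintf("pooled_f%g", fraction))
}

#' Unequal-depth pooling schemes with their gold standards
#'
#' For two replicate controls R1 and R2 with depths `n1 <= n2`, three
#' pooling schemes accommodate the depth imbalance, each with a gold
#' standard drawn from the deeper replicate R2:
#'
#' * `pool_1`: n1/2 reads from R1 + n2/2 from R2; GS_1 = n1/2 + n2/2 from R2.
#' * `pool_2`: n1/2 from R1 + n1/2 from R2; GS_2 = n1 from R2.
#' * `pool_3`: n1 from R1 + n1 from R2; GS_3 = 2 n1 from R2 (requires
#'   `2 n1 <= n2`, otherwise the scheme is skipped with a warning).
#'
#' Within a scheme, the pooled contribution from R2 and the gold standard are
#' drawn disjointly whenever their combined size fits in R2 (avoiding
#' information leakage into the gold standard); for `pool_1` the combined
#' size always exceeds n2, so the gold standard is an independent draw.
#'
#' @param r1,r2 `ReadSet`s with `depth(r1) <= depth(r2)`.
#' @param seed base seed.
#' @return Named list of schemes; each scheme has `scheme_id`, `pooled`,
#'   `gold`, the realized `reads_from_r1` / `reads_from_r2` / `gs_size`, and
#'   a `disjoint` flag.
#' @export
build_unequal_schemes <- function(r1, r2, seed) {
  stopifnot(inherits(r1, "ReadSet"), inherits(r2, "ReadSet"))
  n1 <- r1$depth
  n2 <- r2$depth
  if (n1 > n2)
    pc_stop("poolctrl_bad_arg", "requires depth(r1) <= depth(r2)")
  specs <- list(
    pool_1 = list(a = round_half_even(n1 / 2), b = round_half_even(n2 / 2),
                  g = round_half_even(n1 / 2) + round_half_even(n2 / 2),
                  gs_id = "GS_1"),
    pool_2 = list(a = round_half_even(n1 / 2), b = round_half_even(n1 / 2),
                  g = n1, gs_id = "GS_2"),
    pool_3 = list(a = n1, b = n1, g = 2 * n1, gs_id = "GS_3"))
  out <- list()
  for (id in names(specs)) {
    s <- specs[[id]]
    if (id == "pool_3" && 2 * n1 > n2) {
      warning(sprintf("pool_3 skipped: 2*n1 = %g exceeds n2 = %g", 2 * n1, n2))
      next
    }
    part1 <- subsample_n(r1, s$a, derive_seed(seed, id, "R1"))
    disjoint <- (s$b + s$g) <= n2
    if (disjoint) {
      # one permutation of R2, split into the pooled part and the gold standard
      perm <- with_seed(derive_seed(seed, id, "R2"), sample.int(n2))
      take <- function(idx) {
        df <- r2$reads[sort(idx), , drop = FALSE]
        rownames(df) <- NULL
        structure(list(reads = df, depth = nrow(df),
                       source_label = r2$source_label),
                  class = "ReadSet")
      }
      part2 <- take(perm[seq_len(s$b)])
      gold <- take(perm[s$b + seq_len(s$g)])
    } else {
      part2 <- subsample_n(r2, s$b, derive_seed(seed, id, "R2"))
      gold <- subsample_n(r2, s$g, derive_seed(seed, id, "GS"))
    }
    pooled <- pool_reads(list(part1, part2), source_label = id)
    gold$source_label <- s$gs_id
    out[[id]] <- list(scheme_id = id, pooled = pooled, gold = gold,
                      reads_from_r1 = s$a, reads_from_r2 = s$b,
                      gs_size = s$g, gs_id = s$gs_id, disjoint = disjoint)
  }
  out
}

#' Run a repeated matched-cost pooling experiment end to end
#'
#' For every repeat and fraction, Design M and Design P controls are built
#' from the full controls, and peaks are called for each ChIP sample against
#' (a) its full matching control (the gold standard, computed once), (b) its
#' Design-M control, and (c) the shared Design-P control.  Everything is
#' deterministic given `base_seed`.
#'
#' @param chips list of ChIP `ReadSet`s; `chips[[i]]` is matched to
#'   `controls[[i]]`.
#' @param controls list of full-depth control `ReadSet`s, at least as many as
#'   chips.
#' @param layout `GenomeLayout` used for binning.
#' @param fractions subsample fractions (default `c(0.005, 0.05, 0.25, 0.5)`).
#' @param repeats number of repeated subsampling experiments (default 5).
#' @param base_seed integer base seed.
#' @param fragment_length bp for fragment extension.
#' @param fdr,pseudocount,min_gap_bins passed to [call_peaks()].
#' @return An `ExperimentResult`: `gs` (one `RegionSet` per ChIP) and
#'   `records`, a list with one entry per (repeat, fraction, chip, design)
#'   holding the peak set, control depth and seed provenance.
#' @export
run_experiment <- function(chips, controls, layout,
                           fractions = c(0.005, 0.05, 0.25, 0.5),
                           repeats = 5L, base_seed = 1L,
                           fragment_length = 150L, fdr = 0.05,
                           pseudocount = 1, min_gap_bins = 1L) {
  if (length(controls) < length(chips))
    pc_stop("poolctrl_bad_arg", "fewer controls than ChIP samples")
  if (repeats < 1L)
    pc_stop("poolctrl_bad_arg", "repeats must be >= 1")
  chip_bins <- lapply(chips, bin_counts, layout = layout,
                      fragment_length = fragment_length)
  ctrl_bins <- lapply(controls[seq_along(chips)], bin_counts, layout = layout,
                      fragment_length = fragment_length)
  gs <- lapply(seq_along(chips), function(i) {
    call_peaks(chip_bins[[i]], ctrl_bins[[i]], fdr = fdr,
               pseudocount = pseudocount, min_gap_bins = min_gap_bins)
  })
  records <- list()
  for (t in seq_len(repeats)) {
    for (f in fractions) {
      seed_tf <- derive_seed(base_seed, "rep", t, "f", f)
      m_controls <- make_matching_design(controls[seq_along(chips)], f, seed_tf)
      depths <- vapply(m_controls, `[[`, numeric(1L), "depth")
      if (any(depths < 1000L))
        warning(sprintf(
          "repeat %d fraction %g: control depth %d < 1000 reads; correlations and peak calls are unreliable",
          t, f, min(depths)))
      pooled <- pool_reads(m_controls, source_label = sprintf("P_f%g", f))
      p_bins <- bin_counts(pooled, layout, fragment_length)
      for (i in seq_along(chips)) {
        m_bins <- bin_counts(m_controls[[i]], layout, fragment_length)
        records[[length(records) + 1L]] <- list(
          rep = t, fraction = f, chip = i, design = "M",
          peaks = call_peaks(chip_bins[[i]], m_bins, fdr = fdr,
                             pseudocount = pseudocount,
                             min_gap_bins = min_gap_bins),
          control_depth = m_controls[[i]]$depth, seed = seed_tf)
        records[[length(records) + 1L]] <- list(
          rep = t, fraction = f, chip = i, design = "P",
          peaks = call_peaks(chip_bins[[i]], p_bins, fdr = fdr,
                             pseudocount = pseudocount,
                             min_gap_bins = min_gap_bins),
          control_depth = pooled$depth, seed = seed_tf)
      }
    }
  }
  structure(list(gs = gs, records = records, fractions = fractions,
                 repeats = as.integer(repeats), base_seed = base_seed),
            class = "ExperimentResult")
}

#' @export
print.ExperimentResult <- function(x, ...) {
  cat(sprintf("ExperimentResult: %d ChIP sample(s), %d repeat(s), fractions {%s}, %d peak sets\n",
              length(x$gs), x$repeats,
              paste(x$fractions, collapse = ", "), length(x$records)))
  invisible(x)
}
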