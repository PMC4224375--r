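# Similarity between control samples over enriched-region bins, clustering,
# high/low correlation classes and the pooling recommendation.
#
# The decision statistic is the Pearson correlation between bin-level read
# count vectors restricted to a master list of ChIP-enriched regions;
# dissimilarity for clustering is one minus that correlation.  Empirically,
# pairwise control correlations are strongly bi-modal, and the two modes
# (separated around r = 0.6-0.8) predict whether pooling multiplexed
# controls gains power: pool the high class, sequence the low class deeper.

#' Pearson correlation between two count vectors
#'
#' @param x,y equal-length numeric vectors (length >= 3) with nonzero
#'   variance.
#' @return The product-moment correlation.  A zero-variance vector raises a
#'   classed error (`poolctrl_zero_variance`) so the caller can decide how to
#'   treat the pair.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    pc_stop("poolctrl_bad_arg", "vectors must have equal length >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    pc_stop("poolctrl_zero_variance",
            "correlation undefined: a vector has zero variance")
  stats::cor(x, y)
}

#' Normalized Euclidean distance between two count vectors
#'
#' Each vector is scaled to unit total (counts divided by the vector sum)
#' before taking the Euclidean distance, so the measure is invariant to
#' sequencing depth and is 0 iff the vectors are proportionally identical.
#'
#' @param x,y equal-length nonnegative vectors with positive sums.
#' @return The distance.
#' @export
normalized_euclidean <- function(x, y) {
  if (length(x) != length(y))
    pc_stop("poolctrl_bad_arg", "vectors must have equal length")
  if (sum(x) <= 0 || sum(y) <= 0)
    pc_stop("poolctrl_bad_arg", "vectors must have positive sums")
  sqrt(sum((x / sum(x) - y / sum(y))^2))
}

#' Pairwise correlation report for a set of control samples
#'
#' Restricts every sample's bin counts to the master-list bins, computes all
#' pairwise Pearson correlations (on raw counts by default; `log1p = TRUE`
#' applies log(1 + x) first for heavy-tailed data) and classifies each pair
#' into the high or low correlation class.
#'
#' Pairs involving a zero-variance vector have undefined correlation; they
#' are reported with `r = NA`, classed low and flagged, since a flat count
#' vector over enriched regions indicates insufficient depth.
#'
#' @param samples list of `BinCounts`, one per control sample, sharing a
#'   layout.
#' @param master a `MasterList` of ChIP-enriched regions.
#' @param groups optional function or named vector mapping a pair label
#'   `"A|B"` to a group (`MBRG`, `MTG`, `MCG`, ...); defaults to `"other"`.
#' @param labels sample labels; default taken from each sample's source.
#' @param method,fixed_threshold passed to [classify_pairs()].
#' @param log1p log-transform counts before correlating.
#' @return A `CorrelationReport` with the correlation and dissimilarity
#'   matrices, per-pair table (pair, group, r, class, flagged) and the
#'   restricted count matrix used.
#' @export
pairwise_report <- function(samples, master, groups = NULL, labels = NULL,
                            method = c("fixed_threshold", "mixture"),
                            fixed_threshold = 0.7, log1p = FALSE) {
  method <- match.arg(method)
  if (!is.list(samples) || length(samples) < 2L)
    pc_stop("poolctrl_bad_arg", "need at least two samples")
  if (is.null(labels)) {
    labels <- vapply(seq_along(samples), function(i) {
      lb <- samples[[i]]$source_label
      if (is.null(lb) || !nzchar(lb)) sprintf("sample_%d", i) else lb
    }, character(1L))
  }
  if (anyDuplicated(labels))
    labels <- make.unique(labels)
  idx <- master_bin_indices(samples[[1L]]$layout, master)
  if (length(idx) < 3L)
    pc_stop("poolctrl_bad_arg", "master list selects fewer than 3 bins")
  mat <- vapply(samples, function(s) flatten_counts(s)[idx],
                numeric(length(idx)))
  colnames(mat) <- labels
  if (log1p) mat <- log1p(mat)
  n <- ncol(mat)
  vars <- apply(mat, 2L, stats::var)
  r <- suppressWarnings(stats::cor(mat))
  diag(r) <- 1
  pairs <- utils::combn(n, 2L)
  pair_df <- data.frame(
    a = labels[pairs[1L, ]], b = labels[pairs[2L, ]],
    r = r[cbind(pairs[1L, ], pairs[2L, ])],
    flagged = vars[pairs[1L, ]] == 0 | vars[pairs[2L, ]] == 0,
    stringsAsFactors = FALSE)
  pair_df$r[pair_df$flagged] <- NA_real_
  key <- paste(pair_df$a, pair_df$b, sep = "|")
  pair_df$group <- if (is.null(groups)) "other"
    else if (is.function(groups)) vapply(key, groups, character(1L))
    else {
      g <- unname(groups[key])
      g[is.na(g)] <- "other"
      g
    }
  rep <- structure(list(sample_labels = labels,
                        pearson = r,
                        dissimilarity = 1 - r,
                        pairs = pair_df,
                        counts = mat,
                        threshold_used = NA_real_,
                        method = method),
                   class = "CorrelationReport")
  classify_pairs(rep, method = method, fixed_threshold = fixed_threshold)
}

#' @export
print.CorrelationReport <- function(x, ...) {
  cat(sprintf("CorrelationReport: %d samples, %d pairs (%d high / %d low), threshold %.3f [%s]\n",
              length(x$sample_labels), nrow(x$pairs),
              sum(x$pairs$class == "high"), sum(x$pairs$class == "low"),
              x$threshold_used, x$method))
  invisible(x)
}

#' Control-similarity report for a synthetic scenario
#'
#' Runs the similarity stage end to end on a generated scenario: bins every
#' sample, calls gold-standard peaks for each ChIP against its full matching
#' control, builds the master list from those peak sets, and computes the
#' pairwise control correlation report over the master-list bins.
#'
#' @param scen a `Scenario` from [generate_scenario()].
#' @param fragment_length bp for fragment extension (default 150).
#' @param fixed_threshold correlation threshold (default 0.7).
#' @param fdr peak-calling FDR for the master list (default 0.05).
#' @return A `CorrelationReport` over the scenario's control samples.
#' @export
scenario_report <- function(scen, fragment_length = 150L,
                            fixed_threshold = 0.7, fdr = 0.05) {
  stopifnot(inherits(scen, "Scenario"))
  chip_bins <- lapply(scen$chips, bin_counts, layout = scen$layout,
                      fragment_length = fragment_length)
  ctrl_bins <- lapply(scen$controls, bin_counts, layout = scen$layout,
                      fragment_length = fragment_length)
  gs <- lapply(seq_along(chip_bins), function(i) {
    call_peaks(chip_bins[[i]], ctrl_bins[[min(i, length(ctrl_bins))]],
               fdr = fdr)
  })
  master <- build_master_list(gs)
  pairwise_report(ctrl_bins, master, fixed_threshold = fixed_threshold)
}

#' Classify sample pairs into high/low correlation classes
#'
#' `fixed_threshold`: a pair is high iff `r >= threshold`; the default 0.7 is
#' the midpoint of the empirical 0.6-0.8 band separating the two modes of
#' the pairwise-correlation density.  `mixture`: fit a two-component Gaussian
#' mixture to the Fisher z-transformed correlations and use the density
#' crossing point between the component means as the threshold; if the
#' component means are closer than 0.1 in z-space the bi-modality is not
#' credible and the method falls back to the fixed threshold.
#'
#' @param report a `CorrelationReport`.
#' @param method `"fixed_threshold"` or `"mixture"`.
#' @param fixed_threshold correlation threshold for the fixed method
#'   (default 0.7).
#' @return The report with updated `class` labels, `threshold_used` and
#'   `method`.
#' @export
classify_pairs <- function(report, method = c("fixed_threshold", "mixture"),
                           fixed_threshold = 0.7) {
  stopifnot(inherits(report, "CorrelationReport"))
  method <- match.arg(method)
  r <- report$pairs$r
  thr <- fixed_threshold
  used <- "fixed_threshold"
  if (method == "mixture") {
    ok <- !is.na(r)
    if (sum(ok) < 6L)
      pc_stop("poolctrl_bad_arg",
              "mixture classification needs >= 6 pairs with defined correlation; use the fixed_threshold method")
    z <- atanh(pmin(pmax(r[ok], -0.999999), 0.999999))
    # Mclust() resolves mclustBIC in the calling frame; bind it locally so
    # the package works without attaching mclust
    mclustBIC <- mclust::mclustBIC
    fit <- tryCatch(
      mclust::Mclust(z, G = 2L, modelNames = "V",
                     verbose = FALSE),
      error = function(e) NULL)
    if (!is.null(fit) && abs(diff(fit$parameters$mean)) >= 0.1) {
      mu <- fit$parameters$mean
      sd <- sqrt(fit$parameters$variance$sigmasq)
      if (length(sd) == 1L) sd <- rep(sd, 2L)
      pro <- fit$parameters$pro
      o <- order(mu)
      mu <- mu[o]; sd <- sd[o]; pro <- pro[o]
      grid <- seq(mu[1L], mu[2L], length.out = 2001L)
      d1 <- pro[1L] * stats::dnorm(grid, mu[1L], sd[1L])
      d2 <- pro[2L] * stats::dnorm(grid, mu[2L], sd[2L])
      cross <- which(d2 >= d1)
      zstar <- if (length(cross)) grid[cross[1L]] else mean(mu)
      thr <- tanh(zstar)
      used <- "mixture"
    } else {
      used <- "fixed_threshold"
    }
  }
  cls <- ifelse(!is.na(r) & r >= thr, "high", "low")
  report$pairs$class <- cls
  report$threshold_used <- thr
  report$method <- used
  report
}

#' Hierarchical clustering of control samples
#'
#' Agglomerative clustering on either one-minus-Pearson dissimilarity or the
#' normalized Euclidean distance between the restricted count vectors.
#'
#' @param report a `CorrelationReport` from [pairwise_report()].
#' @param metric `"one_minus_pearson"` (default) or `"normalized_euclidean"`.
#' @param linkage `"average"` (default) or `"complete"`.
#' @return An `hclust` tree over the sample labels; merge heights are
#'   non-decreasing.
#' @export
hcluster <- function(report, metric = c("one_minus_pearson",
                                        "normalized_euclidean"),
                     linkage = c("average", "complete")) {
  stopifnot(inherits(report, "CorrelationReport"))
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  n <- length(report$sample_labels)
  if (n < 2L)
    pc_stop("poolctrl_bad_arg", "clustering needs >= 2 samples")
  d <- if (metric == "one_minus_pearson") {
    m <- report$dissimilarity
    m[is.na(m)] <- 2  # undefined pairs are maximally dissimilar
    stats::as.dist(m)
  } else {
    p <- sweep(report$counts, 2L, colSums(report$counts), "/")
    stats::dist(t(p))
  }
  stats::hclust(d, method = linkage)
}

#' Write a dendrogram in Newick format
#'
#' @param hc an `hclust` tree from [hcluster()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Pooling recommendation for a candidate group of control samples
#'
#' Multiplexed controls should be pooled only when every pairwise correlation
#' within the candidate group belongs to the high class; otherwise the gain
#' in effective depth does not materialize and further sequencing of each
#' control is the better investment.  The deciding statistic reported is the
#' minimum pairwise correlation within the group.
#'
#' @param report a classified `CorrelationReport`.
#' @param group_samples labels of the candidate pooling group (default: all
#'   samples in the report).
#' @return A `PoolingRecommendation`: `decision` (`"pool"` or
#'   `"sequence_deeper"`), `min_r`, `threshold`, and the offending low pairs
#'   if any.
#' @export
recommend <- function(report, group_samples = NULL) {
  stopifnot(inherits(report, "CorrelationReport"))
  if (is.null(group_samples)) group_samples <- report$sample_labels
  if (length(group_samples) < 2L)
    pc_stop("poolctrl_bad_arg",
            "a pooling group needs at least two samples; nothing to pool")
  missing <- setdiff(group_samples, report$sample_labels)
  if (length(missing))
    pc_stop("poolctrl_bad_arg", "unknown sample(s): %s",
            paste(missing, collapse = ", "))
  p <- report$pairs
  inside <- p$a %in% group_samples & p$b %in% group_samples
  p <- p[inside, , drop = FALSE]
  low <- p[p$class == "low", , drop = FALSE]
  decision <- if (nrow(low) == 0L) "pool" else "sequence_deeper"
  structure(list(decision = decision,
                 min_r = if (all(is.na(p$r))) NA_real_ else min(p$r, na.rm = TRUE),
                 threshold = report$threshold_used,
                 low_pairs = paste(low$a, low$b, sep = "|"),
                 group = group_samples),
            class = "PoolingRecommendation")
}

#' @export
print.PoolingRecommendation <- function(x, ...) {
  cat(sprintf("Recommendation: %s (min pairwise r = %s, threshold = %.3f)\n",
              x$decision,
              ifelse(is.na(x$min_r), "NA", sprintf("%.3f", x$min_r)),
              x$threshold))
  if (length(x$low_pairs))
    cat("  low pairs:", paste(x$low_pairs, collapse = ", "), "\n")
  invisible(x)
}

#' Write a correlation report as TSV
#'
#' Columns: pair members, group, r, class, flagged.
#'
#' @param report a `CorrelationReport`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  df <- report$pairs[, c("a", "b", "group", "r", "class", "flagged")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a correlation report pair table written by [write_report_tsv()]
#'
#' Reconstructs a minimal `CorrelationReport` (pair table and matrices; no
#' count matrix), sufficient for [recommend()].
#'
#' @param path TSV path.
#' @param threshold threshold to re-apply (default 0.7).
#' @return A `CorrelationReport`.
#' @export
read_report_tsv <- function(path, threshold = 0.7) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  labels <- unique(c(df$a, df$b))
  n <- length(labels)
  r <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  diag(r) <- 1
  r[cbind(match(df$a, labels), match(df$b, labels))] <- df$r
  r[cbind(match(df$b, labels), match(df$a, labels))] <- df$r
  rep <- structure(list(sample_labels = labels, pearson = r,
                        dissimilarity = 1 - r, pairs = df, counts = NULL,
                        threshold_used = threshold,
                        method = "fixed_threshold"),
                   class = "CorrelationReport")
  classify_pairs(rep, method = "fixed_threshold", fixed_threshold = threshold)
}
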