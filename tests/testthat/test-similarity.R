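# Pairwise similarity, classification, clustering, recommendation.

test_that("pearson correlation matches the two-pass sum-formula oracle", {
  expect_equal(pearson_cor(1:10, 1:10), 1)
  expect_equal(pearson_cor(1:10, 20 - (1:10)), -1)
  set.seed(21)
  for (i in 1:5) {
    x <- sample.int(50L, 100L, TRUE)
    y <- sample.int(50L, 100L, TRUE)
    expect_equal(pearson_cor(x, y), bf_pearson(x, y), tolerance = 1e-12)
  }
  expect_error(pearson_cor(rep(1, 10), 1:10),
               class = "poolctrl_zero_variance")
  expect_error(pearson_cor(1:2, 1:2), "length")
})

test_that("pearson is invariant under positive affine maps", {
  set.seed(22)
  x <- rpois(50, 10); y <- rpois(50, 10)
  r <- pearson_cor(x, y)
  expect_equal(pearson_cor(3 * x + 7, y), r, tolerance = 1e-12)
  expect_equal(pearson_cor(x, 0.5 * y + 100), r, tolerance = 1e-12)
})

test_that("normalized Euclidean distance is depth-invariant and matches its formula", {
  x <- c(3, 1, 6)
  expect_equal(normalized_euclidean(x, 2 * x), 0)
  expect_equal(normalized_euclidean(x, x), 0)
  y <- c(1, 1, 8)
  expect_equal(normalized_euclidean(x, y), bf_norm_euclidean(x, y),
               tolerance = 1e-12)
  # hand case: p = (.3,.1,.6), q = (.1,.1,.8) -> sqrt(.04 + 0 + .04)
  expect_equal(normalized_euclidean(x, y), sqrt(0.08), tolerance = 1e-12)
})

test_that("fixed-threshold classification is monotone in the threshold", {
  r <- c(0.9, 0.3, 0.65, 0.75, 0.82, 0.55)
  rep1 <- report_from_r(r, threshold = 0.7)
  expect_equal(rep1$pairs$class[1], "high")  # 0.9 above the 0.6-0.8 band
  expect_equal(rep1$pairs$class[2], "low")   # 0.3 below the band
  high_at <- function(thr) {
    sum(classify_pairs(rep1, "fixed_threshold", thr)$pairs$class == "high")
  }
  thresholds <- seq(0.1, 0.95, by = 0.05)
  expect_true(all(diff(vapply(thresholds, high_at, numeric(1L))) <= 0))
})

test_that("mixture classification finds a threshold between bimodal classes", {
  thresholds <- recovered <- numeric(0)
  for (seed in 1:10) {
    set.seed(seed)
    z <- c(rnorm(100, atanh(0.3), 0.15), rnorm(100, atanh(0.9), 0.15))
    rep0 <- report_from_r(tanh(z))
    fit <- classify_pairs(rep0, method = "mixture")
    expect_equal(fit$method, "mixture")
    thresholds <- c(thresholds, fit$threshold_used)
    truth_high <- rep(c(FALSE, TRUE), each = 100)
    recovered <- c(recovered, mean((fit$pairs$class == "high") == truth_high))
  }
  expect_true(all(thresholds > 0.6 & thresholds < 0.8))
  expect_gte(mean(recovered), 0.95)
})

test_that("mixture method refuses tiny pair sets and falls back when unimodal", {
  expect_error(classify_pairs(report_from_r(c(0.8, 0.3)), "mixture"),
               "6 pairs")
  set.seed(9)
  uni <- report_from_r(tanh(rnorm(50, atanh(0.7), 0.01)))
  fit <- classify_pairs(uni, method = "mixture")
  expect_equal(fit$method, "fixed_threshold")
  expect_equal(fit$threshold_used, 0.7)
})

test_that("pairwise_report computes master-restricted correlations and flags flat vectors", {
  layout <- tiny_layout(nbins = 50L)
  master <- structure(list(regions = data.frame(
    chrom = "chr1", start = 0L, end = 50L * 200L)), class = "MasterList")
  set.seed(30)
  base <- rpois(50, 20)
  s1 <- counts_fixture(base + rpois(50, 2), layout)
  s2 <- counts_fixture(base + rpois(50, 2), layout)
  s3 <- counts_fixture(rep(0L, 50), layout)  # flat: undefined correlation
  rep1 <- pairwise_report(list(s1, s2, s3), master,
                          labels = c("a", "b", "c"))
  p12 <- rep1$pairs[rep1$pairs$a == "a" & rep1$pairs$b == "b", ]
  expect_gt(p12$r, 0.7)
  flagged <- rep1$pairs[rep1$pairs$b == "c" | rep1$pairs$a == "c", ]
  expect_true(all(flagged$flagged))
  expect_true(all(is.na(flagged$r)))
  expect_true(all(flagged$class == "low"))
  expect_true(isSymmetric(rep1$pearson))
  expect_equal(unname(diag(rep1$pearson)), rep(1, 3))
})

test_that("clustering merges the most correlated pair first and ignores input order", {
  r <- matrix(c(1, .99, .1,
                .99, 1, .1,
                .1, .1, 1), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  rep1 <- structure(list(sample_labels = c("A", "B", "C"), pearson = r,
                         dissimilarity = 1 - r,
                         pairs = data.frame(a = c("A", "A", "B"),
                                            b = c("B", "C", "C"),
                                            r = c(.99, .1, .1),
                                            flagged = FALSE, group = "other",
                                            class = c("high", "low", "low")),
                         counts = NULL, threshold_used = 0.7,
                         method = "fixed_threshold"),
                    class = "CorrelationReport")
  hc <- hcluster(rep1)
  first <- sort(rep1$sample_labels[-hc$merge[1, ]])
  expect_equal(first, c("A", "B"))

  # permutation invariance on 6 synthetic samples (cophenetic distances agree)
  layout <- tiny_layout(nbins = 60L)
  master <- structure(list(regions = data.frame(
    chrom = "chr1", start = 0L, end = 12000L)), class = "MasterList")
  set.seed(31)
  shared <- rpois(60, 30)
  samples <- lapply(1:6, function(i)
    counts_fixture(shared + rpois(60, i * 3L), layout))
  labels <- letters[1:6]
  perm <- c(4L, 2L, 6L, 1L, 3L, 5L)
  h1 <- hcluster(pairwise_report(samples, master, labels = labels))
  h2 <- hcluster(pairwise_report(samples[perm], master,
                                 labels = labels[perm]))
  d1 <- as.matrix(stats::cophenetic(h1))[labels, labels]
  d2 <- as.matrix(stats::cophenetic(h2))[labels, labels]
  expect_equal(d1, d2, tolerance = 1e-12)
  # single sample: nothing to cluster
  expect_error(hcluster(structure(list(sample_labels = "A"),
                                  class = "CorrelationReport")), ">= 2")
})

test_that("newick export writes one tree with all sample labels", {
  rep1 <- report_from_r(c(0.9, 0.2, 0.5))
  hc <- hcluster(rep1)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(hc, f)
  tree <- ape::read.tree(f)
  expect_setequal(tree$tip.label, rep1$sample_labels)
})

test_that("pooling is recommended iff every pair in the group is high-class", {
  layout <- tiny_layout(nbins = 50L)
  master <- structure(list(regions = data.frame(
    chrom = "chr1", start = 0L, end = 10000L)), class = "MasterList")
  set.seed(33)
  shared <- rpois(50, 50)
  high1 <- counts_fixture(shared + rpois(50, 2), layout)
  high2 <- counts_fixture(shared + rpois(50, 2), layout)
  lone <- counts_fixture(rpois(50, 50), layout)
  rep1 <- pairwise_report(list(high1, high2, lone), master,
                          labels = c("r1", "r2", "odd"))
  expect_equal(recommend(rep1, c("r1", "r2"))$decision, "pool")
  all3 <- recommend(rep1)
  expect_equal(all3$decision, "sequence_deeper")
  expect_true(any(grepl("odd", all3$low_pairs)))
  expect_equal(all3$min_r, min(rep1$pairs$r))
  expect_error(recommend(rep1, "r1"), "at least two")
})

test_that("report TSV round trip preserves pairs and classes", {
  rep1 <- report_from_r(c(0.91, 0.42, 0.77))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_report_tsv(rep1, f)
  back <- read_report_tsv(f)
  expect_equal(back$pairs$r, rep1$pairs$r)
  expect_equal(back$pairs$class, rep1$pairs$class)
})
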