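# Synthetic scenario generator: correlation dial, planted truth, read sampling.

test_that("the correlation dial hits its extremes exactly", {
  cfg <- scenario_config(layout = genome_layout("chrS", 2e6, 200L), rho = 1)
  rates <- draw_background(cfg, n_samples = 3L, seed = 71)
  expect_equal(rates[, 1], rates[, 2])
  expect_equal(rates[, 1], rates[, 3])
  cfg0 <- scenario_config(layout = genome_layout("chrS", 2e6, 200L), rho = 0)
  r0 <- draw_background(cfg0, n_samples = 2L, seed = 71)
  expect_lt(abs(cor(log(r0[, 1]), log(r0[, 2]))), 0.03)
  expect_error(scenario_config(rho = 1.2), "rho")
})

test_that("measured log-rate correlation tracks rho at intermediate values", {
  cfg <- scenario_config(layout = genome_layout("chrS", 2e6, 200L),
                         rho = 0.8)
  errs <- vapply(1:3, function(s) {
    r <- draw_background(cfg, n_samples = 2L, seed = 700L + s)
    abs(cor(log(r[, 1]), log(r[, 2])) - 0.8)
  }, numeric(1))
  expect_lt(max(errs), 0.05)  # 10,000 bins; the 50k-bin check is in acceptance
})

test_that("planted regions are disjoint, counted and sorted; folds multiply ChIP only", {
  cfg <- scenario_config(layout = genome_layout("chrS", 2e6, 200L),
                         n_regions = 50L)
  rates <- draw_background(cfg, n_samples = 2L, seed = 72)
  planted <- plant_enrichment(rates, cfg, seed = 72)
  tr <- planted$truth
  expect_equal(nrow(tr), 50L)
  expect_true(all(tr$end > tr$start))
  expect_true(all(diff(tr$start) >= (tr$end - tr$start)[-nrow(tr)]))  # disjoint
  expect_true(all(tr$fold >= 8 & tr$fold <= 16))
  # inside regions the ChIP/control rate ratio equals the fold; outside it is 1
  w <- cfg$layout$bin_width
  in_bins <- unlist(Map(function(s, e) (s %/% w + 1L):(e %/% w),
                        tr$start, tr$end))
  ratio <- planted$chip_rates[, 1] / rates[, 1]
  expect_true(all(abs(ratio[-in_bins] - 1) < 1e-12))
  expect_true(all(ratio[in_bins] > 1))
  # degenerate cases
  none <- plant_enrichment(rates, scenario_config(
    layout = cfg$layout, n_regions = 0L), seed = 1)
  expect_equal(none$chip_rates, rates)
  expect_equal(nrow(none$truth), 0L)
  flat <- plant_enrichment(rates, scenario_config(
    layout = cfg$layout, n_regions = 10L, fold_range = c(1, 1)), seed = 1)
  expect_equal(flat$chip_rates, rates, tolerance = 1e-12)
})

test_that("read sampling returns exactly the requested depth with valid coordinates", {
  layout <- genome_layout(c("chrA", "chrB"), c(100000L, 50100L), 200L)
  set.seed(73)
  rates <- exp(rnorm(sum(n_bins(layout))))
  expect_equal(sample_reads(rates, 0L, layout, 1)$depth, 0L)
  rs <- sample_reads(rates, 5000L, layout, 2)
  expect_equal(rs$depth, 5000L)
  expect_true(all(rs$reads$strand %in% c("+", "-")))
  for (chrom in c("chrA", "chrB")) {
    sel <- rs$reads$chrom == chrom
    expect_true(all(rs$reads$pos5[sel] >= 0))
    expect_true(all(rs$reads$pos5[sel] < layout$chrom_lengths[[chrom]]))
  }
  # determinism
  expect_equal(read_key(sample_reads(rates, 1000L, layout, 9)),
               read_key(sample_reads(rates, 1000L, layout, 9)))
})

test_that("bin counts converge to the rate profile as depth grows", {
  layout <- genome_layout("chrS", 2e6, 200L)
  set.seed(74)
  rates <- exp(rnorm(sum(n_bins(layout))))
  # fragment_length 1 keeps each read's midpoint inside its source bin, so
  # the only noise is multinomial sampling
  cor_at <- function(depth) {
    rs <- sample_reads(rates, depth, layout, 75)
    cor(flatten_counts(bin_counts(rs, layout, 1L)), rates)
  }
  shallow <- cor_at(5e4)
  deep <- cor_at(1e6)
  expect_gt(deep, shallow)
  expect_gt(deep, 0.95)
})

test_that("scenario presets set their documented correlation classes", {
  presets <- poolctrl:::scenario_presets()
  expect_gte(presets$mbrg_high$rho, 0.95)
  expect_lte(presets$mbrg_low$rho, 0.4)
  expect_true(presets$mcg_low$rho < 0.1)
  expect_equal(presets$mtg$treatment_frac, 0.05)
  expect_equal(unname(presets$mbrg_unequal_depth$control_depths[2] /
                      presets$mbrg_unequal_depth$control_depths[1]), 3)
})

test_that("scenario output directories contain the declared files and refuse overwrites", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "scen")
  scen <- generate_scenario("mbrg_low", seed = 76, out_dir = out,
                            config = scenario_config(
                              layout = genome_layout("chrS", 4e5, 200L),
                              control_depths = 2e4, chip_depths = 2e4,
                              n_regions = 10L))
  expect_true(file.exists(file.path(out, "chrom.sizes")))
  expect_true(file.exists(file.path(out, "truth_regions.tsv")))
  expect_true(all(file.exists(unlist(scen$paths$controls))))
  expect_true(file.exists(file.path(out, "manifest.yaml")))
  # written tagAlign round-trips to the in-memory reads
  back <- load_reads(scen$paths$controls[1], "tagAlign")
  expect_equal(read_key(back), read_key(scen$controls[[1]]))
  manifest <- yaml::read_yaml(file.path(out, "manifest.yaml"))
  expect_equal(manifest$preset, "mbrg_low")
  expect_equal(manifest$seed, 76L)
  expect_error(generate_scenario("mbrg_low", seed = 77, out_dir = out),
               class = "poolctrl_io")
  expect_silent(suppressMessages(
    generate_scenario("mbrg_low", seed = 77, out_dir = out, force = TRUE,
                      config = scenario_config(
                        layout = genome_layout("chrS", 4e5, 200L),
                        control_depths = 2e4, chip_depths = 2e4,
                        n_regions = 10L))))
})

test_that("the lab-effect preset decorrelates the biased control pair", {
  layout <- genome_layout("chrS", 2e6, 200L)
  plain <- generate_scenario("mcg_high", seed = 78,
    config = scenario_config(layout = layout, control_depths = 2e5,
                             chip_depths = 2e5))
  biased <- generate_scenario("lab_effect", seed = 78,
    config = scenario_config(layout = layout, control_depths = 2e5,
                             chip_depths = 2e5))
  r_of <- function(scen) {
    cor(log(scen$rates[, 1]), log(scen$rates[, 2]))
  }
  expect_lt(r_of(biased), r_of(plain))
  expect_true(biased$lab_biased[2])
})

test_that("treatment perturbation lowers cross-condition correlation slightly", {
  layout <- genome_layout("chrS", 2e6, 200L)
  scen <- generate_scenario("mtg", seed = 79,
    config = scenario_config(layout = layout, control_depths = 1e5,
                             chip_depths = 1e5))
  expect_equal(length(scen$controls), 4L)
  expect_equal(scen$condition, c(1L, 1L, 2L, 3L))
  lr <- log(scen$rates)
  same <- cor(lr[, 1], lr[, 2])        # both untreated
  cross <- cor(lr[, 1], lr[, 3])       # untreated vs treated
  expect_gt(same, cross)
  # only treatment_frac of bins move, so the pair stays in the high class
  expect_gt(cross, 0.8)
})
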