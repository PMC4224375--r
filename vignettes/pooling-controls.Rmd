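---
title: "Pooling ChIP-seq input controls: model, design and validation"
author: "poolctrl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling ChIP-seq input controls: model, design and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package answers

A ChIP-seq experiment detects enrichment of a ChIP sample relative to an
input (control) sample, and the quality of that detection depends on the
coverage of the control. When several samples are multiplexed, each
control can be sequenced shallowly and the reads merged *in silico* into
one deep pooled control — but only if the controls estimate the same
background read distribution. `poolctrl` provides (i) a similarity
statistic that predicts whether pooling will help, (ii) the decision
rule built on it, and (iii) a matched-cost experimental harness that
quantifies what pooling does to peak detection, together with a
synthetic read-level generator that makes the whole chain testable.

## Similarity between control samples

Reads (uniquely mapped, single end; 0-based half-open coordinates, the
5′ end of a minus-strand alignment `[start, end)` being `end − 1`) are
extended from their 5′ end to the average fragment length and counted in
fixed-width genome bins. Two conventions exist for assigning an extended
fragment to bins; the default assigns each fragment to the single bin
containing its midpoint, which makes binning conserve reads exactly
(`sum(counts) + skipped = depth`) and keeps count vectors comparable
across depths. The alternative (`assign = "overlap"`, one count per
overlapped bin) is available but not default, since it counts a read up
to `ceiling(fragment/bin) + 1` times.

Correlations are computed not genome-wide but over the bins spanning a
*master list* of ChIP-enriched regions (the merged union of peak sets,
book-ended intervals merged; a bin qualifies with ≥ 1 bp overlap, the
most inclusive rule, so every sample on a layout selects identical
bins). Background outside enriched regions is dominated by flat noise
that would inflate similarity; restricting to candidate enrichment
regions concentrates the comparison where the control actually matters
for peak calling. When no external peak lists exist, candidate regions
come from an initial comparison of each ChIP against the pool of all
controls (the `correlate` command's auto mode).

The pairwise statistic is the plain Pearson correlation `r` of the raw
restricted count vectors (dissimilarity `1 − r` for clustering). Raw
counts are the default because the decision statistic should reflect the
scale on which the peak caller consumes the control; a `log1p` option
exists for heavy-tailed data. A pair with a zero-variance vector has
undefined correlation and is reported as *low* with a flag — a flat
count vector over enriched regions indicates insufficient depth, which
is precisely the situation in which pooling cannot be vouched for.
Hierarchical clustering (average linkage by default; the choice is
cosmetic for the two-class decision and `complete` is available) and a
depth-invariant normalized Euclidean distance (vectors scaled to unit
sum) support exploratory views; trees export as Newick.

## The high/low decision rule

Empirically, pairwise control correlations separate into two modes, and
the gap between them falls in the 0.6–0.8 range. The default classifier
is a fixed threshold at 0.7, the midpoint of that band; because the band
is an empirical observation rather than a theoretical constant, the
threshold is exposed, and a model-based alternative fits a two-component
Gaussian mixture to the Fisher z-transformed correlations and uses the
density crossing point between the component means. The mixture needs at
least 6 pairs and falls back to the fixed threshold when the fitted
means are closer than 0.1 in z-space (no credible bi-modality). The
recommendation is conservative by construction: a group is pooled only
if *every* pairwise correlation in it is high-class, and the deciding
statistic reported is the minimum pairwise `r`.

## Matched-cost designs

For `c` multiplexed replicates at subsample fraction `f`, Design M
analyzes each ChIP against its own control subsampled to `f`, and Design
P analyzes every ChIP against the pool of exactly those subsamples. The
two designs therefore consume identical reads — the cost identity is
exact, by construction, because the pooled design reuses the Design-M
draws — and differ only in how the reads are organized. Subsample sizes
are `round(f × depth)` with round-half-to-even, so repeat counts are
deterministic. The conventional fraction grid 0.5 %, 5 %, 25 %, 50 %
maps, for two equal replicates, onto pooled controls at 1 %, 10 %, 50 %
and 100 % of one full matching input; at `f = 0.05` the full-design cost
is exactly 20× the reduced design's.

Replicates of very different depths (`n1 ≤ n2`) get three pooling
schemes with size-matched gold standards drawn from the deeper
replicate: `pool_1` = (n1/2, n2/2) vs GS of n1/2 + n2/2; `pool_2` =
(n1/2, n1/2) vs GS of n1; `pool_3` = (n1, n1) vs GS of 2·n1, which
requires `2·n1 ≤ n2` and is otherwise skipped with a warning. Within a
scheme, the pooled contribution from the deep replicate and its gold
standard are drawn disjointly whenever both fit (one permutation, split)
to avoid leaking reads into the reference; for `pool_1` the combined
draw always exceeds `n2`, so there the gold standard is an independent
draw — the one place the no-leakage rule cannot be satisfied.

Every random draw in an experiment is seeded by hashing the base seed
with the repeat index, replicate label and role, so draws are mutually
independent but the entire experiment is bit-reproducible from one
integer.

## The baseline peak caller

Peak callers with rich background models are deliberately out of scope;
external peak lists (BED) plug in unchanged via `import_peaks()`. The
built-in baseline preserves the one property the framework needs — a
ranked peak list whose quality depends on control coverage. Per bin with
ChIP count `x` and control count `y`, it tests equality of the two
Poisson rates given the depth ratio `t` with the exact conditional
binomial test: under the null, `x | x + y ~ Binomial(x + y + pc,
t/(1+t))`, upper tail, with an integer pseudocount `pc` (default 1) so
zero-control bins keep a finite background. The conditional test is used
rather than a Poisson tail at the scaled control count because the
latter treats the observed control as the true rate: ignoring the
control's own sampling noise roughly doubles the null variance and, at
20–30 background reads per bin, floods the list with false positives
(measured planted-region precision ≈ 0.5 versus ≈ 0.99 for the
conditional test at FDR 0.05). Benjamini–Hochberg at `fdr` selects bins;
selected bins separated by at most `min_gap_bins` (default 1)
non-selected bins merge into regions scored by `−log10` of their best
bin p-value, ranked descending with deterministic ties (chromosome
order, then start). A zero-depth control is a classed error rather than
a silent pseudocount-only fit.

## Comparing peak sets

Sensitivity is rank-aware: for each `k` in a grid (default 5, 10, …,
100 %), *both* the candidate and the gold set are truncated to their top
`⌈k% × N⌉` peaks and sensitivity(k) is the fraction of truncated gold
peaks overlapped (≥ 1 bp, configurable) by a truncated candidate peak.
Truncating both sets measures whether the candidate identifies peaks *in
the same rank order* as the gold standard, which is the quantity that
degrades first when a control is too shallow; a `candidate_only` mode
keeps the full gold denominator for conventional sensitivity. PPV is the
fraction of candidate peaks hitting any gold peak. Curves are averaged
pointwise (mean and sample sd) across ChIP samples × repeats.

Motif support uses JASPAR count matrices (pseudocount 1e-4), log2-odds
scores against a zero-order background, and an *exact* score p-value:
the null score distribution is convolved position by position on a
1e-3-bit grid, and the threshold is the smallest score whose tail
probability is ≤ the requested p (default 0.01). Both strands are
scanned; a peak counts as a hit with ≥ 1 position at or above threshold,
and peaks more than 50 % `N` are excluded from the denominator. Because
the score distribution is discrete, the attained tail probability can
sit slightly below the nominal p; the scan reports it.

## The synthetic generator

The generator targets the observable the decision rule consumes — the
pairwise correlation between control backgrounds — with one dial.
Per-bin background rates are log-normal; sample `i`'s log-rate is
`mean_log + sd_log·(√rho·Z_s + √(1−rho)·Z_i)` with `Z_s` shared and
`Z_i` sample-specific, so the between-sample correlation of log-rates
equals `rho` exactly (a weighting by `rho` itself would deliver `rho²`
and make the dial lie). ChIP samples multiply their matching control's
rates by per-region folds drawn uniformly from a range, inside planted
disjoint regions; reads are multinomial over bins, uniform within a bin,
fair-coin strands, emitted as read-level `ReadSet`s so subsampling and
pooling operate on the same objects as real data. Optional features:
condition-specific log-normal perturbations of a fixed bin subset
(treatments), and a smooth multiplicative positional bias
`exp(A·sin(2π·5·pos/genome))` on flagged samples (lab batch effect).

Defaults are chosen once as a desk-scale portrait of the real studies:
one 10-Mb chromosome in 200-bp bins (50,000 bins), two replicate pairs
at 1 M reads per sample — about 20 background reads per bin, matching
the per-bin coverage of a ~10–15 M-read control on a ~100-Mb genome —
`sd_log = 1`, 150 planted 1-kb regions at folds 8–16, fragment length
150 bp. The presets place scenarios on either side of the 0.6–0.8
decision band: `mbrg_high`/`mbrg_unequal_depth` at `rho = 0.95`
(unequal depths 1:3, echoing a 27 M/88 M replicate pair), `mbrg_low` at
`rho = 0.3`, `mtg` at `rho = 0.9` with 5 % of bins perturbed between
conditions (no published effect size exists for treatment differences;
0.05 is a free choice exposed in the config), `mcg_high` at 0.9,
`mcg_low` at 0.05, and `lab_effect` at 0.9 plus bias amplitude 0.6.

What the generator does *not* emulate: GC and mappability bias,
duplicate-read structure, paired-end reads, and the spatially
autocorrelated background of real chromatin. Passing tests therefore
demonstrate that the statistical machinery behaves as designed when its
assumptions hold — not that any particular real pair of controls will
fall in a given class.

## Numerical and testing choices

* Sub-seeds derive from a multiplicative-congruential hash of the base
  seed and a string key, kept within 32-bit integer range; the
  Mersenne-Twister generator with rejection sampling is set explicitly
  and the caller's RNG state is always restored.
* p-values are floored at 1e-300 before `−log10` scoring.
* Region ties (equal scores) break by chromosome order then start, so
  ranks are a deterministic permutation.
* Degenerate inputs are contracts, not surprises: empty read files load
  as empty sets; an empty candidate peak set gives an all-zero curve
  while an empty gold standard is an error; an empty master list warns
  and returns an empty vector; single-sample "groups" cannot be
  recommended for pooling.
* Validation problem sizes: unit fixtures use 1–2-Mb layouts; the
  end-to-end checks run the full 10-Mb default (class recovery across
  20 seeds, matched-cost experiments with 5 repeats, depth attenuation
  at 50 k/200 k/1 M reads over 10 seeds). These sizes keep the complete
  suite within a few minutes while leaving ≥ 20 reads per bin at full
  depth, the regime the defaults are meant to portray.

## Known limitations

The baseline caller has no overdispersion beyond the control (real
chromatin is overdispersed even within a sample), so its absolute FDR on
real data would be optimistic; within the framework it is only ever used
symmetrically across designs, which is what the comparisons need. The
unequal-depth runner analyzes any subset of ChIPs but defaults to the
deeper replicate's; the exact averaging a given study used across its
repeats may differ. BAM input is not parsed (convert to tagAlign/BED6);
mappability correction and fragment-length estimation are out of scope,
with the fragment length supplied per sample (default 150 bp).
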