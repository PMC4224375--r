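# poolctrl

Deciding when multiplexed ChIP-seq input controls can be pooled *in
silico* — and measuring what pooling does to peak detection.

## The problem

Standard ChIP-seq designs pair every ChIP sample with its own input
(control) sample, and sequencing budget spent on controls is budget not
spent on ChIP. Because the power to detect enrichment depends on the
coverage of the control, under-sequenced controls silently cost
sensitivity. When several samples are multiplexed — biological
replicates, treatments of one cell type, or different cell lines —
an attractive option is to sequence each control shallowly and merge
their reads computationally into one deep pooled control.

Whether that works depends on how similar the background read
distributions of the controls are. `poolctrl` implements the complete
decision-and-evaluation framework:

1. **Similarity**: bin the genome (200-bp tiles), extend reads to the
   average fragment length, count reads per bin, restrict the count
   vectors to a master list of ChIP-enriched regions, and compute all
   pairwise Pearson correlations `r` between controls (dissimilarity
   `1 − r`; normalized Euclidean distance and hierarchical clustering are
   also provided).
2. **Classification**: pairwise control correlations are empirically
   bi-modal; a threshold in the 0.6–0.8 band (default 0.7, or a
   two-component Gaussian mixture on Fisher-z values) splits pairs into
   *high* and *low* classes.
3. **Recommendation**: pool only when every pair in the candidate group
   is high-class; otherwise sequence each control deeper.
4. **Evaluation**: matched-cost experiments compare Design M (each
   replicate keeps its own control, subsampled to a fraction *f*) with
   Design P (the same subsamples pooled). Peak sets called with each
   control are compared with the gold standard GS (full matching input)
   by top-k% rank-overlap sensitivity, positive predictive value and PWM
   motif occurrence rates (exact score p-values by dynamic programming).
5. **Unequal depths**: three pooling schemes with matched gold standards
   handle replicates of very different depths (n1 ≤ n2): pool n1/2+n2/2,
   n1/2+n1/2, or n1+n1 reads against gold standards of the same size
   drawn from the deeper replicate.

A read-level synthetic generator with a single correlation dial `rho`
(the pairwise correlation of log background rates between samples)
produces all scenario classes — high/low replicate similarity,
treatments, cell lines, unequal depths, lab batch effects — so the whole
pipeline is testable without external data.

## Worked example

```r
library(poolctrl)

# two biological replicates with strongly shared background (rho = 0.95),
# 1 M reads each on a 10-Mb genome
scen <- generate_scenario("mbrg_high", seed = 7)

# similarity stage: gold-standard peaks -> master list -> pairwise r
rep <- scenario_report(scen)
print(rep)
#> CorrelationReport: 2 samples, 1 pairs (1 high / 0 low), threshold 0.700 [fixed_threshold]
print(recommend(rep))
#> Recommendation: pool (min pairwise r = 0.868, threshold = 0.700)

# matched-cost experiment at 5% control subsamples, 5 repeats
res <- run_experiment(scen$chips, scen$controls, scen$layout,
                      fractions = 0.05, repeats = 5, base_seed = 7)
tab <- summarize_experiment(res)$sensitivity
round(tapply(tab$mean, tab$design, mean), 2)
#>    M    P 
#> 0.52 0.88
```

The replicate controls correlate at r = 0.87 over enriched-region bins —
high class, so pooling is recommended. At one-twentieth of the control
cost, peaks called with the pooled control recover on average 88% of the
gold-standard peaks at matched ranks, versus 52% with the per-replicate
matching controls of the same total cost. On the `mbrg_low` preset
(weakly shared backgrounds) the same experiment shows pooled PPV
collapsing to ~0.45 while matched controls stay near 1.0 — the
situation where the framework correctly says *sequence deeper*.

The command line mirrors the workflow:

```sh
exec/poolctrl simulate  --preset mbrg_high --seed 7 --out scen/
exec/poolctrl correlate --reads scen/control_1.tagAlign.gz,scen/control_2.tagAlign.gz \
                        --chips scen/chip_1.tagAlign.gz,scen/chip_2.tagAlign.gz \
                        --chrom-sizes scen/chrom.sizes --out scen/corr
exec/poolctrl recommend --report scen/corr_report.tsv   # exit 0 = pool, 3 = sequence deeper
```

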