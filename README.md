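# permeth

Permutation inference for capture-based differential DNA methylation and
small-RNA differential expression.

## What it is for

MBDCap-seq (methyl-CpG binding domain capture followed by sequencing)
measures DNA methylation through read density: the more methylated a
region, the more captured fragments align to it. Deciding which promoters
or CpG clusters are differentially methylated between a case and a control
group — at the 2–4 replicates per group typical of animal studies — needs a
statistic that is robust at low coverage and a null distribution that is
not contaminated by the very signals being sought. permeth implements that
analysis for epigenomics researchers working with capture-based
methylation data, together with the companion small-RNA expression test
such studies usually pair it with.

The core pieces:

* **Offset fold-change.** A region's methylation intensity *I* is the
  total read bases inside it. The differential measure is
  *f = (I_case + βL) / (I_control + βL)* with read length *L* = 36 and
  offset multiplier *β* = 10, and the signed score *M = log₂ f*. The
  offset βL shrinks ratios of weakly covered regions toward 1, so noise at
  low coverage cannot masquerade as differential methylation.
* **Methylation units.** Nearby CpG sites (gaps ≤ 300 bp) are merged into
  intervals, and intervals are split at break points where the
  between-sample correlation of adjacent sites drops below 0.3. The
  resulting units — runs of correlated nearby sites — are the testing
  granule.
* **Length-stratified one-sided permutation with events-exclusive
  iteration.** Group labels are permuted (exact enumeration at small n),
  null M-scores are pooled within unit-length strata, hyper- and
  hypomethylation are tested against their own tails, and BH-corrected
  calls at q < α₀ = 0.05 are iteratively excluded — along with candidate
  events — from the null, which is then re-estimated until the call set
  stabilises. The iteration recovers the sensitivity a contaminated null
  destroys.
* **Small RNA.** TPM normalization (counts per million when lengths are
  uniform) and an exact group-label permutation test on mean log₂(TPM+1)
  differences, BH-corrected at q < 0.05, plus subtype composition
  summaries (miRNA / tRF / piRNA / rRNA).
* **Synthetic data.** Generators for toy genomes, case/control site or
  unit intensities with planted hyper/hypo effects and recorded truth, and
  small-RNA count tables — every statistical property of the package is
  validated against them.

## Worked example

Simulate a study at typical conditions — 2000 methylation units, 3
replicates per group, mean depth 200 reads per unit, negative-binomial
noise, 100 units planted differential at 4-fold — and run the iterative
detector:

```r
library(permeth)
library(dplyr)

sim <- simulate_unit_matrix(n_units = 2000, samples_per_group = 3,
                            depth = 200, dispersion = 0.1,
                            frac_planted = 0.05, effect = 4, seed = 42)
fit <- iterative_detect(sim$mat, sim$samples, sim$regions, seed = 42)
fit
#> Permutation differential-methylation result
#>   regions tested: 2000
#>   significant:    102 (alpha0 = 0.05, BH)
#>   rounds:         4 (converged)

tidy(fit) |> filter(significant) |> arrange(p) |>
  select(region_id, M, direction, p, q) |> head(5)
#> # A tibble: 5 × 5
#>   region_id      M direction        p       q
#>   <chr>      <dbl> <chr>        <dbl>   <dbl>
#> 1 unit_00066 -1.34 hypo      0.000118 0.00779
#> 2 unit_00158 -1.74 hypo      0.000118 0.00779
#> 3 unit_00205  1.67 hyper     0.000118 0.00799
#> 4 unit_00353 -1.33 hypo      0.000118 0.00779
#> 5 unit_00688  1.59 hyper     0.000118 0.00799

called <- tidy(fit)$region_id[tidy(fit)$significant]
mean(sim$truth$region_id %in% called)   # sensitivity
#> [1] 0.96
mean(!(called %in% sim$truth$region_id)) # false discovery proportion
#> [1] 0.0588
```

102 units are called (53 hyper-, 49 hypomethylated) over 4 rounds of null
re-estimation; 96% of the planted units are recovered and ~6% of the calls
are false — consistent with the nominal BH level. `M` is log₂ of the
offset fold-change (negative = lower methylation in cases), `p` the
one-sided permutation p-value against the unit's length stratum, `q` its
BH correction. `autoplot(fit)` draws the volcano view and
`plot_null_distribution(fit)` the stratified nulls.

The same interface runs from files (BED CpG sites, TSV intensity matrix
and sample sheet) or fully simulated inputs via `run_diffmeth(config,
out_dir)`, which writes the unit BED, call and iteration tables, and a
YAML provenance sidecar. Small-RNA analysis is `tpm_normalize()` +
`permutation_de()`, or `run_smallrna()` end to end.

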