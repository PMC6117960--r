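---
title: "Permutation inference for capture-based differential methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation inference for capture-based differential methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permeth)
library(dplyr)
```

## The measurement model

Methyl-CpG binding domain capture sequencing (MBDCap-seq) enriches
methylated DNA fragments, so the density of aligned short reads over a
genomic region is a proxy for its methylation level. permeth quantifies a
region's *methylation intensity* as the total number of read bases falling
inside it (`region_intensity()`), i.e. each read contributes the length of
its intersection with the region. Intensities are averaged across the
replicates of each group — typically 2–3 animals per group in capture-based
designs — to give per-region case and control intensities $I_{case,j}$ and
$I_{control,j}$.

The differential-methylation measure is the offset fold-change

$$f_j = \frac{I_{case,j} + \beta L}{I_{control,j} + \beta L},$$

with read length $L = 36$ bases and offset multiplier $\beta = 10$ by
default, and the signed score $M_j = \log_2 f_j$. The additive offset
$\beta L$ (360 bases at the defaults) is the crux of the statistic: a
region covered by only a handful of reads cannot produce an extreme ratio,
because both numerator and denominator are dominated by the offset and
$f \to 1$. For strongly covered regions ($I \gg \beta L$) the offset is
negligible and $f$ approaches the raw intensity ratio. `m_score()` isolates
the $f \mapsto M$ mapping so that an alternative signed transform can be
swapped in without touching anything else.

Both parameters are plain configuration values with units: `L` is the
sequenced read length in bases and should match the data; `beta` is
dimensionless and controls how much coverage a region needs before its
ratio is taken seriously.

## Scored regions: promoters and methylation units

Scores can be computed on any region set. Two are built in:

* **Promoters** (`define_promoters()`): 5000 bp upstream of the TSS plus
  the first exon, clipped at chromosome ends, one region per gene;
  methylation here is the strongest correlate of transcriptional
  silencing. Coordinates are 0-based half-open throughout (BED dialect);
  on the minus strand the TSS is the half-open boundary one past the
  5'-most transcribed base, which makes promoter construction exactly
  strand-symmetric. Overlapping promoters of distinct genes are kept
  separate, since scoring is per gene.

* **Methylation units** (`segment_methylation_units()`): nearby CpG sites
  are first merged into *methylation intervals* wherever consecutive sites
  are at most `gap_threshold` apart (default 300 bp, the scale of typical
  CpG clustering), then each interval is split at *break points* —
  adjacent pairs whose Pearson correlation across all samples falls below
  `corr_threshold` (default 0.3, a weak-correlation floor). A unit is
  therefore a maximal run of nearby, correlated CpG sites, and is the
  natural granule for testing: sites inside a unit rise and fall together,
  so testing them separately would pretend to more independent evidence
  than the data contain.

Three segmentation choices deserve a note. Correlations are computed on
all samples pooled, so segmentation never sees group labels and cannot
leak signal into the null. A site pair with zero variance in either
profile gets correlation 0 rather than `NaN`, i.e. it is treated as
uncorrelated and splits — an undefined correlation should never silently
glue sites together. And the break rule is a deterministic threshold on
every adjacent correlation rather than a cut at local minima only; the
latter is available via `mode = "local_minima"` for sensitivity analysis,
but thresholding is order-free and reproduces the "highly correlated
sites within a unit" property exactly, which is also what makes it
checkable against an exhaustive cut-set enumeration in the tests.

## The permutation null and the events-exclusive iteration

Units of different lengths have different background score variability, so
a single pooled null would miscalibrate both short and long units. The null
is therefore *length-stratified*: regions are binned into `n_strata`
(default 5) quantile bins of length — member-site count for units, bp span
otherwise — and each region is tested only against null scores from its own
stratum.

Null scores come from group-label permutation: case/control labels are
reassigned across samples (group sizes preserved), $M$ is recomputed for
every region, and the scores are pooled within each stratum. With 3 vs 3
samples there are only $\binom{6}{3} = 20$ distinct assignments, so the
implementation switches to exact enumeration whenever the number of
distinct assignments is at most `n_perm` (default 1000); sampling is used
only for larger designs. Because all assignments preserve group sizes, the
pooled scores are exchangeable with the observed ones under the null.

Testing is one-sided, because capture backgrounds can make the null of $M$
asymmetric: hypermethylation is judged against the upper tail and
hypomethylation against the lower tail, with the add-one estimator
$p = (1 + \#\{M_{null} \ge M_{obs}\})/(1 + N)$ so that $p > 0$ always and
ties count conservatively into the tail. Both one-sided p-values are
reported for every region (`p_hyper`, `p_hypo`); the sign of $M$ decides
which direction a region can be *called* in, so hyper- and hypo-calls are
mutually exclusive. The Benjamini–Hochberg correction is applied per
direction and per region role over **all** regions, not only the regions
whose sign routed them into that direction: under the null, the one-sided
p-values of all regions in one direction are uniform, which is the
assumption the step-up procedure rests on. (Correcting only the
sign-routed half would operate on p-values that are uniform on
$(0, \tfrac12)$ and inflate the false discovery rate toward twice the
nominal level; we measured exactly that on synthetic mixtures before
settling on the present scheme.)

A single-pass permutation test has a subtler flaw: true differential
regions participate in the null. Their permuted scores — including the
observed extreme ones under the identity assignment — fatten the null
tails, so the null is biased toward conservatism and weak true events are
masked. The *events-exclusive* iteration (`iterative_detect()`) fixes
this: after each round, every region that looks like an event — called at
$q < \alpha_0$, or a *candidate* with raw one-sided $p < \alpha_0$ — is
excluded from the next round's null pool, and all regions are re-tested
against the cleaned null. Iteration stops when two consecutive rounds call
the same set (or at `max_iter`, default 10, with a warning). Excluding
candidates and not just confirmed calls is what breaks the bootstrap
deadlock: in a contaminated first-round null, true events may all sit just
above the corrected threshold, and a scheme that only ever excludes
confirmed calls would terminate with none. Calls themselves are always
made at $q < \alpha_0$; the liberal screen only decides what the null is
estimated from. A `null_mode = "region_resample"` variant (null drawn from
the observed scores of other regions in the stratum, no relabelling) is
provided for comparison.

On synthetic data at the study's scale (2000 units, 3 vs 3, depth 200
reads per unit, negative-binomial dispersion 0.1, 100 units planted at
4-fold) the acceptance suite measures ≈97% recovery of planted units at a
mean empirical FDR of ≈0.07, with the iterative scheme detecting at least
as many true positives as the single pass in every seed — the single pass,
with its contaminated null, detects almost none at these settings. Those
numbers are recomputed, not quoted, by `scripts/acceptance.R` and
`tests/testthat/test-acceptance.R`.

## Small RNA differential expression

Small-RNA count tables (features × samples, 4 replicates per group) are
normalized to TPM: counts are divided by feature length in kb and rescaled
so each sample sums to $10^6$. When lengths are not supplied every feature
is treated as 1 kb, reducing TPM to counts per million — appropriate for
miRNA/tRF libraries whose feature lengths are nearly constant. The
per-feature statistic is the difference of group means of
$\log_2(\mathrm{TPM} + 1)$; significance comes from group-label
permutation (exact enumeration of the $\binom{8}{4} = 70$ assignments at
4 vs 4), BH correction, and the $q < 0.05$ cut.

A discreteness limitation is worth stating plainly: with 4 vs 4 samples
the smallest attainable two-sided p-value is $2/70 \approx 0.029$, so a
feature can only reach $q < 0.05$ when a sizeable fraction of the table
shares the floor. This is a property of exact permutation at small $n$,
not of the implementation; with few planted features the honest summary is
the uncorrected p floor and the sign of the fold-change, which is what the
package's tests assert.

## The synthetic-data generator

All calibration rests on generated data with recorded ground truth, at the
study's stated conditions: 2–3 replicates per group for methylation (3 by
default), 4 per group for small RNA, negative-binomial counts with
dispersion 0.1 by default (capture assays are overdispersed; Poisson is
retained as an analytic-check mode).

`simulate_genome()` lays out non-overlapping genes (one toy chromosome per
500 promoters) with CpG-site clusters whose inter-site gaps mix short
spacings with occasional >300 bp breaks, so one genome exercises both the
merge and the split paths. `simulate_intensities()` draws per-site counts
around a lognormal baseline modulated by a per-block latent factor: sites
within a generator block share the factor with strength `rho` (default
0.8), sites in different blocks are independent, which is what makes
block boundaries recoverable by segmentation and gives `split_units()` a
known truth. Planted blocks multiply the case mean by the effect
(hypermethylation) or its reciprocal (hypomethylation), in equal shares.
`simulate_unit_matrix()` is the fast path used by the statistical tests:
units are generated directly with Poisson member-site counts and intensity
`count × L`, skipping read placement. `simulate_smallrna()` produces
negative-binomial count tables with subtype labels (tRF-dominant by
default, as in sperm libraries; set `subtype_props` for miRNA-dominant
somatic tissue).

What the generator does *not* emulate: sequence composition, capture
chemistry and GC bias, copy-number variation, depth differences between
libraries, and correlated effects spanning more than one unit. Passing
tests therefore demonstrate calibration and power under exchangeable,
per-unit-independent noise — not robustness to the systematic artefacts of
real capture data, which upstream normalization would have to address.

## Numerical and degenerate-input choices

* Add-one p-values in sampling mode; exact tail fractions under full
  enumeration (the observed assignment is always in the enumerated set, so
  p > 0 needs no correction there).
* Ties between observed and null scores count into the rejection tail.
* Length strata with fewer than 5 regions merge into their nearest
  neighbor; a stratum emptied by exclusion collapses into the nearest
  filled one with a warning.
* A sample with zero reads yields an all-zero column plus a warning, never
  an error; a zero-total small-RNA sample is dropped with a warning.
* All-region exclusion (an empty null) and non-convergence at `max_iter`
  are reported as an error and a flagged warning respectively.
* Every random draw flows through a single seed argument; reruns from one
  config + seed are byte-identical, which the tests assert on the written
  output files.

## Problem sizes used by the test suite

The statistical checks run at 2000 units (type-I control, parameter
recovery, 10 seeds each), 1000 units × 20 seeds (FDR tracking), 500
features × 10 seeds (small-RNA null), and sub-second brute-force oracle
sweeps; these sizes give stable empirical rates while keeping a full run
of the suite in the low minutes on a single core.

## Known limitations

* No between-sample depth normalization by default (the scored quantity is
  raw captured bases); equal-depth scaling is available behind a flag in
  the quantification step but the statistic itself does not model library
  size.
* No covariate adjustment, paired designs, or chromosome-specific nulls.
* The directional mutual exclusivity means a region's evidence is only
  ever evaluated against one tail per analysis.
* Exact permutation at 2–4 replicates per group has a coarse p-value
  grain; see the small-RNA section above.
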