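---
title: "Z-ratio differential expression and gene-dosage imbalance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Z-ratio differential expression and gene-dosage imbalance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zdosage)
```

## The problem

Trisomy 21 (Down Syndrome, DS) triplicates every gene on chromosome 21 and
perturbs expression genome-wide. A common way to ask *where* and *when* a
gene responds is to take an existing log2-scale microarray compendium of
postmortem brain samples — DS cases and euploid controls spanning many
brain regions and ages from mid-gestation to adulthood — and test, within
each brain region and each developmental age window separately, whether the
gene's expression in the DS group stands out. `zdosage` implements that
analysis as a reusable, fully testable pipeline: per-array standardization,
a Z-ratio differential-expression statistic, and a log2-fold "dosage ratio"
that reads directly as an apparent copy-number class.

## The statistics

**Per-sample Z-score.** Each array (sample) is standardized across its
genes: for gene $g$ on array $s$,

$$ z_{gs} = \frac{x_{gs} - \bar{x}_{\cdot s}}{\mathrm{sd}(x_{\cdot s})}, $$

with $x$ the log2 intensity and the mean and standard deviation taken over
all genes of that array. This removes array-level location and scale, so
arrays hybridized at different overall intensities become comparable. We
read the formula literally as a *per-array* standardization (the
denominator runs over the gene index); the per-gene alternative is
rejected because the next step already standardizes across genes. The
standard deviation uses the $n-1$ (sample) convention throughout;
`sd_type = "population"` is available.

**Winsorization.** The replication profile clips Z-scores to
$[-3, +3]$ — the two-tailed normal 0.003 band — before any group statistic
is formed. Plain clipping (winsorization) is the one reading of "normalize
to a $\pm 3$ linear scale" that guarantees the stated range while leaving
values inside the band untouched; a min–max rescale would instead let a
single outlier compress every other sample's scores. Clipping slightly
perturbs the exact mean-0/sd-1 property, which is why it is off by default
(`run_config(profile = "default")`) and on in the replication profile
(`profile = "replication"`). Whether the original analysis clipped before or
after the ratio is not determinable; we clip before, and the flag is
configurable.

**Z-ratio.** Within a stratum (all samples, one brain region, or one age
rank), let $d_g = \bar z_{g,\mathrm{DS}} - \bar z_{g,\mathrm{ctrl}}$ be the
difference of group-mean Z-scores of gene $g$. Then

$$ Z\text{-ratio}_g = \frac{d_g}{\mathrm{sd}(d_1, \dots, d_n)}, $$

the denominator being the standard deviation of those differences *across
all analyzed genes in the stratum*. A gene is called overexpressed when its
Z-ratio exceeds 1.96, the two-tailed 5% normal critical value; a value
exactly at the cutoff is not called ("over", not "at"). Two-tailed normal
p-values accompany every ratio, and a Benjamini–Hochberg column is emitted
for reference but never gates the call — the method itself is a per-test
$\alpha = 0.05$ procedure.

The gene universe matters: the denominator is a property of the analyzed
gene set. The pipeline defaults to all genes surviving the presence filter
(`universe = "all_filtered"`); restricting to a short list
(`"listed_genes"`) makes the denominator unstable (with five genes it is a
standard deviation of five numbers) and is provided only for exploration.

Because the Z-ratio denominator is estimated from the same genes it
scales, the null distribution of the statistic is close to, but not
exactly, standard normal — per-sample centering also couples genes (the
differences sum to zero across genes). The regression test of the null
behaviour therefore freezes the *empirically established* null call rate
(0.02482 over 200 seeded 500-gene null datasets) rather than asserting
2.5%.

**Dosage ratio.** On the *unstandardized* log2 scale,
$M = \overline{\log_2(\mathrm{DS})} - \overline{\log_2(\mathrm{ctrl})}$
and $R = 2^M$, the DS/control fold ratio. $R$ is binned into copy-number
style classes: $[0.80, 1.30]$ balanced (two copies), $[1.4, 1.7]$
triplicated (three copies — a clean 3:2 dose gives $R = 1.5$,
$M = 0.585$), $> 1.8$ amplified. The stated ranges leave gaps; rather than
silently snapping to the nearest class, the classifier reports the
explicit categories `gap_low` $(1.30, 1.4)$, `gap_high` $(1.7, 1.8]$ (the
amplified bound is strict) and `reduced` $(< 0.80)$, making the
classification a total, monotone function of $R$. M is never computed on
Z-scores: only on the log2 scale does $2^M$ mean a fold change.

## Preprocessing and stratification

**Presence filter.** A probe is retained when its *linear* signal
intensity exceeds 100 in at least half the samples. The comparison is
strict (`> 100`) and "at least half" is `>=`, so on an even sample count
exactly $n/2$ qualifying samples suffice. The filter expects linear
intensities; log2 input is first converted with `to_linear()` ($2^x$).
Upstream-filtered data pass through unchanged (the filter is idempotent).
Background correction, RMA/PLIER summarization and batch correction are
out of scope — the pipeline consumes already-normalized log2 values.

**Age ranks.** The six default bins are 16–22 weeks of gestation, 0–12
months, 2–10, 12–22, 30–39 and 40–42 years. Gestational ages only match
gestational bins; postnatal ages match across the month/year units via
12 M = 1 Y. The bins are disjoint, and ages in the gaps (say 25 Y) are
left *unassigned* with a warning count — the bins are a results artifact
and nothing licenses snapping a gap age to its nearest bin. Overlapping
bin definitions are rejected as a configuration error, which is what
guarantees assignment is single-valued.

**Strata.** Each stratum (whole brain, a region, an age rank) is analyzed
independently; a stratum in which either karyotype group is empty is
skipped with a logged warning rather than imputed or crashed on. The
whole-brain column pools all samples by default; `brain_pooling =
"region_mean"` instead averages the per-region ratios, since either
pooling is defensible and published tables rarely state which was used.

## The synthetic-data generator

`simulate_dataset()` emulates the structure the analysis assumes: log2
value $= \mu_g + \delta_{gs} + \varepsilon$, with per-gene baselines
$\mu_g \sim N(8, 1.5^2)$ log2 units, residual noise
$\varepsilon \sim N(0, 0.2^2)$, and planted effects
$\delta_{gs} = \log_2(\text{fold})$ for DS samples inside the planted
stratum. Defaults mirror a two-group postmortem brain design: all 11
region codes with 5 samples per group per region (55 per karyotype group,
close to the 58-per-group design such compendia use), ages drawn uniformly
over the six bins. Gaussian log2 noise is appropriate for RMA-style
processed intensities; the generator aims at structural fidelity, not
array physics — it has no probe-level cross-hybridization, no
sex-chromosome dosage, no region- or age-correlated baselines, and no
sample-level batch structure. Passing tests on this generator therefore
demonstrate the *statistics* are computed correctly and are recoverable
under the assumed model, not that the model captures every property of
real brain arrays.

A single integer seed fixes the entire stream (sample ages and sexes, gene
baselines, noise), so fixtures regenerate byte-identically and every
simulation in the test suite is reproducible. The generator saves and
restores the caller's RNG state.

## Numerical choices and degenerate inputs

* Standard deviations are sample ($n-1$) unless configured otherwise.
* A zero within-sample standard deviation (a constant array) is an error
  naming the sample; identical DS and control groups make every gene
  difference equal, a zero denominator, and an explicit error — not a NaN.
* Significance flags are computed at full precision; report files display
  two decimals, so a value printing as 1.96 may or may not be flagged, and
  the flag, not the printed value, is authoritative.
* Series-matrix values are written with six decimal places; a write→parse
  round trip preserves values to better than $10^{-5}$.
* Probe collapse defaults to the mean over a gene's probes (median and max
  available); a probe mapping to two genes is an error, unmapped probes
  are dropped with a logged count.
* Network statistics count *distinct* neighbors (multi-edges collapse) and
  use the population variance in the heterogeneity
  $\sqrt{\mathrm{var}(k)}/\bar{k}$, matching the conventions of the
  network-analysis tools such summaries are usually produced with; both
  are configurable. The empty graph returns a flagged all-zero summary.

## Problem sizes used in the checks

The test suite and acceptance checks run entirely on generated data:
parameter recovery uses a planted 1.5-fold gene with 20 samples per group
and residual sd 0.2 over 500 seeded replicates (mean recovered $M$ within
$\pm 0.02$ of 0.585; $\ge 95\%$ of replicates classified triplicated);
stratum specificity uses 100-gene, two-region datasets over 500 seeds with
a majority-vote criterion; the null-rate regression uses 200 seeded
500-gene null datasets. These sizes give sampling error comfortably below
the tolerances they are checked against.

## Limitations

* The method is a per-test $\alpha = 0.05$ normal approximation; there is
  no variance moderation or shrinkage, and the BH column is informational.
* Z-ratio magnitudes depend on the analyzed gene universe; values computed
  over different universes are not directly comparable.
* Dosage categories are descriptive bins on a fold ratio, not copy-number
  calls; confounding (e.g. cell-composition differences between DS and
  control brain) moves $R$ just as real dosage does.
* Real-data replication of published per-region tables depends on probe
  selection, collapse rule and clip ordering, none of which are fully
  specified by such publications; the optional benchmark harness
  (`inst/scripts/gse59630-benchmark.R`) exposes them as parameters and
  reports per-cell deviations rather than asserting exact agreement.
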