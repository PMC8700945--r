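# zdosage

Z-ratio differential expression and gene-dosage imbalance analysis for
stratified log2 microarray studies.

## The problem

Trisomy 21 (Down Syndrome, DS) triplicates every chromosome-21 gene and
dysregulates expression genome-wide. Given a log2-scale expression
compendium of postmortem brain samples — DS cases and euploid controls
spanning several brain regions and ages from mid-gestation to adulthood —
`zdosage` asks, for each gene, **where** (which brain region) and **when**
(which developmental age window) its expression in the DS group stands
out, and whether the shift looks like a gene-dosage (copy-number) effect.
It is written for transcriptomics analysts re-analyzing GEO-style
series-matrix data, and for anyone needing a tested implementation of the
Z-ratio statistic.

## The method

1. **Per-sample Z-score.** Each array is standardized across its genes:
   `z = (x − mean(x)) / sd(x)` over the genes of that sample (log2 scale).
   The replication profile additionally winsorizes Z-scores to [−3, 3].
2. **Z-ratio.** Within a stratum (whole brain, one region, or one age
   rank), for each gene `g`:
   `Z-ratio_g = (z̄_g,DS − z̄_g,ctrl) / sd(d_1, …, d_n)`,
   the denominator being the standard deviation of the group-mean
   differences across all analyzed genes. `Z-ratio > 1.96` (the two-tailed
   5% normal critical value) flags overexpression; two-tailed normal
   p-values are reported alongside.
3. **Dosage ratio.** On unstandardized log2 values,
   `M = mean(log2 DS) − mean(log2 ctrl)` and `R = 2^M`. `R` is binned into
   copy-number style classes: 0.80–1.30 balanced, 1.4–1.7 triplicated
   (a clean 3:2 dose gives R = 1.5), > 1.8 amplified, with the between-bin
   gaps reported explicitly (`gap_low`, `gap_high`, `reduced`).

Around the statistics the package provides: GEO series-matrix read/write,
probe→gene collapse, the linear-intensity presence filter (signal > 100 in
at least half the samples), region/age-rank stratification, interaction
network topology summaries (average distinct neighbors, degree
heterogeneity), a seeded synthetic-data generator with planted fold
changes, and a small CLI (`inst/scripts/zdosage`).

## Worked example

Simulate a three-region study with a 1.5-fold trisomic dose planted for
one gene in the hippocampus only, then run the replication profile:

```r
library(zdosage)

cfg <- sim_config(
  n_genes = 200, n_per_group = 10, regions = c("HIP", "CBC", "DFC"),
  planted = data.frame(gene_id = "G0001", fold_change = 1.5, stratum = "HIP"),
  seed = 42
)
sim <- simulate_dataset(cfg)

rep <- zratio_report(sim$matrix, sim$metadata, config = run_config("replication"))
#> 44 probe(s) removed by presence filter
subset(rep$wide, gene_id == "G0001")
#>  gene_id Brain  HIP  CBC   DFC
#>    G0001  4.08 6.16 1.11 -0.75
```

The planted gene is far over the 1.96 cutoff in HIP (Z-ratio 6.16), drags
the pooled whole-brain column up (4.08, one third of its DS samples carry
the dose), and stays null in the unplanted regions. The dosage report
reads the same shift as an apparent copy-number class:

```r
dos <- dosage_report(sim$matrix, sim$metadata, config = run_config("replication"))
subset(dos$long, gene_id == "G0001" & stratum %in% c("HIP", "CBC"))
#>  gene_id stratum m_value r_ratio    category
#>    G0001     HIP   0.661    1.58 triplicated
#>    G0001     CBC   0.117    1.08    balanced
```

In HIP the recovered `M` ≈ 0.66 log2 units gives `R` ≈ 1.58, inside the
triplicated band around the ideal 1.5; CBC is balanced. A bundled toy
interaction network shows the topology summary:

```r
g <- load_edgelist(system.file("extdata", "toy_network.tsv", package = "zdosage"))
topology_summary(g)
#>  n_nodes n_edges n_components n_multi_edge_pairs avg_neighbors heterogeneity
#>       11      12            1                  1             2     0.6030227
```

See `vignettes/zdosage-methods.Rmd` for the model, its assumptions, every
tunable parameter, and known limitations.

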