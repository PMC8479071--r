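# chromodyn

Temporal analysis of chromatin accessibility and gene expression
across developmental stages, as one tested R pipeline.

Bulk RNA-seq and ATAC-seq time courses over a few developmental
stages (e.g. three limb bud stages with three replicates each) raise
the same chain of questions: which genes and which accessible
chromatin regions change between stages; what temporal shapes those
changes take; whether chromatin modules sit next to expression
modules; which TF binding motifs and footprints mark the modules;
which TF-target interactions they support and how conserved those
are between species; and which otherwise-conserved noncoding
elements have accumulated excess substitutions on one lineage.
chromodyn implements that chain for analysts working with such
designs, together with a synthetic-data generator with planted
ground truth so every stage is testable without sequencing data.

## Methods at a glance

* **Differential calling** — TMM normalization (doubly trimmed
  weighted mean of M-values, factors rescaled to geometric mean 1),
  then an exact-style conditional test on group sums in the
  negative-binomial family: the group-A sum is tested against its
  conditional distribution given the total, with NB(size = n/phi)
  group sums and null means proportional to effective library sizes;
  at dispersion 0 this is the exact binomial conditional test.
  Features pass with |linear FC| >= 1.5 and BH-adjusted p <= 0.05 in
  >= 1 stage pair.
* **Temporal modules** — per-stage means of log2(CPM+1) min-max
  scaled to [0,1]; k-means seeded with the six binary temporal
  patterns (the 2^3 on/off trajectories minus flat (0,0,0) and
  (1,1,1)); a single deterministic Lloyd run; modules named
  stage^hi / stage^lo from their seed; silhouette validation.
* **Association** — peaks assigned to the nearest TSS (midpoint,
  strand-aware sign); each DAC-module x DEG-module cell tested with
  a two-sided Fisher exact test, BH over the 36 cells.
* **Motifs** — PWM scanning with exact p-values (discretized-score
  convolution, verified against brute-force enumeration up to width
  8), hit threshold p < 1e-4, both strands; module enrichment by
  one-sided Fisher on hit-sequence counts against a
  complementary-pattern background module.
* **Footprints** — motif-centered aggregate cut profiles (200-bp
  window, 5-bp moving average) and the depth statistic
  1 − core/flank.
* **Networks** — edges (TF → target) supported by motif hits in
  accessible peaks mapped to curated targets, weight = hit count;
  cross-species similarity S = 1 − D with
  D = (N/M + I/(2J))/2 over connection and target sets
  (N, I symmetric differences; M, J unions).
* **Accelerated regions** — merge conserved elements, drop blocks
  with >50% focal sequence missing, count per-branch substitutions
  by exact Fitch/Sankoff parsimony with fractional attribution over
  minimal reconstructions, test focal-branch excess with a one-sided
  binomial against the branch-length share, BH at FDR < 5%.

## Worked example

Simulate a 500-gene, 3-stage count matrix with 120 planted features
following the six temporal patterns, call differential genes, and
cluster their trajectories:

```r
library(chromodyn)

ids   <- sprintf("f%03d", 1:500)
truth <- make_planted_truth(ids, 120, seed = 1)
cm    <- generate_counts(truth, baseline_mean = 100, fold = 4,
                         dispersion = 0.1, seed = 2)
cm$norm_factors <- tmm_factors(cm)

deg <- call_differential(cm, fc = 1.5, alpha = 0.05)
deg
#> differential_result: 3 contrasts, 137 differential features

head(deg$table[deg$table$significant, ], 3)
#>    feature contrast     logFC       pvalue         padj significant
#> 13    f013    S1/S2 -2.075351 2.509249e-13 1.905286e-11        TRUE
#> 14    f014    S1/S2 -2.029696 1.063455e-07 1.063455e-06        TRUE
#> 22    f022    S1/S2 -1.808164 3.626849e-06 2.789884e-05        TRUE

ms <- cluster_trajectories(stage_means(cm, deg$differential),
                           stage_names = c("E9.75", "E10.5", "E11.5"))
ms
#> module_set: 137 features in 6 modules, average silhouette 0.739

table(ms$module)
#> E10.5^hi E10.5^lo E11.5^hi E11.5^lo E9.75^hi E9.75^lo
#>       25       25       22       23       20       22

mean(names(truth)[truth != "flat"] %in% deg$differential)
#> [1] 1
```

All 120 planted features are recovered (plus a handful of
false positives consistent with the 5% FDR), each module collects
the features planted with its seed pattern, and the average
silhouette of 0.74 reflects the clean separation of the planted
trajectories.

## The full analysis

`analysis/` contains numbered drivers that run the whole study on
one synthetic genome and write their tables under `results/`:

1. `01_simulate.R` — genome fixture, planted temporal programs,
   peak-gene coupling, counts, peak sequences with planted motifs
2. `02_differential.R` — TMM + differential calling (DEGs, DACs)
3. `03_modules.R` — seeded k-means modules and silhouettes
4. `04_association.R` — nearest-gene map and the 6x6 Fisher matrix
5. `05_motifs.R` — genome-wide hit prediction and module enrichment
6. `06_footprints.R` — aggregate cut profiles and footprint depth
7. `07_network.R` — GLI3/HAND2 target networks, cross-species
   similarity, ortholog stage correspondence
8. `08_cars.R` — accelerated-region discovery and annotation

Run them in order from the repository root:
`for s in analysis/0*.R; do Rscript "$s"; done`

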