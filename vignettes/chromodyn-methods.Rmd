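---
title: "chromodyn: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromodyn: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromodyn)
```

## The problem

Limb bud development proceeds through a small number of
morphologically defined stages, and both the transcriptome (RNA-seq)
and the accessible-chromatin landscape (ATAC-seq) change in
characteristic temporal waves across them. chromodyn implements the
downstream analysis of such a three-stage, replicated design as one
coherent pipeline: normalization and differential calling, seeded
clustering of temporal trajectories into named modules, positional
association of chromatin modules with expression modules, motif
scanning and enrichment inside module peaks, aggregate footprint
profiles, motif-supported TF-target networks with a cross-species
similarity score, and detection of conserved noncoding regions with
lineage-accelerated substitution rates.

The package ships a synthetic-data generator with planted ground
truth, so every stage can be scored end to end without sequencing
data. The `analysis/` scripts run the whole study on one synthetic
genome; `scripts/acceptance.R` recomputes the headline recovery
numbers from scratch.

## Differential calling

Counts (genes x samples or peaks x samples) are normalized with TMM:
for each sample against a reference, gene-wise log2 ratios of
depth-scaled counts are doubly trimmed (30% on the log ratio M, 5% on
the average intensity A) and averaged with inverse delta-method
variance weights; factors are rescaled to geometric mean 1. The
implementation reproduces the reference `edgeR::calcNormFactors`
output to ~1e-8 on test fixtures, but is self-contained.

The pairwise test is an exact-style conditional test in the
negative-binomial family rather than a GLM likelihood-ratio test.
For each feature and stage pair the two group sums are modelled as
independent NB variables with size $n_g/\phi$ ($n_g$ replicates,
$\phi$ the feature's dispersion) and null means proportional to the
effective library sizes; the p-value sums the conditional
probabilities (given the total) not exceeding that of the observed
split, in the style of Fisher's exact test. Two properties motivate
this choice:

* at $\phi = 0$ the conditional distribution is *exactly* binomial,
  giving a closed-form oracle the tests exploit;
* it requires no iterative fitting, so the whole pipeline stays
  deterministic and fast.

This deliberately does not numerically reproduce a GLM/LRT analysis;
feature-level p-values will differ, while the calibration and power
properties are tested directly (null false-positive fraction at the
nominal level; >95% sensitivity for 4-fold planted features at
dispersion 0.1).

Dispersion is estimated by per-feature method of moments pooled over
stages, $\hat\phi = \sum_s (v_s - m_s) / \sum_s m_s^2$ floored at 0,
shrunk halfway toward the median dispersion (the 0.5 weight is a
conventional compromise between per-feature noise with 3 replicates
and global bias; it is exposed as a parameter).

Calls use the thresholds |linear FC| >= 1.5 and BH-adjusted p <=
0.05 per contrast; a feature is differential if it passes in at least
one of the three stage pairs. The fold change uses a 0.5 prior count
per group so zero counts cannot produce infinite estimates. The CPM
filter keeps a feature iff CPM >= 1 in *all* replicates of at least
one stage (the weakest reading that still demands within-stage
consistency); peak matrices skip the biotype filter, and no CPM
filter is applied to peaks by default since reproducible-peak calling
happens upstream of the count matrix.

## Temporal modules

Per-feature stage values are the mean over replicates of
log2(CPM + 1) (the +1 offset keeps zeros finite and compresses
depth noise at low counts). Each trajectory is min-max scaled,
$(x - \min x) / \max(x - \min x)$, constant trajectories mapping to
(0,0,0) by convention.

With two signal states and three stages there are $2^3$ binary
trajectories; dropping the two flat ones leaves six, which are the
fixed k-means seeds. Seeding *is* the method: a single deterministic
Lloyd run (max 300 iterations, centroid-shift tolerance 1e-6, ties
to the lowest seed index, an emptied cluster reverts to its seed),
no random restarts. Modules are named from their seed: a single-1
pattern at stage $s$ is "$s$^hi", a single-0 pattern "$s$^lo".
Partitions are validated with the standard silhouette
$s = (b-a)/\max(a,b)$ (singletons score 0). On well-separated
synthetic data the average silhouette is ~0.7-0.85; positive values
indicate separation, and the score is reported rather than
thresholded.

## Peak-gene association

Each peak is assigned the gene whose TSS is nearest its midpoint
(strand-aware sign: positive downstream of the TSS in gene
orientation; exact ties go to the lexicographically smallest gene id
and are flagged). For every DAC-module x DEG-module pair a 2x2 table
is built over the universe of module-assigned peaks whose mapped
gene carries a module label: peak in DAC module a (or not) vs mapped
gene in DEG module b (or not). Each cell gets a two-sided Fisher
exact test; BH correction is applied jointly across all 36 cells
(no stratification is stated for the design, and the joint
correction is the more conservative choice). The reported odds ratio
is the sample ad/bc with a Haldane 0.5 correction only when a cell
is zero. Whether the universe should also include peaks mapped to
non-module genes is genuinely open; the mapped-universe choice is
permutation-testable and is the one the calibration test exercises.

## Motif scanning and enrichment

PWMs carry a background model and pseudocount; scores are
log2((p + c*bg)/((1+c)bg)) bits. Score p-values are exact: scores
are discretized to a 0.001-bit grid (floored, so binning can only be
conservative) and the null distribution of the window score under
the i.i.d. background is obtained by positionwise convolution.
Scanning uses the same discretized matrix, so observed scores and
p-values live in the same exact space; brute-force enumeration over
all $4^w$ words reproduces the DP for every width <= 8 tested. Hits
are positions (both strands, N-containing windows skipped,
reverse-strand hits reported on the forward axis) with p < 1e-4 —
note a width-6 motif cannot reach this threshold
($4^{-6} \approx 2.4\times 10^{-4}$), which the tests assert.

Module enrichment compares a foreground module's peak sequences with
a dissimilar background (the lo module of the same stage, i.e. the
complementary temporal pattern). A sequence is a hit sequence if it
carries >= 1 hit; counts feed a one-sided Fisher test, the reversed
test gives depletion, and BH runs across motifs per direction. This
hit-count classification replaces average-odds scoring so that one
scanning threshold serves both the genome-wide prediction and the
enrichment stage; it is a documented divergence, not an emulation of
any external tool.

## Footprints

Aggregate profiles average a per-base cut-count track over windows
(100-bp flank each side of the motif core; minus-strand windows
reversed; absent positions count 0), followed by a 5-bp centered
moving average with truncated edges. The summary statistic is the
footprint depth, 1 - core mean / flank mean, with the flank defined
as the outermost 50 bp on each side; it is 0 for no protection and
1 for a fully protected core, and recovers the generator's
protection levels {0, 0.4, 0.8} within +-0.05 at 500 sites. Profiles
are raw cut means — no transposase sequence-bias correction is
applied, so depths are comparable across stages for the same motif
but not across motifs with different sequence composition.

## TF-target networks

An edge (TF, gene) exists iff at least one hit of the TF's motif
falls in an accessible peak mapped to the gene and the gene is in
the curated target list; the weight is the number of supporting
hits. With two source TFs, a target reached by both is "shared",
otherwise TF-specific. Each target is assigned the DEG module whose
centroid best correlates (Pearson) with its stage means.

Cross-species comparison maps the second network's targets through a
one-to-one ortholog table (unmapped targets always count as
different) and compares connection sets: with $M$ all connections
(union), $N$ different connections (symmetric difference), $J$ all
targets and $I$ different targets,

$$D = \frac{1}{2}\left(\frac{N}{M} + \frac{I}{2J}\right), \qquad
S = 1 - D.$$

The symmetric-difference/union reading is a design decision: it is
the only assignment that makes $S$ symmetric, equal to 1 for
identical networks, and bounded below by 0.25 for disjoint non-empty
networks — all three identities are asserted in the tests. Stage
correspondence between species is the Spearman correlation of
ortholog expression per stage pair, with average ranks for ties.

## Accelerated conserved regions

Conserved elements are merged transitively across gaps <= 50 bp (the
merge distance is an explicit placeholder — no value is prescribed —
and is a parameter). Alignment blocks missing strictly more than 50%
of the focal species' sequence are dropped (exactly 50% is kept).
Substitutions are counted per branch by exact Fitch/Sankoff
parsimony with minimal-reconstruction counting: when several
minimum-cost reconstructions exist, each branch receives the
expected number of its state changes under the uniform distribution
over all minimal reconstructions, computed by a bottom-up/top-down
DP (no sampling). Columns containing a gap or N in any species are
skipped.

The acceleration test is a one-sided binomial: the focal branch's
(rounded) count against the focal share of total tree length. This
is a deliberately simple stand-in for a full phylogenetic
likelihood model; externally computed per-region p-values can be
passed straight to `call_cars()`, which applies BH and flags regions
with q strictly below 0.05. Parsimony undercounts multiple hits on
long branches, which makes the test conservative at high rates;
under the study conditions (5-taxon tree, 200-bp blocks, rate 0.05
per site per unit branch length, 10x acceleration on the focal
terminal branch) sensitivity is ~1 and the mean false-discovery
proportion ~0.02. Because the single-run false-discovery proportion
is quantized at 1/#discoveries, FDR control is assessed as the mean
FDP over replicate simulations — FDR is an expectation, and one
extra false positive among ~20 discoveries would otherwise flip a
single-run verdict.

CARs are annotated with the nearest gene by TSS distance from the
region midpoint (midpoint rather than edges — a documented choice),
the genes with TSS within 1 Mb (boundary inclusive), and a
DAC-proximity category: within 2 kb of DACs of both species, one, or
neither.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the
study conditions under which all recovery claims are made:

| parameter | default | rationale |
|---|---|---|
| stages x replicates | 3 x 3 | the design the pipeline targets |
| count noise | NB, dispersion 0.1 | typical bulk biological replicates; 0 degenerates to Poisson |
| baseline mean | 100 | moderately expressed features |
| planted fold step | 4 | clearly detectable but not trivial at n = 3 |
| background sequence | i.i.d. uniform ACGT | matches the scanner's default background |
| cut rates | flank 10/bp, protection in [0,1] | Poisson thinning inside the core |
| phylogeny | 5 taxa, total length ~1.5 | smallest tree where placement ambiguity matters |
| substitution rate | 0.05 /site/unit length | ~15 substitutions per 200-bp block |
| acceleration | 10x on the focal branch, 10% of blocks | strong planted signal with a large null majority |

Planted features follow the six binary temporal patterns exactly
(pattern-"1" stage means are fold x the pattern-"0" means), coupled
peaks are placed closer to their partner TSS than half the distance
to any other TSS so nearest-TSS assignment recovers them by
construction, planted motif instances are consensus words (or PWM
draws) at recorded coordinates, and accelerated blocks multiply the
focal branch's Poisson substitution count.

What the generator does *not* emulate — and what passing tests
therefore cannot show about real data: read-level artifacts
(mapping, duplication, GC bias), transposase sequence preference and
fragment-size structure, correlated replicates or batch effects,
overlapping/nested genes and peak boundary uncertainty, indel
evolution (alignment blocks are gapless except for injected missing
data), and rate variation across sites. Results on real data depend
on upstream processing that is out of scope here (alignment, peak
calling, reproducibility filtering, liftover).

## Problem sizes and runtime

The shipped analysis uses one 4-Mb chromosome, 800 genes, 1000
peaks (300-bp), 3 x 3 count matrices, 2 motifs, and 200 alignment
blocks; the full driver sequence runs in about a minute on one CPU,
and the test suite plus acceptance checks in a few minutes. These
sizes were chosen so that every Monte-Carlo assertion has comfortable
error margins (>= 500 sites for footprint depth, >= 2000 features
for calibration, 3000 trajectories for clustering recovery) while
remaining desk-scale.

## Known limitations

* Differential p-values approximate the NB conditional law when
  replicate library sizes differ within a group (the group-sum NB is
  exact only for equal means); calibration is verified empirically.
* TMM factors inherit composition bias when the differential
  fraction is very high (~45% of peaks in the shipped simulation),
  inflating the null call rate slightly — visible and reported in
  the driver output.
* The acceleration test ignores rate variation among branches beyond
  branch length and treats parsimony counts as observed data.
* The enrichment stage classifies sequences by hit presence;
  information in hit multiplicity is used only by the network edge
  weights, not the enrichment statistic.
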