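---
title: "Methods: stage-series multi-omics integration in stageomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-series multi-omics integration in stageomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

stageomics analyses a developmental series sampled at 11 stages with 3
biological replicates per stage. Three abundance layers (metabolome,
proteome, transcriptome) are held in `feature_table` objects — a features ×
(stage, replicate) matrix bound to a `stage_design` — while whole-genome
bisulfite data are held as per-cytosine count tables (chromosome, 0-based
position, strand, CG/CHG/CHH context, methylated/unmethylated read counts,
sample). All genomic coordinates are 0-based half-open internally; the
Bismark-style cytosine report (1-based) is converted on ingest and BED
output stays 0-based, so a single convention holds everywhere. Zero-coverage
cytosines are retained in the tables but excluded from every level
computation: a missing level is `NA`, never 0.

All cross-layer statistics operate on **stage means** (the average of the
three replicates), matching the replicate-averaging convention of the assay
design.

# Differential calling

`call_differential()` compares two stages with a Welch two-sample t test on
`log2(value + 1)` across replicates and declares a feature differential when
both gates pass: absolute fold change ≥ 2 on the stage means (pseudocount 1)
and Benjamini–Hochberg FDR < 0.05, adjusted across all features of the layer
for that stage pair. The FDR family is the smallest defensible one (one
layer, one pair); Benjamini–Yekutieli is available via `fdr_method = "BY"`.
`differential_all_pairs()` runs all 55 unordered pairs; a feature is a
DAM/DEP/DEG when significant in at least one pair. A Welch test on logged
abundances is used for all three layers: one documented, dependency-free
engine with exactly the fold-change + FDR gates of the study design. Count
models with dispersion shrinkage would give somewhat different gene lists;
that trade-off is deliberate and recorded here.

Degenerate inputs: features that are all-zero in both stages are excluded
and reported via the `excluded` attribute; zero-variance groups yield p = 1
when means agree and p = 0 otherwise.

# Trend clustering

DAM stage-mean series are z-score standardized (sample sd; constant series
map to zeros and carry a `degenerate` flag) and clustered into eight trend
clusters labelled I–VIII. The archetypes are fixed shapes on the z scale:
linear decline (I), fast early decay (II), late sigmoid drop (IV), linear
rise (III), late exponential rise (V), early-saturating sigmoid rise (VI),
and Gaussian peaks at S7 (VII) and S6 (VIII). Labels are assigned by
greedily matching each centroid to its most-correlated archetype
(bijection enforced; ties broken by label order).

K-means (Euclidean) is the clustering engine. When k = 8 the centroids are
**initialized at the archetypes** rather than by random restarts: the three
monotone-decreasing (and three increasing) archetypes correlate at
0.87–0.91, and randomly initialized k-means reproducibly merges such pairs
while spending centroids on idiosyncratic non-archetype DAMs — on synthetic
data this lowered the adjusted Rand index from 1.00 to 0.74 even though the
merged solution has the *lower* within-cluster sum of squares, so more
restarts cannot repair it. Anchored initialization is therefore the
default; 20 seeded random restarts remain available (`anchor = FALSE`), as
does Ward hierarchical clustering (`method = "ward"`).

# Association database

`build_association_edges()` tests every (source, metabolite) pair by
Pearson correlation of the 11-point stage means (two-sided p from the t
transform with n − 2 df), adjusts with BH across all tested pairs of the
layer, and retains edges with |r| > 0.85 and FDR < 0.05. Sources are the
layer's differential features and targets the DAMs. Zero-variance series
are skipped and logged. Note that with n = 11 and ~10^4–10^5 tested pairs
the BH step is the binding constraint: the smallest retainable |r| is
approximately 0.9, slightly above the nominal 0.85 gate.

The transcript/translation **consistency filter** removes each (gene,
metabolite) pair supported by both a transcript edge and a protein edge
whose signs disagree; genes without a detected protein pass through.
Sign-only discordance is used (magnitude is not compared) — the narrower
reading of "inconsistent correlation".

`methylation_expression_edges()` correlates each gene's promoter
methylation series (all contexts pooled, replicates pooled per stage, 2-kb
strand-aware promoter) with its expression stage means, BH-adjusted across
genes; both signs are reported. The scan covers **every gene with a covered
promoter**, not only DEGs: planted methylation–expression couplings in the
synthetic benchmark are sub-fold-change by design (see below), and
restricting the scan to DEGs would exclude exactly the couplings the
benchmark must recover. `genome_methylation_dam_correlation()` correlates
the single whole-genome pooled methylation series with every DAM and
summarizes the median r per trend cluster.

# Methylation

Region levels are count-pooled: Σ methylated / Σ (methylated +
unmethylated) over covered context-matched sites in the interval.
`metagene_profile()` rescales each gene body to 40 bins with 2-kb flanks in
100-bp bins, reversing minus-strand genes so "upstream" is always 5′.

`call_dmrs()` is a deliberately simple windowed caller: replicates are
pooled within stage; 100-bp windows at 50-bp steps are tested per context
with Fisher's exact test on the pooled 2×2 count table; BH runs across all
tested windows of a context; windows pass at q < 0.05 **and** |Δ level| ≥
0.1; overlapping or adjacent (gap ≤ 50 bp) significant windows of the same
context and direction merge, and merged intervals re-pool their counts.
Windows with fewer than 4 covered positions in both stages are skipped and
counted. This replaces smoothed beta-binomial DMR models: it is
self-contained, oracle-testable (the Fisher p is cross-checked against a
hypergeometric enumeration in the tests), and its parameters are explicit.
Per-replicate dispersion modelling is out of scope for this caller, so its
p-values are anti-conservative under replicate heterogeneity — the Δ gate
is what keeps the practical false-discovery proportion low.

Promoters are 2000 bp upstream of the annotated 5′ end, strand-aware and
clipped at contig boundaries; 2 kb is the length used for promoter assays
in this system and is a configuration knob, since no methylation window is
canonically defined. siRNA cluster abundance is reads per million total
clean reads, with each 24-nt cluster assigned to the region containing its
midpoint so clusters straddling boundaries are counted exactly once.

# The synthetic generator

`simulate_multiomics()` produces the full benchmark dataset from one seeded
random stream. What it emulates, and what it deliberately does not:

* **Trends.** Each feature's true stage series is *affine* in a
  standardized trend y: `series = scale × (base + amp × (y − min y))`, with
  per-feature log-normal intensity scales. 80% of metabolites carry an
  archetype (correlation 0.995 to the archetype shape plus an orthogonal
  individual component); the remainder are coupling partners with
  idiosyncratic standardized trajectories. Partner trajectories are white
  on the z scale: temporal smoothing makes independent trajectories
  mutually correlated (a 3-point kernel already inflates pairwise |r| sd
  from 0.32 to ~0.45 at n = 11) and floods the |r| > 0.85 gate with
  partner–partner collisions.
* **Couplings.** Planted gene partners reproduce the partner metabolite's
  standardized series at exactly the target correlation 0.97
  (Gram–Schmidt); since both series are affine in their trends, the planted
  Pearson correlation carries to raw stage means exactly. Couplings attach
  to the idiosyncratic partners, not to archetype members: a gene coupled
  to an archetype member at r = 0.97 would correlate almost as strongly
  with every other member of that cluster, making recovery-FDR control
  structurally impossible at these thresholds.
* **Replicate noise** is additive on the standardized-trend scale
  (`noise_sd`, default 0.3, truncated so intensities stay positive). With
  multiplicative noise of the same magnitude (log-normal or
  negative-binomial with dispersion 0.1) the per-side correlation
  attenuation is bounded near 0.983, capping observed planted-edge
  correlations around 0.93–0.94 — below what the |r|/FDR gates at n = 11
  can retain at high sensitivity. Negative-binomial expression **counts**
  (dispersion `nb_dispersion`) are emitted alongside the abundance table
  (`transcript_counts`) for workflows that need them; the analysis pipeline
  consumes the normalized-abundance representation.
* **Amplitudes** are fixed per layer (metabolome base 1.2, amp 3.5; genes
  base 3, amp 10; proteins base 1.5, amp 5), giving stage-series fold
  changes of roughly 6–35 — typical dynamic ranges for developmental
  series, and chosen so a 3v3 Welch test retains power against the sparse
  BH families (the bottom-of-series variance dominates the Welch degrees
  of freedom, which fall to ~2 under additive noise).
* **Methylation.** Cytosines sit in a 150-bp island-like patch per 2-kb
  promoter (20 sites; context mix 25/25/50% CG/CHG/CHH) plus 10 gene-body
  sites, with binomial sampling at Poisson(30) depth. Population levels
  drift linearly: CHH 0.10 → 0.25, CG 0.55 → 0.45, CHG flat 0.30. Planted
  DMRs add +0.3 to the promoter patch's CHH sites from stage S6 onward —
  CHH hypermethylation only, the RdDM-dominant and, at these site
  densities, the only identifiable class (CG/CHG patches hold ~5 sites,
  below the 4-site window gate). Half the planted DMRs sit on planted-edge
  genes (so the transition funnel has DMR-modified correlated DEGs); half
  sit on methylation-coupled genes whose expression tracks the expected
  promoter series with a planted sign at sub-fold-change amplitude — they
  are recoverable by the promoter-coupling scan but never enter the DEG
  set, because a step-shaped DEG at S6 correlates at 0.79–0.91 with
  monotone trend-cluster members and would contaminate the association
  layer.
* **siRNA.** 2000 background 24-nt clusters plus clusters on half the
  planted DMR patches at 5× abundance, declining over the series.
* **Not emulated:** real genome coordinates and sequence context, mapping
  and conversion artifacts, missing values, batch effects, count-level
  mean–variance coupling in the *abundance* tables, or metabolite
  annotation chemistry. Passing the recovery benchmarks therefore shows the
  pipeline's statistical machinery is correct and calibrated under the
  stated generative model — not that real data meet that model.

# Benchmark configurations and problem sizes

The default study conditions (300 metabolites, 5000 genes, 1500 proteins,
200 planted edges at ρ = 0.97, 100 planted DMRs at Δ = 0.3 and depth 30)
are what `scripts/acceptance.R` and the end-to-end tests run; a full
pipeline pass takes ~3 minutes on one CPU. Unit tests use scaled-down
configurations (~80 metabolites, 400 genes) that preserve every structural
property. Two fixtures document their own parameters: the trend-recovery
fixture uses 8 × 50 members at z-scale noise 0.3 (adjusted Rand index ≥
0.8), and the fold-change-4 sensitivity fixture uses replicate log-noise
0.08, chosen by a power analysis of the 3v3 Welch design accounting for
the noncentral-t spread at ~4 degrees of freedom (design power 0.99
against the sparse-family BH threshold; at the generator's default noise
0.3 the design power for FC 4 is ~0.5, so no calling rule could reach 90%
sensitivity there).

# Numerical conventions

Sample (n − 1) standard deviations throughout; constant series are flagged,
not dropped silently, and excluded from correlation scans. Fisher p-values
are clamped to 1 (the exact test can exceed 1 by rounding). BH ties and
ordering follow the step-up definition `q_(i) = min_{j≥i} p_(j) m / j`.
k-means label mapping breaks ties by archetype label order. Pipeline
outputs are byte-stable for a fixed seed: a single seeded stream drives the
generator, clustering is anchored or seeded, and no timestamps enter any
output file.

# Known limitations

The DMR caller pools replicates and inherits Fisher's independence
assumptions; the single-engine Welch test will not match count-model DEG
lists on real RNA-seq; promoter length (2 kb) and the all-context pooled
"C methylation" series are documented defaults where the field has no
single convention; and the consistency filter compares signs only. The
recovery metrics score planted structure — correlations that are real under
the generative model but not planted (e.g. proteins of genes sharing a
partner metabolite) are counted as false positives, making the reported
FDRs conservative.
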