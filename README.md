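# stageomics

Integration of stage-series multi-omics data from developing fruit flesh:
metabolome, proteome and transcriptome profiles over an 11-stage
developmental series (3 biological replicates per stage), together with
whole-genome bisulfite methylation and 24-nt siRNA clusters.

The package implements, as tested reusable components:

- **Stage-pairwise differential calling** for metabolites (DAMs), proteins
  (DEPs) and genes (DEGs) over all `choose(11, 2) = 55` stage pairs, with
  the standard double gate: absolute fold change ≥ 2 on stage means and
  Benjamini–Hochberg FDR < 0.05 (Welch t on `log2(x + 1)` across
  replicates).
- **Trend clustering** of DAM stage-mean series (z-score standardized)
  into eight archetypal clusters I–VIII: early-high decreasing variants
  (I, II, IV), mid-series peaks at S7 and S6 (VII, VIII), and late-high
  increasing variants (III, V, VI).
- **A gene–metabolite association database**: Pearson correlation of
  11-point stage means for every (DEG, DAM) and (DEP, DAM) pair, retained
  at |r| > 0.85 and FDR < 0.05, followed by a transcript/translation
  **consistency filter** that removes gene–metabolite pairs whose
  transcript-level and protein-level correlation signs disagree.
- **Methylation analyses**: pooled region/metagene methylation levels in
  CG/CHG/CHH contexts, a windowed DMR caller (Fisher's exact test on pooled
  counts, BH across windows, minimum-site and minimum-delta gates, window
  merging), strand-aware 2-kb promoter/DMR overlap,
  promoter-methylation–expression coupling, whole-genome-methylation vs
  metabolite correlations, and 24-nt siRNA abundance as reads per million
  total clean reads (midpoint assignment).
- **Adjacent-stage transition accounting**: metabolites significantly
  increased at each next stage, the metabolite-class × transition count
  matrix, and the correlated-DEG / DMR-modified-correlated-DEG funnel per
  transition.
- **A synthetic multi-omics generator** with planted ground truth (trend
  archetypes, gene–metabolite couplings at target correlation 0.97,
  promoter CHH hyper-DMRs, methylation–expression couplings, siRNA
  enrichment) so the whole pipeline is benchmarked end to end without any
  external data.

## Worked example

```r
library(stageomics)

## a small synthetic study: 80 metabolites, 400 genes, 40 planted couplings
cfg <- simulation_config(seed = 101, n_metabolites = 80, n_genes = 400,
                         n_proteins = 160, n_planted_edges = 40,
                         n_planted_dmrs = 30)
man <- run_pipeline(cfg, out_dir = "example_run")
str(man$recovery)
```

```
List of 11
 $ edge_sensitivity        : num 1
 $ edge_fdr                : num 0
 $ n_edges_detected        : int 40
 $ n_edges_true            : int 40
 $ protein_edge_sensitivity: num 1
 $ protein_edge_fdr        : num 0
 $ dmr_sensitivity         : num 1
 $ dmr_fdr                 : num 0.0323
 $ n_dmrs_detected         : int 31
 $ cluster_ari             : num 1
 $ meth_expr_sign_recovery : num 1
```

All 40 planted gene–metabolite couplings are recovered with no false
edges; all 30 planted promoter CHH DMRs are found, with one spurious
window among the 31 calls (the 0.03 false-discovery proportion); the eight
trend clusters match the planted archetype labels exactly (adjusted Rand
index 1); and the sign of every planted promoter-methylation–expression
coupling is recovered.

`example_run/results/` then contains the differential tables per layer,
cluster assignments, DMR calls (TSV and BED), promoter-DMR gene flags,
metagene profiles, the association database (edge lists plus the removed
discordant pairs), methylation couplings, the class × transition matrix,
per-cluster network exports (TSV and GraphML) and a JSON manifest with
record counts and the recovery metrics above.

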