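#' Simulation configuration
#'
#' Parameters of the synthetic multi-omics generator. Defaults define the
#' benchmark study conditions: 11 stages x 3 replicates; 300 metabolites of
#' which 80% carry one of the eight trend archetypes; 5000 genes on one
#' synthetic chromosome (ChrSim) with 200 planted gene-metabolite couplings
#' at target stage-mean correlation 0.97; a 1500-gene proteome containing
#' every coupled gene, a fraction of which is sign-discordant at the protein
#' level; per-cytosine binomial methylation whose population CHH level rises
#' linearly from 0.10 (S1) to 0.25 (S11) while CG falls 0.55 -> 0.45 and CHG
#' stays flat at 0.30; 100 planted CHH promoter hyper-DMRs (+`dmr_delta`
#' from stage `dmr_start_stage` onward), half on coupled-expression genes and
#' half on planted-edge genes; 24-nt siRNA clusters enriched in half of the
#' planted DMRs.
#'
#' Abundance model: each feature's true stage series is affine in a
#' standardized trend y (`series = scale * (base + amp_layer * (y - min y))`),
#' and replicate noise of sd `noise_sd` is added on that standardized trend
#' scale before scaling (so reported intensities stay positive and Pearson
#' structure planted in y carries to raw stage means exactly). Expression is
#' additionally emitted as negative-binomial counts with dispersion
#' `nb_dispersion` around the same series.
#'
#' @param seed Integer seed; a fixed seed makes the full output byte-stable.
#' @param n_metabolites,n_genes,n_proteins Layer sizes.
#' @param frac_dam Fraction of metabolites given a trend archetype.
#' @param n_planted_edges Number of planted gene-metabolite couplings.
#' @param edge_rho Pre-noise stage-mean correlation of planted couplings.
#' @param noise_sd Replicate noise sd on the standardized-trend (z) scale.
#' @param nb_dispersion Negative-binomial dispersion of expression counts.
#' @param meth_sites_per_promoter Cytosines per promoter site patch.
#' @param depth Mean read depth per cytosine.
#' @param chh_start,chh_end Population CHH level at S1 and S11.
#' @param cg_start,cg_end Population CG level at S1 and S11.
#' @param chg_level Flat population CHG level.
#' @param n_planted_dmrs Number of planted promoter DMRs.
#' @param dmr_delta Methylation shift of planted DMRs.
#' @param dmr_start_stage Stage index at which planted DMRs switch on.
#' @param frac_discordant Fraction of coupled genes whose protein series is
#'   sign-flipped (exercises the consistency filter).
#' @param amp Metabolite trend amplitude (relative units above the base
#'   level 1.2; fold change across stages is about `(amp * 3.3 + 1.2)/1.2`).
#' @param body_sites_per_gene Cytosines per gene body.
#' @param n_background_sirna Background siRNA clusters.
#' @param sirna_dmr_fraction Fraction of planted DMRs that receive an siRNA
#'   cluster.
#' @param total_clean_reads Total clean small-RNA reads per sample (RPM
#'   denominator).
#' @param n_stages,replicates Stage design.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_metabolites = 300L,
                              n_genes = 5000L,
                              n_proteins = 1500L,
                              frac_dam = 0.8,
                              n_planted_edges = 200L,
                              edge_rho = 0.97,
                              noise_sd = 0.3,
                              nb_dispersion = 0.1,
                              meth_sites_per_promoter = 20L,
                              depth = 30,
                              chh_start = 0.10, chh_end = 0.25,
                              cg_start = 0.55, cg_end = 0.45,
                              chg_level = 0.30,
                              n_planted_dmrs = 100L,
                              dmr_delta = 0.3,
                              dmr_start_stage = 6L,
                              frac_discordant = 0.1,
                              amp = 3.5,
                              body_sites_per_gene = 10L,
                              n_background_sirna = 2000L,
                              sirna_dmr_fraction = 0.5,
                              total_clean_reads = 2e6,
                              n_stages = 11L,
                              replicates = 3L) {
  cfg <- list(seed = as.integer(seed),
              n_metabolites = as.integer(n_metabolites),
              n_genes = as.integer(n_genes),
              n_proteins = as.integer(n_proteins),
              frac_dam = frac_dam,
              n_planted_edges = as.integer(n_planted_edges),
              edge_rho = edge_rho, noise_sd = noise_sd,
              nb_dispersion = nb_dispersion,
              meth_sites_per_promoter = as.integer(meth_sites_per_promoter),
              depth = depth,
              chh_start = chh_start, chh_end = chh_end,
              cg_start = cg_start, cg_end = cg_end, chg_level = chg_level,
              n_planted_dmrs = as.integer(n_planted_dmrs),
              dmr_delta = dmr_delta,
              dmr_start_stage = as.integer(dmr_start_stage),
              frac_discordant = frac_discordant, amp = amp,
              body_sites_per_gene = as.integer(body_sites_per_gene),
              n_background_sirna = as.integer(n_background_sirna),
              sirna_dmr_fraction = sirna_dmr_fraction,
              total_clean_reads = total_clean_reads,
              n_stages = as.integer(n_stages),
              replicates = as.integer(replicates))
  fracs <- c(frac_dam = cfg$frac_dam, frac_discordant = cfg$frac_discordant,
             sirna_dmr_fraction = cfg$sirna_dmr_fraction)
  if (any(fracs < 0 | fracs > 1))
    stop("fractions must lie in [0, 1]")
  lev <- c(cfg$chh_start, cfg$chh_end, cfg$cg_start, cfg$cg_end,
           cfg$chg_level)
  if (any(lev < 0 | lev > 1)) stop("methylation levels must lie in [0, 1]")
  if (cfg$n_planted_edges > cfg$n_genes)
    stop("n_planted_edges exceeds n_genes")
  if (cfg$n_proteins > cfg$n_genes) stop("n_proteins exceeds n_genes")
  if (cfg$n_planted_edges + cfg$n_planted_dmrs > cfg$n_genes)
    stop("planted DMR genes and planted edge genes exceed n_genes")
  if (cfg$dmr_start_stage < 2L || cfg$dmr_start_stage > cfg$n_stages)
    stop("dmr_start_stage must lie in [2, n_stages]")
  class(cfg) <- "simulation_config"
  cfg
}

# z-standardize a vector (sample sd); constant input -> zeros
zstd <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# component of `raw` orthogonal to `base` (and the constant), unit sample sd
ortho_unit <- function(raw, base) {
  r <- stats::residuals(stats::lm(raw ~ base))
  zstd(r)
}

# idiosyncratic standardized trajectory. Deliberately white on the z scale:
# any temporal smoothing makes independent trajectories mutually correlated
# (a (0.2,0.6,0.2) kernel already inflates pairwise |r| sd from 0.32 to
# ~0.45 at n = 11), which floods the |r| > 0.85 association gate with
# partner-partner collisions
idio_trajectory <- function(n) {
  zstd(stats::rnorm(n))
}

# mix a base shape with an individual orthogonal component at exact cor `a`
mix_exact <- function(base, a) {
  u <- ortho_unit(stats::rnorm(length(base)), base)
  a * base + sqrt(1 - a^2) * u
}

# layer amplitude/base constants of the abundance model (relative units;
# bases keep the series bottom well above the replicate noise floor)
.layer_amp <- c(metabolome = NA, transcriptome = 10, proteome = 5,
                coupled = 0.5)
.layer_base <- c(metabolome = 1.2, transcriptome = 3, proteome = 1.5)

# trend series -> replicate abundance matrix (features x samples)
# series_rel: features x stages relative series; noise additive on that scale
abundance_matrix <- function(series_rel, scale, stage_col, noise_sd,
                             sample_ids) {
  vals <- scale * pmax(series_rel[, stage_col, drop = FALSE] +
                       matrix(stats::rnorm(nrow(series_rel) *
                                             length(stage_col), 0, noise_sd),
                              nrow(series_rel)), 0.05)
  colnames(vals) <- sample_ids
  vals
}

#' Simulate a full synthetic multi-omics dataset with planted ground truth
#'
#' Generates metabolome, proteome and transcriptome feature tables (plus a
#' negative-binomial count matrix for the transcriptome), per-sample
#' cytosine site tables, gene models on one synthetic chromosome, 24-nt
#' siRNA clusters, and the complete ground truth needed for recovery
#' scoring. See [simulation_config()] for the generative model. All
#' randomness flows through a single stream seeded from `config$seed`, so a
#' fixed seed reproduces the dataset exactly.
#'
#' Planted structure: archetype-carrying metabolites hug their trend
#' archetype (correlation 0.995) so the eight clusters are recoverable;
#' coupling-partner metabolites instead follow idiosyncratic smooth
#' trajectories, so planted gene-metabolite edges are identifiable against
#' the shared-trend background. Planted-edge genes reproduce their partner's
#' standardized trend at exactly `edge_rho` (Gram-Schmidt construction).
#' Methylation-coupled genes track their promoter's expected methylation
#' series with a planted sign at sub-fold-change amplitude (they are not
#' differential, keeping the association layer free of step-shaped
#' confounders).
#'
#' @param config A [simulation_config()].
#' @return List with elements `metabolome`, `proteome`, `transcriptome`
#'   ([feature_table()]s), `transcript_counts` (integer matrix), `sites`
#'   (methylation site `data.table`, all samples), `genes`, `promoters`,
#'   `sirna` (cluster list), `total_clean_reads`, `protein_to_gene`,
#'   `design`, `config` and `truth` (list: `trend_of`, `true_edges`,
#'   `discordant_genes`, `true_dmrs`, `coupled_promoters`,
#'   `sirna_dmr_genes`).
#' @export
simulate_multiomics <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cf <- config
  design <- stage_design(cf$n_stages, cf$replicates)
  ns <- cf$n_stages
  stages <- design$stages
  stage_col <- rep(stages, each = cf$replicates)
  n_samples <- ns * cf$replicates

  ## ---- gene models: one synthetic chromosome, genes tiled every 6 kb ----
  spacing <- 6000L; body <- 2000L; prom_bp <- 2000L
  gene_ids <- sprintf("g%04d", seq_len(cf$n_genes))
  strand <- rep(c("+", "-"), length.out = cf$n_genes)
  tile <- (seq_len(cf$n_genes) - 1L) * spacing
  gstart <- tile + 2500L
  gend <- gstart + body
  genes <- data.frame(gene_id = gene_ids, chrom = "ChrSim", start = gstart,
                      end = gend, strand = strand, stringsAsFactors = FALSE)
  chrom_len <- spacing * cf$n_genes + 1000L
  promoters <- promoter_intervals(genes, prom_bp,
                                  chrom_length = c(ChrSim = chrom_len))

  ## ---- metabolite trends: archetype members + idiosyncratic partners ----
  arche <- make_archetypes(ns)
  met_ids <- sprintf("m%04d", seq_len(cf$n_metabolites))
  n_arch <- round(cf$frac_dam * cf$n_metabolites)
  trend_of <- stats::setNames(rep(NA_character_, cf$n_metabolites), met_ids)
  met_z <- matrix(0, cf$n_metabolites, ns,
                  dimnames = list(met_ids, stages))
  if (n_arch > 0) {
    labels <- rep(archetype_labels(), length.out = n_arch)
    trend_of[seq_len(n_arch)] <- labels
    for (i in seq_len(n_arch))
      met_z[i, ] <- mix_exact(arche[labels[i], ], 0.995)
  }
  pool <- setdiff(seq_len(cf$n_metabolites), seq_len(n_arch))
  if (cf$n_planted_edges > 0 && length(pool) == 0)
    stop("no metabolites left for planted couplings; lower frac_dam or ",
         "n_planted_edges")
  # idiosyncratic trajectories are kept identifiable by construction:
  # rejection-sampled away from the archetype cones (|r| < 0.8) and from
  # each other (|r| < 0.85), so a partner never mimics a trend cluster and
  # planted couplings never collide with a foreign partner
  drawn <- list()
  for (i in pool) {
    for (try in 1:200) {
      z <- idio_trajectory(ns)
      ok <- all(abs(stats::cor(z, t(arche))) < 0.8) &&
        (length(drawn) == 0 ||
           all(abs(vapply(drawn, function(d) stats::cor(z, d),
                          numeric(1))) < 0.85))
      if (ok) break
    }
    met_z[i, ] <- z
    drawn[[length(drawn) + 1L]] <- z
  }
  partner_of_edge <- if (cf$n_planted_edges > 0)
    pool[(seq_len(cf$n_planted_edges) - 1L) %% length(pool) + 1L]
  else integer(0)

  ## ---- metabolome values ----
  trended_met <- seq_len(cf$n_metabolites) %in%
    c(seq_len(n_arch), unique(partner_of_edge))
  met_shift <- met_z - apply(met_z, 1, min)
  met_shift[!trended_met, ] <- 0          # null metabolites stay flat
  met_rel <- cf$amp * met_shift + .layer_base[["metabolome"]]
  met_scale <- exp(stats::rnorm(cf$n_metabolites, 12, 0.5))
  met_vals <- abundance_matrix(met_rel, met_scale, stage_col, cf$noise_sd,
                               design$sample_ids)
  rownames(met_vals) <- met_ids
  classes <- c("Amino acid", "Amino acid derivatives", "Anthocyanins",
               "Alkaloids", "Benzoic acid derivatives", "Carbohydrates",
               "Catechin derivatives", "Coumarins", "Flavanone", "Flavone",
               "Flavone C-glycosides", "Flavonol",
               "Hydroxycinnamoyl derivatives", "Indole derivatives",
               "Lipids_Fatty acids", "Lipids_Glycerolipids",
               "Lipids_Glycerophospholipids",
               "Nucleotide and its derivates", "Organic acids", "Others",
               "Phenolamides", "Phytohormones", "Proanthocyanidins",
               "Quinate and its derivatives", "Vitamins")
  class_of <- stats::setNames(sample(classes, cf$n_metabolites,
                                     replace = TRUE), met_ids)
  metabolome <- feature_table(met_vals, "metabolome", design,
                              class_of = class_of)

  ## ---- gene roles: planted-edge genes, then methylation-coupled genes ----
  edge_genes <- if (cf$n_planted_edges > 0) seq_len(cf$n_planted_edges)
                else integer(0)
  n_coupled <- if (cf$n_planted_dmrs > 0) {
    if (length(edge_genes)) cf$n_planted_dmrs -
      min(cf$n_planted_dmrs %/% 2L, length(edge_genes))
    else cf$n_planted_dmrs
  } else 0L
  coupled_genes <- if (n_coupled > 0)
    cf$n_planted_edges + seq_len(n_coupled) else integer(0)
  dmr_edge_genes <- if (cf$n_planted_dmrs > n_coupled)
    edge_genes[seq_len(cf$n_planted_dmrs - n_coupled)] else integer(0)
  dmr_genes <- c(dmr_edge_genes, coupled_genes)

  ## ---- methylation sites ----
  drift <- function(a, b) a + (b - a) * (seq_len(ns) - 1) / (ns - 1)
  base_level <- rbind(CG = drift(cf$cg_start, cf$cg_end),
                      CHG = rep(cf$chg_level, ns),
                      CHH = drift(cf$chh_start, cf$chh_end))
  colnames(base_level) <- stages
  ctx_prob <- c(CG = 0.25, CHG = 0.25, CHH = 0.5)  # context mix of sites

  patch_bp <- 150L
  npp <- cf$meth_sites_per_promoter
  # promoter patch: clustered cytosines (island-like), one per promoter
  patch_off <- sample.int(prom_bp - patch_bp, cf$n_genes, replace = TRUE)
  patch_start <- promoters$start + patch_off
  prom_pos <- patch_start[rep(seq_len(cf$n_genes), each = npp)] +
    as.vector(replicate(cf$n_genes,
                        sort(sample.int(patch_bp, npp)))) - 1L
  prom_gene <- rep(seq_len(cf$n_genes), each = npp)
  nbs <- cf$body_sites_per_gene
  body_pos <- gstart[rep(seq_len(cf$n_genes), each = nbs)] +
    as.vector(replicate(cf$n_genes, sort(sample.int(body, nbs)))) - 1L
  pos0 <- c(prom_pos, body_pos)
  site_gene <- c(prom_gene, rep(seq_len(cf$n_genes), each = nbs))
  in_promoter <- c(rep(TRUE, length(prom_pos)), rep(FALSE, length(body_pos)))
  n_sites <- length(pos0)
  context <- sample(names(ctx_prob), n_sites, replace = TRUE,
                    prob = ctx_prob)
  site_strand <- sample(c("+", "-"), n_sites, replace = TRUE)

  # planted DMRs: CHH hypermethylation of the promoter patch from
  # dmr_start_stage onward (the RdDM-dominant context)
  step_mask <- matrix(0, n_sites, ns)
  dmr_site <- in_promoter & context == "CHH" & site_gene %in% dmr_genes
  step_mask[dmr_site, seq(cf$dmr_start_stage, ns)] <- cf$dmr_delta
  lev_mat <- base_level[context, , drop = FALSE] + step_mask
  lev_mat <- pmin(pmax(lev_mat, 0.005), 0.995)

  cov <- matrix(stats::rpois(n_sites * n_samples, cf$depth), n_sites)
  stage_of_col <- rep(seq_len(ns), each = cf$replicates)
  meth <- matrix(0L, n_sites, n_samples)
  for (j in seq_len(n_samples))
    meth[, j] <- stats::rbinom(n_sites, cov[, j], lev_mat[, stage_of_col[j]])
  sites <- data.table::data.table(
    chrom = "ChrSim",
    pos0 = rep(pos0, n_samples),
    strand = rep(site_strand, n_samples),
    context = rep(context, n_samples),
    meth = as.integer(meth),
    unmeth = as.integer(cov - meth),
    stage = rep(stages[stage_of_col], each = n_sites),
    rep = rep(rep(seq_len(cf$replicates), ns), each = n_sites))

  ## ---- expression ----
  gene_y <- matrix(0, cf$n_genes, ns, dimnames = list(gene_ids, stages))
  gene_amp <- rep(0, cf$n_genes)
  true_edges <- NULL
  if (cf$n_planted_edges > 0) {
    for (k in seq_len(cf$n_planted_edges)) {
      m <- met_z[partner_of_edge[k], ]
      u <- ortho_unit(stats::rnorm(ns), m)
      gene_y[edge_genes[k], ] <- cf$edge_rho * m +
        sqrt(1 - cf$edge_rho^2) * u
    }
    gene_amp[edge_genes] <- .layer_amp[["transcriptome"]]
    true_edges <- data.frame(gene_id = gene_ids[edge_genes],
                             metabolite_id = met_ids[partner_of_edge],
                             stringsAsFactors = FALSE)
  }
  # methylation-coupled genes: expression tracks the expected pooled
  # promoter methylation series with a planted sign, at sub-fold-change
  # amplitude
  coupled_sign <- character(0)
  if (length(coupled_genes)) {
    coupled_sign <- sample(c("+", "-"), length(coupled_genes),
                           replace = TRUE)
    for (k in seq_along(coupled_genes)) {
      g <- coupled_genes[k]
      idx <- which(in_promoter & site_gene == g)
      z <- zstd(colMeans(lev_mat[idx, , drop = FALSE]))
      gene_y[g, ] <- if (coupled_sign[k] == "+") z else -z
    }
    gene_amp[coupled_genes] <- .layer_amp[["coupled"]]
  }
  gene_shift <- gene_y - apply(gene_y, 1, min)
  gene_rel <- gene_amp * gene_shift + .layer_base[["transcriptome"]]
  gene_scale <- exp(stats::rnorm(cf$n_genes, 5.5, 0.8))
  expr <- abundance_matrix(gene_rel, gene_scale, stage_col, cf$noise_sd,
                           design$sample_ids)
  rownames(expr) <- gene_ids
  transcriptome <- feature_table(expr, "transcriptome", design)
  mu <- gene_scale * gene_rel[, stage_col, drop = FALSE]
  transcript_counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                             size = 1 / cf$nb_dispersion),
                              nrow = cf$n_genes,
                              dimnames = list(gene_ids, design$sample_ids))

  ## ---- proteome: subset of genes; some coupled genes sign-flipped ----
  prot_gene_idx <- unique(c(edge_genes,
                            sample(setdiff(seq_len(cf$n_genes), edge_genes),
                                   max(0L, cf$n_proteins -
                                         length(edge_genes)))))
  prot_gene_idx <- sort(prot_gene_idx[seq_len(min(cf$n_proteins,
                                                  length(prot_gene_idx)))])
  n_disc <- round(cf$frac_discordant * cf$n_planted_edges)
  discordant <- if (n_disc > 0) sort(sample(edge_genes, n_disc))
                else integer(0)
  flip <- ifelse(prot_gene_idx %in% discordant, -1, 1)
  prot_ids <- paste0("p_", gene_ids[prot_gene_idx])
  prot_y <- gene_y[prot_gene_idx, , drop = FALSE] * flip
  prot_amp <- ifelse(prot_gene_idx %in% edge_genes,
                     .layer_amp[["proteome"]], 0)
  prot_shift <- prot_y - apply(prot_y, 1, min)
  prot_rel <- prot_amp * prot_shift + .layer_base[["proteome"]]
  prot_scale <- exp(stats::rnorm(length(prot_gene_idx), 10, 0.5))
  prot_vals <- abundance_matrix(prot_rel, prot_scale, stage_col,
                                cf$noise_sd, design$sample_ids)
  rownames(prot_vals) <- prot_ids
  proteome <- feature_table(prot_vals, "proteome", design)
  protein_to_gene <- stats::setNames(gene_ids[prot_gene_idx], prot_ids)

  ## ---- siRNA clusters: background + enrichment in planted DMRs ----
  n_bg <- cf$n_background_sirna
  bg_start <- sort(sample.int(chrom_len - 240L, n_bg))
  sirna_int <- data.frame(cluster_id = sprintf("sir%05d", seq_len(n_bg)),
                          chrom = "ChrSim", start = bg_start,
                          end = bg_start + 200L, stringsAsFactors = FALSE)
  sirna_mu <- rep(20, n_bg)
  sirna_dmr_genes <- character(0)
  if (length(dmr_genes)) {
    n_in <- round(cf$sirna_dmr_fraction * length(dmr_genes))
    in_dmr <- sort(sample(dmr_genes, n_in))
    sirna_dmr_genes <- gene_ids[in_dmr]
    add <- data.frame(cluster_id = sprintf("sirDMR%04d", seq_along(in_dmr)),
                      chrom = "ChrSim", start = patch_start[in_dmr],
                      end = patch_start[in_dmr] + patch_bp,
                      stringsAsFactors = FALSE)
    sirna_int <- rbind(sirna_int, add)
    sirna_mu <- c(sirna_mu, rep(100, length(in_dmr)))
  }
  # 24-nt siRNA output fades over the series
  stage_fac <- drift(1.3, 0.6)
  mu_mat <- outer(sirna_mu, stage_fac[match(stage_col, stages)])
  sirna_counts <- matrix(stats::rnbinom(length(mu_mat), mu = mu_mat,
                                        size = 10),
                         nrow = nrow(mu_mat))
  dimnames(sirna_counts) <- list(sirna_int$cluster_id, design$sample_ids)
  total_reads <- stats::setNames(rep(cf$total_clean_reads, n_samples),
                                 design$sample_ids)

  ## ---- ground truth ----
  true_dmrs <- if (length(dmr_genes))
    data.frame(gene_id = gene_ids[dmr_genes], chrom = "ChrSim",
               start = patch_start[dmr_genes],
               end = patch_start[dmr_genes] + patch_bp,
               context = "CHH", direction = "+",
               stage_on = stages[cf$dmr_start_stage],
               stringsAsFactors = FALSE)
  else data.frame()
  true_protein_edges <- if (cf$n_planted_edges > 0)
    data.frame(protein_id = paste0("p_", gene_ids[edge_genes]),
               metabolite_id = met_ids[partner_of_edge],
               concordant = !(edge_genes %in% discordant),
               stringsAsFactors = FALSE)
  else NULL
  truth <- list(
    trend_of = trend_of,
    true_edges = true_edges,
    true_protein_edges = true_protein_edges,
    discordant_genes = gene_ids[discordant],
    true_dmrs = true_dmrs,
    coupled_promoters = if (length(coupled_genes))
      data.frame(gene_id = gene_ids[coupled_genes], sign = coupled_sign,
                 stringsAsFactors = FALSE) else data.frame(),
    sirna_dmr_genes = sirna_dmr_genes)

  list(metabolome = metabolome, proteome = proteome,
       transcriptome = transcriptome, transcript_counts = transcript_counts,
       sites = sites, genes = genes, promoters = promoters,
       sirna = list(intervals = sirna_int, counts = sirna_counts),
       total_clean_reads = total_reads,
       protein_to_gene = protein_to_gene,
       design = design, config = cf, truth = truth)
}
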