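#' Export the gene-metabolite network
#'
#' Writes one bipartite graph per group (trend cluster or metabolite class):
#' nodes are typed gene/metabolite, edges carry `r`, `q`, `sign` and
#' `layer`. TSV edge lists round-trip losslessly; GraphML is written with
#' igraph. Empty groups are emitted as empty graphs.
#'
#' @param database A `gene_metabolite_database`.
#' @param group_by `"cluster"` (trend clusters I-VIII) or `"class"`.
#' @param format `"tsv"` or `"graphml"`.
#' @param out_dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"network"`).
#' @return Character vector of written file paths (named by group).
#' @export
export_network <- function(database, group_by = c("cluster", "class"),
                           format = c("tsv", "graphml"), out_dir,
                           prefix = "network") {
  group_by <- match.arg(group_by)
  format <- match.arg(format)
  if (!format %in% c("tsv", "graphml")) stop("unknown format")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  edges <- database$edges
  groups <- if (group_by == "cluster") {
    cl <- database$metabolite_clusters
    if (is.null(cl)) stop("database carries no cluster assignment")
    stats::setNames(cl$cluster_label, cl$feature_id)
  } else {
    if (is.null(database$class_of)) stop("database carries no class map")
    database$class_of
  }
  levels <- if (group_by == "cluster") archetype_labels()
            else sort(unique(unname(groups)))
  files <- character(0)
  for (g in levels) {
    mets <- names(groups)[!is.na(groups) & groups == g]
    sub <- edges[edges$target_id %in% mets, , drop = FALSE]
    safe <- gsub("[^A-Za-z0-9_-]+", "_", g)
    path <- file.path(out_dir, paste0(prefix, "_", safe, ".", format))
    if (format == "tsv") {
      data.table::fwrite(sub[, c("source_id", "target_id", "layer", "r",
                                 "p_value", "q_value", "sign")],
                         path, sep = "\t")
    } else {
      nodes <- data.frame(
        name = c(unique(sub$source_id), unique(sub$target_id)),
        type = c(rep("gene", length(unique(sub$source_id))),
                 rep("metabolite", length(unique(sub$target_id)))),
        stringsAsFactors = FALSE)
      gr <- igraph::graph_from_data_frame(
        sub[, c("source_id", "target_id", "r", "q_value", "sign", "layer")],
        directed = FALSE, vertices = nodes)
      igraph::write_graph(gr, path, format = "graphml")
    }
    files[g] <- path
  }
  files
}

#' Read a network edge-list TSV back
#' @param path TSV written by [export_network()].
#' @return Edge `data.frame`.
#' @export
read_network_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t",
                                  colClasses = list(
                                    character = c("source_id", "target_id",
                                                  "layer", "sign"))))
}

#' Class x chromosome gene counts
#'
#' The number of distinct genes on each chromosome with at least one
#' database edge to a metabolite of each class; genes absent from the gene
#' models are bucketed on chromosome "Others".
#'
#' @param database A `gene_metabolite_database`.
#' @param gene_models Gene model `data.frame`.
#' @return Integer matrix classes x chromosomes.
#' @export
chromosome_class_counts <- function(database, gene_models) {
  edges <- database$edges
  if (is.null(database$class_of)) stop("database carries no class map")
  gene <- if ("gene_id" %in% names(edges)) edges$gene_id else edges$source_id
  cls <- unname(database$class_of[edges$target_id])
  cls[is.na(cls)] <- "Others"
  chrom <- gene_models$chrom[match(gene, gene_models$gene_id)]
  chrom[is.na(chrom)] <- "Others"
  dt <- unique(data.table::data.table(gene = gene, cls = cls,
                                      chrom = chrom))
  tab <- table(dt$cls, dt$chrom)
  matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
}

# ---- recovery scoring against planted ground truth ----

#' Recovery metrics of a pipeline run against planted ground truth
#'
#' Scores edge recovery (transcript layer, before the consistency filter,
#' since discordant planted pairs are removed by design), DMR recovery
#' (overlap with planted intervals, detections pooled over all adjacent
#' stage pairs), trend-cluster recovery (adjusted Rand index over
#' archetype-labeled metabolites) and methylation-expression sign recovery.
#'
#' @param truth Ground-truth list from [simulate_multiomics()].
#' @param transcript_edges Transcript-metabolite edges.
#' @param dmrs Stacked DMR calls.
#' @param clusters Cluster assignment of the called DAMs.
#' @param meth_expr Methylation-expression edge table.
#' @param protein_edges Optional protein-metabolite edges.
#' @return Named list of metrics.
#' @export
recovery_metrics <- function(truth, transcript_edges, dmrs, clusters,
                             meth_expr, protein_edges = NULL) {
  out <- list()
  if (!is.null(truth$true_edges) && nrow(truth$true_edges)) {
    key_true <- paste(truth$true_edges$gene_id,
                      truth$true_edges$metabolite_id)
    key_det <- paste(transcript_edges$source_id, transcript_edges$target_id)
    tp <- sum(key_det %in% key_true)
    out$edge_sensitivity <- tp / length(key_true)
    out$edge_fdr <- if (length(key_det)) 1 - tp / length(key_det) else 0
    out$n_edges_detected <- length(key_det)
    out$n_edges_true <- length(key_true)
  }
  if (!is.null(protein_edges) && !is.null(truth$true_protein_edges) &&
      nrow(truth$true_protein_edges)) {
    tpe <- truth$true_protein_edges
    key_true <- paste(tpe$protein_id, tpe$metabolite_id)[tpe$concordant]
    key_det <- paste(protein_edges$source_id, protein_edges$target_id)
    tp <- sum(key_det %in% key_true)
    out$protein_edge_sensitivity <- tp / length(key_true)
    out$protein_edge_fdr <- if (length(key_det)) {
      key_any <- paste(tpe$protein_id, tpe$metabolite_id)
      1 - sum(key_det %in% key_any) / length(key_det)
    } else 0
  }
  if (!is.null(truth$true_dmrs) && nrow(truth$true_dmrs)) {
    td <- truth$true_dmrs
    hit_true <- rep(FALSE, nrow(td))
    false_det <- 0L
    if (nrow(dmrs)) {
      gr_d <- GenomicRanges::GRanges(dmrs$chrom,
                                     IRanges::IRanges(dmrs$start + 1L,
                                                      dmrs$end))
      gr_t <- GenomicRanges::GRanges(td$chrom,
                                     IRanges::IRanges(td$start + 1L, td$end))
      ov <- GenomicRanges::findOverlaps(gr_d, gr_t)
      same_ctx <- dmrs$context[S4Vectors::queryHits(ov)] ==
        td$context[S4Vectors::subjectHits(ov)]
      hit_true[unique(S4Vectors::subjectHits(ov)[same_ctx])] <- TRUE
      false_det <- nrow(dmrs) -
        length(unique(S4Vectors::queryHits(ov)[same_ctx]))
    }
    out$dmr_sensitivity <- mean(hit_true)
    out$dmr_fdr <- if (nrow(dmrs)) false_det / nrow(dmrs) else 0
    out$n_dmrs_detected <- nrow(dmrs)
  }
  labeled <- names(truth$trend_of)[!is.na(truth$trend_of)]
  common <- intersect(labeled, clusters$feature_id)
  if (length(common) >= 2) {
    out$cluster_ari <- mclust::adjustedRandIndex(
      truth$trend_of[common],
      clusters$cluster_label[match(common, clusters$feature_id)])
  }
  if (!is.null(truth$coupled_promoters) && nrow(truth$coupled_promoters)) {
    cp <- truth$coupled_promoters
    m <- meth_expr[match(cp$gene_id, meth_expr$gene_id), , drop = FALSE]
    ok <- !is.na(m$r) & m$is_significant & m$sign == cp$sign
    out$meth_expr_sign_recovery <- mean(ok, na.rm = FALSE)
    out$meth_expr_sign_recovery[is.na(out$meth_expr_sign_recovery)] <- 0
  }
  out
}

# write ground truth as a TSV bundle
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(data.table::data.table(
    metabolite_id = names(truth$trend_of),
    archetype = ifelse(is.na(truth$trend_of), "none", truth$trend_of)),
    file.path(dir, "trend_of.tsv"), sep = "\t")
  if (!is.null(truth$true_edges))
    data.table::fwrite(truth$true_edges,
                       file.path(dir, "true_edges.tsv"), sep = "\t")
  if (nrow(truth$true_dmrs))
    data.table::fwrite(truth$true_dmrs,
                       file.path(dir, "true_dmrs.tsv"), sep = "\t")
  if (nrow(truth$coupled_promoters))
    data.table::fwrite(truth$coupled_promoters,
                       file.path(dir, "coupled_promoters.tsv"), sep = "\t")
  data.table::fwrite(data.table::data.table(
    gene_id = truth$discordant_genes),
    file.path(dir, "discordant_genes.tsv"), sep = "\t")
  invisible(dir)
}

#' Run the full integration pipeline
#'
#' Orchestrates the whole analysis: (synthetic mode) simulate and write all
#' input formats, then stage-pairwise differential calling on the three
#' layers, trend clustering of DAMs, methylation analyses (global series,
#' metagene profile, adjacent-stage DMRs, promoter overlap, siRNA RPM),
#' association-database construction with the consistency filter,
#' methylation couplings, adjacent-stage transition accounting, and network
#' exports. Writes a JSON manifest (config, seed, per-output record counts,
#' recovery metrics when ground truth exists). Outputs are deterministic
#' for a fixed config and seed. On failure, partial outputs are removed.
#'
#' @param config A [simulation_config()] (synthetic mode) or a named list of
#'   input paths (file mode) with elements `metabolome`, `proteome`,
#'   `transcriptome` (stage-table TSVs), `genes` (BED6), `sirna`
#'   (cluster TSV), `cytosine_reports` (`data.frame` path/stage/rep),
#'   `protein_to_gene` (TSV protein_id, gene_id), `total_clean_reads`
#'   (TSV sample_id, reads) and optional `seed`.
#' @param out_dir Output directory.
#' @param promoter_bp Promoter window (default 2000).
#' @param fc_threshold,q_threshold Differential gates (defaults 2, 0.05).
#' @param r_threshold Association |r| gate (default 0.85).
#' @param dmr_window_bp,dmr_step_bp,dmr_min_sites,dmr_delta_min DMR caller
#'   parameters (defaults 100/50/4/0.1).
#' @param write_inputs Write the simulated input files (default TRUE).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir,
                         promoter_bp = 2000L, fc_threshold = 2,
                         q_threshold = 0.05, r_threshold = 0.85,
                         dmr_window_bp = 100L, dmr_step_bp = 50L,
                         dmr_min_sites = 4L, dmr_delta_min = 0.1,
                         write_inputs = TRUE) {
  created <- !dir.exists(out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(file.path(out_dir, c("inputs", "results")),
                          recursive = TRUE), add = TRUE)
  res_dir <- file.path(out_dir, "results")
  dir.create(res_dir, showWarnings = FALSE)

  if (inherits(config, "simulation_config")) {
    sim <- simulate_multiomics(config)
    seed <- config$seed
    if (write_inputs) write_sim_inputs(sim, file.path(out_dir, "inputs"))
  } else {
    sim <- load_pipeline_inputs(config)
    seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  }
  design <- sim$design
  counts <- list()
  tsv <- function(x, name) {
    p <- file.path(res_dir, name)
    data.table::fwrite(x, p, sep = "\t")
    counts[[name]] <<- nrow(x)
    p
  }

  ## differential (3 layers)
  dam <- differential_all_pairs(sim$metabolome, fc_threshold, q_threshold)
  dep <- differential_all_pairs(sim$proteome, fc_threshold, q_threshold)
  deg <- differential_all_pairs(sim$transcriptome, fc_threshold, q_threshold)
  tsv(dam, "differential_metabolome.tsv")
  tsv(dep, "differential_proteome.tsv")
  tsv(deg, "differential_transcriptome.tsv")
  dams <- significant_features(dam)
  deps <- significant_features(dep)
  degs <- significant_features(deg)

  ## trends
  met_means <- stage_means(sim$metabolome)
  zm <- zscore_series(met_means[dams, , drop = FALSE])
  zm <- zm[!attr(zm, "degenerate"), , drop = FALSE]
  clusters <- cluster_trends(zm, k = 8L, seed = seed)
  tsv(clusters, "clusters.tsv")

  ## methylation
  contexts <- c("CG", "CHG", "CHH")
  glob <- vapply(contexts, function(cx)
    global_methylation_series(sim$sites, design, cx),
    numeric(length(design$stages)))
  glob_all <- global_methylation_series(sim$sites, design)
  glob_df <- data.frame(stage = design$stages, C = glob_all,
                        CG = glob[, "CG"], CHG = glob[, "CHG"],
                        CHH = glob[, "CHH"], row.names = NULL)
  tsv(glob_df, "global_methylation.tsv")
  prof <- metagene_profile(sim$sites, sim$genes, design)
  tsv(prof, "metagene_profile.tsv")
  pairs <- adjacent_pairs(design)
  site_stage <- split(sim$sites, sim$sites$stage)
  dmrs <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    call_dmrs(site_stage[[pairs[i, 1]]], site_stage[[pairs[i, 2]]],
              dmr_window_bp, dmr_step_bp, dmr_min_sites, dmr_delta_min,
              q_threshold)))
  tsv(dmrs, "dmrs.tsv")
  write_dmr_bed(dmrs, file.path(res_dir, "dmrs.bed"))
  pdg <- promoter_dmr_genes(dmrs, sim$genes, promoter_bp)
  tsv(pdg$by_gene, "promoter_dmr_genes.tsv")
  promoters <- promoter_intervals(sim$genes, promoter_bp)
  rpm_regions <- if (nrow(dmrs)) {
    data.frame(region_id = paste0("dmr", seq_len(nrow(dmrs))),
               chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end)
  } else data.frame(region_id = character(0), chrom = character(0),
                    start = integer(0), end = integer(0))
  rpm <- sirna_rpm_in_regions(sim$sirna, rpm_regions, sim$total_clean_reads)
  tsv(data.frame(region_id = rownames(rpm), rpm, check.names = FALSE),
      "sirna_rpm_dmrs.tsv")

  ## association
  expr_means <- stage_means(sim$transcriptome)
  prot_means <- stage_means(sim$proteome)
  te <- build_association_edges(expr_means[degs, , drop = FALSE],
                                met_means[dams, , drop = FALSE],
                                layer = "transcript-metabolite",
                                r_threshold, q_threshold)
  pe <- build_association_edges(prot_means[deps, , drop = FALSE],
                                met_means[dams, , drop = FALSE],
                                layer = "protein-metabolite",
                                r_threshold, q_threshold)
  tsv(te, "edges_transcript.tsv")
  tsv(pe, "edges_protein.tsv")
  db <- consistency_filter(te, pe, sim$protein_to_gene,
                           metabolite_clusters = clusters,
                           class_of = sim$metabolome$class_of)
  tsv(db$edges, "database_edges.tsv")
  tsv(db$removed_pairs, "database_removed_pairs.tsv")

  # scan every gene with a covered promoter (couplings need not be DEGs)
  prom_series <- promoter_methylation_series(sim$sites, promoters, design)
  me <- methylation_expression_edges(prom_series, expr_means, q_threshold)
  tsv(me, "methylation_expression_edges.tsv")
  gm <- genome_methylation_dam_correlation(glob_all,
                                           met_means[dams, , drop = FALSE],
                                           clusters)
  tsv(gm$edges, "genome_methylation_dam.tsv")
  tsv(gm$cluster_summary, "genome_methylation_cluster_summary.tsv")

  ## transitions
  inc <- next_stage_increases(dam, design)
  ctt <- class_transition_table(inc, sim$metabolome$class_of)
  tsv(data.frame(metabolite_class = rownames(ctt), ctt,
                 check.names = FALSE), "class_transition_table.tsv")
  funnel <- transition_correlated_degs(inc, db, deg,
                                       pdg$by_gene$gene_id, design)
  tsv(funnel$summary, "transitions.tsv")

  ## exports
  net_files <- export_network(db, "cluster", "tsv",
                              file.path(res_dir, "networks"))
  export_network(db, "cluster", "graphml", file.path(res_dir, "networks"))
  ccc <- chromosome_class_counts(db, sim$genes)
  tsv(data.frame(metabolite_class = rownames(ccc), ccc,
                 check.names = FALSE), "chromosome_class_counts.tsv")

  ## recovery + manifest
  metrics <- NULL
  if (!is.null(sim$truth))
    metrics <- recovery_metrics(sim$truth, te, dmrs, clusters, me,
                                protein_edges = pe)
  manifest <- list(
    package = "stageomics",
    version = as.character(utils::packageVersion("stageomics")),
    seed = seed,
    mode = if (inherits(config, "simulation_config")) "synthetic" else
      "files",
    config = if (inherits(config, "simulation_config")) unclass(config)
             else config,
    n_dams = length(dams), n_degs = length(degs), n_deps = length(deps),
    n_dmrs = nrow(dmrs), n_database_edges = nrow(db$edges),
    record_counts = counts,
    outputs = sort(c(names(counts), basename(unname(net_files)))),
    recovery = metrics)
  jsonlite::write_json(manifest, file.path(res_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ok <- TRUE
  invisible(manifest)
}

# write DMRs as BED6+ (name = context:stagepair, score = -log10 q)
write_dmr_bed <- function(dmrs, path) {
  if (!nrow(dmrs)) {
    file.create(path)
    return(invisible(path))
  }
  dt <- data.table::data.table(
    chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
    name = paste0(dmrs$context, ":", dmrs$stage_a, "-", dmrs$stage_b),
    score = round(-log10(pmax(dmrs$q_value, 1e-300)), 3), strand = ".")
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# write simulated inputs in the standard exchange formats
write_sim_inputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stage_table(sim$metabolome, file.path(dir, "metabolome.tsv"))
  write_stage_table(sim$proteome, file.path(dir, "proteome.tsv"))
  write_stage_table(sim$transcriptome, file.path(dir, "transcriptome.tsv"))
  write_gene_bed(sim$genes, file.path(dir, "genes.bed"))
  write_sirna_clusters(sim$sirna, file.path(dir, "sirna_clusters.tsv"))
  data.table::fwrite(data.table::data.table(
    protein_id = names(sim$protein_to_gene),
    gene_id = unname(sim$protein_to_gene)),
    file.path(dir, "protein_to_gene.tsv"), sep = "\t")
  data.table::fwrite(data.table::data.table(
    sample_id = names(sim$total_clean_reads),
    reads = unname(sim$total_clean_reads)),
    file.path(dir, "total_clean_reads.tsv"), sep = "\t")
  meth_dir <- file.path(dir, "methylation")
  dir.create(meth_dir, showWarnings = FALSE)
  dt <- data.table::as.data.table(sim$sites)
  for (s in unique(dt$stage)) for (r in sort(unique(dt$rep))) {
    sub <- dt[dt$stage == s & dt$rep == r]
    data.table::setorderv(sub, c("chrom", "pos0"))
    write_cytosine_report(sub, file.path(meth_dir,
                                         paste0(s, "_R", r, ".cov.txt")))
  }
  write_ground_truth(sim$truth, file.path(dir, "ground_truth"))
  invisible(dir)
}

# load pipeline inputs from files (file mode)
load_pipeline_inputs <- function(config) {
  need <- c("metabolome", "proteome", "transcriptome", "genes", "sirna",
            "cytosine_reports", "protein_to_gene", "total_clean_reads")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("missing input(s): ", paste(miss, collapse = ", "))
  for (f in c("metabolome", "proteome", "transcriptome", "genes", "sirna",
              "protein_to_gene", "total_clean_reads"))
    if (!file.exists(config[[f]])) stop("missing input file: ", config[[f]])
  design <- if (!is.null(config$design)) config$design else stage_design()
  cr <- config$cytosine_reports
  sites <- data.table::rbindlist(lapply(seq_len(nrow(cr)), function(i) {
    if (!file.exists(cr$path[i])) stop("missing input file: ", cr$path[i])
    read_cytosine_report(cr$path[i], cr$stage[i], cr$rep[i])
  }))
  p2g <- data.table::fread(config$protein_to_gene, sep = "\t")
  tcr <- data.table::fread(config$total_clean_reads, sep = "\t")
  list(metabolome = read_stage_table(config$metabolome, "metabolome",
                                     design),
       proteome = read_stage_table(config$proteome, "proteome", design),
       transcriptome = read_stage_table(config$transcriptome,
                                        "transcriptome", design),
       genes = read_gene_bed(config$genes),
       sirna = read_sirna_clusters(config$sirna, design),
       sites = sites,
       protein_to_gene = stats::setNames(p2g$gene_id, p2g$protein_id),
       total_clean_reads = stats::setNames(tcr$reads, tcr$sample_id),
       design = design, truth = NULL)
}
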