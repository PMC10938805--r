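#' Pearson correlation of two stage-mean series
#'
#' Product-moment correlation with a two-sided p-value from the t transform
#' (`t = r * sqrt(n - 2) / sqrt(1 - r^2)`, n - 2 df). Zero-variance input
#' yields `r = NA` (such pairs are excluded upstream).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `r` and `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_))
  r <- stats::cor(x, y)
  p <- cor_p(r, n)
  list(r = r, p = p)
}

# two-sided p from the t transform of a Pearson r at n points
cor_p <- function(r, n) {
  r2 <- pmin(r^2, 1 - 1e-15)
  tt <- abs(r) * sqrt((n - 2) / (1 - r2))
  2 * stats::pt(-tt, n - 2)
}

#' Cross-layer association edges
#'
#' Tests every (source feature, metabolite) pair on their stage-mean series
#' (replicate means, 11 points by default) with Pearson correlation, adjusts
#' across all tested pairs of the layer with BH, and retains edges with
#' `|r| > r_threshold` and `q < q_threshold`. Per the study design, sources
#' are restricted to the layer's differential features (DEGs or DEPs) and
#' targets to DAMs before calling this function. Zero-variance series are
#' skipped (recorded in the `skipped` attribute).
#'
#' @param source_means Matrix source features x stages (stage means).
#' @param target_means Matrix metabolites x stages.
#' @param layer Edge layer label (e.g. `"transcript-metabolite"`).
#' @param r_threshold Correlation gate (default 0.85).
#' @param q_threshold FDR gate (default 0.05).
#' @return `data.frame` `source_id`, `target_id`, `layer`, `r`, `p_value`,
#'   `q_value`, `sign`.
#' @export
build_association_edges <- function(source_means, target_means,
                                    layer = "transcript-metabolite",
                                    r_threshold = 0.85,
                                    q_threshold = 0.05) {
  n <- ncol(source_means)
  stopifnot(n == ncol(target_means), n >= 3)
  ok_s <- apply(source_means, 1, stats::sd) > 0
  ok_t <- apply(target_means, 1, stats::sd) > 0
  skipped <- c(rownames(source_means)[!ok_s], rownames(target_means)[!ok_t])
  sm <- source_means[ok_s, , drop = FALSE]
  tm <- target_means[ok_t, , drop = FALSE]
  out <- data.frame(source_id = character(0), target_id = character(0),
                    layer = character(0), r = numeric(0),
                    p_value = numeric(0), q_value = numeric(0),
                    sign = character(0))
  if (nrow(sm) && nrow(tm)) {
    rmat <- stats::cor(t(sm), t(tm))
    pmat <- cor_p(rmat, n)
    q <- bh_adjust(as.vector(pmat))
    keep <- abs(as.vector(rmat)) > r_threshold & q < q_threshold
    if (any(keep)) {
      # which(arr.ind) enumerates in column-major order, matching q[keep]
      ij <- which(matrix(keep, nrow(rmat)), arr.ind = TRUE)
      out <- data.frame(
        source_id = rownames(sm)[ij[, 1]],
        target_id = rownames(tm)[ij[, 2]],
        layer = layer,
        r = rmat[ij], p_value = pmat[ij], q_value = q[keep],
        sign = ifelse(rmat[ij] >= 0, "+", "-"),
        stringsAsFactors = FALSE, row.names = NULL)
      # order rows by target then source for stable output
      out <- out[order(out$target_id, out$source_id), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  attr(out, "n_tested") <- nrow(sm) * nrow(tm)
  attr(out, "skipped") <- skipped
  out
}

#' Transcript/translation consistency filter and database assembly
#'
#' For each (gene, metabolite) pair supported by both a transcript edge and
#' a protein edge, the pair is removed when the two correlation signs
#' disagree ("debatable" genes); concordant pairs, genes without a detected
#' protein, and protein edges without a transcript counterpart pass through.
#'
#' @param transcript_edges,protein_edges Edge `data.frame`s from
#'   [build_association_edges()] (protein edges keyed by protein id).
#' @param protein_to_gene Named character vector protein id -> gene id;
#'   every protein edge's source must be present.
#' @param metabolite_clusters Optional [cluster_trends()] assignment.
#' @param class_of Optional metabolite -> class map.
#' @return A `gene_metabolite_database`: list with `edges` (all retained
#'   edges; protein edges carry `gene_id`), `removed_pairs`
#'   (`data.frame` gene_id, target_id), `metabolite_clusters`, `class_of`.
#' @export
consistency_filter <- function(transcript_edges, protein_edges,
                               protein_to_gene,
                               metabolite_clusters = NULL, class_of = NULL) {
  te <- transcript_edges; pe <- protein_edges
  unknown <- setdiff(pe$source_id, names(protein_to_gene))
  if (length(unknown))
    stop("protein(s) mapped to no gene: ", paste(unknown, collapse = ", "))
  te$gene_id <- te$source_id
  pe$gene_id <- unname(protein_to_gene[pe$source_id])
  key_t <- paste(te$gene_id, te$target_id)
  key_p <- paste(pe$gene_id, pe$target_id)
  common <- intersect(key_t, key_p)
  discordant <- common[te$sign[match(common, key_t)] !=
                       pe$sign[match(common, key_p)]]
  te_keep <- te[!key_t %in% discordant, , drop = FALSE]
  pe_keep <- pe[!key_p %in% discordant, , drop = FALSE]
  edges <- rbind(te_keep, pe_keep)
  rownames(edges) <- NULL
  removed <- if (length(discordant)) {
    parts <- strsplit(discordant, " ", fixed = TRUE)
    data.frame(gene_id = vapply(parts, `[`, "", 1),
               target_id = vapply(parts, `[`, "", 2),
               stringsAsFactors = FALSE)
  } else data.frame(gene_id = character(0), target_id = character(0))
  structure(list(edges = edges, removed_pairs = removed,
                 metabolite_clusters = metabolite_clusters,
                 class_of = class_of),
            class = "gene_metabolite_database")
}

#' @export
print.gene_metabolite_database <- function(x, ...) {
  cat("gene_metabolite_database:", nrow(x$edges), "edges (",
      nrow(x$removed_pairs), "discordant pairs removed )\n")
  invisible(x)
}

#' Promoter methylation / expression coupling
#'
#' Correlates each gene's promoter methylation level series (all contexts
#' pooled, replicates pooled per stage) with its expression stage means;
#' BH adjustment across all tested genes; both signs are reported. Genes
#' with an undefined promoter level at any stage or a zero-variance series
#' are skipped (listed in the `skipped` attribute).
#'
#' @param promoter_levels Matrix genes x stages from
#'   [promoter_methylation_series()].
#' @param expression_means Matrix genes x stages (same gene ids).
#' @param q_threshold FDR gate (default 0.05).
#' @return `data.frame` `gene_id`, `r`, `p_value`, `q_value`, `sign`,
#'   `is_significant`.
#' @export
methylation_expression_edges <- function(promoter_levels, expression_means,
                                         q_threshold = 0.05) {
  genes <- intersect(rownames(promoter_levels), rownames(expression_means))
  pl <- promoter_levels[genes, , drop = FALSE]
  em <- expression_means[genes, , drop = FALSE]
  ok <- apply(pl, 1, function(x) !anyNA(x) && stats::sd(x) > 0) &
        apply(em, 1, function(x) stats::sd(x) > 0)
  skipped <- genes[!ok]
  pl <- pl[ok, , drop = FALSE]; em <- em[ok, , drop = FALSE]
  n <- ncol(pl)
  r <- vapply(seq_len(nrow(pl)), function(i) stats::cor(pl[i, ], em[i, ]),
              numeric(1))
  p <- cor_p(r, n)
  q <- bh_adjust(p)
  out <- data.frame(gene_id = rownames(pl), r = r, p_value = p, q_value = q,
                    sign = ifelse(r >= 0, "+", "-"),
                    is_significant = q < q_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "skipped") <- skipped
  out
}

#' Whole-genome methylation vs metabolite correlations
#'
#' Correlates the single global (all-context pooled) methylation level
#' series with every DAM's stage-mean series and summarizes the median r
#' per trend cluster.
#'
#' @param global_series Named numeric vector, one pooled level per stage.
#' @param met_means Matrix metabolites x stages (DAMs).
#' @param clusters [cluster_trends()] assignment of the same metabolites.
#' @return List with `edges` (`data.frame` metabolite_id, r, p_value,
#'   q_value, sign) and `cluster_summary` (`data.frame` cluster_label,
#'   n, median_r).
#' @export
genome_methylation_dam_correlation <- function(global_series, met_means,
                                               clusters) {
  n <- length(global_series)
  stopifnot(n == ncol(met_means))
  ok <- apply(met_means, 1, stats::sd) > 0
  mm <- met_means[ok, , drop = FALSE]
  r <- as.vector(stats::cor(t(mm), global_series))
  p <- cor_p(r, n)
  edges <- data.frame(metabolite_id = rownames(mm), r = r, p_value = p,
                      q_value = bh_adjust(p), sign = ifelse(r >= 0, "+", "-"),
                      stringsAsFactors = FALSE, row.names = NULL)
  lab <- clusters$cluster_label[match(edges$metabolite_id,
                                      clusters$feature_id)]
  keep <- !is.na(lab)
  summ <- if (any(keep)) {
    dt <- data.table::data.table(cluster_label = lab[keep], r = edges$r[keep])
    as.data.frame(dt[, list(n = .N, median_r = stats::median(r)),
                     by = "cluster_label"][order(cluster_label)])
  } else data.frame(cluster_label = character(0), n = integer(0),
                    median_r = numeric(0))
  list(edges = edges, cluster_summary = summ)
}
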