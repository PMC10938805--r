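#' Metabolites increased at the next stage
#'
#' For each adjacent stage pair of the design, the set of metabolites whose
#' differential record for exactly that pair is significant with direction
#' "up" (accumulated at the later stage).
#'
#' @param dam_records Differential records from [differential_all_pairs()]
#'   on the metabolome.
#' @param design A [stage_design()].
#' @return Named list of character vectors, one per transition
#'   (`"S1 vs S2"`, ... — `n_stages - 1` entries).
#' @export
next_stage_increases <- function(dam_records, design) {
  pairs <- adjacent_pairs(design)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    sel <- dam_records$stage_a == pairs[i, 1] &
      dam_records$stage_b == pairs[i, 2] &
      dam_records$is_significant & dam_records$direction == "up"
    sort(unique(dam_records$feature_id[sel]))
  })
  names(out) <- paste(pairs[, 1], "vs", pairs[, 2])
  out
}

#' Class x transition count matrix
#'
#' The number of increased metabolites of each class at each adjacent-stage
#' transition (10 columns for 11 stages). Metabolites without a class are
#' bucketed as "Others". Column sums equal the increase-set sizes.
#'
#' @param increase_sets Output of [next_stage_increases()].
#' @param class_of Named character vector metabolite -> class.
#' @return Integer matrix classes x transitions.
#' @export
class_transition_table <- function(increase_sets, class_of) {
  cls <- function(ids) {
    x <- unname(class_of[ids])
    x[is.na(x)] <- "Others"
    x
  }
  all_classes <- sort(unique(unlist(lapply(increase_sets, cls))))
  if (!length(all_classes)) all_classes <- "Others"
  out <- vapply(increase_sets, function(ids)
    table(factor(cls(ids), levels = all_classes)),
    integer(length(all_classes)))
  out <- matrix(out, nrow = length(all_classes),
                dimnames = list(all_classes, names(increase_sets)))
  out
}

#' Correlated-DEG / DMR-modified funnel per transition
#'
#' For each adjacent transition: correlated genes are the genes with a
#' database edge to at least one metabolite increased at that transition;
#' Correlated DEGs are those that are also significant DEGs for the same
#' adjacent pair; DMR-modified correlated DEGs additionally carry at least
#' one promoter DMR. By construction DMR-modified is a subset of Correlated
#' DEGs, which is a subset of both the pair's DEGs and the correlated genes.
#'
#' @param increase_sets Output of [next_stage_increases()].
#' @param database A `gene_metabolite_database` from [consistency_filter()].
#' @param deg_records Differential records of the transcriptome.
#' @param dmr_gene_ids Character vector of genes with >= 1 promoter DMR
#'   (from [promoter_dmr_genes()]`$by_gene$gene_id`).
#' @param design A [stage_design()].
#' @param include_decreased Also count edges to decreased DAMs of the pair
#'   (default FALSE: increased set only).
#' @param dam_records Required when `include_decreased = TRUE`.
#' @return List with `summary` (`data.frame` per transition: counts and the
#'   DMR-modified fraction) and `sets` (per-transition id lists).
#' @export
transition_correlated_degs <- function(increase_sets, database, deg_records,
                                       dmr_gene_ids, design,
                                       include_decreased = FALSE,
                                       dam_records = NULL) {
  pairs <- adjacent_pairs(design)
  edges <- database$edges
  edge_gene <- if ("gene_id" %in% names(edges)) edges$gene_id
               else edges$source_id
  sets <- list(); rows <- list()
  for (i in seq_len(nrow(pairs))) {
    tr <- paste(pairs[i, 1], "vs", pairs[i, 2])
    mets <- increase_sets[[tr]]
    if (include_decreased) {
      if (is.null(dam_records))
        stop("dam_records needed when include_decreased = TRUE")
      sel <- dam_records$stage_a == pairs[i, 1] &
        dam_records$stage_b == pairs[i, 2] & dam_records$is_significant
      mets <- sort(unique(c(mets, dam_records$feature_id[sel])))
    }
    correlated <- sort(unique(edge_gene[edges$target_id %in% mets]))
    degs_pair <- deg_records$feature_id[
      deg_records$stage_a == pairs[i, 1] &
        deg_records$stage_b == pairs[i, 2] & deg_records$is_significant]
    corr_degs <- intersect(correlated, degs_pair)
    dmr_mod <- intersect(corr_degs, dmr_gene_ids)
    sets[[tr]] <- list(increased_metabolites = mets,
                       correlated_genes = correlated,
                       correlated_degs = corr_degs,
                       dmr_modified_correlated_degs = dmr_mod)
    rows[[tr]] <- data.frame(
      transition = tr, n_increased_metabolites = length(mets),
      n_correlated_genes = length(correlated),
      n_degs_pair = length(unique(degs_pair)),
      n_correlated_degs = length(corr_degs),
      n_dmr_modified = length(dmr_mod),
      frac_dmr_modified = if (length(corr_degs))
        length(dmr_mod) / length(corr_degs) else NA_real_,
      stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       sets = sets)
}
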