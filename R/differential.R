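#' False-discovery-rate adjustment
#'
#' Benjamini-Hochberg step-up q-values (`q_(i) = min_{j >= i} p_(j) * m / j`
#' on the sorted p-values, capped at 1, returned in input order). The
#' Benjamini-Yekutieli variant is available for dependent tests.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` (default) or `"BY"`.
#' @return Numeric vector of q-values in input order.
#' @export
bh_adjust <- function(p_values, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = method)
}

# vectorized Welch two-sample t on rows of two matrices (log scale)
welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se2 <- va / na + vb / nb
  tt <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  # degenerate rows: zero variance in both groups
  degen <- se2 == 0
  p[degen & (mb - ma) == 0] <- 1
  p[degen & (mb - ma) != 0] <- 0
  p
}

#' Stage-pairwise differential calling
#'
#' Calls differential features between two stages of one layer with the
#' standard double gate: absolute fold-change >= `fc_threshold` on stage
#' means and BH FDR < `q_threshold`. The test is a Welch two-sample t on
#' `log2(value + pseudocount)` across replicates; q-values are BH-adjusted
#' across all features of the layer for this stage pair. Features that are
#' all-zero in both stages are excluded (reported in the `excluded`
#' attribute).
#'
#' @param table A [feature_table()].
#' @param stage_a,stage_b Stage labels (`stage_a` earlier).
#' @param fc_threshold Fold-change gate (default 2).
#' @param q_threshold FDR gate (default 0.05).
#' @param pseudocount Pseudocount on the layer's abundance scale (default 1).
#' @param fdr_method `"BH"` or `"BY"`.
#' @return `data.frame` with one row per tested feature: `feature_id`,
#'   `layer`, `stage_a`, `stage_b`, `log2fc`, `p_value`, `q_value`,
#'   `direction`, `is_significant`.
#' @export
call_differential <- function(table, stage_a, stage_b, fc_threshold = 2,
                              q_threshold = 0.05, pseudocount = 1,
                              fdr_method = "BH") {
  stopifnot(inherits(table, "feature_table"))
  design <- table$design
  for (s in c(stage_a, stage_b))
    if (!s %in% design$stages) stop("unknown stage: ", s)
  if (design$replicates < 2) stop("need >= 2 replicates per stage")
  va <- table$values[, sample_ids(design, stage_a), drop = FALSE]
  vb <- table$values[, sample_ids(design, stage_b), drop = FALSE]
  keep <- !(rowSums(va) == 0 & rowSums(vb) == 0)
  excluded <- rownames(table$values)[!keep]
  va <- va[keep, , drop = FALSE]; vb <- vb[keep, , drop = FALSE]
  la <- log2(va + pseudocount); lb <- log2(vb + pseudocount)
  p <- welch_rows(la, lb)
  q <- bh_adjust(p, method = fdr_method)
  log2fc <- log2((rowMeans(vb) + pseudocount) /
                 (rowMeans(va) + pseudocount))
  out <- data.frame(
    feature_id = rownames(va), layer = table$layer,
    stage_a = stage_a, stage_b = stage_b,
    log2fc = log2fc, p_value = p, q_value = q,
    direction = ifelse(log2fc >= 0, "up", "down"),
    is_significant = abs(log2fc) >= log2(fc_threshold) & q < q_threshold,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "excluded") <- excluded
  out
}

#' Differential calling over all stage pairs
#'
#' Runs [call_differential()] for every unordered stage pair of the design
#' (`choose(n_stages, 2)` pairs; 55 for 11 stages). A feature is a
#' DAM/DEP/DEG if it is significant in at least one pair
#' (see [significant_features()]).
#'
#' @inheritParams call_differential
#' @return `data.frame` of stacked per-pair records.
#' @export
differential_all_pairs <- function(table, fc_threshold = 2,
                                   q_threshold = 0.05, pseudocount = 1,
                                   fdr_method = "BH") {
  pairs <- all_stage_pairs(table$design)
  res <- lapply(seq_len(nrow(pairs)), function(i)
    call_differential(table, pairs[i, 1], pairs[i, 2], fc_threshold,
                      q_threshold, pseudocount, fdr_method))
  do.call(rbind, res)
}

#' Features significant in at least one stage pair
#'
#' @param records Differential records from [differential_all_pairs()].
#' @return Character vector of feature ids.
#' @export
significant_features <- function(records) {
  unique(records$feature_id[records$is_significant])
}

#' Write differential records as TSV
#' @param records Differential records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_differential <- function(records, path) {
  data.table::fwrite(records, path, sep = "\t")
  invisible(path)
}
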