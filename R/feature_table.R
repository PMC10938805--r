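#' Feature abundance table for one omics layer
#'
#' Container for a features x (stage, replicate) abundance matrix of one
#' layer (metabolome, proteome or transcriptome). Values must be finite and
#' non-negative; feature ids must be unique. Metabolome tables may carry a
#' feature -> class annotation (`class_of`) used for transition accounting.
#'
#' @param values Numeric matrix, rows = features (rownames = feature ids),
#'   columns named exactly as `design$sample_ids`.
#' @param layer One of `"metabolome"`, `"proteome"`, `"transcriptome"`.
#' @param design A [stage_design()].
#' @param class_of Optional named character vector mapping feature id ->
#'   class label.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, layer, design, class_of = NULL) {
  layer <- match.arg(layer, c("metabolome", "proteome", "transcriptome"))
  stopifnot(inherits(design, "stage_design"))
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("values must have feature ids as rownames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  if (!identical(colnames(values), design$sample_ids)) {
    missing <- setdiff(design$sample_ids, colnames(values))
    extra   <- setdiff(colnames(values), design$sample_ids)
    if (length(missing) || length(extra))
      stop("sample columns do not match design",
           if (length(missing)) paste0("; missing: ",
                                       paste(missing, collapse = ", ")),
           if (length(extra)) paste0("; unexpected: ",
                                     paste(extra, collapse = ", ")))
    values <- values[, design$sample_ids, drop = FALSE]
  }
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("values must be finite numbers")
  if (any(values < 0))
    stop("values must be non-negative")
  if (!is.null(class_of)) {
    class_of <- class_of[rownames(values)]
    names(class_of) <- rownames(values)
    class_of[is.na(class_of)] <- "Others"
  }
  structure(
    list(values = values, layer = layer, design = design, class_of = class_of),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table [", x$layer, "]: ", nrow(x$values), " features x ",
      length(x$design$stages), " stages x ", x$design$replicates,
      " replicates\n", sep = "")
  invisible(x)
}

#' Feature ids of a table
#' @param table A `feature_table`.
#' @return Character vector of feature ids.
#' @export
feature_ids <- function(table) rownames(table$values)

#' Per-stage mean abundances
#'
#' Averages replicate columns within each stage, yielding the stage-mean
#' series used for trend clustering and all cross-layer correlations
#' (replicate means, not medians).
#'
#' @param table A `feature_table`.
#' @return Numeric matrix features x stages (columns in design order).
#' @export
stage_means <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  st <- stage_of_sample(colnames(table$values))
  out <- vapply(table$design$stages, function(s)
    rowMeans(table$values[, st == s, drop = FALSE]),
    numeric(nrow(table$values)))
  dimnames(out) <- list(rownames(table$values), table$design$stages)
  out
}
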