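#' Read a stage-series abundance table
#'
#' Expects a TSV with a `feature_id` column, one column per
#' `<stage>_R<k>` sample of the design, and (optionally, metabolome) a
#' `class` column. Column set must exactly cover the design; duplicate
#' feature ids, missing/extra sample columns and negative values are errors.
#'
#' @param path Path to the TSV file.
#' @param layer Omics layer of the table.
#' @param design A [stage_design()] (default 11 stages x 3 replicates).
#' @return A [feature_table()].
#' @export
read_stage_table <- function(path, layer, design = stage_design()) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "feature_id"))
  if (!"feature_id" %in% names(dt))
    stop("missing feature_id column in ", path)
  ids <- dt$feature_id
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate feature id(s): ", paste(dup, collapse = ", "))
  class_of <- NULL
  if ("class" %in% names(dt)) {
    class_of <- stats::setNames(as.character(dt$class), ids)
  }
  value_cols <- setdiff(names(dt), c("feature_id", "class"))
  missing <- setdiff(design$sample_ids, value_cols)
  extra   <- setdiff(value_cols, design$sample_ids)
  if (length(missing))
    stop("missing sample column(s): ", paste(missing, collapse = ", "))
  if (length(extra))
    stop("unexpected column(s): ", paste(extra, collapse = ", "))
  values <- as.matrix(dt[, design$sample_ids, with = FALSE])
  rownames(values) <- ids
  feature_table(values, layer, design, class_of = class_of)
}

#' Write a stage-series abundance table
#'
#' Inverse of [read_stage_table()]; numbers are written with full precision
#' so that a write/read round trip reproduces values to at least 12
#' significant digits.
#'
#' @param table A [feature_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_stage_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  dt <- data.table::data.table(feature_id = rownames(table$values))
  if (!is.null(table$class_of))
    dt[, "class" := table$class_of[dt$feature_id]]
  dt <- cbind(dt, data.table::as.data.table(table$values))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML key/value file selecting input paths, stage design and analysis
#' parameters; keys are passed through to [simulation_config()] (synthetic
#' mode) or used as file paths (file mode).
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config file must contain a key/value mapping")
  cfg
}
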