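#' Read gene models from BED6
#'
#' BED6 columns: chrom, start, end, name, score, strand. Coordinates are
#' 0-based half-open throughout the package. Gene names must be unique and
#' strand must be `+` or `-` (promoters are strand-aware).
#'
#' @param path BED6 file path.
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"),
                          colClasses = list(character = c(1, 4, 5, 6)))
  if (any(dt$start >= dt$end))
    stop("invalid interval (start >= end) for: ",
         paste(dt$name[dt$start >= dt$end], collapse = ", "))
  if (any(dt$start < 0)) stop("negative start coordinate")
  dup <- unique(dt$name[duplicated(dt$name)])
  if (length(dup))
    stop("duplicate gene name(s): ", paste(dup, collapse = ", "))
  if (any(!dt$strand %in% c("+", "-")))
    stop("strand must be + or - (promoter definition requires a strand)")
  data.frame(gene_id = dt$name, chrom = dt$chrom,
             start = as.integer(dt$start), end = as.integer(dt$end),
             strand = dt$strand, stringsAsFactors = FALSE)
}

#' Write gene models as BED6
#' @param genes Gene model `data.frame` (see [read_gene_bed()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  dt <- data.table::data.table(chrom = genes$chrom, start = genes$start,
                               end = genes$end, name = genes$gene_id,
                               score = ".", strand = genes$strand)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Strand-aware promoter intervals
#'
#' The promoter is a fixed-length window immediately upstream of the
#' annotated 5' end: `[start - upstream_bp, start)` for `+` genes and
#' `[end, end + upstream_bp)` for `-` genes (0-based half-open), clipped at
#' the chromosome start (and end, when `chrom_length` is given). Default
#' 2 kb, the length cloned for promoter assays in this system; promoters
#' never overlap the gene body of their own gene.
#'
#' @param genes Gene model `data.frame`.
#' @param upstream_bp Window length in bp (> 0), default 2000.
#' @param chrom_length Optional named vector of chromosome lengths used to
#'   clip `-`-strand promoters.
#' @return `data.frame` `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
promoter_intervals <- function(genes, upstream_bp = 2000L,
                               chrom_length = NULL) {
  upstream_bp <- as.integer(upstream_bp)
  if (is.na(upstream_bp) || upstream_bp <= 0L)
    stop("upstream_bp must be a positive integer")
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(0L, genes$start - upstream_bp), genes$end)
  end <- ifelse(plus, genes$start, genes$end + upstream_bp)
  if (!is.null(chrom_length)) {
    lim <- chrom_length[genes$chrom]
    end <- ifelse(!plus & !is.na(lim), pmin(end, lim), end)
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = as.integer(start), end = as.integer(end),
             strand = genes$strand, stringsAsFactors = FALSE)
}

#' Read 24-nt siRNA clusters
#'
#' BED-like TSV with header: chrom, start, end, cluster_id, then one read
#' count column per sample id. Coordinates 0-based half-open.
#'
#' @param path File path.
#' @param design A [stage_design()]; count columns must cover its samples.
#' @return List with `intervals` (`data.frame`) and `counts` (matrix
#'   clusters x samples).
#' @export
read_sirna_clusters <- function(path, design = stage_design()) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  need <- c("chrom", "start", "end", "cluster_id")
  if (!all(need %in% names(dt)))
    stop("siRNA cluster table must have columns: ",
         paste(need, collapse = ", "))
  if (any(dt$start >= dt$end)) stop("invalid siRNA cluster interval")
  cols <- setdiff(names(dt), need)
  missing <- setdiff(design$sample_ids, cols)
  if (length(missing))
    stop("missing siRNA count column(s): ", paste(missing, collapse = ", "))
  counts <- as.matrix(dt[, design$sample_ids, with = FALSE])
  if (any(counts < 0)) stop("negative siRNA read count")
  rownames(counts) <- dt$cluster_id
  list(intervals = data.frame(cluster_id = dt$cluster_id, chrom = dt$chrom,
                              start = as.integer(dt$start),
                              end = as.integer(dt$end),
                              stringsAsFactors = FALSE),
       counts = counts)
}

#' Write 24-nt siRNA clusters
#' @param clusters List as returned by [read_sirna_clusters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sirna_clusters <- function(clusters, path) {
  dt <- data.table::data.table(chrom = clusters$intervals$chrom,
                               start = clusters$intervals$start,
                               end = clusters$intervals$end,
                               cluster_id = clusters$intervals$cluster_id)
  dt <- cbind(dt, data.table::as.data.table(clusters$counts))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
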