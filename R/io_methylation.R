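#' Read a per-sample cytosine report
#'
#' Parses the Bismark-style cytosine report dialect: whitespace-separated
#' columns chrom, position (1-based), strand, count methylated, count
#' unmethylated, context (CG/CHG/CHH) and trinucleotide. Positions are
#' converted to the package's internal 0-based convention on ingest.
#' Zero-coverage sites are retained; their level is undefined (NA), never 0.
#'
#' @param path Report file path.
#' @param stage Stage label of the sample.
#' @param rep Replicate number of the sample.
#' @return A `data.table` of methylation sites with columns `chrom`, `pos0`
#'   (0-based), `strand`, `context`, `meth`, `unmeth`, `stage`, `rep`.
#' @export
read_cytosine_report <- function(path, stage, rep = 1L) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "pos", "strand", "meth",
                                        "unmeth", "context", "tri"),
                          colClasses = list(character = c(1, 3, 6, 7)))
  if (!is.integer(dt$pos) && any(dt$pos != floor(dt$pos)))
    stop("non-integer position in ", path)
  if (!is.numeric(dt$meth) || !is.numeric(dt$unmeth) ||
      any(dt$meth != floor(dt$meth)) || any(dt$unmeth != floor(dt$unmeth)))
    stop("non-integer methylation counts in ", path)
  if (any(dt$meth < 0) || any(dt$unmeth < 0))
    stop("negative methylation count in ", path)
  bad <- setdiff(unique(dt$context), c("CG", "CHG", "CHH"))
  if (length(bad))
    stop("unknown methylation context(s): ", paste(bad, collapse = ", "))
  if (any(!dt$strand %in% c("+", "-")))
    stop("strand must be + or -")
  out <- data.table::data.table(
    chrom = dt$chrom, pos0 = as.integer(dt$pos) - 1L, strand = dt$strand,
    context = dt$context, meth = as.integer(dt$meth),
    unmeth = as.integer(dt$unmeth), stage = stage, rep = as.integer(rep))
  out
}

#' Write a per-sample cytosine report
#'
#' Inverse of [read_cytosine_report()]: writes 1-based positions in the
#' Bismark cytosine-report dialect. The trinucleotide column is emitted as
#' the context (the simulator does not model local sequence).
#'
#' @param sites Site table for a single sample (columns as returned by
#'   [read_cytosine_report()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(sites, path) {
  dt <- data.table::data.table(
    chrom = sites$chrom, pos = sites$pos0 + 1L, strand = sites$strand,
    meth = sites$meth, unmeth = sites$unmeth, context = sites$context,
    tri = sites$context)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Per-site methylation level
#'
#' `meth / (meth + unmeth)`; `NA` for zero-coverage sites (a missing level
#' is not a zero level).
#'
#' @param sites Site table.
#' @return Numeric vector of levels in \[0, 1\] or `NA`.
#' @export
site_level <- function(sites) {
  cov <- sites$meth + sites$unmeth
  ifelse(cov > 0, sites$meth / cov, NA_real_)
}
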