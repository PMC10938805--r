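#' Pooled methylation level of a genomic interval
#'
#' Weighted (count-pooled) level: `sum(meth) / sum(meth + unmeth)` over all
#' covered sites of the requested context inside the 0-based half-open
#' interval. Undefined (`NA`) when the interval contains no covered site —
#' a missing level is never reported as 0.
#'
#' @param sites Methylation site table (any number of samples; counts are
#'   pooled).
#' @param chrom Chromosome.
#' @param start,end Interval, 0-based half-open.
#' @param context Optional context filter (`"CG"`, `"CHG"`, `"CHH"`); all
#'   contexts pooled when `NULL`.
#' @return Level in \[0, 1\] or `NA`.
#' @export
region_methylation_level <- function(sites, chrom, start, end,
                                     context = NULL) {
  sel <- sites$chrom == chrom & sites$pos0 >= start & sites$pos0 < end
  if (!is.null(context)) sel <- sel & sites$context %in% context
  m <- sum(sites$meth[sel]); u <- sum(sites$unmeth[sel])
  if (m + u == 0) return(NA_real_)
  m / (m + u)
}

#' Stage-wise global methylation level series
#'
#' Pools all sites (replicates and positions) per stage and context.
#'
#' @param sites Site table covering all samples.
#' @param design A [stage_design()].
#' @param context Optional context filter; all contexts pooled when `NULL`.
#' @return Named numeric vector, one pooled level per stage in design order.
#' @export
global_methylation_series <- function(sites, design, context = NULL) {
  dt <- data.table::as.data.table(sites)
  if (!is.null(context)) {
    sel <- sites$context %in% context  # evaluate outside the frame
    dt <- dt[sel]
  }
  agg <- dt[, list(m = sum(meth), u = sum(unmeth)), by = "stage"]
  lev <- ifelse(agg$m + agg$u > 0, agg$m / (agg$m + agg$u), NA_real_)
  stats::setNames(lev[match(design$stages, agg$stage)], design$stages)
}

#' Per-gene promoter methylation level series
#'
#' Pooled (all-context by default) methylation level of each gene's promoter
#' at each stage, replicates pooled. Genes whose promoter has no covered
#' site at some stage get `NA` for that stage.
#'
#' @param sites Site table covering all samples.
#' @param promoters Promoter intervals from [promoter_intervals()].
#' @param design A [stage_design()].
#' @param context Optional context filter.
#' @return Matrix genes x stages of levels (possibly `NA`).
#' @export
promoter_methylation_series <- function(sites, promoters, design,
                                        context = NULL) {
  dt <- data.table::as.data.table(sites)
  if (!is.null(context)) {
    sel <- sites$context %in% context  # evaluate outside the frame
    dt <- dt[sel]
  }
  hits <- overlap_sites_intervals(dt, promoters)
  out <- matrix(NA_real_, nrow(promoters), length(design$stages),
                dimnames = list(promoters$gene_id, design$stages))
  if (!nrow(hits)) return(out)
  agg <- hits[, list(m = sum(meth), u = sum(unmeth)),
              by = c("interval_id", "stage")]
  agg <- agg[agg$m + agg$u > 0]
  out[cbind(match(agg$interval_id, promoters$gene_id),
            match(agg$stage, design$stages))] <- agg$m / (agg$m + agg$u)
  out
}

# internal: join sites to intervals (data.frame with gene_id/chrom/start/end)
# returns site rows annotated with interval_id (sites in several intervals
# are repeated)
overlap_sites_intervals <- function(sites, intervals) {
  gr_sites <- GenomicRanges::GRanges(sites$chrom,
                                     IRanges::IRanges(sites$pos0 + 1L,
                                                      width = 1L))
  id_col <- if ("gene_id" %in% names(intervals)) intervals$gene_id
            else intervals$region_id
  gr_int <- GenomicRanges::GRanges(intervals$chrom,
                                   IRanges::IRanges(intervals$start + 1L,
                                                    intervals$end))
  ov <- GenomicRanges::findOverlaps(gr_sites, gr_int)
  out <- data.table::as.data.table(sites)[S4Vectors::queryHits(ov)]
  out[, "interval_id" := id_col[S4Vectors::subjectHits(ov)]]
  out
}

#' Metagene methylation profile
#'
#' Average methylation level over genes rescaled to a fixed number of body
#' bins plus fixed-width flanking bins, per context and stage. Minus-strand
#' genes are reversed so that "upstream" is always the 5' flank. Bin level
#' is the count-pooled level across all genes' sites in that bin; bins with
#' no covered site are `NA`.
#'
#' @param sites Site table covering all samples.
#' @param genes Gene models (see [read_gene_bed()]).
#' @param design A [stage_design()].
#' @param n_body_bins Gene-body bins (default 40).
#' @param flank_bp Flank length in bp (default 2000).
#' @param flank_bin_bp Flank bin width in bp (default 100).
#' @return `data.frame` `context`, `stage`, `bin`, `region`
#'   (upstream/body/downstream), `level`. Bins are numbered 1..(2 *
#'   flank_bp/flank_bin_bp + n_body_bins) from the 5' flank.
#' @export
metagene_profile <- function(sites, genes, design, n_body_bins = 40L,
                             flank_bp = 2000L, flank_bin_bp = 100L) {
  if (nrow(genes) == 0) stop("need at least one gene")
  nf <- as.integer(flank_bp / flank_bin_bp)
  ext <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = pmax(0L, genes$start - flank_bp),
                    end = genes$end + flank_bp)
  dt <- overlap_sites_intervals(data.table::as.data.table(sites), ext)
  gi <- match(dt$interval_id, genes$gene_id)
  plus <- genes$strand[gi] == "+"
  rel <- ifelse(plus, dt$pos0 - genes$start[gi],
                (genes$end[gi] - 1L) - dt$pos0)
  len <- genes$end[gi] - genes$start[gi]
  bin <- integer(nrow(dt))
  up <- rel < 0
  dn <- rel >= len
  bd <- !up & !dn
  bin[up] <- 1L + ((rel[up] + flank_bp) %/% flank_bin_bp)
  bin[bd] <- nf + 1L + pmin(n_body_bins - 1L,
                            (rel[bd] * n_body_bins) %/% len[bd])
  bin[dn] <- nf + n_body_bins + 1L +
    pmin(nf - 1L, (rel[dn] - len[dn]) %/% flank_bin_bp)
  dt[, "bin" := bin]
  agg <- dt[, list(m = sum(meth), u = sum(unmeth)),
            by = c("context", "stage", "bin")]
  n_bins <- 2L * nf + n_body_bins
  grid <- data.table::CJ(context = sort(unique(sites$context)),
                         stage = design$stages, bin = seq_len(n_bins))
  out <- merge(grid, agg, by = c("context", "stage", "bin"),
               all.x = TRUE, sort = FALSE)
  out[, "level" := ifelse(!is.na(m) & (m + u) > 0, m / (m + u), NA_real_)]
  region <- function(b) ifelse(b <= nf, "upstream",
                        ifelse(b <= nf + n_body_bins, "body", "downstream"))
  res <- data.frame(context = out$context,
                    stage = factor(out$stage, levels = design$stages),
                    bin = out$bin, region = region(out$bin),
                    level = out$level, stringsAsFactors = FALSE)
  res[order(res$context, res$stage, res$bin), , drop = FALSE]
}

# Fisher two-sided p for pooled 2x2 window counts
fisher_p <- function(ma, ua, mb, ub) {
  n <- length(ma)
  p <- numeric(n)
  for (i in seq_len(n))
    p[i] <- stats::fisher.test(matrix(c(ma[i], ua[i], mb[i], ub[i]),
                                      2))$p.value
  pmin(p, 1)  # fisher.test can exceed 1 by rounding error
}

#' Windowed DMR calling between two stages
#'
#' Simplified differentially-methylated-region caller: per context, counts
#' are pooled over replicates within each stage, sliding windows
#' (`window_bp` wide, `step_bp` apart) are tested with Fisher's exact test
#' on the pooled 2x2 (meth/unmeth x stage) table, q-values are BH-adjusted
#' across all tested windows of the context, and windows passing
#' `q < q_threshold` and `|delta| >= delta_min` are merged when overlapping
#' or within `step_bp` of each other (same context and delta sign). Windows
#' with fewer than `min_sites` positions covered in both stages are skipped.
#'
#' @param sites_a,sites_b Site tables for the two stages (replicates pooled
#'   internally); `sites_a` is the earlier stage.
#' @param window_bp,step_bp Window geometry (defaults 100/50).
#' @param min_sites Minimum covered positions per window (default 4).
#' @param delta_min Minimum |level_b - level_a| (default 0.1).
#' @param q_threshold FDR gate (default 0.05).
#' @param contexts Contexts to scan (default all three).
#' @return `data.frame` of merged DMRs: `chrom`, `start`, `end`, `context`,
#'   `stage_a`, `stage_b`, `level_a`, `level_b`, `delta`, `p_value`,
#'   `q_value`, `n_sites`. Attribute `n_windows_tested` / `n_windows_skipped`
#'   record the scan log.
#' @export
call_dmrs <- function(sites_a, sites_b, window_bp = 100L, step_bp = 50L,
                      min_sites = 4L, delta_min = 0.1, q_threshold = 0.05,
                      contexts = c("CG", "CHG", "CHH")) {
  stage_a <- unique(sites_a$stage); stage_b <- unique(sites_b$stage)
  if (length(stage_a) != 1L || length(stage_b) != 1L)
    stop("each input must contain sites of exactly one stage")
  pool <- function(x) data.table::as.data.table(x)[
    , list(m = sum(meth), u = sum(unmeth)),
    by = c("chrom", "pos0", "context")]
  a <- pool(sites_a); b <- pool(sites_b)
  ab <- merge(a, b, by = c("chrom", "pos0", "context"),
              suffixes = c("_a", "_b"))
  ab <- ab[(ab$m_a + ab$u_a) > 0 & (ab$m_b + ab$u_b) > 0]
  ab <- ab[ab$context %in% contexts]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), context = character(0),
                      stage_a = character(0), stage_b = character(0),
                      level_a = numeric(0), level_b = numeric(0),
                      delta = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), n_sites = integer(0))
  if (!nrow(ab)) return(empty)
  # expand each site into every window covering it
  w_lo <- pmax(0L, as.integer(ceiling((ab$pos0 - window_bp + 1) / step_bp)))
  w_hi <- ab$pos0 %/% step_bp
  reps <- w_hi - w_lo + 1L
  idx <- rep(seq_len(nrow(ab)), reps)
  win <- ab[idx]
  win[, "w" := w_lo[idx] + (sequence(reps) - 1L)]
  agg <- win[, list(ma = sum(m_a), ua = sum(u_a), mb = sum(m_b),
                    ub = sum(u_b), n_sites = .N),
             by = c("chrom", "context", "w")]
  tested <- agg[agg$n_sites >= min_sites]
  n_skipped <- nrow(agg) - nrow(tested)
  if (!nrow(tested)) {
    attr(empty, "n_windows_tested") <- 0L
    attr(empty, "n_windows_skipped") <- n_skipped
    return(empty)
  }
  tested[, "level_a" := ma / (ma + ua)]
  tested[, "level_b" := mb / (mb + ub)]
  tested[, "delta" := level_b - level_a]
  tested[, "p" := fisher_p(ma, ua, mb, ub)]
  tested[, "q" := bh_adjust(p), by = "context"]
  sig <- tested[tested$q < q_threshold & abs(tested$delta) >= delta_min]
  if (!nrow(sig)) {
    attr(empty, "n_windows_tested") <- nrow(tested)
    attr(empty, "n_windows_skipped") <- n_skipped
    return(empty)
  }
  sig[, "start" := w * step_bp]
  sig[, "end" := w * step_bp + window_bp]
  sig[, "sign" := ifelse(delta >= 0, "+", "-")]
  data.table::setorderv(sig, c("chrom", "context", "sign", "start"))
  # merge overlapping/adjacent significant windows (gap <= step_bp)
  grp <- integer(nrow(sig)); g <- 0L; last_end <- -Inf
  key_prev <- ""
  for (i in seq_len(nrow(sig))) {
    key <- paste(sig$chrom[i], sig$context[i], sig$sign[i])
    if (key != key_prev || sig$start[i] > last_end + step_bp) {
      g <- g + 1L; last_end <- sig$end[i]
    } else last_end <- max(last_end, sig$end[i])
    grp[i] <- g; key_prev <- key
  }
  sig[, "grp" := grp]
  merged <- sig[, list(chrom = chrom[1], start = min(start), end = max(end),
                       context = context[1], p_value = min(p),
                       q_value = min(q)),
                by = "grp"]
  # recompute pooled levels and site counts over each merged interval
  lev <- lapply(seq_len(nrow(merged)), function(i) {
    s <- ab[ab$chrom == merged$chrom[i] & ab$context == merged$context[i] &
            ab$pos0 >= merged$start[i] & ab$pos0 < merged$end[i]]
    c(la = sum(s$m_a) / sum(s$m_a + s$u_a),
      lb = sum(s$m_b) / sum(s$m_b + s$u_b), n = nrow(s))
  })
  lev <- do.call(rbind, lev)
  out <- data.frame(chrom = merged$chrom, start = merged$start,
                    end = merged$end, context = merged$context,
                    stage_a = stage_a, stage_b = stage_b,
                    level_a = lev[, "la"], level_b = lev[, "lb"],
                    delta = lev[, "lb"] - lev[, "la"],
                    p_value = merged$p_value, q_value = merged$q_value,
                    n_sites = as.integer(lev[, "n"]),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_windows_tested") <- nrow(tested)
  attr(out, "n_windows_skipped") <- n_skipped
  out
}

#' Genes whose promoter overlaps a DMR
#'
#' Overlap means any shared base between the DMR and the strand-aware
#' promoter interval (0-based half-open on both sides).
#'
#' @param dmrs DMR `data.frame` from [call_dmrs()] (possibly stacked over
#'   stage pairs).
#' @param genes Gene models.
#' @param upstream_bp Promoter length (default 2000).
#' @return List with `by_gene` (`data.frame` gene_id, n_dmrs, contexts — a
#'   comma-separated flag set of contexts present) and `overlaps`
#'   (`data.frame` gene_id x DMR row index pairs).
#' @export
promoter_dmr_genes <- function(dmrs, genes, upstream_bp = 2000L) {
  prom <- promoter_intervals(genes, upstream_bp)
  if (!nrow(dmrs)) {
    return(list(by_gene = data.frame(gene_id = character(0),
                                     n_dmrs = integer(0),
                                     contexts = character(0)),
                overlaps = data.frame(gene_id = character(0),
                                      dmr = integer(0))))
  }
  gr_d <- GenomicRanges::GRanges(dmrs$chrom,
                                 IRanges::IRanges(dmrs$start + 1L, dmrs$end))
  gr_p <- GenomicRanges::GRanges(prom$chrom,
                                 IRanges::IRanges(prom$start + 1L, prom$end))
  ov <- GenomicRanges::findOverlaps(gr_d, gr_p)
  overlaps <- data.frame(
    gene_id = prom$gene_id[S4Vectors::subjectHits(ov)],
    dmr = S4Vectors::queryHits(ov), stringsAsFactors = FALSE)
  if (!nrow(overlaps)) {
    return(list(by_gene = data.frame(gene_id = character(0),
                                     n_dmrs = integer(0),
                                     contexts = character(0)),
                overlaps = overlaps))
  }
  dt <- data.table::as.data.table(overlaps)
  dt[, "context" := dmrs$context[dt$dmr]]
  by_gene <- dt[, list(n_dmrs = .N,
                       contexts = paste(sort(unique(context)),
                                        collapse = ",")),
                by = "gene_id"]
  list(by_gene = as.data.frame(by_gene), overlaps = overlaps)
}

#' siRNA cluster abundance (RPM) in regions
#'
#' Assigns each 24-nt siRNA cluster to the region containing its midpoint
#' (so a cluster is never double-counted) and reports reads per million
#' total clean reads per region and sample.
#'
#' @param clusters List with `intervals` and `counts` (see
#'   [read_sirna_clusters()]).
#' @param regions `data.frame` with `region_id` (or `gene_id`), `chrom`,
#'   `start`, `end`.
#' @param total_clean_reads Named vector of per-sample total clean reads
#'   (> 0).
#' @return Matrix regions x samples of RPM values (0 for empty regions).
#' @export
sirna_rpm_in_regions <- function(clusters, regions, total_clean_reads) {
  if (any(total_clean_reads <= 0))
    stop("total_clean_reads must be positive")
  id_col <- if ("region_id" %in% names(regions)) regions$region_id
            else regions$gene_id
  mid <- (clusters$intervals$start + clusters$intervals$end) %/% 2L
  gr_c <- GenomicRanges::GRanges(clusters$intervals$chrom,
                                 IRanges::IRanges(mid + 1L, width = 1L))
  gr_r <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start + 1L,
                                                  regions$end))
  ov <- GenomicRanges::findOverlaps(gr_c, gr_r)
  samples <- colnames(clusters$counts)
  out <- matrix(0, nrow(regions), length(samples),
                dimnames = list(id_col, samples))
  if (length(ov)) {
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    for (j in seq_along(samples)) {
      sums <- tapply(clusters$counts[q, j], s, sum)
      out[as.integer(names(sums)), j] <- sums
    }
  }
  sweep(out, 2, total_clean_reads[samples], "/") * 1e6
}
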