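#' Stage-series experimental design
#'
#' Describes the developmental series: an ordered set of stage labels and a
#' fixed number of biological replicates per stage. The default mirrors a
#' fruit-development series sampled at 11 time points with 3 replicates.
#' The label order is fixed and used everywhere downstream (stage means,
#' adjacent-stage transitions, trend archetypes).
#'
#' @param n_stages Number of stages (default 11).
#' @param replicates Replicates per stage (default 3).
#' @param stage_labels Optional character vector of unique stage names;
#'   defaults to `S1..Sn`.
#' @return An object of class `stage_design` with elements `stages`,
#'   `replicates` and `sample_ids` (ordered `<stage>_R<k>` names).
#' @export
stage_design <- function(n_stages = 11L, replicates = 3L, stage_labels = NULL) {
  if (is.null(stage_labels)) {
    n_stages <- as.integer(n_stages)
    if (is.na(n_stages) || n_stages < 2L)
      stop("need at least 2 stages")
    stage_labels <- paste0("S", seq_len(n_stages))
  }
  stage_labels <- as.character(stage_labels)
  if (anyDuplicated(stage_labels))
    stop("stage labels must be unique")
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L)
    stop("replicates must be a positive integer")
  ids <- as.vector(t(outer(stage_labels, seq_len(replicates),
                           function(s, k) paste0(s, "_R", k))))
  structure(
    list(stages = stage_labels, replicates = replicates, sample_ids = ids),
    class = "stage_design"
  )
}

#' @export
print.stage_design <- function(x, ...) {
  cat("stage_design:", length(x$stages), "stages x", x$replicates,
      "replicates\n  stages:", paste(x$stages, collapse = " "), "\n")
  invisible(x)
}

#' Sample identifiers of a design
#'
#' @param design A `stage_design`.
#' @param stage Optional stage label; restrict to that stage's samples.
#' @return Character vector of `<stage>_R<k>` sample ids.
#' @export
sample_ids <- function(design, stage = NULL) {
  stopifnot(inherits(design, "stage_design"))
  if (is.null(stage)) return(design$sample_ids)
  if (!stage %in% design$stages) stop("unknown stage: ", stage)
  paste0(stage, "_R", seq_len(design$replicates))
}

#' Adjacent stage pairs of a design
#'
#' @param design A `stage_design`.
#' @return Two-column character matrix with one row per adjacent pair
#'   (`n_stages - 1` rows), earlier stage first.
#' @export
adjacent_pairs <- function(design) {
  s <- design$stages
  cbind(a = s[-length(s)], b = s[-1])
}

#' All unordered stage pairs of a design
#'
#' @param design A `stage_design`.
#' @return Two-column character matrix, one row per unordered pair
#'   (`choose(n_stages, 2)` rows), earlier stage first.
#' @export
all_stage_pairs <- function(design) {
  s <- design$stages
  idx <- utils::combn(length(s), 2)
  cbind(a = s[idx[1, ]], b = s[idx[2, ]])
}

# internal: map sample ids back to stage labels
stage_of_sample <- function(ids) sub("_R[0-9]+$", "", ids)
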