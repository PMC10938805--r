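#' Z-score standardization of a stage-mean series
#'
#' `(x - mean) / sd` with the sample sd (n - 1). A constant series is
#' returned as all zeros and flagged via the `degenerate` attribute.
#'
#' @param series Numeric vector (one feature's stage means) or a matrix
#'   (features x stages, standardized row-wise).
#' @return Standardized vector/matrix; attribute `degenerate` marks
#'   zero-variance rows.
#' @export
zscore_series <- function(series) {
  if (is.matrix(series)) {
    out <- t(apply(series, 1, zscore_series))
    dimnames(out) <- dimnames(series)
    attr(out, "degenerate") <-
      apply(series, 1, function(x) isTRUE(stats::sd(x) == 0))
    return(out)
  }
  s <- stats::sd(series)
  if (!is.finite(s) || s == 0) {
    out <- rep(0, length(series))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (series - mean(series)) / s
  attr(out, "degenerate") <- FALSE
  out
}

#' Cluster metabolite trend series into archetypal clusters I-VIII
#'
#' K-means (Euclidean, seeded) on z-scored stage-mean series, with clusters
#' mapped to the labels I-VIII by greedily matching each centroid to its
#' most-correlated trend archetype (correlation distance; bijection
#' enforced, ties broken by label order). When `k = 8`, the k-means
#' centroids are initialized at the eight archetypes (anchored
#' initialization): random restarts tend to merge the strongly correlated
#' monotone archetype pairs and spend centroids on idiosyncratic outliers,
#' whereas anchoring keeps each cluster on its archetypal shape. With
#' `anchor = FALSE` (or `k != 8`) 20 seeded random restarts are used. Row
#' order does not affect the assignment.
#'
#' @param z_matrix Numeric matrix, features x stages, z-scored rows.
#' @param k Number of clusters (default 8).
#' @param seed Seed for the k-means restarts.
#' @param nstart Number of k-means restarts when not anchored (default 20).
#' @param method `"kmeans"` (default) or `"ward"` (hierarchical, Ward.D2 on
#'   Euclidean distance).
#' @param anchor Initialize centroids at the archetypes when `k = 8`
#'   (default TRUE).
#' @return `data.frame` `feature_id`, `cluster_label`, `centroid_distance`.
#' @export
cluster_trends <- function(z_matrix, k = 8L, seed = 1L, nstart = 20L,
                           method = c("kmeans", "ward"), anchor = TRUE) {
  method <- match.arg(method)
  if (nrow(z_matrix) < k)
    stop("need at least k = ", k, " rows to cluster")
  if (is.null(rownames(z_matrix)))
    rownames(z_matrix) <- paste0("f", seq_len(nrow(z_matrix)))
  ord <- order(rownames(z_matrix))  # row-order invariance
  zm <- z_matrix[ord, , drop = FALSE]
  if (nrow(zm) == k) {
    member <- seq_len(k)         # trivial partition, one row per cluster
    centers <- zm
  } else if (method == "kmeans") {
    set.seed(seed)
    if (anchor && k == 8L) {
      km <- stats::kmeans(zm, centers = make_archetypes(ncol(zm)),
                          iter.max = 100)
    } else {
      km <- stats::kmeans(zm, centers = k, nstart = nstart, iter.max = 100)
    }
    member <- km$cluster
    centers <- km$centers
  } else {
    hc <- stats::hclust(stats::dist(zm), method = "ward.D2")
    member <- stats::cutree(hc, k = k)
    centers <- t(vapply(seq_len(k), function(i)
      colMeans(zm[member == i, , drop = FALSE]), numeric(ncol(zm))))
  }
  arche <- make_archetypes(ncol(z_matrix))
  labels <- archetype_labels()
  if (k != nrow(arche))
    labels <- c(labels, paste0("C", seq_len(max(0, k - nrow(arche)))))
  # greedy bijection centroid <-> archetype by correlation
  cm <- stats::cor(t(centers), t(arche))
  if (k > nrow(arche))
    cm <- cbind(cm, matrix(-Inf, k, k - nrow(arche)))
  lab_of <- character(k)
  free_c <- seq_len(k); free_a <- seq_len(k)
  for (i in seq_len(k)) {
    sub <- cm[free_c, free_a, drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)
    best <- best[order(best[, 2], best[, 1]), , drop = FALSE][1, ]
    lab_of[free_c[best[1]]] <- labels[free_a[best[2]]]
    free_c <- free_c[-best[1]]; free_a <- free_a[-best[2]]
  }
  dist_to <- sqrt(rowSums((zm - centers[member, , drop = FALSE])^2))
  out <- data.frame(feature_id = rownames(zm),
                    cluster_label = lab_of[member],
                    centroid_distance = dist_to,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[match(rownames(z_matrix), out$feature_id), , drop = FALSE]
}
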