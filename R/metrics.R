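# Evaluation metrics: adjusted Rand index, percentage of abnormal spots,
# and the empirical power / clustering-FDR summaries used by the
# simulation studies.

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected partition agreement in \[-1, 1\]; invariant to label
#' permutations of either argument and symmetric in its arguments.
#'
#' @param labels_a,labels_b equal-length label vectors (any atomic type).
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("labelings must have equal length")
  if (length(labels_a) < 2L) stop("need at least 2 items")
  mclust::adjustedRandIndex(labels_a, labels_b)
}

#' Percentage of abnormal spots (PAS)
#'
#' Fraction of spots whose label differs from at least 6 of their 10
#' Euclidean nearest neighboring spots; lower means spatially smoother
#' domains. For N <= 10 spots all N - 1 neighbors are used with threshold
#' `ceiling(0.6 * (N - 1))`. Ties at the boundary neighbor distance are
#' broken by spot index.
#'
#' @param labels per-spot labels (no missing values).
#' @param spots a [spot_set()] (or coordinate matrix).
#' @return PAS in \[0, 1\].
#' @export
pas <- function(labels, spots) {
  spots <- as_spot_set(spots)
  n <- n_spots(spots)
  if (length(labels) != n) stop("labels must match the spot set")
  if (anyNA(labels)) stop("unlabeled spot")
  k <- if (n > 10L) 10L else n - 1L
  thresh <- if (n > 10L) 6L else ceiling(0.6 * (n - 1L))
  nn <- knn_index(spots$coords, k)
  ndiff <- vapply(seq_len(n),
                  function(i) sum(labels[nn[i, ]] != labels[i]), 0L)
  mean(ndiff >= thresh)
}

#' Per-gene empirical detection power over replicates
#'
#' @param svg_results list of [detect_svgs()] results sharing one gene
#'   layout.
#' @param truth optional data.frame with columns `gene_id` and `is_svg`
#'   (true status), merged into the output when given.
#' @return data.frame with `gene_id` and `power` (fraction of replicates in
#'   which the gene was declared an SVG).
#' @export
empirical_power <- function(svg_results, truth = NULL) {
  if (length(svg_results) == 0L) stop("no replicates")
  ids <- svg_results[[1L]]$gene_id
  hits <- vapply(svg_results, function(r) {
    if (!identical(r$gene_id, ids))
      stop("replicates do not share the gene layout")
    as.numeric(r$is_svg)
  }, numeric(length(ids)))
  out <- data.frame(gene_id = ids, power = rowMeans(hits))
  if (!is.null(truth)) out <- merge(out, truth, by = "gene_id", sort = FALSE)
  out
}

#' Empirical FDR of the final gene clustering
#'
#' A false discovery is any truly non-spatial gene appearing in the final
#' clustering output (clusters or singletons); the FDR is that count
#' divided by the total number of genes in the output, and 0 when the
#' output is empty.
#'
#' @param clusters a `gene_clusters` data.frame ([cluster_genes()]).
#' @param nonspatial_ids gene ids that are truly non-spatial.
#' @return Empirical false discovery proportion in \[0, 1\].
#' @export
empirical_fdr <- function(clusters, nonspatial_ids) {
  if (nrow(clusters) == 0L) return(0)
  sum(clusters$gene_id %in% nonspatial_ids) / nrow(clusters)
}
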