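# Downstream analysis: per-gene-cluster spatially smoothed PCA embeddings,
# aggregation, and graph-based clustering of spots into spatial domains.
# The smoothed-PCA embedding approximates spatially aware dimension
# reduction behind a pluggable interface: each gene vector is replaced by a
# row-stochastic Gaussian-kernel average over spots before ordinary PCA, so
# the leading components emphasize spatially coherent variation.

#' Spatially smooth an expression block
#'
#' Replaces every gene's spot vector by the row-stochastic
#' Gaussian-kernel-weighted average over spots:
#' smoothed y_i = sum_j w_ij y_j with w_ij proportional to
#' exp(-d_ij^2 / (2 h^2)). Constants are preserved exactly; as h -> 0 the
#' operator tends to the identity.
#'
#' @param block_expr genes x spots matrix (one gene cluster).
#' @param spots a [spot_set()].
#' @param bandwidth kernel bandwidth h > 0; the default is the median
#'   distance to the 10th nearest neighboring spot — a local neighborhood
#'   scale, so smoothing pools information across adjacent spots without
#'   blurring structures that span only a few spot spacings.
#' @return Smoothed matrix of the same shape.
#' @export
spatial_smooth <- function(block_expr, spots, bandwidth = NULL) {
  spots <- as_spot_set(spots)
  block_expr <- as.matrix(block_expr)
  if (ncol(block_expr) != n_spots(spots))
    stop("block columns must match the spot set")
  d <- pairwise_distances(spots)
  if (is.null(bandwidth)) bandwidth <- local_bandwidth(d)
  if (!is.numeric(bandwidth) || bandwidth <= 0)
    stop("bandwidth must be positive")
  W <- exp(-d^2 / (2 * bandwidth^2))
  W <- W / rowSums(W)
  out <- block_expr %*% t(W)
  dimnames(out) <- dimnames(block_expr)
  out
}

#' Spatial embedding of one gene cluster
#'
#' Smooths the cluster's expression block ([spatial_smooth()]) and takes
#' the top-d principal component scores over spots (genes as variables,
#' gene-centered). A singleton cluster contributes its smoothed, centered
#' gene vector as a one-column block.
#'
#' @param cluster_expr genes x spots matrix for one cluster.
#' @param spots a [spot_set()].
#' @param d number of dimensions to retain; default `min(20, genes - 1)`
#'   (capped at the available rank).
#' @param bandwidth smoothing bandwidth, see [spatial_smooth()].
#' @return N x d score matrix (class `embedding_block`, attribute
#'   `"cluster_id"` settable by the caller), columns ordered by decreasing
#'   explained variance.
#' @export
cluster_embedding <- function(cluster_expr, spots, d = NULL,
                              bandwidth = NULL) {
  cluster_expr <- as.matrix(cluster_expr)
  if (nrow(cluster_expr) == 0L) stop("empty cluster")
  sm <- spatial_smooth(cluster_expr, spots, bandwidth)
  if (nrow(sm) == 1L) {
    block <- matrix(sm[1L, ] - mean(sm[1L, ]), ncol = 1L)
  } else {
    dmax <- min(nrow(sm) - 1L, ncol(sm) - 1L)
    if (is.null(d)) d <- min(20L, dmax)
    d <- min(d, dmax)
    pc <- prcomp(t(sm), center = TRUE, scale. = FALSE)
    block <- pc$x[, seq_len(d), drop = FALSE]
  }
  rownames(block) <- colnames(cluster_expr)
  class(block) <- c("embedding_block", class(block))
  block
}

#' Aggregate per-cluster embedding blocks
#'
#' Column-wise concatenation of the blocks (shared spot order), optionally
#' rescaling each block by the standard deviation of its leading component
#' so every gene cluster enters the aggregate on the same footing
#' (within-block variance ordering is preserved; large clusters otherwise
#' dominate the spot graph simply through their larger score scale).
#'
#' @param blocks list of N x d_i score matrices.
#' @param standardize per-block rescaling by the leading component's sd.
#' @return N x sum(d_i) matrix; attribute `"block_sizes"` records the
#'   boundaries.
#' @export
aggregate_embeddings <- function(blocks, standardize = FALSE) {
  if (length(blocks) == 0L) stop("no embedding blocks to aggregate")
  ns <- vapply(blocks, nrow, 0L)
  if (length(unique(ns)) != 1L)
    stop("embedding blocks disagree on the number of spots")
  blocks <- lapply(blocks, function(b) {
    b <- unclass(b)
    s1 <- sd(b[, 1L])
    if (standardize && s1 > 0) b <- b / s1
    b
  })
  out <- do.call(cbind, blocks)
  colnames(out) <- paste0("dim", seq_len(ncol(out)))
  attr(out, "block_sizes") <- vapply(blocks, ncol, 0L)
  out
}

# median distance to the k-th nearest neighboring spot
local_bandwidth <- function(d, k = 10L) {
  k <- min(k, nrow(d) - 1L)
  median(apply(d, 1L, function(r) sort(r)[k + 1L]))
}

# k nearest neighbors by Euclidean distance (self excluded), brute force;
# ties at the k-th distance broken by index.
knn_index <- function(x, k) {
  d <- as.matrix(dist(x))
  n <- nrow(d)
  k <- min(k, n - 1L)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    cand <- seq_len(n)[-i]
    out[i, ] <- cand[order(d[i, cand])][seq_len(k)]
  }
  out
}

# Shared-nearest-neighbor graph: edge between i and j if either lists the
# other among its k neighbors; weight = Jaccard overlap of neighbor sets
# (including self), zero-weight edges pruned.
snn_graph <- function(x, k) {
  nn <- knn_index(x, k)
  n <- nrow(nn)
  k <- ncol(nn)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                              x = 1, dims = c(n, n))
  diag(adj) <- 1                      # count self in the neighbor sets
  shared <- Matrix::tcrossprod(adj)   # |N(i) & N(j)|
  jac <- shared / (2 * (k + 1) - shared)
  sym <- (adj + Matrix::t(adj)) > 0
  jac <- jac * sym
  diag(jac) <- 0
  jac <- Matrix::drop0(jac)
  igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE,
                                      diag = FALSE)
}

#' Cluster spots into spatial domains
#'
#' Builds a shared-nearest-neighbor graph on the embedding rows and runs a
#' graph community algorithm: `leiden`/`louvain` at a resolution when the
#' number of domains is unknown, or `walktrap` cut at `k_domains` when it
#' is known.
#'
#' @param embedding N x d matrix (rows = spots, in spot order).
#' @param method `"leiden"`, `"louvain"` or `"walktrap"`.
#' @param k_domains target number of domains (required for walktrap;
#'   ignored by leiden/louvain).
#' @param resolution resolution for leiden/louvain (default 1).
#' @param knn neighborhood size of the spot graph (default 10).
#' @param seed RNG seed for the community detection.
#' @return Integer vector of domain labels (1-based, contiguous), class
#'   `domain_labels`, named by the embedding rownames when present.
#' @export
detect_domains <- function(embedding, method = c("leiden", "louvain",
                                                 "walktrap"),
                           k_domains = NULL, resolution = 1, knn = 10L,
                           seed = 1L) {
  method <- match.arg(method)
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (!is.null(k_domains)) {
    if (k_domains > n) stop("k_domains exceeds the number of spots")
    if (k_domains == 1L) {
      labels <- rep(1L, n)
      names(labels) <- rownames(embedding)
      return(structure(labels, class = "domain_labels"))
    }
  }
  if (knn < 1L) stop("knn must be >= 1")
  g <- snn_graph(embedding, knn)
  memb <- switch(method,
    leiden = withr::with_seed(seed,
      igraph::membership(igraph::cluster_leiden(
        g, objective_function = "modularity", resolution = resolution,
        n_iterations = 10L))),
    louvain = withr::with_seed(seed,
      igraph::membership(igraph::cluster_louvain(
        g, resolution = resolution))),
    walktrap = {
      if (is.null(k_domains))
        stop("walktrap needs k_domains")
      wt <- igraph::cluster_walktrap(g)
      tryCatch(igraph::cut_at(wt, no = k_domains),
               error = function(e) igraph::membership(wt))
    })
  labels <- as.integer(factor(as.integer(memb)))
  names(labels) <- rownames(embedding)
  structure(labels, class = "domain_labels")
}

#' Domain detection from aggregated per-cluster embeddings
#'
#' Convenience wrapper: computes one [cluster_embedding()] per gene
#' cluster, aggregates (per-block standardized), and calls
#' [detect_domains()]. Within one coherent pattern group the leading few
#' components carry the group's spatial structure, so the default keeps
#' `d = 5` dimensions per cluster; clusters below `min_cluster_size`
#' genes (by default the singletons, which in noisy data are dominated by
#' single-gene noise and false discoveries) are excluded from the
#' aggregate unless nothing else is available.
#'
#' @param expr genes x spots matrix.
#' @param spots a [spot_set()].
#' @param clusters a `gene_clusters` data.frame ([cluster_genes()]).
#' @param d dimensions per cluster block (default 5, capped at the rank).
#' @param bandwidth smoothing bandwidth.
#' @param min_cluster_size smallest gene-cluster size entering the
#'   aggregate (default 2; ignored when no cluster qualifies).
#' @param standardize per-block rescaling, see [aggregate_embeddings()].
#' @inheritParams detect_domains
#' @return A `domain_labels` vector; the aggregated embedding is attached
#'   as attribute `"embedding"`.
#' @export
domains_from_clusters <- function(expr, spots, clusters, d = 5L,
                                  bandwidth = NULL,
                                  method = c("leiden", "louvain",
                                             "walktrap"),
                                  k_domains = NULL, resolution = 1,
                                  knn = 10L, seed = 1L,
                                  min_cluster_size = 2L,
                                  standardize = TRUE) {
  expr <- as_expression_matrix(expr)
  if (nrow(clusters) == 0L) stop("empty gene clustering")
  sizes <- table(clusters$cluster)
  big <- names(sizes)[sizes >= min_cluster_size]
  keep <- if (length(big)) clusters[clusters$cluster %in% big, ] else clusters
  blocks <- lapply(split(keep$gene_id, keep$cluster, drop = TRUE),
                   function(g) {
    cluster_embedding(expr[g, , drop = FALSE], spots, d, bandwidth)
  })
  emb <- aggregate_embeddings(blocks, standardize = standardize)
  rownames(emb) <- colnames(expr)
  labels <- detect_domains(emb, method, k_domains, resolution, knn, seed)
  attr(labels, "embedding") <- emb
  labels
}

#' Pooled top-SVG baseline for domain detection
#'
#' The comparison baseline: a single embedding from the pooled top SVGs
#' (ranked by combined p-value), then [detect_domains()] — i.e. domain
#' detection without the gene clustering step.
#'
#' @param expr genes x spots matrix.
#' @param spots a [spot_set()].
#' @param svg_result a [detect_svgs()] result.
#' @param n_top number of top SVGs to pool (default 3000, capped at the
#'   available SVGs).
#' @param d embedding dimensions (default 20, capped at the rank).
#' @param bandwidth smoothing bandwidth.
#' @inheritParams detect_domains
#' @return A `domain_labels` vector with attribute `"embedding"`.
#' @export
pooled_baseline <- function(expr, spots, svg_result, n_top = 3000L,
                            d = 20L, bandwidth = NULL,
                            method = c("leiden", "louvain", "walktrap"),
                            k_domains = NULL, resolution = 1, knn = 10L,
                            seed = 1L) {
  expr <- as_expression_matrix(expr)
  svgs <- svg_result[svg_result$is_svg, ]
  if (nrow(svgs) == 0L) stop("no SVGs available for the pooled baseline")
  top <- svgs$gene_id[order(svgs$p_combined)][seq_len(min(n_top, nrow(svgs)))]
  emb <- cluster_embedding(expr[top, , drop = FALSE], spots, d, bandwidth)
  rownames(emb) <- colnames(expr)
  labels <- detect_domains(emb, method, k_domains, resolution, knn, seed)
  attr(labels, "embedding") <- unclass(emb)
  labels
}
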