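#' Kernel specification
#'
#' A kernel spec names one member of the spatial kernel bank: a family
#' (`gaussian` or `cosine`) plus a positive length-scale parameter, the
#' Gaussian bandwidth l or the Cosine period phi (same units as the spot
#' coordinates).
#'
#' @param family `"gaussian"` or `"cosine"`.
#' @param scale positive length parameter.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("gaussian", "cosine"), scale) {
  family <- match.arg(family)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0)
    stop("kernel scale must be a single positive number")
  structure(list(family = family, scale = as.numeric(scale)),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("kernel_spec: %s(scale = %.4g)\n", x$family, x$scale))
  invisible(x)
}

#' Build a kernel matrix from pairwise distances
#'
#' Gaussian: K(d) = exp(-d^2 / (2 l^2)); Cosine: K(d) = cos(2 pi d / phi).
#' Both give unit diagonal. Gaussian kernels are positive semidefinite;
#' Cosine kernels need not be (the score test accepts signed spectra).
#'
#' @param distances symmetric distance matrix from [pairwise_distances()].
#' @param spec a [kernel_spec()].
#' @return Kernel matrix with the spec attached as attribute `"spec"`.
#' @export
build_kernel <- function(distances, spec) {
  if (!inherits(spec, "kernel_spec")) stop("spec must be a kernel_spec")
  distances <- as.matrix(distances)
  K <- switch(spec$family,
    gaussian = exp(-distances^2 / (2 * spec$scale^2)),
    cosine   = cos(2 * pi * distances / spec$scale))
  attr(K, "spec") <- spec
  K
}

#' Default 10-kernel bank
#'
#' Five Gaussian bandwidths and five Cosine periods, both set to the
#' `quantiles` of the nonzero pairwise distance distribution. The
#' data-adaptive scales span smooth (large scale) to fine (small scale)
#' spatial patterns and are reproducible from the coordinates alone.
#'
#' @param distances distance matrix (or a `spot_set`, in which case
#'   distances are computed).
#' @param quantiles probabilities of the nonzero-distance quantiles used as
#'   scales for both families.
#' @return An object of class `kernel_bank`: a list of [kernel_spec()]s,
#'   Gaussian first, scales strictly increasing within each family.
#' @export
default_kernel_bank <- function(distances,
                                quantiles = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  if (inherits(distances, "spot_set"))
    distances <- pairwise_distances(distances)
  dvec <- distances[upper.tri(distances)]
  dvec <- dvec[dvec > 0]
  if (length(dvec) == 0L)
    stop("all pairwise distances are zero; cannot set kernel scales")
  scales <- unname(quantile(dvec, quantiles, names = FALSE))
  scales <- sort(unique(scales))
  if (length(scales) < length(quantiles))
    stop("degenerate geometry: distance quantiles are not distinct")
  specs <- c(lapply(scales, function(s) kernel_spec("gaussian", s)),
             lapply(scales, function(s) kernel_spec("cosine", s)))
  structure(specs, class = "kernel_bank")
}

#' @export
print.kernel_bank <- function(x, ...) {
  cat("kernel_bank with", length(x), "kernels:\n")
  for (s in x) cat(sprintf("  %s(%.4g)\n", s$family, s$scale))
  invisible(x)
}

kernel_names <- function(bank) {
  vapply(bank, function(s) sprintf("%s_%.4g", s$family, s$scale), "")
}

# Truncated eigenbasis of one kernel matrix: keeps the leading eigenpairs
# (by |lambda|) holding all but `rank_tol` of the total |lambda| mass.
# With rank_tol ~ 1e-8 this reproduces quadratic forms in K to the same
# relative accuracy while the retained rank on smooth 2-D geometries is far
# below N.
kernel_basis <- function(K, rank_tol = 1e-8) {
  eig <- eigen(K, symmetric = TRUE)
  ord <- order(abs(eig$values), decreasing = TRUE)
  lam <- eig$values[ord]
  mass <- cumsum(abs(lam)) / sum(abs(lam))
  r <- which(mass >= 1 - rank_tol)[1L]
  if (is.na(r)) r <- length(lam)
  idx <- ord[seq_len(r)]
  list(values = eig$values[idx],
       vectors = eig$vectors[, idx, drop = FALSE],
       spec = attr(K, "spec"),
       trace = sum(diag(K)))
}

# Drop basis components whose |eigenvalue| is negligible relative to the
# largest. Callers prune the SAME basis for the statistic and its null
# spectrum, so the test stays exact for the pruned kernel; the pruned and
# unpruned kernels differ by a relative spectral mass of order tol * rank.
prune_basis <- function(basis, tol = 1e-5) {
  keep <- abs(basis$values) >= tol * max(abs(basis$values))
  if (all(keep)) return(basis)
  basis$values <- basis$values[keep]
  basis$vectors <- basis$vectors[, keep, drop = FALSE]
  basis
}

#' Precompute the kernel context for a spot geometry
#'
#' Builds (or accepts) the kernel bank for a spot set and caches a
#' truncated eigendecomposition of every kernel. The context is the
#' workhorse shared by [detect_svgs()] and the adjusted retests in
#' [svg_pipeline()]: null spectra for any covariate design are derived from
#' the cached bases without touching the N x N kernels again.
#'
#' @param spots a [spot_set()].
#' @param bank a `kernel_bank`, or `NULL` for [default_kernel_bank()].
#' @param rank_tol relative spectral-mass tolerance of the truncated
#'   eigenbasis (see Details in the package vignette).
#' @return An object of class `kernel_context`.
#' @export
kernel_context <- function(spots, bank = NULL, rank_tol = 1e-8) {
  spots <- as_spot_set(spots)
  d <- pairwise_distances(spots)
  if (is.null(bank)) bank <- default_kernel_bank(d)
  bases <- lapply(bank, function(spec) {
    kernel_basis(build_kernel(d, spec), rank_tol = rank_tol)
  })
  names(bases) <- kernel_names(bank)
  structure(list(spots = spots, bank = bank, bases = bases,
                 rank_tol = rank_tol),
            class = "kernel_context")
}

#' @export
print.kernel_context <- function(x, ...) {
  cat("kernel_context:", n_spots(x$spots), "spots,",
      length(x$bank), "kernels, retained ranks",
      paste(vapply(x$bases, function(b) length(b$values), 0L),
            collapse = "/"), "\n")
  invisible(x)
}
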