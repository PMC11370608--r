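# Simulation generators: a 53-gene correlated-module design on random
# spots (pattern-group power/FDR/ARI study), a layered cortex-like tissue
# with three domain-specific SVG clusters, and pure-null calibration data.

#' Six canonical spatial pattern surfaces
#'
#' Deterministic surfaces on the unit square, standardized to mean 0 and
#' sd 1 over the supplied spots: (1) Gaussian hotspot at (0.3, 0.3);
#' (2) linear gradient along x; (3) diagonal streak; (4) annulus around
#' the center; (5) two opposing hotspots; (6) periodic stripes along y.
#' The six surfaces are pairwise distinguishable (absolute correlation
#' below 0.5 on dense spot sets).
#'
#' @param coords N x 2 coordinate matrix in the unit square.
#' @return N x 6 matrix, columns `pattern1..pattern6`.
#' @export
spatial_patterns <- function(coords) {
  x <- coords[, 1L]; y <- coords[, 2L]
  p <- cbind(
    pattern1 = exp(-((x - 0.3)^2 + (y - 0.3)^2) / (2 * 0.12^2)),
    pattern2 = x,
    pattern3 = exp(-((x - y)^2 / 2) / (2 * 0.08^2)),
    pattern4 = exp(-(sqrt((x - 0.5)^2 + (y - 0.5)^2) - 0.35)^2 /
                     (2 * 0.06^2)),
    pattern5 = exp(-((x - 0.15)^2 + (y - 0.85)^2) / (2 * 0.1^2)) +
               exp(-((x - 0.85)^2 + (y - 0.15)^2) / (2 * 0.1^2)),
    pattern6 = cos(2 * pi * y / 0.45))
  scale(p)
}

# within-group gene-gene correlation matrix
group_correlation <- function(p, structure, rho) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  switch(structure,
    cs  = { m <- matrix(rho, p, p); diag(m) <- 1; m },
    ar1 = rho^abs(outer(seq_len(p), seq_len(p), "-")),
    stop("unknown correlation structure: ", structure))
}

# n x p draws from N(0, sd^2 * R)
rmvn_rows <- function(n, R, sd = 1) {
  L <- chol(R)
  (matrix(rnorm(n * ncol(R)), n) %*% L) * sd
}

#' Simulate the 53-gene pattern-group design
#'
#' Generates 53 genes over `n_spots` spots uniform on the unit square:
#' g1-g10 independent noise; g11-g20 correlated (CS or AR(1), parameter
#' `rho`) non-spatial noise; g21-g30, g31-g40, g41-g50 three
#' correlated-noise groups with spatial means `s_g * f_p(coords)` for
#' patterns 1-3, the effect strength `s_g` increasing linearly across each
#' group; g51-g53 single genes with the unique patterns 4-6. Each gene is
#' standardized across spots.
#'
#' @param seed RNG seed; identical arguments give bit-identical output.
#' @param n_spots number of spots (>= 100; default 2000).
#' @param structure within-group correlation structure, `"cs"` or
#'   `"ar1"`.
#' @param rho within-group correlation parameter in \[0, 1).
#' @param strength spatial-effect strengths across the 10 members of each
#'   pattern group, as multiples of the noise sd.
#' @param single_strength effect strength of the three unique-pattern
#'   genes.
#' @param spots optional [spot_set()] to reuse (shares coordinates — and
#'   cached kernel spectra — across replicates; replicate randomness then
#'   enters only through the expression noise).
#' @return list with elements `expr` (53 x N matrix, rownames g1..g53),
#'   `spots`, and `truth` (data.frame `gene_id`, `role`, `group` where
#'   `group` is NA for non-spatial genes, 1-3 for the pattern groups and
#'   4-6 for the unique genes).
#' @export
simulate_scenario_one <- function(seed = 1L, n_spots = 2000L,
                                  structure = c("cs", "ar1"), rho = 0.6,
                                  strength = seq(0.25, 1.5,
                                                 length.out = 10L),
                                  single_strength = 1,
                                  spots = NULL) {
  structure <- match.arg(structure)
  if (n_spots < 100L) stop("n_spots must be at least 100")
  if (length(strength) != 10L) stop("strength grid must have 10 entries")
  withr::with_seed(seed, {
    if (is.null(spots)) {
      coords <- cbind(runif(n_spots), runif(n_spots))
      spots <- spot_set(sprintf("s%04d", seq_len(n_spots)), coords)
    }
    n <- n_spots(spots)
    pat <- spatial_patterns(spots$coords)
    R <- group_correlation(10L, structure, rho)
    expr <- matrix(NA_real_, 53L, n,
                   dimnames = list(paste0("g", 1:53), spots$spot_ids))
    expr[1:10, ] <- t(matrix(rnorm(n * 10L), n))
    expr[11:20, ] <- t(rmvn_rows(n, R))
    for (grp in 1:3) {
      rows <- 20L + (grp - 1L) * 10L + (1:10)
      noise <- rmvn_rows(n, R)
      means <- outer(pat[, grp], strength)
      expr[rows, ] <- t(means + noise)
    }
    for (k in 1:3)
      expr[50L + k, ] <- single_strength * pat[, 3L + k] + rnorm(n)
    expr <- t(scale(t(expr)))
  })
  truth <- data.frame(
    gene_id = paste0("g", 1:53),
    role = rep(c("independent", "correlated", "pattern1", "pattern2",
                 "pattern3", "pattern4", "pattern5", "pattern6"),
               c(10, 10, 10, 10, 10, 1, 1, 1)),
    group = c(rep(NA_integer_, 20L), rep(1:3, each = 10L), 4L, 5L, 6L),
    is_svg = rep(c(FALSE, TRUE), c(20L, 33L)))
  list(expr = expr, spots = spots, truth = truth)
}

# sinusoidally perturbed horizontal layer boundaries; returns layer index
# per spot, 1 (top cortex band) .. length(widths) (bottom band)
layer_assign <- function(coords, widths, amp = 0.03, freq = 1.5) {
  bounds <- 1 - cumsum(widths)[-length(widths)]
  x <- coords[, 1L]; y <- coords[, 2L]
  wave <- amp * sin(2 * pi * freq * x)
  below <- vapply(bounds, function(b) y < b + wave, logical(length(x)))
  as.integer(1L + rowSums(below))
}

#' Simulate a layered cortex-like tissue
#'
#' Spots on a grid covering the unit square are partitioned into 5
#' parallel, sinusoidally curved strata (4 cortex-like layers over one
#' white-matter-like band, relative widths 0.25/0.15/0.15/0.15/0.30).
#' A random subset of genes becomes domain-specific SVGs in three
#' clusters: cluster 1 elevated in layer 1; cluster 2 elevated across
#' layers 2-4 with a random primary layer carrying the full effect and the
#' other two layers half of it; cluster 3 elevated in the white-matter
#' band. Remaining genes are pure noise. Per-gene baseline means and noise
#' variances are sampled from log-normal distributions to emulate the
#' spread seen in filtered cortex data, and each SVG cluster shares a
#' non-spatial latent factor so that within-cluster gene correlations
#' resemble co-regulated marker genes.
#'
#' @param seed RNG seed.
#' @param n_genes total genes (default 4865).
#' @param n_spots number of grid spots (default 3484).
#' @param svg_counts genes per SVG cluster (default `c(800, 150, 1050)`).
#' @param effect_range uniform range of the SVG effect size in noise-sd
#'   units.
#' @param factor_loading loading of the shared within-cluster latent
#'   factor, in noise-sd units.
#' @param widths relative widths of the 5 strata (top to bottom).
#' @return list with `expr` (n_genes x n_spots), `spots`, and `truth`
#'   (list: `genes` data.frame with `gene_id`, `cluster` (1-3 or NA),
#'   `is_svg`; `domains` integer layer label per spot, 1-5 with 5 = white
#'   matter).
#' @export
simulate_layered <- function(seed = 1L, n_genes = 4865L, n_spots = 3484L,
                             svg_counts = c(800L, 150L, 1050L),
                             effect_range = c(2, 3.5),
                             factor_loading = 0.6,
                             widths = c(0.25, 0.15, 0.15, 0.15, 0.30)) {
  if (sum(svg_counts) > n_genes)
    stop("svg_counts exceed the number of genes")
  withr::with_seed(seed, {
    nx <- ceiling(sqrt(n_spots))
    ny <- ceiling(n_spots / nx)
    gx <- (rep(seq_len(nx), ny)[seq_len(n_spots)] - 0.5) / nx
    gy <- (rep(seq_len(ny), each = nx)[seq_len(n_spots)] - 0.5) / ny
    spots <- spot_set(sprintf("s%05d", seq_len(n_spots)), cbind(gx, gy))
    domains <- layer_assign(spots$coords, widths)

    gene_ids <- sprintf("gene%05d", seq_len(n_genes))
    svg_idx <- sample(n_genes, sum(svg_counts))
    cluster <- rep(NA_integer_, n_genes)
    cluster[svg_idx] <- rep(1:3, svg_counts)

    mu <- rlnorm(n_genes, meanlog = 0, sdlog = 0.6)
    sigma <- rlnorm(n_genes, meanlog = log(0.8), sdlog = 0.4)
    effect <- runif(n_genes, effect_range[1L], effect_range[2L])

    # domain indicator profile per cluster
    n <- n_spots
    in_l1 <- as.numeric(domains == 1L)
    in_wm <- as.numeric(domains == 5L)
    latent <- matrix(rnorm(3L * n), 3L)   # shared per-cluster factors

    expr <- matrix(rnorm(n_genes * n), n_genes) * sigma + mu
    rownames(expr) <- gene_ids
    colnames(expr) <- spots$spot_ids
    for (g in which(!is.na(cluster))) {
      cl <- cluster[g]
      prof <- switch(cl,
        in_l1,
        { primary <- sample(2:4, 1L)
          as.numeric(domains == primary) +
            0.5 * as.numeric(domains %in% setdiff(2:4, primary)) },
        in_wm)
      expr[g, ] <- expr[g, ] + effect[g] * sigma[g] * prof +
        factor_loading * sigma[g] * latent[cl, ]
    }
  })
  truth <- list(genes = data.frame(gene_id = gene_ids, cluster = cluster,
                                   is_svg = !is.na(cluster)),
                domains = domains)
  list(expr = expr, spots = spots, truth = truth)
}

#' Simulate pure-null expression
#'
#' i.i.d. standard normal expression with no spatial structure, for
#' type-I-error calibration.
#'
#' @param seed RNG seed.
#' @param n_genes,n_spots dimensions (both >= 2).
#' @return list with `expr`, `spots` (uniform on the unit square), and
#'   `truth` marking every gene non-spatial.
#' @export
simulate_null <- function(seed = 1L, n_genes = 500L, n_spots = 400L) {
  if (n_genes < 2L || n_spots < 2L) stop("need at least 2 genes and spots")
  withr::with_seed(seed, {
    coords <- cbind(runif(n_spots), runif(n_spots))
    spots <- spot_set(sprintf("s%04d", seq_len(n_spots)), coords)
    expr <- matrix(rnorm(n_genes * n_spots), n_genes,
                   dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                   spots$spot_ids))
  })
  truth <- data.frame(gene_id = rownames(expr), role = "independent",
                      is_svg = FALSE)
  list(expr = expr, spots = spots, truth = truth)
}
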