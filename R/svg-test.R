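# Step 1: per-gene variance-component score test of H0: sigma_s^2 = 0 in
# y ~ MVN(X beta, sigma_s^2 K + delta I), run over the kernel bank,
# Cauchy-combined across kernels and BH-selected across genes.

#' Fit the null (non-spatial) model for one gene
#'
#' Ordinary least squares of the expression vector on the covariate design
#' (by default the intercept alone). The residual variance uses the
#' unbiased divisor N - k so the identity-kernel score statistic is exact.
#'
#' @param y numeric expression vector over spots.
#' @param design N x k covariate matrix including the intercept; `NULL`
#'   means intercept only.
#' @return An object of class `null_fit` with elements `design`,
#'   `coefficients`, `residuals`, `residual_variance`, `rank` and a
#'   `degenerate` flag (TRUE when y is constant given the design; such
#'   genes are skipped with p = 1).
#' @export
fit_null <- function(y, design = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(design)) design <- matrix(1, n, 1L)
  design <- as.matrix(design)
  if (nrow(design) != n) stop("design rows must match length(y)")
  k <- ncol(design)
  if (n <= k) stop("need more spots than covariates")
  qrx <- qr(design)
  if (qrx$rank < k) stop("rank-deficient design")
  res <- qr.resid(qrx, y)
  s2 <- sum(res^2) / (n - k)
  degenerate <- s2 <= .Machine$double.eps * max(mean(y^2), 1)
  structure(list(design = design, qr = qrx,
                 coefficients = qr.coef(qrx, y),
                 residuals = res, residual_variance = s2,
                 rank = k, degenerate = degenerate),
            class = "null_fit")
}

#' Null spectrum of a kernel under a covariate design
#'
#' Eigenvalues (descending) of P0 K P0, where P0 projects off the design
#' column space. Under H0 the score statistic r' K r / delta-hat is
#' distributed as the weighted chi-square sum with these weights.
#'
#' @param K symmetric kernel matrix.
#' @param design N x k covariate design (full column rank); `NULL` for
#'   intercept only.
#' @return An object of class `kernel_spectrum` with element `values`.
#' @export
kernel_spectrum <- function(K, design = NULL) {
  K <- as.matrix(K)
  n <- nrow(K)
  if (!isSymmetric(unname(K), tol = 1e-8)) stop("K must be symmetric")
  if (is.null(design)) design <- matrix(1, n, 1L)
  design <- as.matrix(design)
  qrx <- qr(design)
  if (qrx$rank < ncol(design)) stop("rank-deficient design")
  Q <- qr.Q(qrx)
  M <- K - Q %*% crossprod(Q, K)
  M <- M - (M %*% Q) %*% t(Q)
  M <- (M + t(M)) / 2
  vals <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  structure(list(values = vals, rank = qrx$rank), class = "kernel_spectrum")
}

# Same spectrum from a cached truncated kernel eigenbasis: the nonzero
# eigenvalues of P0 K P0 equal those of G^{1/2} Lambda G^{1/2} with
# G = I - W W', W = U' Q, Q an orthonormal design basis. Exact for the
# retained rank; agrees with kernel_spectrum() to the basis tolerance.
spectrum_from_basis <- function(basis, Q) {
  lam <- basis$values
  W <- crossprod(basis$vectors, Q)
  sv <- svd(W, nu = ncol(W), nv = 0)
  d2 <- pmin(sv$d^2, 1)
  shrink <- 1 - sqrt(1 - d2)
  # G^{1/2} = I - P diag(shrink) P'
  B <- -sv$u %*% (shrink * t(sv$u))
  diag(B) <- diag(B) + 1
  M <- B %*% (lam * B)
  M <- (M + t(M)) / 2
  eigen(M, symmetric = TRUE, only.values = TRUE)$values
}

#' Variance-component score test for one gene and one kernel
#'
#' Statistic T = r' K r / delta-hat with r the null-model residuals;
#' p-value from the weighted chi-square tail with the null spectrum of
#' P0 K P0 (see [davies_tail()]).
#'
#' @param y expression vector (used only for degenerate handling).
#' @param nullfit a [fit_null()] result.
#' @param K kernel matrix.
#' @param spectrum matching [kernel_spectrum()]; computed from `K` and the
#'   null design when omitted.
#' @return list with elements `statistic` and `p`.
#' @export
score_test <- function(y, nullfit, K, spectrum = NULL) {
  if (!inherits(nullfit, "null_fit")) stop("nullfit must be a null_fit")
  if (nullfit$degenerate) {
    warning("degenerate null fit (zero residual variance); p = 1")
    return(list(statistic = NA_real_, p = 1))
  }
  if (is.null(spectrum)) spectrum <- kernel_spectrum(K, nullfit$design)
  r <- nullfit$residuals
  stat <- drop(crossprod(r, K %*% r)) / nullfit$residual_variance
  list(statistic = stat, p = davies_tail(stat, spectrum$values))
}

# Vectorized score tests over genes for one cached kernel basis.
# R: N x m matrix of null residuals; s2: per-gene residual variances.
score_tests_basis <- function(basis, spec_values, R, s2) {
  Ur <- crossprod(basis$vectors, R)              # r x m
  stats <- colSums(basis$values * Ur^2) / s2
  lam <- spec_values[abs(spec_values) > max(abs(spec_values)) * 1e-14]
  p_liu <- vapply(stats, liu_tail, 0, lam = lam)
  p <- p_liu
  # moment-matched screen only beyond the inversion's resolution; all
  # decision-relevant probabilities go through the exact inversion
  todo <- which(is.na(p_liu) | p_liu >= 1e-9)
  if (length(todo)) {
    pg <- imhof_tail_many(stats[todo], lam)
    ref <- p_liu[todo]
    bad <- which(is.na(pg) | pg < 1e-8 | pg > 1 + 1e-6 |
                   (!is.na(ref) & abs(pg - ref) > 0.1))
    pg[bad] <- vapply(stats[todo][bad], davies_tail, 0,
                      weights = spec_values)
    p[todo] <- pg
  }
  list(statistic = stats, p = vapply(p, clamp_p, 0))
}

#' Detect spatially variable genes
#'
#' Runs the multi-kernel score test for every gene: per-kernel p-values,
#' equal-weight Cauchy combination, and Benjamini-Hochberg q-values across
#' genes at FDR level `alpha`. Constant genes are dropped with a warning
#' before testing.
#'
#' @param expr genes x spots matrix of normalized expression, rownames =
#'   gene ids, columns in spot order.
#' @param spots a [spot_set()] or a precomputed [kernel_context()].
#' @param bank optional `kernel_bank` (ignored when `spots` is already a
#'   context); default [default_kernel_bank()].
#' @param alpha FDR level for the SVG call (default 0.05).
#' @param design optional covariate matrix including intercept; default
#'   intercept only.
#' @param rank_tol spectral tolerance passed to [kernel_context()].
#' @return An object of class `svg_test`: a data.frame with columns
#'   `gene_id`, `p_kernel_1..10`, `p_combined`, `q_value`, `is_svg`, with
#'   attributes `m1` (number of SVGs), `alpha`, and `context` (the kernel
#'   context, reusable by [svg_pipeline()]).
#' @export
detect_svgs <- function(expr, spots, bank = NULL, alpha = 0.05,
                        design = NULL, rank_tol = 1e-8) {
  expr <- as_expression_matrix(expr)
  ctx <- if (inherits(spots, "kernel_context")) spots
         else kernel_context(spots, bank, rank_tol)
  if (ncol(expr) != n_spots(ctx$spots))
    stop("expression columns do not match the spot set")
  n <- ncol(expr)
  keep <- apply(expr, 1L, function(v) sd(v) > 0)
  if (!all(keep)) {
    warning(sum(!keep), " constant gene(s) dropped before testing")
    expr <- expr[keep, , drop = FALSE]
  }
  if (nrow(expr) == 0L) stop("no non-constant genes to test")
  if (is.null(design)) design <- matrix(1, n, 1L)
  design <- as.matrix(design)

  qrx <- qr(design)
  if (qrx$rank < ncol(design)) stop("rank-deficient design")
  Q <- qr.Q(qrx)
  R <- t(expr) - Q %*% crossprod(Q, t(expr))   # N x m residuals
  s2 <- colSums(R^2) / (n - qrx$rank)

  nk <- length(ctx$bases)
  pk <- matrix(NA_real_, nrow(expr), nk,
               dimnames = list(rownames(expr), paste0("p_kernel_", seq_len(nk))))
  for (i in seq_len(nk)) {
    b <- prune_basis(ctx$bases[[i]])
    spec_values <- spectrum_from_basis(b, Q)
    pk[, i] <- score_tests_basis(b, spec_values, R, s2)$p
  }
  p_comb <- apply(pk, 1L, cauchy_combine)
  q <- p.adjust(p_comb, method = "BH")
  out <- data.frame(gene_id = rownames(expr), pk, p_combined = p_comb,
                    q_value = q, is_svg = q <= alpha,
                    row.names = NULL, check.names = FALSE)
  structure(out, class = c("svg_test", "data.frame"),
            m1 = sum(out$is_svg), alpha = alpha, context = ctx)
}

#' @export
print.svg_test <- function(x, ...) {
  cat("svg_test:", nrow(x), "genes tested,", attr(x, "m1"),
      "SVGs at FDR", attr(x, "alpha"), "\n")
  print(head(as.data.frame(x)[, c("gene_id", "p_combined", "q_value",
                                  "is_svg")]), ...)
  invisible(x)
}

#' Write an SVG test result to TSV
#'
#' @param x an `svg_test` object.
#' @param path output path.
#' @param header_lines optional `#`-prefixed header lines.
#' @export
write_svg_test <- function(x, path, header_lines = NULL) {
  write_tsv(as.data.frame(x), path, header_lines)
}
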