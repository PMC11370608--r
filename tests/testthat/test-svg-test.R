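test_that("fit_null matches the normal equations", {
  withr::with_seed(11, {
    y <- rnorm(50)
    nf <- fit_null(y)
    expect_equal(unname(nf$coefficients), mean(y))
    expect_lt(abs(sum(nf$residuals)), 1e-10)
    expect_equal(nf$residual_variance, var(y), tolerance = 1e-12)

    X <- cbind(1, rnorm(50), runif(50))
    y2 <- rnorm(50)
    nf2 <- fit_null(y2, X)
    beta <- solve(crossprod(X), crossprod(X, y2))
    expect_equal(unname(nf2$coefficients), drop(beta), tolerance = 1e-10)
    expect_lt(max(abs(crossprod(X, nf2$residuals))), 1e-8 * 50)
    expect_equal(nf2$residual_variance,
                 sum(nf2$residuals^2) / (50 - 3), tolerance = 1e-12)
  })
  # constant gene is degenerate
  nf3 <- fit_null(rep(2, 20))
  expect_true(nf3$degenerate)
  expect_error(fit_null(rnorm(10), cbind(1, rep(1, 10))), "rank")
})

test_that("kernel spectra follow projection identities", {
  n <- 40
  I_spec <- kernel_spectrum(diag(n))
  expect_equal(sort(I_spec$values, decreasing = TRUE),
               c(rep(1, n - 1), 0), tolerance = 1e-10)
  ones <- matrix(1, n, n)
  expect_lt(max(abs(kernel_spectrum(ones)$values)), 1e-8)
  # trace identity on a random PSD kernel with a random design
  withr::with_seed(13, {
    A <- matrix(rnorm(30 * 30), 30)
    K <- crossprod(A) / 30
    X <- cbind(1, rnorm(30))
    spec <- kernel_spectrum(K, X)
    Q <- qr.Q(qr(X))
    P0K <- K - Q %*% crossprod(Q, K)
    expect_equal(sum(spec$values), sum(diag(P0K)), tolerance = 1e-6)
  })
  expect_error(kernel_spectrum(matrix(rnorm(9), 3)), "symmetric")
})

test_that("low-rank spectrum path matches the direct computation", {
  sp <- random_spots(70, seed = 17)
  ctx <- kernel_context(sp, rank_tol = 1e-14)
  d <- pairwise_distances(sp)
  withr::with_seed(18, X <- cbind(1, rnorm(70), runif(70)))
  Q <- qr.Q(qr(X))
  for (i in c(2, 7, 10)) {
    K <- build_kernel(d, ctx$bank[[i]])
    direct <- kernel_spectrum(K, X)$values
    fast <- svgclust:::spectrum_from_basis(ctx$bases[[i]], Q)
    k <- min(length(fast), 40)
    expect_equal(sort(fast, decreasing = TRUE)[1:k],
                 sort(direct, decreasing = TRUE)[1:k], tolerance = 1e-8)
  }
})

test_that("identity-kernel score test is exact", {
  withr::with_seed(19, y <- rnorm(100))
  nf <- fit_null(y)
  st <- score_test(y, nf, diag(100))
  expect_equal(st$statistic, 99, tolerance = 1e-10)
  expect_equal(st$p, pchisq(99, df = 99, lower.tail = FALSE),
               tolerance = 1e-4)
  # degenerate gene: p = 1 with a warning
  nfd <- fit_null(rep(1, 30))
  expect_warning(std <- score_test(rep(1, 30), nfd, diag(30)), "degenerate")
  expect_equal(std$p, 1)
})

test_that("per-kernel p-values are uniform under the null", {
  n <- 200
  sp <- random_spots(n, seed = 23)
  d <- pairwise_distances(sp)
  K <- build_kernel(d, kernel_spec("gaussian", 0.3))
  spec <- kernel_spectrum(K)
  withr::with_seed(29, {
    pvals <- vapply(seq_len(2000), function(i) {
      y <- rnorm(n)
      score_test(y, fit_null(y), K, spec)$p
    }, 0)
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 1.36 / sqrt(2000))   # 0.05 critical value
})

test_that("detect_svgs flags extreme spatial signal and not pure noise", {
  n <- 300
  sp <- random_spots(n, seed = 41)
  bump <- exp(-((sp$coords[, 1] - 0.4)^2 + (sp$coords[, 2] - 0.6)^2) /
                (2 * 0.15^2))
  withr::with_seed(42, {
    expr <- rbind(signal = bump + rnorm(n, sd = 0.05),
                  noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  })
  res <- detect_svgs(expr, sp)
  expect_s3_class(res, "svg_test")
  expect_true(res$is_svg[res$gene_id == "signal"])
  expect_lt(res$q_value[res$gene_id == "signal"], 1e-10)
  expect_true(all(res$q_value >= res$p_combined - 1e-12))
  expect_equal(attr(res, "m1"), sum(res$is_svg))

  # constant genes are dropped, empty input errors
  expr2 <- rbind(expr, flat = rep(1, n))
  expect_warning(res2 <- detect_svgs(expr2, sp), "constant")
  expect_equal(nrow(res2), 4L)
  expect_error(suppressWarnings(detect_svgs(matrix(1, 2, n), sp)),
               "no non-constant")
})

test_that("cached spectra equal per-gene recomputation", {
  sp <- random_spots(50, seed = 43)
  withr::with_seed(44, expr <- matrix(rnorm(3 * 50), 3,
                                      dimnames = list(paste0("g", 1:3))))
  ctx <- kernel_context(sp, rank_tol = 1e-14)
  res <- detect_svgs(expr, ctx)
  d <- pairwise_distances(sp)
  for (g in 1:3) {
    nf <- fit_null(expr[g, ])
    for (i in c(1, 8)) {
      K <- build_kernel(d, ctx$bank[[i]])
      st <- score_test(expr[g, ], nf, K)
      expect_equal(res[g, 1 + i], st$p, tolerance = 1e-4,
                   ignore_attr = TRUE)
    }
  }
})
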