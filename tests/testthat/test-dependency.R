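test_that("correlated sets select by absolute correlation and exclude self", {
  n <- 200
  withr::with_seed(51, {
    base <- rnorm(n)
    expr <- rbind(g1 = base + rnorm(n, sd = 0.1),
                  g2 = base + rnorm(n, sd = 0.1),      # near-duplicate of g1
                  g3 = -base + rnorm(n, sd = 0.1),     # anti-correlated
                  g4 = rnorm(n))
  })
  ids <- rownames(expr)
  s1 <- correlated_set(expr, "g1", ids, threshold = 0.5)
  expect_true(all(c("g2", "g3") %in% s1))
  expect_false("g1" %in% s1)
  expect_false("g4" %in% s1)
  # an exact duplicate is always selected
  expr2 <- rbind(expr, g5 = expr["g1", ])
  expect_true("g5" %in% correlated_set(expr2, "g1", rownames(expr2),
                                       threshold = 0.99))
  # zero-variance genes are excluded with a warning
  expr3 <- rbind(expr, flat = rep(1, n))
  expect_warning(s3 <- correlated_set(expr3, "g1", rownames(expr3)),
                 "zero-variance")
  expect_false("flat" %in% s3)
  expect_error(correlated_set(expr, "nope", ids), "not among")
})

test_that("correlated sets recover the simulated gene groups", {
  sim <- simulate_scenario_one(seed = 61, structure = "cs", rho = 0.6)
  ids <- paste0("g", 21:53)
  s21 <- correlated_set(sim$expr, "g21", ids, threshold = 0.3)
  expect_true(all(paste0("g", 22:30) %in% s21))
  expect_false(any(paste0("g", 31:40) %in% s21))
  # symmetry of the selection relation
  expect_true("g21" %in% correlated_set(sim$expr, "g22", ids,
                                        threshold = 0.3))
})

test_that("adjustment covariates follow the more-than-3 PC rule", {
  n <- 100
  withr::with_seed(53, {
    expr_small <- matrix(rnorm(2 * n), 2, dimnames = list(c("a", "b")))
    covs <- adjustment_covariates(expr_small, c("a", "b"))
    expect_equal(ncol(covs), 2L)
    expect_lt(max(abs(colMeans(covs))), 1e-12)   # centered member genes
    expect_equal(unname(covs[, 1]), unname(expr_small["a", ] -
                                             mean(expr_small["a", ])))
  })
  # 5 identical genes: first PC explains everything
  one <- rnorm(n)
  expr_dup <- matrix(rep(one, 5), 5, byrow = TRUE,
                     dimnames = list(paste0("d", 1:5)))
  covs_dup <- adjustment_covariates(expr_dup, paste0("d", 1:5))
  expect_equal(attr(covs_dup, "kj"), 1L)
  # engineered variance shares (0.5, 0.25, 0.15, 0.10): 80% needs 3 PCs
  withr::with_seed(54, {
    U <- qr.Q(qr(cbind(1, matrix(rnorm(n * 4), n))))[, 2:5]
    V <- qr.Q(qr(matrix(rnorm(16), 4)))
    X <- U %*% diag(sqrt(c(0.5, 0.25, 0.15, 0.10))) %*% t(V)
  })
  expr_sh <- t(X); rownames(expr_sh) <- paste0("s", 1:4)
  covs_sh <- adjustment_covariates(expr_sh, paste0("s", 1:4))
  expect_equal(attr(covs_sh, "kj"), 3L)
  expect_error(adjustment_covariates(expr_dup, character()), "empty")
})

test_that("adjusted test detects leftover signal and full explanation", {
  n <- 400
  sp <- random_spots(n, seed = 55)
  ctx <- kernel_context(sp)
  f <- exp(-((sp$coords[, 1] - 0.5)^2 + (sp$coords[, 2] - 0.5)^2) /
             (2 * 0.2^2))
  f <- (f - mean(f)) / sd(f)
  withr::with_seed(56, {
    covs <- cbind(rnorm(n), rnorm(n))
    y_spatial <- f + rnorm(n, sd = 0.3)
  })
  # y an exact linear function of a covariate: fully explained
  at1 <- adjusted_test(3 + 2 * covs[, 1], covs[, 1, drop = FALSE], ctx)
  expect_true(at1$fully_explained)
  expect_equal(at1$p_combined, 1)
  # pure-noise covariates leave strong spatial signal significant
  at2 <- adjusted_test(y_spatial, covs, ctx)
  expect_lt(at2$p_combined, 1e-6)
  expect_equal(at2$kj, 2L)
  # two strongly correlated genes sharing one pattern, adjusted by each
  # other: both lose significance
  withr::with_seed(57, {
    y1 <- f + rnorm(n, sd = 0.1)
    y2 <- f + rnorm(n, sd = 0.1)
  })
  p1 <- adjusted_test(y1, cbind(y2 - mean(y2)), ctx)$p_combined
  p2 <- adjusted_test(y2, cbind(y1 - mean(y1)), ctx)$p_combined
  expect_gt(p1, 0.05)
  expect_gt(p2, 0.05)
  # unadjusted (NULL covariates) reduces to the plain test
  expect_lt(adjusted_test(y1, NULL, ctx)$p_combined, 1e-10)
})

test_that("gene graph honors threshold and unique flags", {
  ids <- paste0("g", 1:4)
  cors <- diag(4)
  cors[1, 2] <- cors[2, 1] <- 0.9
  cors[3, 4] <- cors[4, 3] <- 0.7
  cors[1, 3] <- cors[3, 1] <- 0.2
  g <- build_gene_graph(ids, cors, threshold = 0.5)
  expect_equal(igraph::ecount(g), 2L)
  expect_equal(igraph::count_components(g), 2L)
  expect_equal(sort(igraph::E(g)$weight), c(0.7, 0.9))
  # below threshold everywhere: edgeless
  g0 <- build_gene_graph(ids, diag(4), threshold = 0.5)
  expect_equal(igraph::ecount(g0), 0L)
  # a unique-flagged gene stays isolated despite high correlation
  gu <- build_gene_graph(ids, cors, threshold = 0.5,
                         unique_flags = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(igraph::degree(gu)[["g1"]], 0)
  expect_error(build_gene_graph(ids, matrix(rnorm(16), 4), 0.5), "symmetric")
})

test_that("leiden clustering recovers components and is deterministic", {
  ids <- paste0("g", 1:7)
  cors <- diag(7)
  cors[1:3, 1:3] <- 0.8; cors[4:6, 4:6] <- 0.8; diag(cors) <- 1
  g <- build_gene_graph(ids, cors, threshold = 0.5)
  cl <- cluster_genes(g, seed = 3L)
  expect_equal(attr(cl, "n_clusters"), 3L)   # two blocks + isolated g7
  expect_equal(length(unique(cl$cluster[cl$gene_id %in% ids[1:3]])), 1L)
  expect_equal(length(unique(cl$cluster[cl$gene_id %in% ids[4:6]])), 1L)
  expect_true(cl$is_singleton[cl$gene_id == "g7"])
  cl2 <- cluster_genes(g, seed = 3L)
  expect_identical(cl$cluster, cl2$cluster)
})

test_that("the full pipeline organizes a small pattern-group dataset", {
  sim <- simulate_scenario_one(seed = 71, n_spots = 600)
  pipe <- svg_pipeline(sim$expr, sim$spots, seed = 5L)
  expect_s3_class(pipe, "svg_pipeline")
  cl <- pipe$clusters
  truth <- sim$truth
  # every output gene is a detected SVG, and i in Sj <=> j in Si held
  expect_true(all(cl$gene_id %in% pipe$svg$gene_id[pipe$svg$is_svg]))
  dep <- pipe$dependency
  expect_true(all(dep$p_adjusted >= 0 & dep$p_adjusted <= 1))
  # the three pattern groups stay together whenever detected
  for (grp in 1:3) {
    members <- truth$gene_id[!is.na(truth$group) & truth$group == grp]
    got <- cl$cluster[cl$gene_id %in% members]
    if (length(got) > 1) expect_equal(length(unique(got)), 1L)
  }
})

test_that("a null dataset yields an empty clustering", {
  nd <- simulate_null(seed = 73, n_genes = 40, n_spots = 150)
  pipe <- svg_pipeline(nd$expr, nd$spots)
  expect_lte(attr(pipe$svg, "m1"), 2L)
  expect_lte(nrow(pipe$clusters), 2L)
})
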