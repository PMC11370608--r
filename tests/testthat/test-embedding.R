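test_that("spatial smoothing preserves constants and the small-bandwidth limit", {
  sp <- random_spots(60, seed = 81)
  withr::with_seed(82, block <- rbind(a = rnorm(60), b = rep(3, 60)))
  sm <- spatial_smooth(block, sp, bandwidth = 1e-4)
  expect_equal(sm, block, tolerance = 1e-8)
  sm2 <- spatial_smooth(block, sp, bandwidth = 0.2)
  expect_equal(unname(sm2["b", ]), rep(3, 60), tolerance = 1e-12)
  expect_error(spatial_smooth(block, sp, bandwidth = -1), "positive")
})

test_that("smoothing a step function matches the direct weighted average", {
  # 1-D arrangement embedded in 2-D
  x <- seq(0, 1, length.out = 40)
  sp <- spot_set(paste0("s", 1:40), cbind(x, 0))
  y <- as.numeric(x > 0.5)
  sm <- spatial_smooth(matrix(y, 1), sp, bandwidth = 0.05)
  W <- exp(-outer(x, x, "-")^2 / (2 * 0.05^2))
  expect_equal(unname(sm[1, ]), drop(W %*% y / rowSums(W)),
               tolerance = 1e-12)
  # interior means preserved, boundary softened
  expect_lt(max(abs(sm[1, 1:10])), 1e-6)
  expect_gt(min(sm[1, 31:40]), 1 - 1e-6)
  expect_true(all(diff(sm[1, ]) >= -1e-12))
})

test_that("cluster embeddings respect rank bounds", {
  sp <- random_spots(50, seed = 83)
  withr::with_seed(84, two <- matrix(rnorm(100), 2,
                                     dimnames = list(c("a", "b"))))
  emb <- cluster_embedding(two, sp)
  expect_equal(ncol(emb), 1L)
  # 10 duplicates of one gene: first PC explains all variance
  one <- rnorm(50)
  dup <- matrix(rep(one, 10), 10, byrow = TRUE,
                dimnames = list(paste0("d", 1:10)))
  embd <- cluster_embedding(dup, sp, d = 5)
  pcvar <- apply(embd, 2, var)
  expect_gt(pcvar[1] / sum(pcvar), 1 - 1e-8)
})

test_that("aggregation binds blocks and checks spot counts", {
  b1 <- matrix(rnorm(30), 10); b2 <- matrix(rnorm(20), 10)
  agg <- aggregate_embeddings(list(b1, b2))
  expect_equal(dim(agg), c(10L, 5L))
  expect_equal(attr(agg, "block_sizes"), c(3L, 2L))
  expect_equal(unname(agg[, 1:3]), b1)
  one <- aggregate_embeddings(list(b1))
  expect_equal(unname(unclass(one)), b1, ignore_attr = TRUE)
  expect_error(aggregate_embeddings(list(b1, matrix(0, 9, 2))), "disagree")
  # per-block standardization scales by the leading column sd
  std <- aggregate_embeddings(list(b1), standardize = TRUE)
  expect_equal(sd(std[, 1]), 1, tolerance = 1e-12)
  expect_equal(unname(std[, 2] / std[, 3]), unname(b1[, 2] / b1[, 3]))
})

test_that("domain detection separates well-separated clouds", {
  withr::with_seed(85, {
    emb <- rbind(matrix(rnorm(80, 0, 0.3), 40),
                 matrix(rnorm(80, 6, 0.3), 40))
  })
  truth <- rep(1:2, each = 40)
  lab_w <- detect_domains(emb, method = "walktrap", k_domains = 2)
  expect_equal(adjusted_rand_index(lab_w, truth), 1)
  # resolution-based methods may split a cloud, but never merge across the
  # separation: every community must be pure
  lab_l <- detect_domains(emb, method = "leiden", seed = 2)
  expect_true(all(vapply(split(truth, as.integer(lab_l)),
                         function(v) length(unique(v)) == 1L, TRUE)))
  # determinism and trivial cases
  expect_identical(as.integer(detect_domains(emb, method = "leiden", seed = 2)),
                   as.integer(lab_l))
  expect_equal(unique(as.integer(detect_domains(emb, k_domains = 1))), 1L)
  expect_error(detect_domains(emb, k_domains = 100), "exceeds")
  # sign flips of embedding columns do not change the partition
  lab_f <- detect_domains(emb %*% diag(c(-1, 1)), method = "walktrap",
                          k_domains = 2)
  expect_equal(adjusted_rand_index(lab_f, lab_w), 1)
})

test_that("embeddings are stable under gene order within a cluster", {
  sp <- random_spots(60, seed = 86)
  withr::with_seed(87, expr <- matrix(rnorm(600), 10,
                                      dimnames = list(paste0("g", 1:10))))
  e1 <- cluster_embedding(expr, sp, d = 3)
  e2 <- cluster_embedding(expr[sample(10), ], sp, d = 3)
  for (j in 1:3)
    expect_equal(abs(cor(e1[, j], e2[, j])), 1, tolerance = 1e-8)
})

test_that("two-domain synthetic data is recovered from one embedding block", {
  n <- 300
  sp <- random_spots(n, seed = 88)
  left <- sp$coords[, 1] < 0.5
  withr::with_seed(89, {
    expr <- t(replicate(8, 2 * left + rnorm(n, sd = 0.3)))
  })
  rownames(expr) <- paste0("g", 1:8)
  emb <- cluster_embedding(expr, sp, d = 3, bandwidth = 0.02)
  km <- kmeans(emb[, 1], 2, nstart = 5)$cluster
  expect_equal(adjusted_rand_index(km, left), 1)
})

test_that("pooled baseline truncates dimensions and orders by significance", {
  n <- 250
  sp <- random_spots(n, seed = 90)
  left <- sp$coords[, 1] < 0.5
  withr::with_seed(91, {
    expr <- rbind(t(replicate(20, 1.5 * left + rnorm(n, sd = 0.4))),
                  t(replicate(10, rnorm(n))))
  })
  rownames(expr) <- paste0("g", 1:30)
  svg <- detect_svgs(expr, sp)
  bl <- pooled_baseline(expr, sp, svg, n_top = 20, d = 20,
                        method = "walktrap", k_domains = 2)
  expect_lte(ncol(attr(bl, "embedding")), 19L)
  expect_gte(adjusted_rand_index(bl, left), 0.8)
})

test_that("block order does not change the detected domains", {
  withr::with_seed(92, {
    b1 <- cbind(rep(c(0, 5), each = 30) + rnorm(60, 0, 0.2))
    b2 <- cbind(rnorm(60, 0, 0.2))
  })
  l1 <- detect_domains(aggregate_embeddings(list(b1, b2)),
                       method = "walktrap", k_domains = 2)
  l2 <- detect_domains(aggregate_embeddings(list(b2, b1)),
                       method = "walktrap", k_domains = 2)
  expect_equal(adjusted_rand_index(l1, l2), 1)
})
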