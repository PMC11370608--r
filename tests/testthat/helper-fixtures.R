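# Shared fixtures. Heavy simulation studies are computed lazily and cached
# for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

random_spots <- function(n, seed = 1L, d = 2L) {
  withr::with_seed(seed,
    spot_set(paste0("s", seq_len(n)), matrix(runif(n * d), n)))
}

grid_spots <- function(nx, ny = nx) {
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  spot_set(paste0("s", seq_len(nx * ny)), as.matrix(g))
}

# Monte-Carlo oracle for the weighted chi-square upper tail
mc_quadform_tail <- function(q, lam, n_draws, seed = 1L) {
  withr::with_seed(seed, {
    draws <- matrix(rchisq(n_draws * length(lam), df = 1), length(lam))
    mean(colSums(lam * draws) > q)
  })
}

# the shared multi-replicate pattern-group study (acceptance criteria 2-4)
scenario_study <- function(n_reps = 50L, base_seed = 20260401L) {
  cached(paste0("scenario_study_", n_reps, "_", base_seed), {
    base <- simulate_scenario_one(seed = base_seed)
    ctx <- kernel_context(base$spots)
    truth <- base$truth
    reps <- lapply(seq_len(n_reps), function(i) {
      sim <- simulate_scenario_one(seed = base_seed + i, spots = base$spots)
      pipe <- svg_pipeline(sim$expr, ctx, seed = 7L)
      cl <- pipe$clusters
      merged <- merge(cl, truth, by = "gene_id")
      true_svg <- merged[merged$gene_id %in% truth$gene_id[truth$is_svg], ]
      list(svg = pipe$svg,
           ari = adjusted_rand_index(true_svg$cluster, true_svg$group),
           fdr = empirical_fdr(cl, truth$gene_id[!truth$is_svg]))
    })
    list(truth = truth,
         svg_results = lapply(reps, `[[`, "svg"),
         ari = vapply(reps, `[[`, 0, "ari"),
         fdr = vapply(reps, `[[`, 0, "fdr"))
  })
}

# the shared layered domain-detection study (acceptance criterion 8)
layered_study <- function(n_reps = 10L, base_seed = 550L) {
  cached(paste0("layered_study_", n_reps, "_", base_seed), {
    rows <- lapply(seq_len(n_reps), function(i) {
      sim <- simulate_layered(seed = base_seed + i, n_genes = 1200L,
                              n_spots = 1500L,
                              svg_counts = c(197L, 37L, 259L))
      ctx <- kernel_context(sim$spots)
      pipe <- svg_pipeline(sim$expr, ctx, seed = 7L)
      dom <- domains_from_clusters(sim$expr, sim$spots, pipe$clusters,
                                   method = "walktrap", k_domains = 5L,
                                   seed = 7L)
      bl <- pooled_baseline(sim$expr, sim$spots, pipe$svg,
                            method = "walktrap", k_domains = 5L, seed = 7L)
      c(ari_clustered = adjusted_rand_index(dom, sim$truth$domains),
        ari_pooled = adjusted_rand_index(bl, sim$truth$domains),
        pas_clustered = pas(dom, sim$spots),
        pas_pooled = pas(bl, sim$spots))
    })
    as.data.frame(do.call(rbind, rows))
  })
}
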