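cfg_lin <- propagation_config(method = "linear")

test_that("nearest-phenotype selection orders by distance and finds twins", {
  w <- small_world(seed = 50, n_mouse_traits = 12L)
  # a mouse phenotype with the disease's own seed set sits at distance 0
  dis <- w$human_traits[[1]]
  twin <- trait_seed_set("MPtwin", "mouse", dis$seeds)
  mice <- c(w$mouse_traits, list(MPtwin = twin))
  MP <- propagate_traits(w$network, mice, cfg_lin)
  dp <- propagate_traits(w$network, list(dis), cfg_lin)[, 1]
  sel <- select_nearest_phenotypes(dp, MP, k = 5)
  expect_equal(sel$phenotype_id[1], "MPtwin")
  expect_lt(sel$distance[1], 1e-6)
  expect_true(all(diff(sel$distance) >= 0))
  expect_error(select_nearest_phenotypes(dp, MP, k = 99), "exceeds")

  # planted worlds: same-module phenotypes occupy the top ranks
  prec <- c()
  for (s in 1:3) {
    w2 <- small_world(seed = 50 + s, n_mouse_traits = 18L)
    MP2 <- propagate_traits(w2$network, w2$mouse_traits, cfg_lin)
    for (dis2 in w2$human_traits[1:3]) {
      dp2 <- propagate_traits(w2$network, list(dis2), cfg_lin)[, 1]
      s3 <- select_nearest_phenotypes(dp2, MP2, k = 3)
      mods <- vapply(w2$mouse_traits[s3$phenotype_id], function(t) t$modules[1], 1L)
      prec <- c(prec, mean(mods %in% dis2$modules))
    }
  }
  expect_gte(mean(prec), 0.9)
})

test_that("geometric-mean aggregation matches brute force and its identities", {
  w <- small_world(seed = 55, n_genes = 150L, n_mouse_traits = 12L,
                   n_modules = 5L)
  dis <- w$human_traits[[1]]
  sel_ids <- vapply(w$mouse_traits[1:5], `[[`, "", "trait_id")
  rkg <- holdout_aggregate_ranking(w$network, dis, sel_ids, w$mouse_traits, cfg_lin)

  # brute-force exp-mean-log oracle over 5 phenotypes
  held <- lapply(w$mouse_traits[1:5], function(mt) setdiff(mt$seeds, dis$seeds))
  S <- propagate_traits(w$network, held, cfg_lin)
  S <- pmax(S, .Machine$double.eps)
  brute <- exp(rowMeans(log(S)))
  expect_lt(max(abs(rkg$score - unname(brute[rkg$gene]))), 1e-12)

  # AM-GM: geometric mean never exceeds the arithmetic mean
  expect_true(all(rkg$score <= rowMeans(S)[rkg$gene] + 1e-15))

  # aggregation is invariant to the order of the selected phenotypes
  rkg_rev <- holdout_aggregate_ranking(w$network, dis, rev(sel_ids),
                                       w$mouse_traits, cfg_lin)
  expect_equal(rkg$score[order(rkg$gene)], rkg_rev$score[order(rkg_rev$gene)])
  expect_equal(rkg$rank[order(rkg$gene)], rkg_rev$rank[order(rkg_rev$gene)])

  # k = 1 reduces to the single phenotype's own score ranking
  rk1 <- holdout_aggregate_ranking(w$network, dis, sel_ids[1], w$mouse_traits,
                                   cfg_lin)
  expect_equal(rk1$score, unname(S[rk1$gene, 1]), tolerance = 1e-12)

  # ranks are a permutation and ties would break lexicographically
  expect_setequal(rkg$rank, seq_len(nrow(rkg)))
})

test_that("hand arithmetic: geometric mean orders (0.3,0.3) above (0.1,0.4)", {
  expect_equal(exp(mean(log(c(0.1, 0.4)))), 0.2, tolerance = 1e-12)
  expect_gt(exp(mean(log(c(0.3, 0.3)))), exp(mean(log(c(0.1, 0.4)))))
})

test_that("hold-out hygiene: no disease seed remains in any used phenotype", {
  w <- small_world(seed = 56)
  dis <- w$human_traits[[1]]
  sel_ids <- vapply(w$mouse_traits[1:4], `[[`, "", "trait_id")
  held <- lapply(w$mouse_traits[sel_ids], function(mt) setdiff(mt$seeds, dis$seeds))
  expect_length(intersect(unlist(held), dis$seeds), 0)
  # a phenotype emptied by the hold-out is dropped with a warning
  clone <- trait_seed_set("MPclone", "mouse",
                          dis$seeds[rep(seq_along(dis$seeds), length.out = 10)])
  mice <- c(w$mouse_traits, list(MPclone = clone))
  expect_warning(
    holdout_aggregate_ranking(w$network, dis, c("MPclone", sel_ids[1]), mice,
                              cfg_lin),
    "dropped")
  expect_error(suppressWarnings(
    holdout_aggregate_ranking(w$network, dis, "MPclone", mice, cfg_lin)),
    "lost their seeds")
})

test_that("propagation-selected phenotypes beat random ones at gene recovery", {
  w <- generate_world(synthetic_world_config(
    rng_seed = 57, n_genes = 250L, n_modules = 8L, module_size = 20L,
    n_human_traits = 8L, n_mouse_traits = 24L, human_seeds_range = c(6L, 10L)))
  b <- benchmark_gene_recovery(w$human_traits, w$mouse_traits, w$network,
                               cfg_lin, k = 10, rng_seed = 3)
  a <- b$auroc[b$strategy == "propagation_topk"]
  r <- b$auroc[b$strategy == "random"]
  expect_gt(mean(a), mean(r))
  expect_true("propagation_topk vs random k 10" %in% names(attr(b, "t_tests")))
})

test_that("removal fraction 0 gives perfect selection stability", {
  w <- small_world(seed = 58, n_human_traits = 2L, n_mouse_traits = 18L)
  rb <- selection_robustness(w$human_traits, w$mouse_traits, w$network, cfg_lin,
                             k = 5, removal_fractions = 0, n_repeats = 2,
                             rng_seed = 4)
  expect_true(all(rb$stability == 1))
})
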