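test_that("world generation is reproducible and honors the configuration", {
  cfg <- synthetic_world_config(rng_seed = 42L)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$module_truth, w2$module_truth)
  expect_identical(lapply(w1$human_traits, `[[`, "seeds"),
                   lapply(w2$human_traits, `[[`, "seeds"))
  expect_identical(igraph::as_edgelist(w1$network),
                   igraph::as_edgelist(w2$network))
  expect_identical(igraph::E(w1$network)$weight, igraph::E(w2$network)$weight)

  # every seed gene exists in the network
  nodes <- igraph::V(w1$network)$name
  for (t in c(w1$human_traits, w1$mouse_traits)) {
    expect_true(all(t$seeds %in% nodes))
  }
  # every generated mouse trait has >= 10 seeds (the monogenic-model filter)
  expect_true(all(vapply(w1$mouse_traits, function(t) length(t$seeds), 0) >= 10))
})

test_that("infeasible or inconsistent configurations are rejected", {
  expect_error(synthetic_world_config(n_genes = 100, n_modules = 10,
                                      module_size = 20), "infeasible")
  expect_error(synthetic_world_config(p_in = 0.1, p_out = 0.2), "p_out")
  expect_error(synthetic_world_config(mouse_seeds_range = c(5, 8)), ">= 10")
  expect_error(synthetic_world_config(seed_noise_frac = 1.5), "seed_noise_frac")
})

test_that("noise-free traits draw every seed inside their generating modules", {
  w <- small_world(seed = 3, seed_noise_frac = 0)
  for (t in c(w$human_traits, w$mouse_traits)) {
    mods <- w$module_truth[t$seeds]
    expect_true(all(mods %in% t$modules))
  }
})

test_that("realized edge counts concentrate around the binomial expectation", {
  # binomial oracle: intra-module edges ~ Bin(n_modules*C(m,2), p_in)
  cfg <- synthetic_world_config(rng_seed = 9L, n_genes = 220L, n_modules = 10L,
                                module_size = 20L, p_in = 0.3, p_out = 0.01,
                                n_human_traits = 2L, n_mouse_traits = 0L)
  w <- generate_world(cfg)
  el <- igraph::as_edgelist(w$network)
  m1 <- w$module_truth[el[, 1]]
  m2 <- w$module_truth[el[, 2]]
  intra <- sum(m1 == m2 & m1 > 0)
  n_pairs <- 10 * choose(20, 2)
  mu <- n_pairs * 0.3
  sdv <- sqrt(n_pairs * 0.3 * 0.7)
  expect_lt(abs(intra - mu), 4 * sdv)
  inter_pairs <- choose(220, 2) - n_pairs
  inter <- nrow(el) - intra
  mu2 <- inter_pairs * 0.01
  expect_lt(abs(inter - mu2), 4 * sqrt(mu2 * 0.99))
})

test_that("traits sharing a generating module share an organ label", {
  w <- small_world(seed = 5, n_human_traits = 12L)
  traits <- w$human_traits
  for (i in seq_along(traits)) for (j in seq_along(traits)) {
    if (i < j && length(intersect(traits[[i]]$modules, traits[[j]]$modules))) {
      expect_gt(length(intersect(traits[[i]]$organs, traits[[j]]$organs)), 0)
    }
  }
})

test_that("expression matrix has planted cell-type signal and correct shape", {
  w <- generate_expression(small_world(seed = 7), n_celltypes = 20L,
                           signal_celltypes = 3L, effect_size = 2)
  E <- w$expression
  expect_identical(dim(E), c(200L, 20L))
  expect_true(all(is.finite(E)) && all(E >= 0))
  # direct F-test oracle: the 3 planted cell types have the smallest p-values
  Es <- scale_expression(E)
  sel <- select_celltypes_anova(Es, attr(E, "signal_genes"))
  top3 <- sel$cell_type[order(sel$p)][1:3]
  expect_setequal(top3, attr(E, "signal_celltypes"))
  # determinism
  w2 <- generate_expression(small_world(seed = 7), n_celltypes = 20L,
                            signal_celltypes = 3L, effect_size = 2)
  expect_identical(E, w2$expression)
  expect_error(generate_expression(w, n_celltypes = 5, signal_celltypes = 9),
               "signal_celltypes")
})

test_that("a null expression matrix yields ~alpha false cell-type selections", {
  hits <- 0; total <- 0
  for (s in 1:5) {
    w <- generate_expression(small_world(seed = 20 + s), effect_size = 0)
    Es <- scale_expression(w$expression)
    sel <- suppressWarnings(
      select_celltypes_anova(Es, attr(w$expression, "signal_genes"),
                             alpha = 0.01))
    hits <- hits + sum(sel$selected); total <- total + nrow(sel)
  }
  # expected alpha * total = 1; allow generous Poisson slack
  expect_lte(hits, 6)
})

test_that("write_world round-trips the network and tables as plain text", {
  w <- generate_expression(small_world(seed = 11))
  dir <- withr_local_tempdir()
  write_world(w, dir)
  g2 <- load_network(file.path(dir, "network.tsv"), min_weight = 0)
  # the edge-list format carries exactly the non-isolated nodes
  connected <- igraph::V(w$network)$name[igraph::degree(w$network) > 0]
  expect_setequal(igraph::V(g2)$name, connected)
  expect_equal(igraph::ecount(g2), igraph::ecount(w$network))
  ann <- read_organ_annotations(file.path(dir, "organs.tsv"))
  expect_setequal(ann[["HT01"]], w$human_traits[["HT01"]]$organs)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(length(truth$module_truth), 200)
})
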