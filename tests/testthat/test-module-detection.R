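test_that("recursive Walktrap yields an exhaustive partition within size bounds", {
  for (s in 1:5) {
    w <- small_world(seed = 40 + s)
    part <- recursive_walktrap(w$network, max_size = 20, max_rounds = 5)
    nodes <- igraph::V(w$network)$name
    expect_setequal(part$gene, nodes)
    expect_false(anyDuplicated(part$gene) > 0)
    sizes <- table(part$module_id)
    rounds <- tapply(part$round, part$module_id, unique)
    oversized <- names(sizes)[sizes > 20]
    expect_true(all(unlist(rounds[oversized]) == 5))
  }
})

test_that("two 10-cliques joined by one edge are split into distinct modules", {
  g <- igraph::make_full_graph(10) %du% igraph::make_full_graph(10)
  igraph::V(g)$name <- paste0("v", 1:20)
  g <- igraph::add_edges(g, c(1, 11))
  igraph::E(g)$weight <- 1
  part <- recursive_walktrap(g)
  m <- setNames(part$module_id, part$gene)
  expect_length(unique(m[paste0("v", 1:10)]), 1)
  expect_length(unique(m[paste0("v", 11:20)]), 1)
  expect_false(m[["v1"]] == m[["v11"]])
  # a below-threshold network still terminates at round 1
  expect_true(all(part$round == 1))
})

test_that("module-trait association matches exact rank-sum enumeration", {
  # complement-reference mode on a tiny module admits an exact null:
  # enumerate all C(12, 4) assignments of the observed scores
  set.seed(9)
  scores <- runif(12)
  mod <- scores[1:4]; rest <- scores[5:12]
  p_pkg <- phenoprop:::wilcox_greater_p(mod, rest)
  w_obs <- sum(rank(scores)[1:4]) - 4 * 5 / 2
  combos <- combn(12, 4)
  w_all <- apply(combos, 2, function(idx) {
    sum(rank(scores)[idx]) - 4 * 5 / 2
  })
  p_exact <- mean(w_all >= w_obs)
  expect_equal(p_pkg, p_exact, tolerance = 1e-12)
})

test_that("associations need elevated scores AND a trait seed in the module", {
  w <- small_world(seed = 46)
  cfg <- propagation_config(method = "linear")
  P <- propagate_traits(w$network, w$human_traits, cfg)
  part <- recursive_walktrap(w$network)
  assoc <- associate_modules(part, P, w$human_traits)
  expect_true(all(assoc$adjusted_p[assoc$associated] < 0.05))
  expect_true(all(assoc$n_trait_seeds_in_module[assoc$associated] >= 1))
  # no significant call without a seed gene, regardless of p
  no_seed <- assoc[assoc$n_trait_seeds_in_module == 0, ]
  expect_false(any(no_seed$associated))
  # BH q-values are monotone in p within each trait
  for (tid in unique(assoc$trait_id)) {
    sub <- assoc[assoc$trait_id == tid, ]
    o <- order(sub$wilcoxon_p)
    expect_true(all(diff(sub$adjusted_p[o]) >= -1e-12))
  }
  # the generating module of each trait is found
  found <- 0
  for (t in w$human_traits) {
    gen_genes <- names(w$module_truth)[w$module_truth %in% t$modules]
    hit <- assoc$associated & assoc$trait_id == t$trait_id &
      vapply(assoc$module_id, function(m) {
        length(intersect(part$gene[part$module_id == m], gen_genes)) > 0
      }, logical(1))
    found <- found + any(hit)
  }
  expect_gte(found / length(w$human_traits), 0.95)
})

test_that("a module scoring like the global distribution is not associated", {
  set.seed(10)
  g <- random_graph(60, 0.2, seed = 10)
  P <- matrix(runif(60), 60, 1,
              dimnames = list(sort(igraph::V(g)$name), "t1"))
  part <- recursive_walktrap(g)
  traits <- list(trait_seed_set("t1", "human", rownames(P)[1:3]))
  assoc <- associate_modules(part, P, traits)
  expect_false(any(assoc$associated[assoc$adjusted_p > 0.5]))
})

test_that("hypergeometric over-representation matches the exact tail", {
  universe <- paste0("u", 1:1000)
  mod <- universe[1:10]
  sets <- list(hit = universe[1:10], none = universe[500:520],
               partial = universe[6:25])
  res <- overrepresentation_test(mod, sets, universe)
  # exact oracle via dhyper sums
  p_hit <- sum(dhyper(10:10, 10, 990, 10))
  p_partial <- sum(dhyper(5:10, 20, 980, 10))
  expect_equal(res$p[res$set_name == "hit"], p_hit, tolerance = 1e-12)
  expect_equal(res$p[res$set_name == "partial"], p_partial, tolerance = 1e-12)
  expect_equal(res$p[res$set_name == "none"],
               phyper(-1, 21, 979, 10, lower.tail = FALSE))
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-12))
  expect_error(overrepresentation_test(c("zzz"), sets, universe), "universe")
})

test_that("module composition fractions match a hand-computed toy", {
  part <- data.frame(gene = paste0("g", 1:9),
                     module_id = rep(c("A", "B", "C"), each = 3),
                     round = 1L, stringsAsFactors = FALSE)
  out <- module_composition_fractions(
    part,
    candidate_genes = list(t1 = c("g1", "g4"), t2 = c("g2")),
    ciliary_genes = c("g4", "g5", "g6"),
    known_genes = paste0("g", 7:9))
  expect_equal(out$frac_candidate[out$module_id == "A"], 2 / 3)
  expect_equal(out$frac_ciliary[out$module_id == "B"], 1)
  expect_equal(out$frac_known[out$module_id == "C"], 1)   # saturation
  expect_identical(out$display, c(TRUE, TRUE, TRUE))
  out2 <- module_composition_fractions(part, character(), display_min = 1.1)
  expect_false(any(out2$display))
})
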