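cfg_lin <- propagation_config(method = "linear")

test_that("feature tables are min-max scaled with held-out signal", {
  w <- small_world(seed = 80, n_mouse_traits = 18L)
  MP <- propagate_traits(w$network, w$mouse_traits, cfg_lin)
  dis <- w$human_traits[[1]]
  train <- dis$seeds[1:5]
  ft <- build_feature_table(dis, train, w$network, w$mouse_traits, MP,
                            config = cfg_lin, n_permutations = 99,
                            rng_seed = 1)
  expect_true(all(ft$prop >= 0 & ft$prop <= 1))
  expect_equal(range(ft$mp), c(0, 1))
  # held-out disease genes carry a stronger propagation feature than average
  held <- setdiff(dis$seeds, train)
  expect_gt(mean(ft$prop[ft$gene %in% held]), mean(ft$prop) + 0.1)
  expect_gt(mean(ft$mp[ft$gene %in% held]), mean(ft$mp))
  # determinism
  ft2 <- build_feature_table(dis, train, w$network, w$mouse_traits, MP,
                             config = cfg_lin, n_permutations = 99,
                             rng_seed = 1)
  expect_identical(ft, ft2)
})

test_that("a constant feature column maps to zeros with a warning", {
  expect_warning(z <- phenoprop:::minmax_scale(rep(2, 5)), "constant")
  expect_identical(z, rep(0, 5))
})

test_that("training rounds use each seed gene at most once", {
  w <- generate_world(synthetic_world_config(
    rng_seed = 81, n_genes = 250L, n_modules = 8L,
    n_human_traits = 4L, human_seed_counts = c(21L, 20L, 23L, 22L),
    human_seeds_range = c(10L, 23L), n_mouse_traits = 16L))
  MP <- propagate_traits(w$network, w$mouse_traits, cfg_lin)
  model <- train_combined_model(w$human_traits, w$network, w$mouse_traits, MP,
                                config = cfg_lin, n_permutations = 49,
                                rng_seed = 5)
  rows <- model$pooled_rows
  expect_named(model$coefficients, c("(Intercept)", "prop", "mp"))
  # per disease: floor(n_seeds / 5) rounds, and a gene never labels
  # positive in the round where it was used for training (disjoint chunks)
  for (dis in w$human_traits) {
    sub <- rows[rows$disease_id == dis$trait_id, ]
    expect_equal(length(unique(sub$round)), floor(length(dis$seeds) / 5))
    n_pos_by_round <- tapply(sub$label, sub$round, sum)
    # each round reserves all non-training seeds as positives
    expect_true(all(n_pos_by_round == length(dis$seeds) - 5))
  }
  expect_error(train_combined_model(w$human_traits[1], w$network,
                                    features = character()), "nonempty")
})

test_that("combined scores are monotone in positively weighted features", {
  model <- structure(list(
    coefficients = c(`(Intercept)` = -2, prop = 3, mp = 1.5),
    features = c("prop", "mp")), class = "priority_model")
  ft <- data.frame(gene = c("a", "b"), prop = c(0.2, 0.2), mp = c(0.1, 0.9))
  sc <- predict_priority(model, ft)
  expect_gt(sc[["b"]], sc[["a"]])
  ft2 <- ft; ft2$prop[1] <- 0.9
  expect_gt(predict_priority(model, ft2)[["a"]], sc[["a"]])
})

test_that("evaluation reports per-round metrics and final rankings exclude seeds", {
  w <- generate_world(synthetic_world_config(
    rng_seed = 82, n_genes = 250L, n_modules = 8L,
    n_human_traits = 6L, human_seed_counts = c(20L, 21L, 20L, 20L, 12L, 11L),
    human_seeds_range = c(10L, 22L), n_mouse_traits = 24L))
  MP <- propagate_traits(w$network, w$mouse_traits, cfg_lin)
  model <- train_combined_model(w$human_traits[1:4], w$network, w$mouse_traits,
                                MP, config = cfg_lin, n_permutations = 49,
                                rng_seed = 6)
  ev <- evaluate_model(model, w$human_traits[5:6], w$network, w$mouse_traits,
                       MP, config = cfg_lin, n_rounds = 2, n_negatives = 150,
                       n_permutations = 49, rng_seed = 7)
  expect_equal(nrow(ev), 2 * 2)
  expect_true(all(ev$pr_auc >= 0 & ev$pr_auc <= 1))
  expect_true(all(ev$partial_auroc >= 0 & ev$partial_auroc <= 1))
  pooled <- attr(ev, "pooled")
  expect_equal(sort(unique(pooled$round)), 1:2)
  # deterministic reruns
  ev2 <- evaluate_model(model, w$human_traits[5:6], w$network, w$mouse_traits,
                        MP, config = cfg_lin, n_rounds = 2, n_negatives = 150,
                        n_permutations = 49, rng_seed = 7)
  expect_identical(ev$pr_auc, ev2$pr_auc)

  fr <- final_ranking(w$human_traits[[5]], model, w$network, w$mouse_traits,
                      MP, config = cfg_lin, top_k = 50, n_permutations = 49,
                      rng_seed = 8)
  expect_length(intersect(fr$gene, w$human_traits[[5]]$seeds), 0)
  expect_equal(nrow(fr), 50)
  expect_identical(fr$rank, 1:50)
  # held-out module genes are enriched at the top of the ranking
  truth <- setdiff(names(w$module_truth)[
    w$module_truth %in% w$human_traits[[5]]$modules],
    w$human_traits[[5]]$seeds)
  hits <- sum(fr$gene[1:50] %in% truth)
  random_expectation <- 50 * length(truth) / (250 - 12)
  expect_gt(hits, 3 * random_expectation)
  expect_gte(hits, 0.7 * length(truth))
})
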