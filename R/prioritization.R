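#' Per-gene feature table for one disease
#'
#' Computes the three candidate-gene features for a disease from a small
#' set of training genes, over every gene in the network:
#' \describe{
#'   \item{prop}{1 minus the permutation-null empirical p-value of the
#'     propagation score seeded on the training genes (corrects for hub
#'     bias).}
#'   \item{mp}{1 minus the normalized aggregate rank from the nearest mouse
#'     phenotypes: the training-gene profile selects the `n_phenotypes`
#'     closest phenotypes, the training genes are held out of their seed
#'     sets, and the re-propagated scores are combined by geometric mean.}
#'   \item{expr}{the expression-similarity score from a fitted
#'     [fit_and_score_expression()] model.}
#' }
#' Each feature is min-max scaled to `[0, 1]` over all genes (a constant
#' column maps to zeros with a warning), so features share one range and
#' p-values/ranks are oriented "higher = better".
#'
#' @param disease A [trait_seed_set()] (used for its id; the features are
#'   computed from `training_genes` only).
#' @param training_genes The training seed genes (default design: 5).
#' @param network Interaction network.
#' @param mouse_traits List of mouse [trait_seed_set()]s.
#' @param mouse_profiles Precomputed genes x phenotypes score matrix
#'   (computed if `NULL`).
#' @param expression_scores Named per-gene score vector (e.g.
#'   `fit$scores`), or `NULL` to omit the expression feature.
#' @param config A [propagation_config()].
#' @param features Subset of `c("prop", "mp", "expr")` to compute.
#' @param n_permutations Permutations for the prop feature; default 1000.
#' @param n_phenotypes Nearest phenotypes for the mp feature; default 10.
#' @param rng_seed Integer seed (permutations).
#' @return Data frame with `gene` plus one column per feature, all in
#'   `[0, 1]`; attributes `disease_id` and `training_genes`.
#' @export
build_feature_table <- function(disease, training_genes, network,
                                mouse_traits = NULL, mouse_profiles = NULL,
                                expression_scores = NULL,
                                config = propagation_config(),
                                features = c("prop", "mp"),
                                n_permutations = 1000L, n_phenotypes = 10L,
                                rng_seed = NULL) {
  features <- match.arg(features, c("prop", "mp", "expr"), several.ok = TRUE)
  nodes <- sort(igraph::V(network)$name)
  training_genes <- intersect(training_genes, nodes)
  if (length(training_genes) == 0) stopf("no training genes in the network")
  out <- data.frame(gene = nodes, stringsAsFactors = FALSE)

  if ("prop" %in% features) {
    pn <- permutation_pvalues(network, training_genes, config,
                              n_permutations = n_permutations,
                              rng_seed = rng_seed)
    out$prop <- minmax_scale(1 - pn$pvalues[nodes], "prop feature")
  }
  if ("mp" %in% features) {
    if (is.null(mouse_traits)) stopf("mp feature needs mouse_traits")
    if (is.null(mouse_profiles)) {
      mouse_profiles <- propagate_traits(network, mouse_traits, config)
    }
    train_prof <- propagate_traits(network, list(training_genes), config)[, 1]
    sel <- select_nearest_phenotypes(train_prof, mouse_profiles,
                                     k = min(n_phenotypes, ncol(mouse_profiles)))
    holdout <- trait_seed_set(disease$trait_id, disease$trait_class,
                              training_genes)
    rkg <- holdout_aggregate_ranking(network, holdout, sel, mouse_traits, config)
    rk <- rkg$rank[match(nodes, rkg$gene)]
    out$mp <- minmax_scale(1 - rk / length(nodes), "mp feature")
  }
  if ("expr" %in% features) {
    if (is.null(expression_scores)) stopf("expr feature needs expression_scores")
    es <- expression_scores[nodes]
    es[is.na(es)] <- min(expression_scores, na.rm = TRUE)
    out$expr <- minmax_scale(es, "expr feature")
  }
  attr(out, "disease_id") <- disease$trait_id
  attr(out, "training_genes") <- training_genes
  out
}

# Pooled training rows across diseases and rounds. Each disease contributes
# floor(n_seeds / n_train) rounds with disjoint training gene sets; per
# round, positives = remaining seeds, negatives = sampled non-associated
# genes.
build_training_rows <- function(training_diseases, network, mouse_traits,
                                mouse_profiles, expression_scores, config,
                                features, negatives_per_round, n_train,
                                n_permutations, n_phenotypes, rng_seed) {
  nodes <- sort(igraph::V(network)$name)
  rows <- list()
  for (di in seq_along(training_diseases)) {
    dis <- training_diseases[[di]]
    seeds <- intersect(dis$seeds, nodes)
    if (length(seeds) < 2 * n_train) {
      stopf("training disease %s needs >= %d seeds in the network",
            dis$trait_id, 2 * n_train)
    }
    set.seed(derive_seed(rng_seed, 100L + di))
    shuffled <- sample(seeds)
    n_rounds <- floor(length(seeds) / n_train)
    for (r in seq_len(n_rounds)) {
      train <- shuffled[((r - 1) * n_train + 1):(r * n_train)]
      ft <- build_feature_table(dis, train, network, mouse_traits,
                                mouse_profiles, expression_scores, config,
                                features, n_permutations, n_phenotypes,
                                rng_seed = derive_seed(rng_seed, 10000L + 100L * di + r))
      positives <- setdiff(seeds, train)
      set.seed(derive_seed(rng_seed, 20000L + 100L * di + r))
      negatives <- sample(setdiff(nodes, seeds),
                          min(negatives_per_round, length(setdiff(nodes, seeds))))
      sub <- ft[ft$gene %in% c(positives, negatives), , drop = FALSE]
      sub$label <- as.integer(sub$gene %in% positives)
      sub$disease_id <- dis$trait_id
      sub$round <- r
      rows[[length(rows) + 1L]] <- sub
    }
  }
  do.call(rbind, rows)
}

#' Train the pooled candidate-gene prioritization model
#'
#' For each training disease (the design uses four diseases with at least
#' 20 seed genes), splits its seeds into disjoint 5-gene training sets
#' (one per round; every seed is used at most once for training), builds
#' the per-round feature tables, labels the remaining seeds positive and
#' `negatives_per_round` sampled non-associated genes negative, pools all
#' rounds and diseases, and fits one logistic regression. Predictions stay
#' disease-specific because the features are computed per disease.
#'
#' @param training_diseases List of [trait_seed_set()]s, each with at least
#'   `2 * n_train` seeds.
#' @inheritParams build_feature_table
#' @param negatives_per_round Sampled negatives per round; default 150.
#' @param n_train Training genes per round; default 5.
#' @param rng_seed Integer seed driving splits, sampling and permutations.
#' @return A `priority_model`: `coefficients` (named, incl. intercept),
#'   `features`, `training_info` (diseases, rounds, pooled counts),
#'   `pooled_rows` (the training table).
#' @export
train_combined_model <- function(training_diseases, network, mouse_traits = NULL,
                                 mouse_profiles = NULL, expression_scores = NULL,
                                 config = propagation_config(),
                                 features = c("prop", "mp"),
                                 negatives_per_round = 150L, n_train = 5L,
                                 n_permutations = 1000L, n_phenotypes = 10L,
                                 rng_seed = 1L) {
  if (length(features) == 0) stopf("feature subset must be nonempty")
  pooled <- build_training_rows(training_diseases, network, mouse_traits,
                                mouse_profiles, expression_scores, config,
                                features, negatives_per_round, n_train,
                                n_permutations, n_phenotypes, rng_seed)
  fit_priority_model(pooled, features,
                     training_info = list(
                       diseases = vapply(training_diseases, `[[`, "", "trait_id"),
                       n_positive = sum(pooled$label == 1),
                       n_negative = sum(pooled$label == 0),
                       n_train = n_train,
                       negatives_per_round = negatives_per_round))
}

#' Fit a prioritization model on a pooled feature table
#'
#' Unpenalized logistic maximum likelihood, with a ridge fallback
#' (lambda = 1e-6) when the fit does not converge or separates.
#'
#' @param pooled_rows Data frame with feature columns and a 0/1 `label`.
#' @param features Feature columns to use.
#' @param training_info Optional metadata stored with the model.
#' @return A `priority_model`.
#' @export
fit_priority_model <- function(pooled_rows, features, training_info = NULL) {
  stopifnot(all(features %in% names(pooled_rows)), "label" %in% names(pooled_rows))
  X <- as.matrix(pooled_rows[, features, drop = FALSE])
  y <- pooled_rows$label
  fit <- suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                         family = stats::binomial()))
  coefs <- fit$coefficients
  separated <- !fit$converged || any(fit$fitted.values > 1 - 1e-10) &&
    any(fit$fitted.values < 1e-10)
  if (separated || anyNA(coefs)) {
    if (ncol(X) >= 2) {
      rf <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                           lambda = 1e-6, standardize = FALSE)
      coefs <- c(as.numeric(rf$a0), drop(as.matrix(rf$beta)))
    }
  }
  names(coefs) <- c("(Intercept)", features)
  structure(list(coefficients = coefs, features = features,
                 training_info = training_info, pooled_rows = pooled_rows),
            class = "priority_model")
}

#' @export
print.priority_model <- function(x, ...) {
  cat(sprintf("<priority_model> features: %s\n", paste(x$features, collapse = "+")))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Combined model score for a feature table
#'
#' @param model A `priority_model`.
#' @param feature_table A [build_feature_table()] result containing the
#'   model's features.
#' @return Named numeric vector of predicted probabilities in (0, 1).
#' @export
predict_priority <- function(model, feature_table) {
  X <- as.matrix(feature_table[, model$features, drop = FALSE])
  p <- stats::plogis(drop(X %*% model$coefficients[model$features]) +
                       model$coefficients[["(Intercept)"]])
  stats::setNames(p, feature_table$gene)
}

#' Evaluate prioritization models on held-out diseases
#'
#' For each test disease (the design uses six diseases with at least 10
#' seeds, disjoint from training) and each of `n_rounds` train/test splits:
#' samples `n_train` training genes, builds the feature table, scores all
#' genes with each model, and evaluates against positives = the remaining
#' seeds and negatives = `n_negatives` sampled control genes. Reports
#' PR AUC, standardized partial AUROC (specificity 0.95-1.0) and AUROC per
#' disease and round, plus pooled per-round metrics.
#'
#' @param models A `priority_model` or named list of them (evaluated on
#'   shared feature tables).
#' @param test_diseases List of [trait_seed_set()]s; a disease with fewer
#'   than `n_train + 1` seeds is skipped with a note.
#' @inheritParams train_combined_model
#' @param n_rounds Test splits per disease; default 10.
#' @param n_negatives Sampled control genes per round; default 1000
#'   (capped by availability).
#' @return Data frame of `model`, `disease_id`, `round`, `pr_auc`,
#'   `partial_auroc`, `auroc`; attribute `pooled` holds per-model,
#'   per-round metrics over all test diseases pooled.
#' @export
evaluate_model <- function(models, test_diseases, network, mouse_traits = NULL,
                           mouse_profiles = NULL, expression_scores = NULL,
                           config = propagation_config(), n_rounds = 10L,
                           n_negatives = 1000L, n_train = 5L,
                           n_permutations = 1000L, n_phenotypes = 10L,
                           rng_seed = 1L) {
  if (inherits(models, "priority_model")) models <- list(model = models)
  feats_needed <- unique(unlist(lapply(models, `[[`, "features")))
  nodes <- sort(igraph::V(network)$name)
  rows <- list(); pooled_scores <- list()
  for (di in seq_along(test_diseases)) {
    dis <- test_diseases[[di]]
    seeds <- intersect(dis$seeds, nodes)
    if (length(seeds) < n_train + 1) {
      message(sprintf("test disease %s skipped: fewer than %d seeds",
                      dis$trait_id, n_train + 1))
      next
    }
    for (r in seq_len(n_rounds)) {
      set.seed(derive_seed(rng_seed, 30000L + 100L * di + r))
      train <- sample(seeds, n_train)
      positives <- setdiff(seeds, train)
      ft <- build_feature_table(dis, train, network, mouse_traits,
                                mouse_profiles, expression_scores, config,
                                feats_needed, n_permutations, n_phenotypes,
                                rng_seed = derive_seed(rng_seed, 40000L + 100L * di + r))
      set.seed(derive_seed(rng_seed, 50000L + 100L * di + r))
      avail <- setdiff(nodes, seeds)
      negatives <- sample(avail, min(n_negatives, length(avail)))
      eval_genes <- c(positives, negatives)
      lab <- eval_genes %in% positives
      idx <- match(eval_genes, ft$gene)
      for (mn in names(models)) {
        sc <- predict_priority(models[[mn]], ft)[idx]
        rows[[length(rows) + 1L]] <- data.frame(
          model = mn, disease_id = dis$trait_id, round = r,
          pr_auc = pr_auc(sc, lab),
          partial_auroc = partial_auroc(sc, lab),
          auroc = auroc(sc, lab), stringsAsFactors = FALSE)
        key <- paste(mn, r, sep = ".")
        pooled_scores[[key]] <- rbind(pooled_scores[[key]],
                                      cbind(score = sc, label = lab))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  pooled <- do.call(rbind, lapply(names(pooled_scores), function(key) {
    m <- pooled_scores[[key]]
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    data.frame(model = parts[1], round = as.integer(parts[2]),
               pr_auc = pr_auc(m[, "score"], m[, "label"]),
               partial_auroc = partial_auroc(m[, "score"], m[, "label"]),
               auroc = auroc(m[, "score"], m[, "label"]),
               stringsAsFactors = FALSE)
  }))
  attr(out, "pooled") <- pooled
  out
}

#' Final candidate-gene ranking for a disease
#'
#' Computes the features from all of the disease's seed genes, scores every
#' gene with the trained model, excludes the seed genes, and returns the
#' top candidates with their per-feature values.
#'
#' @param disease A [trait_seed_set()].
#' @param model A `priority_model`.
#' @inheritParams build_feature_table
#' @param top_k Number of candidates returned; default 100.
#' @return Data frame of `gene`, `score`, the feature columns and `rank`;
#'   no seed gene appears. Attribute `all_scores` holds the full
#'   non-seed score vector (for enrichment analyses).
#' @export
final_ranking <- function(disease, model, network, mouse_traits = NULL,
                          mouse_profiles = NULL, expression_scores = NULL,
                          config = propagation_config(), top_k = 100L,
                          n_permutations = 1000L, n_phenotypes = 10L,
                          rng_seed = 1L) {
  ft <- build_feature_table(disease, disease$seeds, network, mouse_traits,
                            mouse_profiles, expression_scores, config,
                            model$features, n_permutations, n_phenotypes,
                            rng_seed = rng_seed)
  sc <- predict_priority(model, ft)
  keep <- !(ft$gene %in% disease$seeds)
  cand <- ft[keep, , drop = FALSE]
  cand$score <- sc[keep]
  cand <- cand[order(-cand$score, cand$gene), ]
  cand$rank <- seq_len(nrow(cand))
  out <- utils::head(cand, top_k)
  rownames(out) <- NULL
  attr(out, "all_scores") <- stats::setNames(cand$score, cand$gene)
  out
}
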