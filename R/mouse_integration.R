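#' Select the mouse phenotypes nearest to a disease
#'
#' Ranks model-organism phenotypes by similarity to a disease, by default
#' the Euclidean distance between z-scored propagation profiles (20 nearest
#' phenotypes are used for joint clustering, 10 for gene prediction).
#' Alternative strategies: Jaccard distance on seed-gene overlap, a fixed
#' distance cutoff, or a random draw (baseline).
#'
#' @param disease_profile Named numeric propagation score vector of the
#'   disease (or a `propagation_profile`).
#' @param mouse_profiles Genes x phenotypes propagation score matrix over
#'   the same node set.
#' @param k Number of phenotypes to select (top-k strategies).
#' @param strategy One of `"propagation_topk"` (default),
#'   `"propagation_threshold"`, `"jaccard_topk"`, `"random"`.
#' @param distance_cutoff Threshold strategy only: phenotypes with distance
#'   at most the cutoff are selected.
#' @param disease_seeds,mouse_traits Seed genes of the disease and the list
#'   of mouse [trait_seed_set()]s (required for `"jaccard_topk"`).
#' @param rng_seed Seed for the random strategy.
#' @return A `phenotype_selection` data frame (`phenotype_id`, `distance`),
#'   ordered ascending by distance for top-k strategies, with the strategy
#'   in attributes.
#' @export
select_nearest_phenotypes <- function(disease_profile, mouse_profiles, k = 20L,
                                      strategy = c("propagation_topk",
                                                   "propagation_threshold",
                                                   "jaccard_topk", "random"),
                                      distance_cutoff = NULL,
                                      disease_seeds = NULL, mouse_traits = NULL,
                                      rng_seed = NULL) {
  strategy <- match.arg(strategy)
  if (inherits(disease_profile, "propagation_profile")) {
    disease_profile <- disease_profile$scores
  }
  stopifnot(identical(names(disease_profile), rownames(mouse_profiles)))
  n_phen <- ncol(mouse_profiles)
  if (strategy %in% c("propagation_topk", "jaccard_topk", "random") &&
      k > n_phen) {
    stopf("k = %d exceeds the number of mouse phenotypes (%d)", k, n_phen)
  }

  if (strategy == "jaccard_topk") {
    if (is.null(disease_seeds) || is.null(mouse_traits)) {
      stopf("jaccard_topk needs disease_seeds and mouse_traits")
    }
    d <- vapply(mouse_traits, function(mt) {
      1 - length(intersect(disease_seeds, mt$seeds)) /
        length(union(disease_seeds, mt$seeds))
    }, numeric(1))
    names(d) <- vapply(mouse_traits, `[[`, "", "trait_id")
    d <- d[colnames(mouse_profiles)]
  } else {
    zd <- zscore_profile(disease_profile)
    Z <- zscore_columns(mouse_profiles)
    d <- sqrt(colSums((Z - zd)^2))
  }

  sel <- switch(strategy,
    propagation_topk = , jaccard_topk = order(d, names(d))[seq_len(k)],
    propagation_threshold = {
      if (is.null(distance_cutoff)) stopf("distance_cutoff required")
      which(d <= distance_cutoff)[order(d[d <= distance_cutoff])]
    },
    random = {
      if (!is.null(rng_seed)) set.seed(rng_seed)
      sample(seq_len(n_phen), k)
    })
  out <- data.frame(phenotype_id = colnames(mouse_profiles)[sel],
                    distance = unname(d[sel]), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "strategy") <- strategy
  attr(out, "k") <- if (strategy == "propagation_threshold") NA_integer_ else as.integer(k)
  attr(out, "distance_cutoff") <- distance_cutoff
  class(out) <- c("phenotype_selection", "data.frame")
  out
}

#' Hold-out gene ranking from selected mouse phenotypes
#'
#' Removes the disease's known genes from the seed sets of the selected
#' mouse phenotypes, re-propagates each phenotype, and aggregates the
#' resulting per-gene scores by geometric mean (or by counting how often a
#' gene appears as a seed, as a propagation-free baseline). Genes are
#' ranked descending by the aggregate, ties broken lexicographically.
#'
#' @param network Interaction network.
#' @param disease A [trait_seed_set()]; its seeds are held out from every
#'   phenotype's seed set.
#' @param selection A [select_nearest_phenotypes()] result (or character
#'   vector of phenotype ids).
#' @param mouse_traits List of mouse [trait_seed_set()]s.
#' @param config A [propagation_config()].
#' @param aggregation `"geometric_mean"` (default) or `"seed_count"`.
#' @return Data frame of `gene`, `score`, `rank` (a permutation of
#'   `1..n_genes`).
#' @export
holdout_aggregate_ranking <- function(network, disease, selection, mouse_traits,
                                      config = propagation_config(),
                                      aggregation = c("geometric_mean",
                                                      "seed_count")) {
  aggregation <- match.arg(aggregation)
  phen_ids <- if (is.data.frame(selection)) selection$phenotype_id else selection
  if (length(phen_ids) == 0) stopf("empty phenotype selection")
  mt_ids <- vapply(mouse_traits, `[[`, "", "trait_id")
  sel_traits <- mouse_traits[match(phen_ids, mt_ids)]
  held <- lapply(sel_traits, function(mt) setdiff(mt$seeds, disease$seeds))
  empty <- lengths(held) == 0
  if (any(empty)) {
    warning(sprintf("%d phenotype(s) dropped: no seeds left after hold-out",
                    sum(empty)))
    held <- held[!empty]; phen_ids <- phen_ids[!empty]
  }
  if (length(held) == 0) stopf("all selected phenotypes lost their seeds")

  nodes <- sort(igraph::V(network)$name)
  if (aggregation == "seed_count") {
    agg <- vapply(nodes, function(g) sum(vapply(held, function(s) g %in% s,
                                                logical(1))), numeric(1))
  } else {
    names(held) <- phen_ids
    S <- propagate_traits(network, held, config)
    S <- pmax(S, .Machine$double.eps)  # disconnected components can score 0
    agg <- exp(rowMeans(log(S)))
  }
  ord <- order(-agg, nodes)
  rk <- integer(length(agg)); rk[ord] <- seq_along(agg)
  out <- data.frame(gene = nodes, score = unname(agg), rank = rk,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "aggregation") <- aggregation
  attr(out, "phenotypes") <- phen_ids
  out
}

#' Benchmark disease-gene recovery via mouse phenotypes
#'
#' For each disease and selection strategy: selects phenotypes, holds out
#' the disease genes from their seed sets, builds the aggregate ranking and
#' scores the recovery of the held-out disease genes by AUROC (positives =
#' disease seeds, negatives = all other network genes). Supports grids of
#' `k` and random-selection baselines.
#'
#' @param diseases List of human [trait_seed_set()]s.
#' @param mouse_traits List of mouse [trait_seed_set()]s.
#' @param network Interaction network.
#' @param config A [propagation_config()].
#' @param k Vector of phenotype counts to evaluate; default 10 (the optimum
#'   for gene recovery).
#' @param strategies Subset of the [select_nearest_phenotypes()] strategies.
#' @param aggregation Passed to [holdout_aggregate_ranking()].
#' @param mouse_profiles Optional precomputed genes x phenotypes score
#'   matrix (computed if missing).
#' @param rng_seed Seed for random selections.
#' @return Data frame of `disease_id`, `strategy`, `k`, `auroc`, with
#'   attribute `t_tests`: two-sample t-tests of each strategy's AUROC
#'   vector against the first strategy's, per `k`.
#' @export
benchmark_gene_recovery <- function(diseases, mouse_traits, network,
                                    config = propagation_config(),
                                    k = 10L,
                                    strategies = c("propagation_topk", "random"),
                                    aggregation = "geometric_mean",
                                    mouse_profiles = NULL, rng_seed = NULL) {
  if (is.null(mouse_profiles)) {
    mouse_profiles <- propagate_traits(network, mouse_traits, config)
  }
  disease_profiles <- propagate_traits(network, diseases, config)
  nodes <- rownames(mouse_profiles)
  rows <- list()
  for (di in seq_along(diseases)) {
    dis <- diseases[[di]]
    pos <- intersect(dis$seeds, nodes)
    if (length(pos) == 0) stopf("disease %s has no seeds in the network", dis$trait_id)
    for (kk in k) for (st in strategies) {
      sel <- select_nearest_phenotypes(
        disease_profiles[, dis$trait_id], mouse_profiles, k = kk, strategy = st,
        disease_seeds = dis$seeds, mouse_traits = mouse_traits,
        rng_seed = if (st == "random" && !is.null(rng_seed))
          derive_seed(rng_seed, di * 1000L + kk) else NULL)
      rkg <- holdout_aggregate_ranking(network, dis, sel, mouse_traits, config,
                                       aggregation = aggregation)
      lab <- rkg$gene %in% pos
      rows[[length(rows) + 1L]] <- data.frame(
        disease_id = dis$trait_id, strategy = st, k = kk,
        auroc = auroc(rkg$score, lab), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ref <- strategies[1]
  tt <- list()
  for (kk in unique(out$k)) for (st in setdiff(strategies, ref)) {
    a <- out$auroc[out$strategy == ref & out$k == kk]
    b <- out$auroc[out$strategy == st & out$k == kk]
    if (length(a) >= 2 && length(b) >= 2) {
      tt[[paste(ref, "vs", st, "k", kk)]] <- stats::t.test(a, b)
    }
  }
  attr(out, "t_tests") <- tt
  out
}

#' Robustness of phenotype selection to seed removal
#'
#' Repeatedly removes a fraction of each disease's seed genes, recomputes
#' the nearest-phenotype selection by propagation distance and by Jaccard
#' seed overlap, and measures stability as the overlap of the perturbed
#' top-k with the original top-k.
#'
#' @inheritParams benchmark_gene_recovery
#' @param k Selection size; default 20 (the clustering context).
#' @param removal_fractions Fractions of seed genes removed; default
#'   `c(0.6, 0.8)`.
#' @param n_repeats Random removals per disease and fraction; default 10.
#' @param rng_seed Integer seed.
#' @return Data frame of `disease_id`, `fraction`, `repeat_id`, `strategy`,
#'   `stability` (in `[0, 1]`), with attributes `summary` (mean stability
#'   per strategy and fraction) and `t_tests` (two-sample t-test
#'   propagation vs jaccard per fraction). Diseases whose seed set is too
#'   small to lose the fraction and keep one seed are skipped with a note.
#' @export
selection_robustness <- function(diseases, mouse_traits, network,
                                 config = propagation_config(), k = 20L,
                                 removal_fractions = c(0.6, 0.8),
                                 n_repeats = 10L, mouse_profiles = NULL,
                                 rng_seed = NULL) {
  if (is.null(mouse_profiles)) {
    mouse_profiles <- propagate_traits(network, mouse_traits, config)
  }
  rows <- list()
  for (di in seq_along(diseases)) {
    dis <- diseases[[di]]
    base_prof <- propagate_traits(network, list(dis), config)[, 1]
    orig <- list(
      propagation = select_nearest_phenotypes(base_prof, mouse_profiles, k = k),
      jaccard = select_nearest_phenotypes(base_prof, mouse_profiles, k = k,
                                          strategy = "jaccard_topk",
                                          disease_seeds = dis$seeds,
                                          mouse_traits = mouse_traits))
    for (f in removal_fractions) {
      n_keep <- length(dis$seeds) - floor(f * length(dis$seeds))
      if (n_keep < 1) {
        message(sprintf("disease %s skipped at fraction %g: too few seeds",
                        dis$trait_id, f))
        next
      }
      for (rep_i in seq_len(n_repeats)) {
        if (!is.null(rng_seed)) {
          set.seed(derive_seed(rng_seed, di * 10000L + round(f * 100) * 100L + rep_i))
        }
        keep <- sample(dis$seeds, n_keep)
        keep_in_net <- intersect(keep, rownames(mouse_profiles))
        if (length(keep_in_net) == 0) next
        prof <- propagate_traits(network, list(keep_in_net), config)[, 1]
        for (st in c("propagation", "jaccard")) {
          sel <- if (st == "propagation") {
            select_nearest_phenotypes(prof, mouse_profiles, k = k)
          } else {
            select_nearest_phenotypes(prof, mouse_profiles, k = k,
                                      strategy = "jaccard_topk",
                                      disease_seeds = keep,
                                      mouse_traits = mouse_traits)
          }
          stab <- length(intersect(sel$phenotype_id,
                                   orig[[st]]$phenotype_id)) / k
          rows[[length(rows) + 1L]] <- data.frame(
            disease_id = dis$trait_id, fraction = f, repeat_id = rep_i,
            strategy = st, stability = stab, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  smry <- stats::aggregate(stability ~ strategy + fraction, out, mean)
  tt <- list()
  for (f in unique(out$fraction)) {
    a <- out$stability[out$strategy == "propagation" & out$fraction == f]
    b <- out$stability[out$strategy == "jaccard" & out$fraction == f]
    if (length(a) >= 2 && stats::sd(c(a, b)) > 0) {
      tt[[as.character(f)]] <- stats::t.test(a, b)
    }
  }
  attr(out, "summary") <- smry
  attr(out, "t_tests") <- tt
  out
}
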