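#' Jaccard distance matrix between trait seed sets
#'
#' Distance between two traits is one minus the intersection-over-union of
#' their seed gene sets; disjoint sets are at distance 1.
#'
#' @param traits List of [trait_seed_set()] objects (>= 2).
#' @return Symmetric matrix with zero diagonal and attribute
#'   `metric = "jaccard"`.
#' @export
jaccard_distance_matrix <- function(traits) {
  if (length(traits) < 2) stopf("need at least two traits")
  sets <- lapply(traits, `[[`, "seeds")
  if (any(lengths(sets) == 0)) stopf("empty seed set")
  ids <- vapply(traits, `[[`, "", "trait_id")
  n <- length(sets)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    uni <- length(union(sets[[i]], sets[[j]]))
    D[i, j] <- D[j, i] <- 1 - inter / uni
  }
  attr(D, "metric") <- "jaccard"
  D
}

#' Euclidean distance matrix between z-scored propagation profiles
#'
#' Each trait's profile is standardized across genes ([zscore_profile()]),
#' then pairwise Euclidean distances are taken between traits.
#'
#' @param profiles Genes x traits score matrix (e.g. from
#'   [propagate_traits()]), or a list of `propagation_profile` objects over
#'   an identical node set.
#' @return Symmetric matrix with attribute `metric = "euclidean_zscore"`.
#' @export
propagation_distance_matrix <- function(profiles) {
  X <- profiles_as_matrix(profiles)
  if (ncol(X) < 2) stopf("need at least two profiles")
  Z <- zscore_columns(X)
  D <- as.matrix(stats::dist(t(Z)))
  attr(D, "metric") <- "euclidean_zscore"
  D
}

profiles_as_matrix <- function(profiles) {
  if (is.matrix(profiles)) return(profiles)
  stopifnot(is.list(profiles))
  nodes <- names(profiles[[1]]$scores)
  for (p in profiles) {
    if (!identical(names(p$scores), nodes)) stopf("profiles cover different node sets")
  }
  X <- vapply(profiles, function(p) p$scores, numeric(length(nodes)))
  colnames(X) <- vapply(seq_along(profiles), function(i) {
    profiles[[i]]$trait_id %||% paste0("trait", i)
  }, character(1))
  rownames(X) <- nodes
  X
}

#' Hierarchically cluster traits from a distance matrix
#'
#' Agglomerates with the Ward-D2 update rule (Lance-Williams recurrence on
#' squared distances) by default, matching the convention for clustering
#' traits on propagation distances.
#'
#' @param dist Symmetric trait distance matrix.
#' @param linkage Linkage method passed to [stats::hclust()]; default
#'   `"ward.D2"`.
#' @param k Optional number of flat clusters to cut the tree into (the joint
#'   human+mouse analysis uses 11).
#' @return List with `hclust` (the tree) and `labels` (named cluster ids if
#'   `k` was given, else `NULL`).
#' @export
cluster_traits <- function(dist, linkage = "ward.D2", k = NULL) {
  hc <- stats::hclust(stats::as.dist(dist), method = linkage)
  labels <- NULL
  if (!is.null(k)) {
    if (k > nrow(dist)) stopf("k = %d exceeds the number of traits (%d)", k, nrow(dist))
    labels <- stats::cutree(hc, k = k)
  }
  list(hclust = hc, labels = labels)
}

#' Recovery of trait pairs with shared clinical phenotypes
#'
#' Scores every unordered trait pair by the negative of its distance and
#' asks how well that score separates pairs that share at least one organ
#' phenotype (positives) from pairs that share none. The AUROC is computed
#' by the Mann-Whitney rank statistic; its confidence interval by a
#' stratified bootstrap that resamples positive and negative pairs
#' independently with replacement (percentile 95% CI). Per-organ AUROCs
#' take as positives the pairs in which both traits show that organ
#' phenotype; by default the negatives include pairs sharing other
#' phenotypes (`exclusive_negatives = TRUE` removes them).
#'
#' @param dist Trait distance matrix (e.g. from [jaccard_distance_matrix()]
#'   or [propagation_distance_matrix()]).
#' @param annotations Named list mapping every trait id in `dist` to its
#'   organ phenotype labels.
#' @param n_boot Bootstrap replicates; default 2000 stratified replicates.
#' @param rng_seed Integer seed for the bootstrap.
#' @param exclusive_negatives Per-organ analysis only: drop negative pairs
#'   that share a different phenotype. Default `FALSE`.
#' @return A `recovery_result` list: `auroc`, `ci_low`, `ci_high`,
#'   `n_positive_pairs`, `n_negative_pairs`, `per_phenotype` (named AUROC
#'   vector).
#' @export
evaluate_phenotype_recovery <- function(dist, annotations, n_boot = 2000L,
                                        rng_seed = NULL,
                                        exclusive_negatives = FALSE) {
  ids <- rownames(dist)
  miss <- setdiff(ids, names(annotations))
  if (length(miss)) stopf("traits without annotation: %s", paste(miss, collapse = ", "))
  pr <- utils::combn(seq_along(ids), 2)
  score <- -dist[cbind(pr[1, ], pr[2, ])]
  shared <- mapply(function(i, j) {
    length(intersect(annotations[[ids[i]]], annotations[[ids[j]]])) > 0
  }, pr[1, ], pr[2, ])
  if (all(shared) || !any(shared)) {
    stopf("need both phenotype-sharing and non-sharing trait pairs")
  }
  auc <- auroc(score, shared)

  if (!is.null(rng_seed)) set.seed(rng_seed)
  pos <- which(shared); neg <- which(!shared)
  boot <- vapply(seq_len(n_boot), function(b) {
    ip <- sample(pos, length(pos), replace = TRUE)
    ineg <- sample(neg, length(neg), replace = TRUE)
    auroc(c(score[ip], score[ineg]),
          c(rep(TRUE, length(ip)), rep(FALSE, length(ineg))))
  }, numeric(1))
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)

  organs <- sort(unique(unlist(annotations[ids])))
  per <- vapply(organs, function(org) {
    both <- mapply(function(i, j) {
      org %in% annotations[[ids[i]]] && org %in% annotations[[ids[j]]]
    }, pr[1, ], pr[2, ])
    keep <- if (exclusive_negatives) both | !shared else rep(TRUE, length(both))
    if (!any(both[keep]) || all(both[keep])) return(NA_real_)
    auroc(score[keep], both[keep])
  }, numeric(1))

  structure(list(auroc = auc, ci_low = min(ci[1], auc), ci_high = max(ci[2], auc),
                 n_positive_pairs = length(pos), n_negative_pairs = length(neg),
                 per_phenotype = per, n_boot = as.integer(n_boot)),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("<recovery_result> AUROC %.3f (95%% CI %.3f-%.3f), %d positive / %d negative pairs\n",
              x$auroc, x$ci_low, x$ci_high, x$n_positive_pairs, x$n_negative_pairs))
  invisible(x)
}
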