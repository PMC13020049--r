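#' Propagation settings
#'
#' Bundles the parameters of the personalized-PageRank random walk with
#' restart. `damping` is the probability of following an edge at each step
#' (its complement is the restart probability); the fixed point solves
#' \eqn{x = d P^T x + (1 - d) r} with \eqn{P} the (optionally weighted)
#' row-stochastic transition matrix and \eqn{r} the restart distribution,
#' uniform over the seed genes.
#'
#' @param damping Probability of following an edge, in `[0, 1)`. Default 0.85,
#'   the convention of the standard PageRank implementations.
#' @param tol Convergence tolerance on the L1 residual between iterates.
#' @param max_iter Iteration cap for the power method.
#' @param weighted Use edge confidence weights as transition weights
#'   (default); `FALSE` treats the network as unweighted.
#' @param method `"power"` (default) iterates to the fixed point; `"linear"`
#'   solves the equivalent sparse linear system \eqn{(I - d P^T) y = r} and
#'   normalizes, which shares one factorization across many restart vectors.
#'   Both return the same profile to numerical precision.
#' @return A `propagation_config` list.
#' @export
propagation_config <- function(damping = 0.85, tol = 1e-12, max_iter = 1000L,
                               weighted = TRUE, method = c("power", "linear")) {
  method <- match.arg(method)
  if (damping < 0 || damping >= 1) stopf("damping must be in [0, 1), got %g", damping)
  if (tol <= 0) stopf("tol must be > 0")
  structure(list(damping = damping, tol = tol, max_iter = as.integer(max_iter),
                 weighted = weighted, method = method),
            class = "propagation_config")
}

# Column-stochastic transition operator t(P) of a network, plus dangling flags.
transition_operator <- function(network, weighted = TRUE) {
  use_w <- weighted && "weight" %in% igraph::edge_attr_names(network)
  A <- igraph::as_adjacency_matrix(network, attr = if (use_w) "weight" else NULL,
                                   sparse = TRUE)
  A <- methods::as(A, "CsparseMatrix")
  s <- Matrix::rowSums(A)
  dangling <- s == 0
  Pt <- Matrix::t(Matrix::Diagonal(x = ifelse(dangling, 0, 1 / pmax(s, 1e-300))) %*% A)
  list(Pt = Pt, dangling = dangling, nodes = rownames(A))
}

# Block propagation: R is a (nodes x k) matrix of restart distributions
# (columns sum to 1). Mass reaching a dangling node is teleported back to the
# column's own restart distribution.
propagate_block <- function(op, R, config) {
  d <- config$damping
  R <- methods::as(R, "CsparseMatrix")
  if (d == 0) return(as.matrix(R))
  if (config$method == "linear") {
    # Fixed point with dangling->restart teleport equals the normalized
    # solution of (I - d*Pt) y = r (see methods vignette).
    n <- nrow(op$Pt)
    A <- Matrix::Diagonal(n) - d * op$Pt
    Y <- as.matrix(Matrix::solve(A, R))
    return(sweep(Y, 2, colSums(Y), "/"))
  }
  X <- as.matrix(R)
  dang <- which(op$dangling)
  for (iter in seq_len(config$max_iter)) {
    Xn <- d * as.matrix(op$Pt %*% X)
    dm <- if (length(dang)) colSums(X[dang, , drop = FALSE]) else numeric(ncol(X))
    Xn <- Xn + as.matrix(R %*% Matrix::Diagonal(x = d * dm + (1 - d), n = ncol(X)))
    res <- max(colSums(abs(Xn - X)))
    X <- Xn
    if (res < config$tol) return(X)
  }
  stopf("propagation did not converge in %d iterations (L1 residual %.3g)",
        config$max_iter, res)
}

# Restart matrix: uniform over each seed set; drops seeds missing from the
# network with a warning, errors if a set loses all its seeds.
restart_matrix <- function(nodes, seed_sets) {
  k <- length(seed_sets)
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (s in seq_len(k)) {
    seeds <- unique(seed_sets[[s]])
    keep <- seeds[seeds %in% nodes]
    if (length(keep) < length(seeds)) {
      warning(sprintf("%d seed gene(s) absent from the network were dropped",
                      length(seeds) - length(keep)))
    }
    if (length(keep) == 0) stopf("no seed genes present in the network")
    idx <- match(keep, nodes)
    i <- c(i, idx); j <- c(j, rep.int(s, length(idx)))
    x <- c(x, rep.int(1 / length(idx), length(idx)))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(length(nodes), k))
}

#' Network propagation for one trait
#'
#' Runs a random walk with restart from the trait's seed genes and returns
#' the stationary visiting probability of every gene in the network. Seed
#' genes each receive equal restart weight; the profile sums to 1.
#'
#' @param network An [igraph::igraph] interaction network (see
#'   [load_network()]).
#' @param seeds Character vector of seed genes; seeds absent from the network
#'   are dropped with a warning.
#' @param config A [propagation_config()].
#' @param trait_id Optional identifier stored with the profile.
#' @return A `propagation_profile`: list with `trait_id`, `scores` (named
#'   numeric over all network nodes, summing to 1) and `config`.
#' @export
propagate <- function(network, seeds, config = propagation_config(),
                      trait_id = NULL) {
  op <- transition_operator(network, config$weighted)
  R <- restart_matrix(op$nodes, list(seeds))
  x <- drop(propagate_block(op, R, config))
  names(x) <- op$nodes
  structure(list(trait_id = trait_id, scores = x, config = config),
            class = "propagation_profile")
}

#' Network propagation for many traits at once
#'
#' Propagates every trait's seed set over the same network in one block
#' computation (the transition operator is built once).
#'
#' @param network Interaction network.
#' @param traits List of [trait_seed_set()] objects, or a named list of seed
#'   gene vectors.
#' @param config A [propagation_config()].
#' @return Numeric matrix, genes x traits, each column summing to 1.
#' @export
propagate_traits <- function(network, traits, config = propagation_config()) {
  seed_sets <- lapply(traits, function(t) if (is.list(t)) t$seeds else t)
  ids <- vapply(seq_along(traits), function(i) {
    t <- traits[[i]]
    if (is.list(t) && !is.null(t$trait_id)) t$trait_id
    else names(traits)[i] %||% paste0("trait", i)
  }, character(1))
  op <- transition_operator(network, config$weighted)
  R <- restart_matrix(op$nodes, seed_sets)
  X <- propagate_block(op, R, config)
  dimnames(X) <- list(op$nodes, ids)
  X
}

#' Standardize a propagation profile
#'
#' z-scores a single trait's per-gene propagation scores across all genes
#' (mean 0, SD 1; sample SD convention).
#'
#' @param profile A `propagation_profile`, or a numeric vector of scores.
#' @return Named numeric vector of z-scores.
#' @export
zscore_profile <- function(profile) {
  x <- if (inherits(profile, "propagation_profile")) profile$scores else profile
  if (length(unique(x)) < 2) stopf("cannot z-score a constant profile")
  (x - mean(x)) / stats::sd(x)
}

# Column-wise z-scoring of a genes x traits score matrix.
zscore_columns <- function(X) {
  Z <- scale(X)
  attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  Z
}

#' Permutation-null empirical p-values for a propagation profile
#'
#' Corrects for network bias towards well-connected genes: the observed
#' profile is compared against profiles from `n_permutations` random seed
#' sets of the same size, drawn uniformly (without replacement) from all
#' network nodes. The add-one empirical p-value for gene g is
#' \eqn{(1 + \#\{b : s_b(g) \ge s_{obs}(g)\}) / (B + 1)}, never zero.
#'
#' @inheritParams propagate
#' @param n_permutations Number of random seed sets (default 1000).
#' @param rng_seed Integer seed making the permutations reproducible.
#' @param degree_matched If `TRUE`, permutation seeds are sampled from degree
#'   bins matched to the observed seeds (sensitivity analysis); default
#'   `FALSE`, uniform sampling.
#' @return A `permutation_null`: list with `trait_id`, `n_permutations`,
#'   `pvalues` (named, in (0, 1]) and the observed `scores`.
#' @export
permutation_pvalues <- function(network, seeds, config = propagation_config(),
                                n_permutations = 1000L, rng_seed = NULL,
                                trait_id = NULL, degree_matched = FALSE) {
  if (n_permutations < 1) stopf("n_permutations must be >= 1")
  op <- transition_operator(network, config$weighted)
  nodes <- op$nodes
  seeds <- unique(seeds[seeds %in% nodes])
  if (length(seeds) == 0) stopf("no seed genes present in the network")
  obs <- drop(propagate_block(op, restart_matrix(nodes, list(seeds)), config))

  if (!is.null(rng_seed)) set.seed(rng_seed)
  k <- length(seeds)
  perm_sets <- if (degree_matched) {
    deg <- igraph::degree(network)[nodes]
    bins <- cut(rank(deg, ties.method = "first"), breaks = 10, labels = FALSE)
    seed_bins <- bins[match(seeds, nodes)]
    lapply(seq_len(n_permutations), function(b) {
      unlist(lapply(seed_bins, function(bb) sample(nodes[bins == bb], 1L)))
    })
  } else {
    lapply(seq_len(n_permutations), function(b) sample(nodes, k))
  }

  ge <- numeric(length(nodes))
  chunk <- 250L
  for (start in seq(1L, n_permutations, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_permutations)
    S <- propagate_block(op, restart_matrix(nodes, perm_sets[idx]), config)
    ge <- ge + rowSums(S >= obs)
  }
  p <- (1 + ge) / (n_permutations + 1)
  names(p) <- names(obs) <- nodes
  structure(list(trait_id = trait_id, n_permutations = as.integer(n_permutations),
                 pvalues = p, scores = obs),
            class = "permutation_null")
}
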