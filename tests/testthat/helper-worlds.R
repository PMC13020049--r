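# Shared fixtures, built in code.

library(igraph)

# A small undirected weighted graph from an edge triple list.
toy_graph <- function(edges) {
  df <- data.frame(gene_a = edges[[1]], gene_b = edges[[2]],
                   weight = edges[[3]], stringsAsFactors = FALSE)
  phenoprop:::network_from_edges(df)
}

# A 5-node weighted path a-b-c-d-e.
path5 <- function() {
  toy_graph(list(c("a", "b", "c", "d"), c("b", "c", "d", "e"),
                 c(0.9, 0.5, 0.7, 0.8)))
}

# Random connected-ish Erdos-Renyi test graph with weights.
random_graph <- function(n, p = 0.1, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  igraph::E(g)$weight <- stats::runif(igraph::ecount(g), 0.4, 1)
  g
}

# Default small planted world for fast tests.
small_world <- function(seed = 1, ...) {
  args <- list(rng_seed = seed, n_genes = 200L, n_modules = 6L,
               module_size = 18L, n_human_traits = 6L, n_mouse_traits = 18L,
               human_seeds_range = c(4L, 10L))
  dots <- list(...)
  args[names(dots)] <- dots
  generate_world(do.call(synthetic_world_config, args))
}

# Dense-solve propagation oracle: solves (I - d*Pt - d*r*dangling') x = (1-d) r.
dense_propagate_oracle <- function(network, seeds, damping, weighted = TRUE) {
  op <- phenoprop:::transition_operator(network, weighted)
  n <- length(op$nodes)
  r <- numeric(n)
  idx <- match(intersect(seeds, op$nodes), op$nodes)
  r[idx] <- 1 / length(idx)
  A <- diag(n) - damping * as.matrix(op$Pt) -
    damping * r %*% t(as.numeric(op$dangling))
  x <- solve(A, (1 - damping) * r)
  names(x) <- op$nodes
  x
}

withr_local_tempdir <- function() {
  d <- tempfile("phenoprop")
  dir.create(d)
  d
}

# Brute-force AUROC: fraction of concordant (positive, negative) pairs,
# ties counting one half.
bruteforce_auroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
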