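#' Recursive Walktrap partition of a protein network
#'
#' Runs Walktrap community detection on the full network (connected
#' components handled independently) and re-clusters every module larger
#' than `max_size` as an induced subgraph, recursing until each module has
#' at most `max_size` genes or `max_rounds` clustering rounds have been
#' spent on its lineage. Protein complexes are expected to be small, hence
#' the default cap of 20 genes. Module ids encode the lineage
#' (e.g. `m.2.1` = community 1 of round-2 re-clustering of community 2).
#'
#' @param network Interaction network (edge weights, if present, are used by
#'   Walktrap).
#' @param max_size Largest module size that is not re-clustered; default 20.
#' @param max_rounds Maximum clustering rounds per lineage; default 5. A
#'   module that Walktrap cannot split further is retained unsplit.
#' @param steps Random-walk length for Walktrap; default 4.
#' @return A `module_partition`: data frame with columns `gene`,
#'   `module_id`, `round` (round of creation), covering every network node
#'   exactly once.
#' @export
recursive_walktrap <- function(network, max_size = 20L, max_rounds = 5L,
                               steps = 4L) {
  genes <- character(0); mods <- character(0); rounds <- integer(0)
  emit <- function(g, id, round) {
    genes <<- c(genes, g)
    mods <<- c(mods, rep(id, length(g)))
    rounds <<- c(rounds, rep(as.integer(round), length(g)))
  }
  recurse <- function(g, prefix, round) {
    comp <- igraph::components(g)
    multi <- comp$no > 1
    for (ci in seq_len(comp$no)) {
      vs <- igraph::V(g)$name[comp$membership == ci]
      cid <- if (multi) paste0(prefix, ".c", ci) else prefix
      if (length(vs) == 1) { emit(vs, cid, round); next }
      sub <- igraph::induced_subgraph(g, vs)
      wt <- igraph::cluster_walktrap(sub, steps = steps)
      mem <- igraph::membership(wt)
      if (length(unique(mem)) == 1) {
        # unsplittable: further rounds are no-ops, lineage is exhausted
        emit(vs, cid, if (length(vs) > max_size) max_rounds else round)
        next
      }
      for (m in sort(unique(mem))) {
        gm <- names(mem)[mem == m]
        mid <- paste0(cid, ".", m)
        if (length(gm) <= max_size || round >= max_rounds) {
          emit(gm, mid, round)
        } else {
          recurse(igraph::induced_subgraph(sub, gm), mid, round + 1)
        }
      }
    }
  }
  recurse(network, "m", 1L)
  part <- data.frame(gene = genes, module_id = mods, round = rounds,
                     stringsAsFactors = FALSE)
  part <- part[order(part$gene), ]
  rownames(part) <- NULL
  stopifnot(identical(sort(part$gene), sort(igraph::V(network)$name)),
            !anyDuplicated(part$gene))
  class(part) <- c("module_partition", "data.frame")
  part
}

#' Associate protein modules with traits
#'
#' A module is tested per trait with a one-sided (greater) Wilcoxon rank-sum
#' test of the trait's propagation scores inside the module against the
#' scores over the full network (the module included in the reference, or
#' its complement with `reference = "complement"`). P-values are BH-adjusted
#' across all tested modules within each trait (or jointly with
#' `adjust_scope = "global"`), and a module is called associated when its
#' adjusted p-value is below `alpha` and it contains at least one of the
#' trait's seed genes.
#'
#' @param partition A [recursive_walktrap()] partition.
#' @param profiles Genes x traits propagation score matrix over the same
#'   node set.
#' @param traits List of [trait_seed_set()] objects matching the profile
#'   columns.
#' @param alpha Significance level on the adjusted p-value; default 0.05.
#' @param reference `"all"` (default) compares module scores against all
#'   network scores; `"complement"` against non-module scores only.
#' @param adjust_scope BH adjustment within each trait (default) or across
#'   all module-trait pairs.
#' @return Data frame of `module_id`, `trait_id`, `n_genes`,
#'   `n_trait_seeds_in_module`, `wilcoxon_p`, `adjusted_p`, `associated`.
#'   Modules with fewer than 2 genes are skipped.
#' @export
associate_modules <- function(partition, profiles, traits, alpha = 0.05,
                              reference = c("all", "complement"),
                              adjust_scope = c("per_trait", "global")) {
  reference <- match.arg(reference)
  adjust_scope <- match.arg(adjust_scope)
  nodes <- rownames(profiles)
  stopifnot(setequal(partition$gene, nodes))
  mod_genes <- split(partition$gene, partition$module_id)
  mod_genes <- mod_genes[lengths(mod_genes) >= 2]
  ids <- vapply(traits, `[[`, "", "trait_id")
  stopifnot(all(ids %in% colnames(profiles)))

  res <- list()
  for (t in seq_along(traits)) {
    tid <- ids[t]
    sc <- profiles[, tid]
    names(sc) <- nodes
    p <- vapply(mod_genes, function(gm) {
      x <- sc[gm]
      y <- if (reference == "all") sc else sc[setdiff(nodes, gm)]
      wilcox_greater_p(x, y)
    }, numeric(1))
    nseed <- vapply(mod_genes, function(gm) {
      length(intersect(gm, traits[[t]]$seeds))
    }, integer(1))
    res[[tid]] <- data.frame(module_id = names(mod_genes), trait_id = tid,
                             n_genes = unname(lengths(mod_genes)),
                             n_trait_seeds_in_module = unname(nseed),
                             wilcoxon_p = unname(p), row.names = NULL,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (adjust_scope == "per_trait") {
    out$adjusted_p <- stats::ave(out$wilcoxon_p, out$trait_id,
                                 FUN = function(p) stats::p.adjust(p, "BH"))
  } else {
    out$adjusted_p <- stats::p.adjust(out$wilcoxon_p, "BH")
  }
  out$associated <- out$adjusted_p < alpha & out$n_trait_seeds_in_module >= 1
  out
}

# One-sided (greater) rank-sum p-value of x against reference y. Exact when
# feasible and tie-free; otherwise normal approximation with tie correction
# and continuity correction (the reference = "all" mode always has ties,
# since x is contained in y).
wilcox_greater_p <- function(x, y) {
  m <- length(x); n <- length(y)
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (!has_ties && m * n <= 1e6) {
    return(stats::wilcox.test(x, y, alternative = "greater", exact = TRUE)$p.value)
  }
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n / 2
  tie_tab <- table(r)
  sigma2 <- m * n / 12 * ((m + n + 1) - sum(tie_tab^3 - tie_tab) /
                            ((m + n) * (m + n - 1)))
  z <- (W - mu - 0.5) / sqrt(sigma2)
  stats::pnorm(z, lower.tail = FALSE)
}

#' Over-representation of a gene module in gene sets
#'
#' One-sided hypergeometric tail test of the overlap between the module and
#' each supplied gene set, within a fixed gene universe, with BH adjustment
#' across sets. This is the generic stand-in for annotating modules against
#' any functional collection.
#'
#' @param module_genes Character vector, a subset of `universe`.
#' @param gene_sets Named list of gene sets (intersected with the universe).
#' @param universe Background gene universe (nonempty).
#' @return Data frame of `set_name`, `set_size`, `overlap`, `p`, `q`.
#' @export
overrepresentation_test <- function(module_genes, gene_sets, universe) {
  if (length(universe) == 0) stopf("empty gene universe")
  universe <- unique(universe)
  if (!all(module_genes %in% universe)) stopf("module genes must lie in the universe")
  module_genes <- unique(module_genes)
  N <- length(universe); n <- length(module_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    k <- length(intersect(set, module_genes))
    p <- stats::phyper(k - 1, length(set), N - length(set), n, lower.tail = FALSE)
    data.frame(set_name = nm, set_size = length(set), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  out
}

#' Class-composition fractions of protein modules
#'
#' For each module, the fraction of member genes that are prioritized
#' candidates (aggregated across traits), known ciliary genes, or known
#' disease genes; modules are flagged for display when any fraction exceeds
#' `display_min`.
#'
#' @param partition A [recursive_walktrap()] partition.
#' @param candidate_genes Character vector, or per-trait list of character
#'   vectors (aggregated by union).
#' @param ciliary_genes,known_genes Character vectors of gene classes.
#' @param display_min Display threshold on the maximum fraction; default 0.6.
#' @return Data frame of `module_id`, `n_genes`, `frac_candidate`,
#'   `frac_ciliary`, `frac_known`, `display`.
#' @export
module_composition_fractions <- function(partition, candidate_genes,
                                         ciliary_genes = character(),
                                         known_genes = character(),
                                         display_min = 0.6) {
  cand <- unique(unlist(candidate_genes))
  mod_genes <- split(partition$gene, partition$module_id)
  frac <- function(gm, cls) length(intersect(gm, cls)) / length(gm)
  out <- data.frame(
    module_id = names(mod_genes),
    n_genes = lengths(mod_genes),
    frac_candidate = vapply(mod_genes, frac, numeric(1), cls = cand),
    frac_ciliary = vapply(mod_genes, frac, numeric(1), cls = ciliary_genes),
    frac_known = vapply(mod_genes, frac, numeric(1), cls = known_genes),
    stringsAsFactors = FALSE)
  out$display <- pmax(out$frac_candidate, out$frac_ciliary, out$frac_known) > display_min
  rownames(out) <- NULL
  out
}
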