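#' Load an interaction network from a TSV edge list
#'
#' Reads a tab-delimited edge list (header required; columns `gene_a`,
#' `gene_b`, `weight`, optional `source`), applies the confidence filter,
#' removes self-loops and collapses duplicate unordered pairs keeping the
#' maximum weight. The node set is the set of endpoints of surviving edges,
#' ordered lexicographically.
#'
#' @param path Path to the edge-list TSV.
#' @param min_weight Minimum edge confidence retained; the threshold is
#'   inclusive (an edge with weight exactly `min_weight` is kept). Default
#'   0.4, the usual STRING-style confidence cut.
#' @return An undirected [igraph::igraph] with a `weight` edge attribute.
#' @export
load_network <- function(path, min_weight = 0.4) {
  if (!file.exists(path)) stopf("network file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  if (nrow(df) == 0) stopf("empty network file: %s", path)
  need <- c("gene_a", "gene_b", "weight")
  if (!all(need %in% names(df))) {
    stopf("edge list must have header columns gene_a, gene_b, weight")
  }
  w <- suppressWarnings(as.numeric(df$weight))
  bad <- which(!is.finite(w) | w <= 0 | df$gene_a == "" | df$gene_b == "" |
                 is.na(df$gene_a) | is.na(df$gene_b))
  if (length(bad)) {
    stopf("malformed edge row at line %d of %s", bad[1] + 1L, path)
  }
  df$weight <- w
  network_from_edges(df, min_weight = min_weight)
}

# Build the network from an in-memory edge data frame (gene_a, gene_b, weight).
network_from_edges <- function(df, min_weight = 0) {
  df <- df[df$weight >= min_weight & df$gene_a != df$gene_b, , drop = FALSE]
  if (nrow(df) == 0) stopf("no edges survive the filters")
  a <- pmin(df$gene_a, df$gene_b)
  b <- pmax(df$gene_a, df$gene_b)
  key <- paste(a, b, sep = "\r")
  w <- tapply(df$weight, key, max)
  parts <- strsplit(names(w), "\r", fixed = TRUE)
  edges <- data.frame(gene_a = vapply(parts, `[`, "", 1L),
                      gene_b = vapply(parts, `[`, "", 2L),
                      weight = as.numeric(w), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::permute(g, match(igraph::V(g)$name, sort(igraph::V(g)$name)))
}

#' Write a network as a TSV edge list
#'
#' Inverse of [load_network()]: reloading the written file reproduces the
#' same node and edge sets.
#'
#' @param network Interaction network.
#' @param path Output path.
#' @export
write_network <- function(network, path) {
  el <- igraph::as_data_frame(network, what = "edges")
  df <- data.frame(gene_a = pmin(el$from, el$to), gene_b = pmax(el$from, el$to),
                   weight = el$weight %||% rep(1, nrow(el)))
  df <- df[order(df$gene_a, df$gene_b), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' A trait and its seed genes
#'
#' Container for one trait (a human disease or a mouse phenotype) with its
#' curated seed genes and, for human traits, organ-phenotype annotations.
#'
#' @param trait_id Trait identifier.
#' @param trait_class `"human"` or `"mouse"`.
#' @param seeds Character vector of seed genes (deduplicated; must be
#'   nonempty).
#' @param organs Character vector of organ phenotypes (human traits).
#' @param modules Integer ids of generating modules (synthetic worlds only;
#'   ground truth, not used by the methods).
#' @return A `trait_seed_set` list.
#' @export
trait_seed_set <- function(trait_id, trait_class = c("human", "mouse"),
                           seeds, organs = character(), modules = integer()) {
  trait_class <- match.arg(trait_class)
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0) stopf("trait %s has no seed genes", trait_id)
  structure(list(trait_id = trait_id, trait_class = trait_class,
                 seeds = seeds, organs = unique(organs), modules = modules),
            class = "trait_seed_set")
}

#' @export
print.trait_seed_set <- function(x, ...) {
  cat(sprintf("<trait_seed_set> %s (%s): %d seed genes%s\n", x$trait_id,
              x$trait_class, length(x$seeds),
              if (length(x$organs)) paste0("; organs: ",
                                           paste(x$organs, collapse = ", ")) else ""))
  invisible(x)
}

#' Filter gene-trait evidence into seed sets
#'
#' Applies the evidence-score filters used to define seed genes: a record
#' survives if its score strictly exceeds its source's threshold (per-source
#' overrides, e.g. a stricter ClinVar cut, else the default), and traits with
#' too few surviving genes are dropped. Genes absent from a supplied network
#' are flagged in the `missing_from_network` attribute but kept (they are
#' dropped, with a warning, at propagation time).
#'
#' @param records Data frame with columns `gene`, `trait_id`, `trait_class`
#'   (`human`/`mouse`), `source`, `score` (in `[0, 1]`).
#' @param default_threshold Score threshold (strict `>`); default 0.5.
#' @param per_source_thresholds Named numeric vector of per-source overrides;
#'   default `c(ClinVar = 0.8)`.
#' @param min_seeds Named vector of minimum surviving seed counts per trait
#'   class; default `c(human = 2, mouse = 10)` (mouse models specific to a
#'   single gene are excluded).
#' @param organ_annotations Optional named list mapping `trait_id` to organ
#'   phenotype labels.
#' @param network Optional network used to flag out-of-network genes.
#' @return List of [trait_seed_set()] objects (possibly empty, with a
#'   warning).
#' @export
filter_gene_trait_evidence <- function(records, default_threshold = 0.5,
                                       per_source_thresholds = c(ClinVar = 0.8),
                                       min_seeds = c(human = 2, mouse = 10),
                                       organ_annotations = NULL,
                                       network = NULL) {
  stopifnot(all(c("gene", "trait_id", "trait_class", "source", "score") %in%
                  names(records)))
  if (default_threshold < 0 || default_threshold > 1 ||
      any(per_source_thresholds < 0 | per_source_thresholds > 1)) {
    stopf("thresholds must lie in [0, 1]")
  }
  thr <- per_source_thresholds[records$source]
  thr[is.na(thr)] <- default_threshold
  keep <- records$score > thr
  surv <- records[keep, , drop = FALSE]
  if (nrow(surv) == 0) {
    warning("no gene-trait records survive the evidence filters")
    return(list())
  }
  nodes <- if (!is.null(network)) igraph::V(network)$name else NULL
  out <- list()
  for (tid in unique(surv$trait_id)) {
    rows <- surv[surv$trait_id == tid, ]
    cls <- rows$trait_class[1]
    genes <- unique(rows$gene)
    need <- if (cls %in% names(min_seeds)) min_seeds[[cls]] else 1
    if (length(genes) < need) next
    organs <- if (!is.null(organ_annotations)) organ_annotations[[tid]] %||% character()
              else character()
    ts <- trait_seed_set(tid, cls, genes, organs)
    if (!is.null(nodes)) {
      attr(ts, "missing_from_network") <- setdiff(genes, nodes)
    }
    out[[tid]] <- ts
  }
  if (length(out) == 0) warning("all traits dropped by the minimum-seed filter")
  out
}

#' Read a gene-set collection (GMT)
#'
#' Parses the standard GMT dialect: one set per line, tab-separated
#' `name`, `description`, then genes. Genes are deduplicated per set.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(nm)) {
    stopf("duplicate gene-set name in %s: %s", path, nm[duplicated(nm)][1])
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- nm
  sets
}

#' Write a gene-set collection (GMT)
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read trait organ-phenotype annotations
#'
#' Tab-delimited table with header columns `trait_id` and `organ`; one row
#' per (trait, organ) pair.
#'
#' @param path Path to the TSV.
#' @return Named list mapping trait id to a character vector of organ labels.
#' @export
read_organ_annotations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("trait_id", "organ") %in% names(df)))
  split(df$organ, df$trait_id)
}
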