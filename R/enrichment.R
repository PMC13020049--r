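#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment of gene sets in a
#' ranked gene list (the final prioritization ranking with the known seed
#' genes excluded). Walking down the ranking, hitting a set member adds its
#' |score|^`weight_exponent` (normalized), missing subtracts a constant;
#' the enrichment score (ES) is the maximum deviation from zero, positive
#' when the set concentrates at the top. Significance comes from gene-label
#' permutation: random sets of the same size; the add-one empirical p-value
#' is one-sided against the same-sign portion of the null (the classic GSEA
#' convention, which keeps null p-values uniform), and NES = ES divided by
#' the mean |null ES| of the same sign. BH adjustment across retained sets.
#'
#' @param ranking Named numeric vector of gene scores (sorted internally,
#'   descending).
#' @param gene_sets Named list of gene sets; each is intersected with the
#'   ranked universe, sets larger than `max_size` are dropped and sets with
#'   empty intersection skipped with a note.
#' @param max_size Largest set size tested; default 2000.
#' @param min_size Smallest set size tested; default 2.
#' @param n_permutations Label permutations; default 1000.
#' @param weight_exponent Exponent on |score| for hit increments; default 1
#'   (classic weighted KS; 0 gives the unweighted statistic).
#' @param rng_seed Integer seed.
#' @return Data frame of `set_name`, `set_size`, `es`, `nes`, `p`, `q`.
#' @export
preranked_gsea <- function(ranking, gene_sets, max_size = 2000L, min_size = 2L,
                           n_permutations = 1000L, weight_exponent = 1,
                           rng_seed = NULL) {
  stopifnot(!is.null(names(ranking)))
  ord <- order(-ranking, names(ranking))
  s <- ranking[ord]
  genes <- names(s)
  N <- length(genes)
  w <- abs(s)^weight_exponent
  pos_of <- stats::setNames(seq_len(N), genes)

  sizes <- integer(0); keep_names <- character(0); hit_lists <- list()
  for (nm in names(gene_sets)) {
    hits <- sort(unname(pos_of[intersect(gene_sets[[nm]], genes)]))
    if (length(hits) == 0) { message(sprintf("set %s skipped: no overlap", nm)); next }
    if (length(hits) > max_size || length(hits) < min_size) next
    keep_names <- c(keep_names, nm)
    hit_lists[[nm]] <- hits
    sizes <- c(sizes, length(hits))
  }
  if (length(keep_names) == 0) {
    return(data.frame(set_name = character(), set_size = integer(),
                      es = numeric(), nes = numeric(), p = numeric(),
                      q = numeric()))
  }

  es_of <- function(hits) gsea_es(hits, w, N)
  es <- vapply(hit_lists, es_of, numeric(1))

  if (!is.null(rng_seed)) set.seed(rng_seed)
  # one null per distinct set size, shared across sets of that size
  null_by_size <- list()
  for (m in unique(sizes)) {
    null_by_size[[as.character(m)]] <- vapply(seq_len(n_permutations), function(b) {
      es_of(sort(sample.int(N, m)))
    }, numeric(1))
  }
  p <- numeric(length(es)); nes <- numeric(length(es))
  for (i in seq_along(es)) {
    nulls <- null_by_size[[as.character(sizes[i])]]
    # classic GSEA convention: compare against the same-sign null portion
    same <- nulls[if (es[i] >= 0) nulls >= 0 else nulls < 0]
    beyond <- if (es[i] >= 0) sum(same >= es[i]) else sum(same <= es[i])
    p[i] <- (1 + beyond) / (length(same) + 1)
    nes[i] <- if (length(same)) es[i] / mean(abs(same)) else NA_real_
  }
  out <- data.frame(set_name = keep_names, set_size = sizes, es = unname(es),
                    nes = nes, p = p, q = stats::p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Signed maximal deviation of the GSEA running sum, computed from the
# sorted hit positions in O(set size). `w` = per-position hit weights over
# the full ranking, N = ranking length.
gsea_es <- function(hits, w, N) {
  m <- length(hits)
  wh <- w[hits]
  NR <- sum(wh)
  if (NR == 0) { wh <- rep(1, m); NR <- m }  # all-zero scores: unweighted
  miss <- 1 / (N - m)
  cumw <- cumsum(wh) / NR
  i <- seq_len(m)
  after <- cumw - (hits - i) * miss           # running sum just after hit i
  before <- c(0, cumw[-m]) - (hits - i) * miss  # just before hit i
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Count diseases with significant enrichment per gene set
#'
#' Tallies, for each gene set, in how many diseases it is significantly
#' enriched (BH-adjusted p below the threshold) across per-disease
#' [preranked_gsea()] results.
#'
#' @param results Named list (one element per disease) of `preranked_gsea`
#'   data frames over the same set collection.
#' @param q_threshold Significance threshold on the BH-adjusted p-value;
#'   default 0.05.
#' @return Data frame of `set_name`, `n_significant` (in
#'   `[0, n_diseases]`).
#' @export
count_significant_diseases <- function(results, q_threshold = 0.05) {
  all_sets <- unique(unlist(lapply(results, `[[`, "set_name")))
  counts <- vapply(all_sets, function(nm) {
    sum(vapply(results, function(df) {
      row <- df[df$set_name == nm, , drop = FALSE]
      nrow(row) > 0 && row$q[1] < q_threshold
    }, logical(1)))
  }, integer(1))
  data.frame(set_name = all_sets, n_significant = unname(counts),
             stringsAsFactors = FALSE)
}
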