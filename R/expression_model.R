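#' Scale an expression matrix across cell types
#'
#' Per-gene z-scoring across cell types (sample-SD convention), turning
#' absolute expression into relative expression patterns; appropriate when
#' the genes of interest are expressed at low absolute levels. Zero-variance
#' genes are dropped with a warning. Scaling is idempotent.
#'
#' @param matrix Numeric genes x cell-types matrix with row and column
#'   names.
#' @return Scaled matrix with attribute `scaled = TRUE`.
#' @export
scale_expression <- function(matrix) {
  if (ncol(matrix) < 2) stopf("need at least two cell types")
  v <- apply(matrix, 1, stats::sd)
  if (all(v == 0)) stopf("all genes have zero variance")
  if (any(v == 0)) {
    warning(sprintf("%d zero-variance gene(s) dropped", sum(v == 0)))
    matrix <- matrix[v > 0, , drop = FALSE]
  }
  out <- t(scale(t(matrix)))
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "scaled") <- TRUE
  out
}

#' Select informative cell types by ANOVA
#'
#' For each cell type, a one-way ANOVA (two groups: known disease genes vs
#' all other genes) on the scaled expression values; cell types with
#' p below `alpha` become model features.
#'
#' @param matrix Scaled expression matrix (see [scale_expression()]).
#' @param positive_genes Known disease genes present in the matrix (>= 2;
#'   at least 2 other genes required too).
#' @param alpha Selection threshold on the F-test p-value; default 0.01.
#' @return Data frame of `cell_type`, `f_statistic`, `p`, `selected`.
#' @export
select_celltypes_anova <- function(matrix, positive_genes, alpha = 0.01) {
  grp <- rownames(matrix) %in% positive_genes
  if (sum(grp) < 2 || sum(!grp) < 2) {
    stopf("need >= 2 positive and >= 2 other genes in the matrix")
  }
  res <- t(apply(matrix, 2, function(x) {
    a <- stats::anova(stats::lm(x ~ grp))
    c(a$`F value`[1], a$`Pr(>F)`[1])
  }))
  out <- data.frame(cell_type = colnames(matrix), f_statistic = res[, 1],
                    p = res[, 2], stringsAsFactors = FALSE)
  out$selected <- out$p < alpha
  rownames(out) <- NULL
  if (!any(out$selected)) warning("no cell type passes the ANOVA filter")
  out
}

#' Fit the expression-similarity model and score all genes
#'
#' Splits genes into training (90%) and held-out test (10% of the known
#' disease genes and 10% of all other genes), selects cell types by ANOVA
#' on the training set, fits a ridge-penalized logistic regression of
#' disease-gene status on the selected cell types, and scores every gene by
#' its predicted probability. The small L2 penalty guarantees a unique,
#' convergent fit under separation.
#'
#' @param matrix Scaled expression matrix.
#' @param positive_genes Known disease genes (>= 5 in the matrix).
#' @param holdout_frac Fraction of positives and of other genes held out;
#'   default 0.10.
#' @param alpha ANOVA selection threshold; default 0.01.
#' @param lambda Ridge penalty; default 1e-4.
#' @param rng_seed Integer seed for the split.
#' @return An `expression_model_fit`: `selected_celltypes`, `coefficients`
#'   (incl. intercept), `scores` (named, in (0,1), all genes),
#'   `holdout_auroc`, `test_genes`, `anova` (the selection table).
#' @export
fit_and_score_expression <- function(matrix, positive_genes,
                                     holdout_frac = 0.10, alpha = 0.01,
                                     lambda = 1e-4, rng_seed = NULL) {
  genes <- rownames(matrix)
  pos <- intersect(positive_genes, genes)
  if (length(pos) < 5) stopf("need >= 5 positive genes in the matrix")
  neg <- setdiff(genes, pos)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  test <- c(sample(pos, max(1L, round(holdout_frac * length(pos)))),
            sample(neg, max(1L, round(holdout_frac * length(neg)))))
  train <- setdiff(genes, test)

  sel <- select_celltypes_anova(matrix[train, , drop = FALSE],
                                pos, alpha = alpha)
  feats <- sel$cell_type[sel$selected]
  if (length(feats) == 0) stopf("no informative cell types; cannot fit the model")

  y <- as.numeric(train %in% pos)
  X <- matrix[train, feats, drop = FALSE]
  fit <- ridge_logistic(X, y, lambda)
  lin <- drop(matrix[, feats, drop = FALSE] %*% fit$beta) + fit$intercept
  scores <- stats::plogis(lin)
  names(scores) <- genes

  structure(list(
    selected_celltypes = feats,
    coefficients = c(`(Intercept)` = fit$intercept, fit$beta),
    scores = scores,
    holdout_auroc = auroc(scores[test], test %in% pos),
    test_genes = test, anova = sel,
    params = list(holdout_frac = holdout_frac, alpha = alpha,
                  lambda = lambda, rng_seed = rng_seed)),
    class = "expression_model_fit")
}

# Ridge-penalized logistic regression (glmnet backend); falls back to an
# unpenalized glm fit when there is a single feature column.
ridge_logistic <- function(X, y, lambda) {
  if (ncol(X) >= 2) {
    fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE)
    beta <- drop(as.matrix(fit$beta))
    list(intercept = as.numeric(fit$a0), beta = beta)
  } else {
    df <- data.frame(y = y, x = X[, 1])
    fit <- suppressWarnings(stats::glm(y ~ x, data = df, family = stats::binomial()))
    list(intercept = unname(stats::coef(fit)[1]),
         beta = stats::setNames(unname(stats::coef(fit)[2]), colnames(X)))
  }
}

#' @export
print.expression_model_fit <- function(x, ...) {
  cat(sprintf("<expression_model_fit> %d cell-type feature(s); holdout AUROC %.3f\n",
              length(x$selected_celltypes), x$holdout_auroc))
  invisible(x)
}
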