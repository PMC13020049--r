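# Classifier evaluation metrics. All are computed from first principles so
# that toy examples can be checked against brute-force threshold sweeps.

#' Area under the ROC curve
#'
#' Rank-based AUROC via the Mann-Whitney identity with midrank tie handling:
#' the probability that a random positive outscores a random negative, ties
#' counting one half.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Logical (or 0/1) vector of true labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stopf("AUROC needs both positives and negatives")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC polyline at distinct score thresholds, from (0,0) to (1,1).
# Tied scores form single vertices, so ties appear as diagonal segments.
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  last <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  tp <- cumsum(y)[last]; fp <- cumsum(!y)[last]
  list(fpr = c(0, fp / n0), tpr = c(0, tp / n1))
}

#' Area under the precision-recall curve
#'
#' Step-wise integral over distinct score thresholds:
#' \eqn{\sum_i prec_i (rec_i - rec_{i-1})}. A random scorer's PR AUC
#' approximates the class prevalence.
#'
#' @inheritParams auroc
#' @return PR AUC in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  if (n1 == 0 || sum(!labels) == 0) stopf("PR AUC needs both classes")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  last <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  tp <- cumsum(y)[last]
  prec <- tp / last
  rec <- tp / n1
  sum(prec * diff(c(0, rec)))
}

#' Standardized partial AUROC at high specificity
#'
#' Area under the ROC curve restricted to specificity in
#' `[1 - fpr_max, 1]` (i.e., false-positive rate in `[0, fpr_max]`),
#' integrated by trapezoids on the distinct-threshold ROC polyline with
#' linear interpolation at the boundary. With `standardize = TRUE` the
#' McClish correction maps the result so that a chance classifier scores 0.5
#' and a perfect one scores 1.
#'
#' @inheritParams auroc
#' @param fpr_max Upper end of the false-positive-rate window; default 0.05
#'   (specificity 0.95-1.0).
#' @param standardize Apply the McClish correction (default `TRUE`).
#' @return Partial AUROC (standardized to `[0, 1]` when `standardize`).
#' @export
partial_auroc <- function(scores, labels, fpr_max = 0.05, standardize = TRUE) {
  rc <- roc_points(scores, labels)
  fpr <- c(rc$fpr, 1); tpr <- c(rc$tpr, 1)
  area <- 0
  for (i in seq_len(length(fpr) - 1)) {
    x0 <- fpr[i]; x1 <- fpr[i + 1]
    if (x0 >= fpr_max) break
    y0 <- tpr[i]; y1 <- tpr[i + 1]
    if (x1 > fpr_max) {
      y1 <- y0 + (y1 - y0) * (fpr_max - x0) / (x1 - x0)
      x1 <- fpr_max
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  if (!standardize) return(area)
  amin <- fpr_max^2 / 2
  amax <- fpr_max
  0.5 * (1 + (area - amin) / (amax - amin))
}
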