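#' Mean absolute error between predicted and true images
#'
#' \eqn{MAE = \frac{1}{n}\sum_i |y_i - \hat y_i|} over all pixel entries of
#' all image pairs.
#'
#' @param pred,true numeric matrices/vectors or lists of them, matching
#'   shapes.
#' @return scalar MAE.
#' @export
mae <- function(pred, true) {
  if (is.list(pred) != is.list(true)) stop("shape mismatch")
  if (is.list(pred)) {
    if (length(pred) != length(true)) stop("shape mismatch")
    pred <- unlist(pred); true <- unlist(true)
  }
  if (length(pred) != length(true)) stop("shape mismatch")
  mean(abs(pred - true))
}

#' Average precision (area under the precision-recall curve)
#'
#' Items are ranked by decreasing score; AP is the step-interpolated area
#' under the precision-recall curve, i.e. the mean of the precision at each
#' positive hit. Ties are broken by original position (stable sort), which
#' matches the brute-force enumeration used in the tests.
#'
#' @param scores numeric scores, larger = more confidently positive.
#' @param labels binary labels (0/1 or logical), at least one positive.
#' @return scalar AP in `[0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  if (sum(labels) == 0) stop("average precision needs at least one positive")
  ord <- order(-scores)
  lab <- labels[ord]
  hits <- cumsum(lab)
  prec_at_hit <- hits[lab == 1] / which(lab == 1)
  mean(prec_at_hit)
}

#' Mean average precision over a set of queries
#'
#' \eqn{MAP = \frac{1}{K}\sum_{i=1}^{K} AP_i}. Queries without a positive
#' label are excluded with a warning.
#'
#' @param queries list of `list(scores = , labels = )` pairs.
#' @return scalar MAP.
#' @export
map_metric <- function(queries) {
  ok <- vapply(queries, function(q) sum(as.logical(q$labels)) > 0, logical(1))
  if (!all(ok)) {
    warning(sum(!ok), " quer", if (sum(!ok) == 1) "y" else "ies",
            " without positives excluded from MAP")
  }
  queries <- queries[ok]
  if (!length(queries)) stop("no evaluable queries for MAP")
  mean(vapply(queries, function(q) average_precision(q$scores, q$labels),
              numeric(1)))
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' \eqn{AUC = P(s_{pos} > s_{neg}) + \frac{1}{2} P(s_{pos} = s_{neg})} over
#' all positive/negative pairs.
#'
#' @param scores numeric scores.
#' @param labels binary labels with both classes present.
#' @return scalar AUC in `[0, 1]`.
#' @export
auc_metric <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
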