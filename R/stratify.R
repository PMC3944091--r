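#' ROC curve of a continuous score against a binary outcome
#'
#' The score is positively oriented (higher score, higher risk). A sample
#' is called positive at threshold t when its score is >= t. Thresholds
#' are the midpoints between adjacent distinct scores plus -Inf/+Inf
#' sentinels, so every achievable confusion table appears exactly once.
#' The AUC is the trapezoidal area under sensitivity vs 1 - specificity.
#'
#' @param scores Numeric vector, one score per sample.
#' @param outcome Binary vector, 1 = event (e.g. distant metastasis).
#' @return An object of class `roc_points` with `thresholds`,
#'   `sensitivity`, `specificity` and `auc`.
#' @export
roc_curve <- function(scores, outcome) {
  outcome <- as.integer(outcome)
  stopifnot(length(scores) == length(outcome),
            all(outcome %in% c(0L, 1L)), all(is.finite(scores)))
  n_pos <- sum(outcome == 1L)
  n_neg <- sum(outcome == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both outcome classes must be present for a ROC curve")
  }
  s <- sort(unique(scores))
  thresholds <- c(-Inf, if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2, Inf)
  sens <- vapply(thresholds,
                 function(t) sum(scores >= t & outcome == 1L) / n_pos,
                 numeric(1))
  spec <- vapply(thresholds,
                 function(t) sum(scores < t & outcome == 0L) / n_neg,
                 numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1L] + sens[ord][-length(ord)]) / 2)
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, auc = auc),
            class = "roc_points")
}

#' @export
print.roc_points <- function(x, ...) {
  cat("ROC curve:", length(x$thresholds), "thresholds, AUC =",
      round(x$auc, 4), "\n")
  invisible(x)
}

#' Optimal ROC cut-off (closest to the ideal corner)
#'
#' Returns the threshold whose operating point minimizes the Euclidean
#' distance from (1 - specificity, sensitivity) to the ideal corner
#' (0, 1). Ties are broken toward higher specificity, then toward the
#' lower threshold. Youden's J (sensitivity + specificity - 1) is
#' available as an alternative criterion.
#'
#' @param roc A `roc_points` object.
#' @param criterion Distance to the (0,1) corner (default) or Youden's J.
#' @return The selected threshold (numeric scalar).
#' @export
optimal_cutoff <- function(roc, criterion = c("closest_topleft", "youden")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(roc, "roc_points"))
  obj <- switch(criterion,
    closest_topleft = (1 - roc$specificity)^2 + (1 - roc$sensitivity)^2,
    youden = -(roc$sensitivity + roc$specificity - 1))
  ord <- order(obj, -roc$specificity, roc$thresholds)
  roc$thresholds[ord[1L]]
}

#' High-sensitivity secondary cut-off
#'
#' Among thresholds whose sensitivity is at least `min_sensitivity`,
#' returns the one with the highest specificity (ties toward the lower
#' threshold). Combined with [optimal_cutoff()] this yields the two cuts
#' that define low / medium / high risk groups.
#'
#' @param roc A `roc_points` object.
#' @param min_sensitivity Lower bound defining the highly sensitive part
#'   of the curve.
#' @return The selected threshold (numeric scalar).
#' @export
second_cutoff_high_sensitivity <- function(roc, min_sensitivity = 0.9) {
  stopifnot(inherits(roc, "roc_points"))
  ok <- roc$sensitivity >= min_sensitivity
  if (!any(ok)) {
    stop("no threshold attains sensitivity >= ", min_sensitivity,
         "; lower min_sensitivity")
  }
  ord <- order(-roc$specificity[ok], roc$thresholds[ok])
  roc$thresholds[ok][ord[1L]]
}

#' Assign low / medium / high risk from two score cut-offs
#'
#' score < cut_low -> low; cut_low <= score < cut_high -> medium;
#' score >= cut_high -> high (intervals closed on the high-risk side).
#'
#' @param scores Named numeric vector of per-sample scores.
#' @param cut_low,cut_high The two thresholds, cut_low <= cut_high.
#' @param sample_ids Sample identifiers; defaults to `names(scores)`.
#' @return A [risk_assignment] with ordered labels low < medium < high.
#' @export
assign_three_groups <- function(scores, cut_low, cut_high,
                                sample_ids = names(scores)) {
  if (cut_low > cut_high) stop("cut_low must not exceed cut_high")
  if (is.null(sample_ids)) sample_ids <- as.character(seq_along(scores))
  label <- ifelse(scores < cut_low, "low",
                  ifelse(scores < cut_high, "medium", "high"))
  risk_assignment(sample_ids, as.numeric(scores), label,
                  levels = c("low", "medium", "high"),
                  classifier = "three_group_cutoffs")
}

#' Two-cluster risk grouping by hierarchical clustering
#'
#' Samples are clustered on the signature genes with distance
#' 1 - correlation and the chosen linkage (average by default, the dChip
#' convention); the tree is cut into two clusters and the cluster with
#' the higher observed event proportion is labelled high risk. If the two
#' clusters have identical event proportions the one with the higher mean
#' signature expression is labelled high risk (documented tie-break).
#'
#' @param matrix Gene x sample expression matrix.
#' @param genes A [signature_genes] object; only symbols present in the
#'   matrix are used.
#' @param correlation Correlation type for the distance.
#' @param event_labels Binary event vector aligned with samples, used
#'   only to orient the cluster labels.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return A [risk_assignment] with labels in \{low, high\}; the score is
#'   the cluster index (1/2 as returned by [stats::cutree()]).
#' @export
two_cluster_risk <- function(matrix, genes,
                             correlation = c("pearson", "spearman"),
                             event_labels, linkage = "average") {
  correlation <- match.arg(correlation)
  validate_expression(matrix)
  if (ncol(matrix) < 2L) stop("need at least two samples to cluster")
  event_labels <- as.integer(event_labels)
  stopifnot(length(event_labels) == ncol(matrix))
  ids <- rownames(matrix)[toupper(rownames(matrix)) %in%
                            toupper(genes$symbols)]
  if (length(ids) < 2L) stop("need at least two signature genes present")
  sub <- matrix[ids, , drop = FALSE]
  cors <- suppressWarnings(stats::cor(sub, method = correlation))
  if (anyNA(cors)) stop("constant sample profile; correlation undefined")
  d <- stats::as.dist(1 - cors)
  if (all(d == 0)) stop("all samples identical; no resolvable clusters")
  tree <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(tree, k = 2L)
  rate <- tapply(event_labels, cl, mean)
  if (rate[["1"]] != rate[["2"]]) {
    high_cl <- as.integer(names(which.max(rate)))
  } else {
    mean_expr <- tapply(colMeans(sub), cl, mean)
    high_cl <- as.integer(names(which.max(mean_expr)))
  }
  risk_assignment(colnames(matrix), as.numeric(cl),
                  ifelse(cl == high_cl, "high", "low"),
                  levels = c("low", "high"),
                  classifier = paste0("two_cluster_", correlation, "_",
                                      linkage))
}
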