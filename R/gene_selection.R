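#' Per-gene one-way ANOVA against a binary grouping
#'
#' For each gene a classical (equal-variance) one-way two-group ANOVA is
#' computed; with two groups F equals the square of the pooled-variance t
#' statistic, so the test is sign-agnostic and also captures genes whose
#' expression is lower in the metastasis group. Computed vectorized over
#' genes; identical to per-gene [stats::aov()] fits.
#'
#' @param matrix Gene x sample expression matrix.
#' @param groups Binary vector (e.g. 1 = distant metastasis) aligned with
#'   the matrix columns.
#' @return A data frame with `gene_id`, `f_statistic`, `p_value` in the
#'   gene order of the matrix.
#' @export
anova_per_gene <- function(matrix, groups) {
  validate_expression(matrix)
  groups <- as.integer(groups)
  stopifnot(length(groups) == ncol(matrix), all(groups %in% c(0L, 1L)))
  n0 <- sum(groups == 0L)
  n1 <- sum(groups == 1L)
  if (n0 < 2L || n1 < 2L) {
    stop("need at least two samples per group for ANOVA")
  }
  n <- n0 + n1
  m0 <- rowMeans(matrix[, groups == 0L, drop = FALSE])
  m1 <- rowMeans(matrix[, groups == 1L, drop = FALSE])
  ss0 <- rowSums((matrix[, groups == 0L, drop = FALSE] - m0)^2)
  ss1 <- rowSums((matrix[, groups == 1L, drop = FALSE] - m1)^2)
  ss_within <- ss0 + ss1
  grand <- (n0 * m0 + n1 * m1) / n
  ss_between <- n0 * (m0 - grand)^2 + n1 * (m1 - grand)^2
  f <- (ss_between / 1) / (ss_within / (n - 2L))
  # degenerate genes: zero residual variance
  zero_within <- ss_within <= .Machine$double.eps * rowSums(matrix^2)
  f[zero_within & ss_between > 0] <- Inf
  f[zero_within & ss_between == 0] <- 0
  p <- stats::pf(f, 1, n - 2L, lower.tail = FALSE)
  data.frame(gene_id = rownames(matrix), f_statistic = f, p_value = p,
             stringsAsFactors = FALSE)
}

#' Select significant genes from per-gene test results
#'
#' Genes with p <= alpha, ordered by ascending p (ties by descending F,
#' then gene id). No multiple-testing correction is applied: the
#' supervised selection is deliberately liberal and its optimism is what
#' the leave-one-out reselection protocol is designed to expose.
#'
#' @param results Data frame from [anova_per_gene()].
#' @param alpha Significance cut-off (default 0.01).
#' @param name Name given to the resulting signature.
#' @return A [signature_genes] object (possibly empty).
#' @export
select_genes <- function(results, alpha = 0.01, name = "anova_selected") {
  keep <- results[results$p_value <= alpha, , drop = FALSE]
  keep <- keep[order(keep$p_value, -keep$f_statistic, keep$gene_id), ,
               drop = FALSE]
  signature_genes(name, keep$gene_id)
}

#' Nearest-centroid prediction by correlation
#'
#' Predicts the class whose training centroid (per-class mean profile)
#' correlates best with the test sample; ties predict class 0
#' (no metastasis). When only one gene is available the correlation is
#' undefined and the nearer centroid in absolute distance is used.
#' Correlation compares the shape of a profile across genes, so class
#' differences that shift every gene by the same amount are invisible to
#' it; informative selections need heterogeneous effect directions or
#' magnitudes.
#'
#' @param train_matrix Gene x sample training matrix.
#' @param train_labels Binary training labels aligned with columns.
#' @param test_sample Numeric vector over the same genes.
#' @return Predicted label, 0L or 1L.
#' @export
nearest_centroid_predict <- function(train_matrix, train_labels,
                                     test_sample) {
  train_labels <- as.integer(train_labels)
  stopifnot(length(train_labels) == ncol(train_matrix),
            length(test_sample) == nrow(train_matrix))
  if (!any(train_labels == 0L) || !any(train_labels == 1L)) {
    stop("both classes must be present in the training set")
  }
  c0 <- rowMeans(train_matrix[, train_labels == 0L, drop = FALSE])
  c1 <- rowMeans(train_matrix[, train_labels == 1L, drop = FALSE])
  if (nrow(train_matrix) == 1L) {
    # correlation is undefined over a single gene: nearest centroid by
    # absolute distance, ties to class 0
    return(if (abs(test_sample - c1) < abs(test_sample - c0)) 1L else 0L)
  }
  if (stats::sd(test_sample) == 0 || stats::sd(c0) == 0 ||
      stats::sd(c1) == 0) {
    stop("constant vector; correlation undefined")
  }
  r0 <- stats::cor(test_sample, c0)
  r1 <- stats::cor(test_sample, c1)
  if (r1 > r0) 1L else 0L
}

#' Leave-one-out cross-validation with in-fold gene reselection
#'
#' For each sample the per-gene ANOVA selection is repeated on the
#' remaining samples only, and the held-out sample is classified by
#' correlation to the per-class centroids of the selected genes. A fold
#' whose selection is empty predicts the training-majority class (ties
#' predict no metastasis); such folds are counted. Reselecting inside
#' every fold keeps the error estimate honest about the optimism of the
#' supervised selection.
#'
#' Gene standardization is also done inside each fold: genes are scaled
#' to training mean 0 and SD 1, and the held-out sample is transformed
#' with the training parameters. Standardizing across all samples first
#' would couple the held-out sample to the training set (with row means
#' forced to zero its values equal minus the training sums), which
#' biases the centroid correlations; per-fold standardization keeps the
#' estimate clean. Pass the matrix on its raw log2 scale.
#'
#' @param matrix Gene x sample expression matrix.
#' @param event_labels Binary outcome vector aligned with columns.
#' @param alpha Selection cut-off passed to [select_genes()].
#' @return An object of class `cv_result`: confusion counts (`tp`, `tn`,
#'   `fp`, `fn`), `accuracy`, `sensitivity`, `specificity`, per-fold
#'   `fold_gene_lists`, `predictions`, and `n_empty_folds`.
#' @export
loocv_with_reselection <- function(matrix, event_labels, alpha = 0.01) {
  validate_expression(matrix)
  event_labels <- as.integer(event_labels)
  n <- ncol(matrix)
  stopifnot(length(event_labels) == n)
  if (n < 4L || !any(event_labels == 0L) || !any(event_labels == 1L)) {
    stop("need n >= 4 with both outcome classes represented")
  }
  preds <- integer(n)
  fold_gene_lists <- vector("list", n)
  n_empty <- 0L
  for (i in seq_len(n)) {
    train <- matrix[, -i, drop = FALSE]
    labs <- event_labels[-i]
    if (!any(labs == 0L) || !any(labs == 1L)) {
      stop("fold ", i, " lost an outcome class entirely")
    }
    # per-fold standardization from training samples only
    mu <- rowMeans(train)
    sd_pop <- sqrt(rowMeans((train - mu)^2))
    keep <- sd_pop > 0
    train_z <- (train[keep, , drop = FALSE] - mu[keep]) / sd_pop[keep]
    test_z <- (matrix[keep, i] - mu[keep]) / sd_pop[keep]
    sel <- select_genes(anova_per_gene(train_z, labs), alpha = alpha)
    fold_gene_lists[[i]] <- sel$symbols
    if (length(sel$symbols) == 0L) {
      n_empty <- n_empty + 1L
      preds[i] <- if (sum(labs == 1L) > sum(labs == 0L)) 1L else 0L
    } else {
      preds[i] <- nearest_centroid_predict(
        train_z[sel$symbols, , drop = FALSE], labs,
        test_z[sel$symbols])
    }
  }
  tp <- sum(preds == 1L & event_labels == 1L)
  tn <- sum(preds == 0L & event_labels == 0L)
  fp <- sum(preds == 1L & event_labels == 0L)
  fn <- sum(preds == 0L & event_labels == 1L)
  structure(list(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = (tp + tn) / n,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    fold_gene_lists = fold_gene_lists,
    predictions = preds,
    n_empty_folds = n_empty
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "LOOCV (reselected genes): accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
    100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity))
  cat(sprintf("confusion: TP %d, FN %d, FP %d, TN %d; empty folds: %d\n",
              x$tp, x$fn, x$fp, x$tn, x$n_empty_folds))
  invisible(x)
}
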