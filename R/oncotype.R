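#' Oncotype-DX-style group scores for one sample
#'
#' Combines the 16 target genes into the four group scores and three
#' single-gene terms of the 21-gene recurrence-score algorithm:
#' \itemize{
#'   \item GRB7 group = 0.9 * GRB7 + 0.1 * ERBB2
#'   \item ER group = (0.8 * ESR1 + 1.2 * PGR + BCL2 + SCUBE2) / 4
#'   \item proliferation group = mean(BIRC5, MKI67, MYBL2, CCNB1, AURKA)
#'   \item invasion group = (CTSL2 + MMP11) / 2
#' }
#' On the original qPCR reference-normalized scale the GRB7 and
#' proliferation groups are floored at 8 and 6.5 respectively; on
#' per-gene z-scored microarray data those floors are meaningless and are
#' off by default.
#'
#' @param sample_expr Named numeric vector of standardized expression for
#'   one sample; must contain all 16 target genes (case-insensitive).
#' @param floors Apply the qPCR-scale group floors (GRB7 group >= 8,
#'   proliferation group >= 6.5).
#' @return A list of class `oncotype_groups` with components
#'   `grb7_group`, `er_group`, `proliferation_group`, `invasion_group`,
#'   `cd68`, `gstm1`, `bag1`.
#' @export
oncotype_group_scores <- function(sample_expr, floors = FALSE) {
  nm <- toupper(names(sample_expr))
  get <- function(sym) {
    i <- match(sym, nm)
    if (is.na(i)) stop("missing Oncotype target gene: ", sym)
    v <- as.numeric(sample_expr[[i]])
    if (!is.finite(v)) stop("non-finite expression for gene: ", sym)
    v
  }
  grb7 <- 0.9 * get("GRB7") + 0.1 * get("ERBB2")
  er <- (0.8 * get("ESR1") + 1.2 * get("PGR") + get("BCL2") + get("SCUBE2")) / 4
  prolif <- mean(c(get("BIRC5"), get("MKI67"), get("MYBL2"),
                   get("CCNB1"), get("AURKA")))
  invasion <- (get("CTSL2") + get("MMP11")) / 2
  if (floors) {
    grb7 <- max(grb7, 8)
    prolif <- max(prolif, 6.5)
  }
  structure(list(grb7_group = grb7, er_group = er,
                 proliferation_group = prolif, invasion_group = invasion,
                 cd68 = get("CD68"), gstm1 = get("GSTM1"),
                 bag1 = get("BAG1")),
            class = "oncotype_groups")
}

#' Unscaled recurrence score from group scores
#'
#' RSu = 0.47 * GRB7 group - 0.34 * ER group
#'   + 1.04 * proliferation group + 0.10 * invasion group
#'   + 0.05 * CD68 - 0.08 * GSTM1 - 0.07 * BAG1.
#'
#' Only the ordering of RSu matters downstream (risk groups are derived
#' from ROC cut-offs), so the 0-100 clinical rescale is not applied.
#'
#' @param groups An `oncotype_groups` object.
#' @return The unscaled recurrence score (numeric scalar).
#' @export
oncotype_rs_unscaled <- function(groups) {
  stopifnot(inherits(groups, "oncotype_groups"))
  with(groups,
       0.47 * grb7_group - 0.34 * er_group + 1.04 * proliferation_group +
         0.10 * invasion_group + 0.05 * cd68 - 0.08 * gstm1 - 0.07 * bag1)
}

#' Unscaled recurrence score for every sample of a matrix
#'
#' @param matrix Standardized gene x sample expression matrix containing
#'   the 16 target genes.
#' @param floors Apply the qPCR-scale group floors (see
#'   [oncotype_group_scores()]).
#' @return Named numeric vector of per-sample unscaled recurrence scores.
#' @export
oncotype_rs <- function(matrix, floors = FALSE) {
  validate_expression(matrix)
  vapply(colnames(matrix), function(s) {
    oncotype_rs_unscaled(oncotype_group_scores(matrix[, s], floors = floors))
  }, numeric(1))
}

#' Per-class average gene-expression profiles (AGPP centroids)
#'
#' Computes, over the signature genes, the mean expression profile of
#' samples with and without a distant-metastasis event. These profiles
#' serve as classification centroids.
#'
#' @param matrix Gene x sample expression matrix.
#' @param event_labels Binary vector (1 = distant metastasis) aligned
#'   with the matrix columns.
#' @param genes A [signature_genes] object restricting the profile; only
#'   symbols present in the matrix are used.
#' @return List of class `agpp_centroids` with `centroid_no_metastasis`,
#'   `centroid_metastasis` (named numeric vectors) and `gene_ids`.
#' @export
agpp_centroids <- function(matrix, event_labels, genes) {
  validate_expression(matrix)
  event_labels <- as.integer(event_labels)
  if (length(event_labels) != ncol(matrix)) {
    stop("event_labels must align with matrix columns")
  }
  if (!all(event_labels %in% c(0L, 1L))) stop("event_labels must be binary")
  if (sum(event_labels == 0L) < 1L || sum(event_labels == 1L) < 1L) {
    stop("need at least one sample in each outcome class")
  }
  ids <- rownames(matrix)[toupper(rownames(matrix)) %in%
                            toupper(genes$symbols)]
  if (length(ids) == 0L) stop("no signature gene present in the matrix")
  sub <- matrix[ids, , drop = FALSE]
  structure(list(
    centroid_no_metastasis = rowMeans(sub[, event_labels == 0L, drop = FALSE]),
    centroid_metastasis = rowMeans(sub[, event_labels == 1L, drop = FALSE]),
    gene_ids = ids
  ), class = "agpp_centroids")
}

#' Classify one sample by correlation to the AGPP centroids
#'
#' The sample is assigned a good prognosis when its correlation with the
#' no-metastasis profile exceeds its correlation with the metastasis
#' profile; exact ties default to good (favouring the lower treatment
#' intensity, and made explicit here).
#'
#' @param sample_expr Named numeric vector covering the centroid genes.
#' @param centroids An `agpp_centroids` object.
#' @param method Correlation type; Spearman uses average ranks for ties.
#' @param tie Label assigned when the two correlations are equal.
#' @return List with `label` ("good"/"bad"), `r_good`, `r_bad`.
#' @export
classify_agpp <- function(sample_expr, centroids,
                          method = c("pearson", "spearman"),
                          tie = c("good", "bad")) {
  method <- match.arg(method)
  tie <- match.arg(tie)
  stopifnot(inherits(centroids, "agpp_centroids"))
  x <- sample_expr[centroids$gene_ids]
  if (anyNA(x)) stop("sample does not cover all centroid genes")
  if (stats::sd(x) == 0) stop("constant sample vector; correlation undefined")
  if (stats::sd(centroids$centroid_no_metastasis) == 0 ||
      stats::sd(centroids$centroid_metastasis) == 0) {
    stop("constant centroid; correlation undefined")
  }
  r_good <- stats::cor(x, centroids$centroid_no_metastasis, method = method)
  r_bad <- stats::cor(x, centroids$centroid_metastasis, method = method)
  label <- if (r_good > r_bad) "good" else if (r_bad > r_good) "bad" else tie
  list(label = label, r_good = r_good, r_bad = r_bad)
}

#' AGPP classification of every sample in a matrix
#'
#' @inheritParams classify_agpp
#' @param matrix Gene x sample expression matrix.
#' @return A [risk_assignment] with labels in \{good, bad\} and score
#'   `r_good - r_bad`.
#' @export
classify_agpp_all <- function(matrix, centroids,
                              method = c("pearson", "spearman"),
                              tie = c("good", "bad")) {
  method <- match.arg(method)
  tie <- match.arg(tie)
  res <- lapply(colnames(matrix), function(s) {
    classify_agpp(matrix[, s], centroids, method = method, tie = tie)
  })
  risk_assignment(sample_ids = colnames(matrix),
                  score = vapply(res, function(r) r$r_good - r$r_bad,
                                 numeric(1)),
                  label = vapply(res, `[[`, character(1), "label"),
                  levels = c("bad", "good"),
                  classifier = paste0("agpp_", method))
}

#' Per-sample risk assignment container
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param score Continuous score that produced the labels.
#' @param label Character vector of risk labels.
#' @param levels Ordered label levels, lowest risk last or first as the
#'   classifier defines; stored as a factor.
#' @param classifier Name of the classifier that produced the assignment.
#' @return A data frame of class `risk_assignment`.
#' @export
risk_assignment <- function(sample_ids, score, label, levels,
                            classifier = "unknown") {
  stopifnot(length(sample_ids) == length(score),
            length(sample_ids) == length(label),
            all(label %in% levels))
  structure(data.frame(sample_id = sample_ids, score = score,
                       label = factor(label, levels = levels),
                       stringsAsFactors = FALSE),
            class = c("risk_assignment", "data.frame"),
            classifier = classifier)
}
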