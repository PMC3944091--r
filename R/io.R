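#' Read a gene x sample expression matrix from TSV
#'
#' Expression values are expected on the log2 scale, genes in rows and
#' samples in columns, with a header row of sample identifiers and the
#' first column holding gene identifiers.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix with gene identifiers as row names and sample
#'   identifiers as column names.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) {
    stop("expression file not found: ", path)
  }
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) {
    stop("expression table must have a gene-id column and at least one sample")
  }
  gene_ids <- as.character(tab[[1L]])
  values <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(values)) {
    bad <- which(!vapply(tab[-1L], is.numeric, logical(1)))
    stop("non-numeric expression values in column(s): ",
         paste(colnames(tab)[-1L][bad], collapse = ", "))
  }
  rownames(values) <- gene_ids
  validate_expression(values)
  values
}

#' Write an expression matrix to TSV
#'
#' @param matrix Numeric gene x sample matrix with dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(matrix, path) {
  validate_expression(matrix)
  tab <- data.frame(gene_id = rownames(matrix), matrix,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate an expression matrix
#'
#' Checks that the object is a numeric matrix with unique, non-missing gene
#' and sample identifiers and finite values.
#'
#' @param matrix Candidate matrix.
#' @param allow_missing Allow `NA` values (used at ingest before the
#'   missing-value policy is applied).
#' @return The matrix, invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(matrix, allow_missing = FALSE) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("expression must be a numeric matrix")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("expression matrix must carry gene and sample identifiers as dimnames")
  }
  dup_g <- unique(rownames(matrix)[duplicated(rownames(matrix))])
  if (length(dup_g) > 0L) {
    stop("duplicate gene identifier(s): ", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(colnames(matrix)[duplicated(colnames(matrix))])
  if (length(dup_s) > 0L) {
    stop("duplicate sample identifier(s): ", paste(dup_s, collapse = ", "))
  }
  if (!allow_missing && anyNA(matrix)) {
    stop("expression matrix contains missing values; impute or drop rows first")
  }
  if (any(is.infinite(matrix))) {
    stop("expression matrix contains non-finite values")
  }
  invisible(matrix)
}

#' Drop genes with missing values
#'
#' Default missing-value policy at ingest: rows (genes) with any `NA` are
#' removed and their count reported.
#'
#' @param matrix Expression matrix, possibly with `NA`s.
#' @return The matrix restricted to complete rows, with attribute
#'   `n_dropped` giving the number of removed genes.
#' @export
drop_incomplete_genes <- function(matrix) {
  validate_expression(matrix, allow_missing = TRUE)
  keep <- stats::complete.cases(matrix)
  out <- matrix[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("all genes removed by missing-value filter")
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Read a per-sample clinical table from CSV
#'
#' @param path Path to a comma-separated file with a `sample_id` column.
#' @return A data frame of clinical covariates.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(tab)) {
    stop("clinical table must contain a 'sample_id' column")
  }
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample_id in clinical table")
  }
  tab
}

#' Write a clinical table to CSV
#'
#' @param clinical Data frame with a `sample_id` column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a signature gene list
#'
#' A signature is a named set of gene symbols, optionally tagged with a
#' role (e.g. the Oncotype-DX group a gene contributes to).
#'
#' @param name Signature name.
#' @param symbols Character vector of unique gene symbols.
#' @param roles Optional character vector of role tags, one per symbol.
#' @return An object of class `signature_genes`.
#' @export
signature_genes <- function(name, symbols, roles = NULL) {
  symbols <- as.character(symbols)
  if (anyDuplicated(symbols)) {
    stop("duplicate symbols in signature '", name, "'")
  }
  if (!is.null(roles) && length(roles) != length(symbols)) {
    stop("roles must have one entry per symbol")
  }
  structure(list(name = name, symbols = symbols, roles = roles),
            class = "signature_genes")
}

#' @export
print.signature_genes <- function(x, ...) {
  cat("Signature '", x$name, "': ", length(x$symbols), " genes\n", sep = "")
  invisible(x)
}

#' @export
length.signature_genes <- function(x) length(x$symbols)

#' Read a signature gene list from JSON
#'
#' Accepts either a bare JSON array of symbols or an object with fields
#' `signature_name` and `genes` (each gene an object with `symbol` and an
#' optional `role`).
#'
#' @param path Path to a JSON file.
#' @param name Signature name used when the file is a bare array.
#' @return A [signature_genes] object.
#' @export
read_signature <- function(path, name = basename(path)) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.character(obj)) {
    return(signature_genes(name, obj))
  }
  genes <- obj$genes
  roles <- if ("role" %in% names(genes)) genes$role else NULL
  signature_genes(obj$signature_name %||% name, genes$symbol, roles)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Collapse probe-level rows to one row per gene
#'
#' Illumina arrays measure probes, several of which may target the same
#' gene. For genes with multiple probes the probe with the highest mean
#' expression across samples is retained (`method = "max_mean"`, the
#' default) or probes are averaged (`method = "mean"`). Probes without a
#' mapping entry are dropped and counted.
#'
#' @param matrix Probe x sample expression matrix.
#' @param probe_to_gene Named character vector mapping probe id to gene
#'   symbol; probes mapped to `NA` or absent from the map are unmapped.
#' @param method Collapse rule for multi-probe genes.
#' @return A gene x sample matrix with attribute `n_unmapped`.
#' @export
collapse_probes <- function(matrix, probe_to_gene,
                            method = c("max_mean", "mean")) {
  method <- match.arg(method)
  validate_expression(matrix)
  genes <- probe_to_gene[rownames(matrix)]
  mapped <- !is.na(genes)
  n_unmapped <- sum(!mapped)
  if (!any(mapped)) stop("no probe maps to a gene; result would be empty")
  m <- matrix[mapped, , drop = FALSE]
  genes <- genes[mapped]
  if (method == "max_mean") {
    means <- rowMeans(m)
    # per gene keep the probe with maximal mean; first wins on exact ties
    ord <- order(genes, -means)
    keep <- ord[!duplicated(genes[ord])]
    out <- m[keep, , drop = FALSE]
    rownames(out) <- genes[keep]
  } else {
    out <- rowsum(m, group = genes) / as.vector(table(genes)[sort(unique(genes))])
    out <- out[sort(unique(genes)), , drop = FALSE]
  }
  out <- out[order(rownames(out)), , drop = FALSE]
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Partition a signature by presence in an expression matrix
#'
#' Symbols are matched case-insensitively against the matrix gene
#' identifiers.
#'
#' @param matrix Gene x sample expression matrix.
#' @param signature A [signature_genes] object.
#' @return A list with `found` and `missing` [signature_genes] objects.
#' @export
map_signature <- function(matrix, signature) {
  stopifnot(inherits(signature, "signature_genes"))
  hit <- toupper(signature$symbols) %in% toupper(rownames(matrix))
  subsig <- function(idx, suffix) {
    signature_genes(paste0(signature$name, suffix),
                    signature$symbols[idx],
                    if (!is.null(signature$roles)) signature$roles[idx])
  }
  list(found = subsig(hit, ""), missing = subsig(!hit, " (missing)"))
}

#' Standardize each gene to zero mean and unit variance
#'
#' Uses the population standard deviation (denominator `n`), so that a
#' z-scored row has exactly unit SD under that convention.
#'
#' @param matrix Gene x sample expression matrix.
#' @return Matrix of the same shape with each row standardized.
#' @export
zscore_genes <- function(matrix) {
  validate_expression(matrix)
  n <- ncol(matrix)
  if (n < 2L) stop("need at least two samples to standardize")
  mu <- rowMeans(matrix)
  centred <- matrix - mu
  sd_pop <- sqrt(rowSums(centred^2) / n)
  zero <- sd_pop == 0
  if (any(zero)) {
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(matrix)[zero], 10L), collapse = ", "))
  }
  centred / sd_pop
}

#' Read a GEO Series Matrix expression table
#'
#' Minimal reader for the standard Series Matrix dialect: the block
#' between `!series_matrix_table_begin` and `!series_matrix_table_end` is
#' parsed as a tab-separated probe x sample table. Metadata lines are
#' ignored. Intended for optionally ingesting a deposited cohort; the rest
#' of the pipeline is exercised through the synthetic generator.
#'
#' @param path Path to an uncompressed series matrix file.
#' @return A numeric probe x sample matrix.
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L) {
    stop("no series-matrix table block found in ", path)
  }
  block <- lines[(beg + 1L):(end - 1L)]
  tab <- utils::read.delim(text = block, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- gsub('"', "", as.character(tab[[1L]]))
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  validate_expression(values, allow_missing = TRUE)
  values
}

#' Built-in Oncotype-DX target-gene signature
#'
#' The 16 target genes of the 21-gene recurrence-score assay, tagged with
#' the group each contributes to (HER2/GRB7, oestrogen, proliferation,
#' invasion, or a single-gene term).
#'
#' @return A [signature_genes] object with role tags.
#' @export
oncotype_signature <- function() {
  read_signature(system.file("extdata", "oncotype_genes.json",
                             package = "prolifsig"))
}

#' Built-in MammaPrint-related signature
#'
#' Seventy entries of the 70-gene prognosis profile under a commonly used
#' symbol mapping; eight entries are unannotated contig/EST identifiers
#' that typically fail to match annotated array platforms (symbol mapping
#' varies with annotation vintage).
#'
#' @return A [signature_genes] object.
#' @export
mammaprint_signature <- function() {
  read_signature(system.file("extdata", "mammaprint_genes.json",
                             package = "prolifsig"))
}
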