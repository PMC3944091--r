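#' Run the full signature-versus-proliferation analysis
#'
#' Composes the whole pipeline on one cohort: per-gene standardization;
#' recurrence-score computation with ROC-derived low/medium/high groups;
#' MammaPrint-style grouping both by AGPP correlation and by two-cluster
#' hierarchical clustering; clinical marker dichotomizations (MAI at 10
#' and 0-2/3-9/>=10, PPH3 at 13, Ki67 at 10%, plus age, diameter, grade
#' and receptor statuses); Kaplan-Meier, log-rank and univariate Cox per
#' factor; stepwise (Wald) multivariate Cox over the univariately
#' significant factors; and supervised gene selection with leave-one-out
#' cross-validation.
#'
#' @param cohort A `synthetic_cohort`, or `NULL` when `expression` and
#'   `clinical` are given directly.
#' @param expression Gene x sample matrix (log2 scale) if no cohort.
#' @param clinical Clinical data frame if no cohort.
#' @param correlation Correlation type for AGPP and clustering.
#' @param alpha Per-gene selection cut-off.
#' @param min_sensitivity Sensitivity bound for the secondary ROC cut.
#' @param stepwise_direction Direction of the multivariate selection.
#' @param p_univariate Log-rank threshold admitting a factor into the
#'   multivariate candidate set.
#' @param run_loocv Run the leave-one-out cross-validation stage (the
#'   most expensive stage).
#' @param out_dir Optional directory; when given, writes `report.tsv`,
#'   `results.json`, `km_curves.tsv` and `run.log`.
#' @param seed Seed controlling any stochastic stage.
#' @return Object of class `prolifsig_analysis`: `report` (Table-1-style
#'   data frame), `assignments`, `cutoffs`, `logrank`, `cox_univariate`,
#'   `cox_multivariate`, `selected_genes`, `cv`, `km`.
#' @export
run_full_analysis <- function(cohort = NULL, expression = NULL,
                              clinical = NULL,
                              correlation = c("pearson", "spearman"),
                              alpha = 0.01, min_sensitivity = 0.9,
                              stepwise_direction = c("forward", "backward"),
                              p_univariate = 0.05, run_loocv = TRUE,
                              out_dir = NULL, seed = 1L) {
  correlation <- match.arg(correlation)
  stepwise_direction <- match.arg(stepwise_direction)
  if (is.null(cohort) == (is.null(expression) || is.null(clinical))) {
    stop("provide exactly one of: a cohort, or expression plus clinical")
  }
  if (!is.null(cohort)) {
    expression <- cohort$expression
    clinical <- cohort$clinical
  }
  set.seed(seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  records <- stage("encode_dmfs", encode_dmfs(clinical))
  idx <- match(colnames(expression), records$sample_id)
  if (anyNA(idx)) stop("[stage: align] samples missing from clinical table")
  records <- records[idx, ]
  event <- records$event

  filtered <- stage("filter", {
    sds <- apply(expression, 1L, stats::sd)
    expression[sds > 0, , drop = FALSE]
  })
  z <- stage("standardize", zscore_genes(filtered))

  ## ---- recurrence score and three risk groups ----
  rs <- stage("recurrence_score", oncotype_rs(z))
  roc <- stage("roc", roc_curve(rs, event))
  cut_high <- optimal_cutoff(roc)
  cut_low <- second_cutoff_high_sensitivity(roc, min_sensitivity)
  if (cut_low > cut_high) cut_low <- cut_high  # degenerate curve
  onco_groups <- assign_three_groups(rs, cut_low, cut_high)

  ## ---- MammaPrint-style grouping (both published routes) ----
  mp <- mammaprint_signature()
  centroids <- stage("agpp", agpp_centroids(z, event, mp))
  agpp <- classify_agpp_all(z, centroids, method = correlation)
  clus <- stage("two_cluster",
                two_cluster_risk(z, mp, correlation, event))

  ## ---- factor table ----
  need <- c("mai", "pph3", "ki67", "age", "tumour_diameter_cm", "grade",
            "er_status", "pr_status", "her2_status", "ck56_status",
            "tnp_status")
  missing_cols <- setdiff(need, names(clinical))
  if (length(missing_cols) > 0L) {
    stop("[stage: factors] missing clinical column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  cl <- clinical[match(colnames(expression), clinical$sample_id), ]
  fct <- function(x, levels) factor(x, levels = levels)
  factors <- list(
    age = fct(ifelse(cl$age < 55, "<55", ">=55"), c("<55", ">=55")),
    tumour_diameter = fct(ifelse(cl$tumour_diameter_cm < 2, "<2cm", ">=2cm"),
                          c("<2cm", ">=2cm")),
    grade = fct(ifelse(cl$grade == 1, "1", "2-3"), c("1", "2-3")),
    er = fct(ifelse(cl$er_status == 1, "positive", "negative"),
             c("positive", "negative")),
    pr = fct(ifelse(cl$pr_status == 1, "positive", "negative"),
             c("positive", "negative")),
    her2 = fct(ifelse(cl$her2_status == 1, "2+-3+", "0-1+"),
               c("0-1+", "2+-3+")),
    mai = fct(ifelse(cl$mai < 10, "<10", ">=10"), c("<10", ">=10")),
    mai3 = fct(ifelse(cl$mai <= 2, "0-2",
                      ifelse(cl$mai <= 9, "3-9", ">=10")),
               c("0-2", "3-9", ">=10")),
    ki67 = fct(ifelse(cl$ki67 < 10, "0-9%", "10-100%"),
               c("0-9%", "10-100%")),
    pph3 = fct(ifelse(cl$pph3 < 13, "<13", ">=13"), c("<13", ">=13")),
    ck56 = fct(ifelse(cl$ck56_status == 1, "positive", "negative"),
               c("negative", "positive")),
    tnp = fct(ifelse(cl$tnp_status == 1, "positive", "negative"),
              c("negative", "positive")),
    oncotype = onco_groups$label,
    mammaprint_agpp = factor(ifelse(agpp$label == "good",
                                    "good", "bad"), c("good", "bad")),
    mammaprint_cluster = clus$label
  )

  ## ---- per-factor KM, log-rank, univariate Cox ----
  logrank <- list()
  cox_uni <- list()
  km <- list()
  report_rows <- list()
  for (nm in names(factors)) {
    g <- factors[[nm]]
    if (nlevels(droplevels(g)) < 2L) {
      logrank[[nm]] <- list(chi2 = NA_real_, df = NA_integer_, p = NA_real_)
      next
    }
    g <- droplevels(g)
    lr <- logrank_test(records, g)
    logrank[[nm]] <- lr
    km[[nm]] <- lapply(split(records, g), km_estimate)
    mm <- stats::model.matrix(~g)[, -1L, drop = FALSE]
    colnames(mm) <- levels(g)[-1L]
    fit <- tryCatch(cox_fit(mm, records), error = function(e) NULL)
    cox_uni[[nm]] <- fit
    for (k in seq_along(levels(g))) {
      lev <- levels(g)[k]
      ev <- sum(event[g == lev])
      ar <- sum(g == lev)
      # HR reported against the first (reference) level
      j <- if (k > 1L && !is.null(fit)) match(lev, names(fit$hr)) else NA
      report_rows[[length(report_rows) + 1L]] <- data.frame(
        factor = nm, group = lev, events = ev, at_risk = ar,
        event_free_pct = event_free_percent(ev, ar),
        logrank_p = if (k == 1L) lr$p else NA_real_,
        hr = if (!is.na(j)) fit$hr[[j]] else NA_real_,
        ci_lower = if (!is.na(j)) fit$ci_lower[[j]] else NA_real_,
        ci_upper = if (!is.na(j)) fit$ci_upper[[j]] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, report_rows)

  ## ---- multivariate over univariately significant factors ----
  sig_factors <- names(Filter(function(l) is.finite(l$p) &&
                                l$p < p_univariate, logrank))
  sig_factors <- setdiff(sig_factors, "mai3")  # avoid duplicating MAI
  cox_multi <- NULL
  if (length(sig_factors) > 0L) {
    cand <- do.call(cbind, lapply(sig_factors, function(nm) {
      g <- droplevels(factors[[nm]])
      mm <- stats::model.matrix(~g)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(nm, "_", levels(g)[-1L])
      mm
    }))
    cox_multi <- tryCatch(
      cox_forward_wald(cand, records, p_enter = p_univariate,
                       direction = stepwise_direction),
      error = function(e) NULL)
  }

  ## ---- supervised gene selection + LOOCV ----
  gene_tests <- stage("anova", anova_per_gene(z, event))
  selected <- select_genes(gene_tests, alpha = alpha)
  # LOOCV standardizes inside each fold, so it gets the raw-scale matrix
  cv <- if (run_loocv) {
    stage("loocv", loocv_with_reselection(filtered, event, alpha = alpha))
  } else {
    NULL
  }

  res <- structure(list(
    report = report,
    assignments = list(oncotype = onco_groups, mammaprint_agpp = agpp,
                       mammaprint_cluster = clus),
    cutoffs = list(rs_low = cut_low, rs_high = cut_high, roc_auc = roc$auc),
    factors = factors,
    records = records,
    logrank = logrank,
    cox_univariate = cox_uni,
    cox_multivariate = cox_multi,
    selected_genes = selected,
    cv = cv,
    km = km,
    seed = seed
  ), class = "prolifsig_analysis")

  if (!is.null(out_dir)) write_analysis(res, out_dir)
  res
}

#' @export
print.prolifsig_analysis <- function(x, ...) {
  cat("Distant-metastasis-free survival analysis\n")
  cat("-----------------------------------------\n")
  print(x$report, row.names = FALSE, digits = 3)
  if (!is.null(x$cv)) {
    cat("\n", length(x$selected_genes$symbols),
        " genes selected at the chosen alpha; ", sep = "")
    cat(sprintf("LOOCV accuracy %.0f%% (sens %.0f%%, spec %.0f%%)\n",
                100 * x$cv$accuracy, 100 * x$cv$sensitivity,
                100 * x$cv$specificity))
  }
  invisible(x)
}

#' Write analysis artifacts to a directory
#'
#' Writes `report.tsv` (the Table-1-style report), `results.json`
#' (cut-offs, per-factor p-values, multivariate model, CV metrics),
#' `km_curves.tsv` (per-factor Kaplan-Meier steps) and `run.log`.
#'
#' @param res A `prolifsig_analysis` object.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res$report, file.path(dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  km_rows <- do.call(rbind, unlist(lapply(names(res$km), function(nm) {
    lapply(names(res$km[[nm]]), function(lev) {
      cv <- res$km[[nm]][[lev]]
      if (length(cv$event_times) == 0L) return(NULL)
      data.frame(factor = nm, group = lev, time = cv$event_times,
                 survival = cv$survival, at_risk = cv$at_risk,
                 events = cv$events, stringsAsFactors = FALSE)
    })
  }), recursive = FALSE))
  utils::write.table(km_rows, file.path(dir, "km_curves.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  out <- list(
    cutoffs = res$cutoffs,
    logrank_p = lapply(res$logrank, `[[`, "p"),
    n_selected_genes = length(res$selected_genes$symbols),
    multivariate = if (!is.null(res$cox_multivariate)) {
      list(included = res$cox_multivariate$included,
           hr = as.list(res$cox_multivariate$hr),
           wald_p = as.list(res$cox_multivariate$wald_p))
    },
    cv = if (!is.null(res$cv)) {
      res$cv[c("accuracy", "sensitivity", "specificity",
               "tp", "tn", "fp", "fn")]
    },
    seed = res$seed
  )
  jsonlite::write_json(out, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg_file <- file.path(dir, "results.json")
  writeLines(c(
    paste("run at:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste("seed:", res$seed),
    paste("results md5:", unname(tools::md5sum(cfg_file)))
  ), file.path(dir, "run.log"))
  invisible(dir)
}
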