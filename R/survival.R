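#' Encode distant-metastasis-free survival records
#'
#' DMFS counts distant metastasis and breast-cancer death as events;
#' other-cause death, locoregional recurrence, second primaries and
#' contralateral disease censor at the last follow-up visit. Two input
#' layouts are accepted:
#' \itemize{
#'   \item pre-encoded: columns `follow_up_months` and `dmfs_event` are
#'     taken as is;
#'   \item event-type: columns `last_followup_months` and `event_type`
#'     (one of `distant_metastasis`, `breast_cancer_death`,
#'     `other_death`, `locoregional`, `second_primary`, `contralateral`,
#'     `alive`), with optional `recurrence_months`. Metastatic events use
#'     the recurrence date when available, otherwise the last follow-up
#'     date.
#' }
#'
#' @param clinical Clinical data frame with a `sample_id` column.
#' @return Data frame with `sample_id`, `time` (months), `event` (0/1).
#' @export
encode_dmfs <- function(clinical) {
  if (!"sample_id" %in% names(clinical)) stop("missing column: sample_id")
  if (all(c("follow_up_months", "dmfs_event") %in% names(clinical))) {
    time <- clinical$follow_up_months
    event <- as.integer(clinical$dmfs_event)
  } else if (all(c("last_followup_months", "event_type") %in%
                 names(clinical))) {
    types <- c("distant_metastasis", "breast_cancer_death", "other_death",
               "locoregional", "second_primary", "contralateral", "alive")
    bad <- setdiff(unique(clinical$event_type), types)
    if (length(bad) > 0L) {
      stop("unknown event_type value(s): ", paste(bad, collapse = ", "))
    }
    is_event <- clinical$event_type %in%
      c("distant_metastasis", "breast_cancer_death")
    rec <- if ("recurrence_months" %in% names(clinical)) {
      clinical$recurrence_months
    } else {
      rep(NA_real_, nrow(clinical))
    }
    time <- ifelse(is_event & !is.na(rec), rec,
                   clinical$last_followup_months)
    event <- as.integer(is_event)
  } else {
    stop("clinical table needs either (follow_up_months, dmfs_event) or ",
         "(last_followup_months, event_type) columns")
  }
  miss <- clinical$sample_id[!is.finite(time) | time <= 0]
  if (length(miss) > 0L) {
    stop("missing or non-positive follow-up time for sample(s): ",
         paste(miss, collapse = ", "))
  }
  if (!all(event %in% c(0L, 1L))) stop("event indicator must be binary")
  data.frame(sample_id = clinical$sample_id, time = as.numeric(time),
             event = event, stringsAsFactors = FALSE)
}

#' Kaplan-Meier product-limit curve
#'
#' Wraps [survival::survfit()]; censored observations tied with events at
#' the same time are, per the product-limit convention, treated as at
#' risk for that event.
#'
#' @param records Data frame with `time` and `event` columns (as from
#'   [encode_dmfs()]).
#' @return Object of class `km_curve` with `event_times` (distinct times
#'   with >= 1 event), `survival`, `at_risk`, `events`, and the total
#'   sample size `n`.
#' @export
km_estimate <- function(records) {
  if (nrow(records) == 0L) stop("no survival records")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  keep <- fit$n.event > 0
  structure(list(event_times = fit$time[keep],
                 survival = fit$surv[keep],
                 at_risk = fit$n.risk[keep],
                 events = fit$n.event[keep],
                 n = nrow(records)),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Right-continuous step-function evaluation; times before the first
#' event return 1.
#'
#' @param curve A `km_curve` object.
#' @param t Time (months), t >= 0.
#' @return Survival probability at `t`.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), t >= 0)
  if (length(curve$event_times) == 0L) return(1)
  i <- findInterval(t, curve$event_times)
  if (i == 0L) 1 else curve$survival[i]
}

#' Log-rank test between survival record groups
#'
#' Standard log-rank chi-square on k groups (k - 1 degrees of freedom),
#' via [survival::survdiff()].
#'
#' @param groups Either a named list of record data frames (each with
#'   `time`, `event`) or a single record data frame, in which case
#'   `group` must give the per-record group membership.
#' @param group Optional grouping vector used with a single data frame.
#' @return List with `chi2`, `df`, `p`.
#' @export
logrank_test <- function(groups, group = NULL) {
  if (is.data.frame(groups)) {
    stopifnot(!is.null(group), length(group) == nrow(groups))
    df <- data.frame(time = groups$time, event = groups$event,
                     g = factor(group))
  } else {
    sizes <- vapply(groups, nrow, integer(1))
    if (any(sizes == 0L)) stop("every group must contain records")
    df <- do.call(rbind, lapply(seq_along(groups), function(i) {
      data.frame(time = groups[[i]]$time, event = groups[[i]]$event, g = i)
    }))
    df$g <- factor(df$g)
  }
  if (nlevels(df$g) < 2L) stop("need at least two groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  df_chi <- nlevels(df$g) - 1L
  list(chi2 = as.numeric(sd$chisq), df = df_chi,
       p = stats::pchisq(as.numeric(sd$chisq), df_chi, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization via [survival::coxph()] with Breslow
#' tie handling (Efron available). Confidence intervals are Wald-type,
#' exp(coef +/- 1.96 * SE); p-values are per-covariate Wald tests.
#'
#' @param covariates Numeric matrix or data frame, one row per record.
#' @param records Data frame with `time` and `event`.
#' @param ties Tie-handling method.
#' @return Object of class `cox_result` with `coefficients`, `se`, `hr`,
#'   `ci_lower`, `ci_upper`, `wald_p`, `included` and `n_events`.
#' @export
cox_fit <- function(covariates, records, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  x <- as.matrix(covariates)
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  stopifnot(nrow(x) == nrow(records))
  constant <- apply(x, 2L, function(v) stats::sd(v) == 0)
  if (any(constant)) {
    stop("constant covariate(s): ",
         paste(colnames(x)[constant], collapse = ", "))
  }
  if (sum(records$event) < ncol(x)) {
    stop("fewer events than covariates; model not identifiable")
  }
  fit <- tryCatch(
    survival::coxph(survival::Surv(records$time, records$event) ~ x,
                    ties = ties,
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) {
        stop("partial likelihood is monotone (complete separation) or ",
             "did not converge: ", conditionMessage(w))
      }
      suppressWarnings(
        survival::coxph(survival::Surv(records$time, records$event) ~ x,
                        ties = ties,
                        control = survival::coxph.control(iter.max = 50)))
    })
  coefs <- stats::coef(fit)
  if (any(!is.finite(coefs)) || any(abs(coefs) > 15)) {
    stop("partial likelihood is monotone (complete separation); ",
         "coefficient diverges")
  }
  se <- sqrt(diag(fit$var))
  names(coefs) <- colnames(x)
  names(se) <- colnames(x)
  z <- coefs / se
  structure(list(coefficients = coefs, se = se,
                 hr = exp(coefs),
                 ci_lower = exp(coefs - 1.96 * se),
                 ci_upper = exp(coefs + 1.96 * se),
                 wald_p = 2 * stats::pnorm(-abs(z)),
                 included = colnames(x),
                 n_events = sum(records$event),
                 loglik = fit$loglik[length(fit$loglik)]),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  tab <- data.frame(coef = x$coefficients, HR = x$hr,
                    `95% CI` = sprintf("%.2f-%.2f", x$ci_lower, x$ci_upper),
                    `Wald p` = signif(x$wald_p, 3), check.names = FALSE)
  print(tab)
  invisible(x)
}

#' Stepwise Cox model selection by Wald p-value
#'
#' Forward: starting from the empty model, repeatedly add the candidate
#' with the smallest Wald p-value below `p_enter` until none qualifies.
#' Backward: starting from the full model, repeatedly drop the covariate
#' with the largest Wald p-value above `p_remove` until all remaining
#' covariates are below it.
#'
#' @param candidates Named numeric matrix or data frame of candidate
#'   covariates, one row per record.
#' @param records Data frame with `time` and `event`.
#' @param p_enter Entry threshold for forward selection.
#' @param p_remove Removal threshold for backward elimination; defaults
#'   to `p_enter`.
#' @param direction Selection direction.
#' @param ties Tie handling passed to [cox_fit()].
#' @return A `cox_result` for the final model (or `NULL` if forward
#'   selection admits no covariate), with an attribute `trace` listing
#'   each step.
#' @export
cox_forward_wald <- function(candidates, records, p_enter = 0.05,
                             p_remove = p_enter,
                             direction = c("forward", "backward"),
                             ties = "breslow") {
  direction <- match.arg(direction)
  x <- as.data.frame(candidates)
  if (ncol(x) == 0L) stop("candidate set is empty")
  trace <- list()
  if (direction == "forward") {
    included <- character(0)
    repeat {
      remaining <- setdiff(names(x), included)
      if (length(remaining) == 0L) break
      pvals <- vapply(remaining, function(v) {
        fit <- tryCatch(
          cox_fit(x[, c(included, v), drop = FALSE], records, ties = ties),
          error = function(e) NULL)
        if (is.null(fit)) NA_real_ else fit$wald_p[[v]]
      }, numeric(1))
      if (all(is.na(pvals)) || min(pvals, na.rm = TRUE) >= p_enter) break
      best <- remaining[which.min(pvals)]
      included <- c(included, best)
      trace[[length(trace) + 1L]] <- list(action = "add", covariate = best,
                                          wald_p = min(pvals, na.rm = TRUE))
    }
    if (length(included) == 0L) {
      return(NULL)
    }
    fit <- cox_fit(x[, included, drop = FALSE], records, ties = ties)
  } else {
    included <- names(x)
    fit <- cox_fit(x, records, ties = ties)
    repeat {
      worst <- which.max(fit$wald_p)
      if (fit$wald_p[worst] <= p_remove || length(included) == 1L) break
      trace[[length(trace) + 1L]] <- list(action = "drop",
                                          covariate = included[worst],
                                          wald_p = fit$wald_p[[worst]])
      included <- included[-worst]
      fit <- cox_fit(x[, included, drop = FALSE], records, ties = ties)
    }
  }
  attr(fit, "trace") <- trace
  fit
}

#' Event-free percentage from event and at-risk counts
#'
#' round(100 * (1 - events / at_risk)) with half-away-from-zero rounding,
#' matching how event-free rates are conventionally printed next to
#' "events/at risk" counts.
#'
#' @param events Number of events.
#' @param at_risk Number of patients at risk.
#' @return Integer percentage.
#' @export
event_free_percent <- function(events, at_risk) {
  if (at_risk <= 0) stop("at_risk must be positive")
  if (events < 0 || events > at_risk) {
    stop("events must lie in [0, at_risk]")
  }
  x <- 100 * (1 - events / at_risk)
  as.integer(sign(x) * floor(abs(x) + 0.5))
}
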