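#' Configuration for the synthetic node-negative breast cancer cohort
#'
#' Defaults emulate the cohort the analysis is designed for: 94
#' lymph-node-negative patients followed for up to 171 months with about
#' a 24% distant-metastasis event rate, a proliferation-driven gene
#' module, and signature gene subsets with a planted (weaker) prognostic
#' effect.
#'
#' @param n_patients Number of patients.
#' @param n_genes Total number of genes on the simulated array.
#' @param n_signature_genes Number of signature-list genes embedded in
#'   the matrix (default 62, the typical overlap of a 70-entry signature
#'   with an annotated platform).
#' @param module_size Size of the proliferation gene module (includes the
#'   five proliferation genes of the recurrence-score assay).
#' @param module_loading Loading of module genes on the latent
#'   proliferation score.
#' @param prolif_effect Log hazard ratio per unit latent proliferation
#'   score.
#' @param signature_effect Log hazard ratio per unit planted signature
#'   score.
#' @param signature_rho Correlation between the signature score and the
#'   proliferation score (prognostic signatures are
#'   proliferation-correlated).
#' @param baseline_hazard Baseline event hazard (events per month); when
#'   `NULL` it is calibrated so the expected observed event fraction
#'   equals `event_target_rate`.
#' @param follow_up_max Administrative censoring horizon in months.
#' @param censor_rate Fraction of patients subject to random uniform
#'   dropout censoring on (0, follow_up_max]; the rest are censored
#'   administratively at `follow_up_max`.
#' @param event_target_rate Target observed event fraction used to
#'   calibrate the baseline hazard.
#' @param noise_sd Residual expression standard deviation (log2 units).
#' @param weibull_shape Shape of the event-time distribution; 1 gives the
#'   default exponential model.
#' @param seed Integer seed; identical configs give identical cohorts.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 94L, n_genes = 2000L,
                              n_signature_genes = 62L, module_size = 50L,
                              module_loading = 1.0,
                              prolif_effect = log(2.5),
                              signature_effect = log(1.3),
                              signature_rho = 0.6,
                              baseline_hazard = NULL,
                              follow_up_max = 171,
                              censor_rate = 0.9,
                              event_target_rate = 0.24,
                              noise_sd = 1.0,
                              weibull_shape = 1,
                              seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_genes = as.integer(n_genes),
              n_signature_genes = as.integer(n_signature_genes),
              module_size = as.integer(module_size),
              module_loading = module_loading,
              prolif_effect = prolif_effect,
              signature_effect = signature_effect,
              signature_rho = signature_rho,
              baseline_hazard = baseline_hazard,
              follow_up_max = follow_up_max,
              censor_rate = censor_rate,
              event_target_rate = event_target_rate,
              noise_sd = noise_sd,
              weibull_shape = weibull_shape,
              seed = as.integer(seed))
  with(cfg, {
    if (n_patients < 1L || n_genes < 1L || n_signature_genes < 1L ||
        module_size < 1L) {
      stop("configuration error: all counts must be >= 1")
    }
    if (n_signature_genes > n_genes) {
      stop("configuration error: n_signature_genes exceeds n_genes")
    }
    if (n_genes < n_signature_genes + module_size + 16L) {
      stop("configuration error: n_genes too small for the signature, ",
           "proliferation module and recurrence-score genes")
    }
    if (censor_rate < 0 || censor_rate > 1 ||
        event_target_rate < 0 || event_target_rate > 1) {
      stop("configuration error: rates must lie in [0, 1]")
    }
    if (follow_up_max <= 0) stop("configuration error: follow_up_max <= 0")
    if (noise_sd <= 0) stop("configuration error: noise_sd <= 0")
    if (abs(signature_rho) > 1) {
      stop("configuration error: signature_rho outside [-1, 1]")
    }
  })
  structure(cfg, class = "simulation_config")
}

# Expected observed-event fraction under the exponential model with
# mixed uniform/administrative censoring, integrating the normal linear
# predictor numerically.
expected_event_rate <- function(h0, eta_sd, follow_up_max, censor_rate,
                                weibull_shape = 1) {
  m <- follow_up_max
  p_event_given_eta <- function(eta) {
    lam <- h0 * exp(eta)
    if (weibull_shape == 1) {
      surv_m <- exp(-lam * m)
      # T ~ Exp(lam), C ~ U(0, m]: P(T < C) = 1 - (1 - exp(-lam*m))/(lam*m)
      p_unif <- 1 - (1 - surv_m) / (lam * m)
      p_admin <- 1 - surv_m
    } else {
      # Weibull hazard h(t) = lam * k * t^(k-1); H(t) = lam * t^k
      k <- weibull_shape
      surv <- function(t) exp(-lam * t^k)
      p_admin <- 1 - surv(m)
      p_unif <- 1 - vapply(lam, function(l) {
        stats::integrate(function(t) exp(-l * t^k) / m, 0, m)$value
      }, numeric(1))
    }
    censor_rate * p_unif + (1 - censor_rate) * p_admin
  }
  if (eta_sd == 0) {
    return(p_event_given_eta(0))
  }
  f <- function(eta) p_event_given_eta(eta) * stats::dnorm(eta, sd = eta_sd)
  stats::integrate(f, -8 * eta_sd, 8 * eta_sd)$value
}

# Solve for the baseline hazard that attains the target event fraction.
calibrate_baseline_hazard <- function(cfg) {
  eta_sd <- sqrt((cfg$prolif_effect + cfg$signature_effect *
                    cfg$signature_rho)^2 +
                   (cfg$signature_effect *
                      sqrt(1 - cfg$signature_rho^2))^2)
  target <- cfg$event_target_rate
  f <- function(log_h0) {
    expected_event_rate(exp(log_h0), eta_sd, cfg$follow_up_max,
                        cfg$censor_rate, cfg$weibull_shape) - target
  }
  exp(stats::uniroot(f, c(-16, 4), tol = 1e-10)$root)
}

#' Simulate a synthetic node-negative breast cancer cohort
#'
#' Each patient carries a latent proliferation score z ~ N(0, 1) and a
#' signature score s = rho * z + sqrt(1 - rho^2) * e. Proliferation
#' module genes (including the five recurrence-score proliferation
#' genes) load on z, signature-list genes load on s, and all other genes
#' are pure noise, each around a gene-specific baseline on the log2
#' scale. The tissue proliferation markers (MAI, PPH3 count, Ki67
#' percent) are monotone noisy transforms of z, thresholded so that the
#' default cohort splits near the conventional clinical cut-points.
#' Event times follow a (by default exponential) proportional-hazards
#' model with linear predictor prolif_effect * z + signature_effect * s;
#' censoring is an independent uniform dropout time on
#' (0, follow_up_max] for a `censor_rate` fraction of patients and
#' administrative at `follow_up_max` otherwise.
#'
#' @param config A [simulation_config()].
#' @return Object of class `synthetic_cohort`: `expression` (gene x
#'   sample matrix), `clinical` (data frame), and `truth` (latent scores,
#'   true risk label and uncensored event time; for tests only, never for
#'   analysis).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  n <- cfg$n_patients
  h0 <- cfg$baseline_hazard %||% calibrate_baseline_hazard(cfg)

  set.seed(cfg$seed)

  sample_ids <- sprintf("P%03d", seq_len(n))
  z <- stats::rnorm(n)
  s <- cfg$signature_rho * z +
    sqrt(1 - cfg$signature_rho^2) * stats::rnorm(n)

  ## ---- survival ----
  eta <- cfg$prolif_effect * z + cfg$signature_effect * s
  lam <- h0 * exp(eta)
  u <- stats::runif(n)
  true_time <- if (cfg$weibull_shape == 1) {
    -log(u) / lam
  } else {
    (-log(u) / lam)^(1 / cfg$weibull_shape)
  }
  dropout <- stats::runif(n) < cfg$censor_rate
  censor_time <- ifelse(dropout, stats::runif(n, 0, cfg$follow_up_max),
                        cfg$follow_up_max)
  time_obs <- pmin(true_time, censor_time)
  event <- as.integer(true_time <= censor_time)
  time_obs <- pmax(time_obs, 0.5)  # months; avoid zero follow-up

  ## ---- proliferation markers: monotone noisy transforms of z ----
  mai <- pmax(0L, as.integer(round(exp(log(8) + 0.9 * z +
                                         0.4 * stats::rnorm(n)))))
  pph3 <- pmax(0L, as.integer(round(exp(log(13) + 0.9 * z +
                                          0.35 * stats::rnorm(n)))))
  ki67 <- pmin(100L, pmax(0L, as.integer(round(
    100 * stats::plogis(-2.0 + 1.0 * z + 0.5 * stats::rnorm(n))))))

  ## ---- other clinical covariates ----
  age <- pmin(90L, pmax(30L, as.integer(round(stats::rnorm(n, 60, 12)))))
  diameter <- round(pmin(8, pmax(0.4, stats::rlnorm(n, log(1.8), 0.45))), 1)
  grade_lin <- z + stats::rnorm(n, sd = 0.8)
  grade <- cut(grade_lin, c(-Inf, stats::qnorm(0.15, sd = sqrt(1.64)),
                            stats::qnorm(0.60, sd = sqrt(1.64)), Inf),
               labels = FALSE)
  er <- as.integer(stats::runif(n) < stats::plogis(1.6 - 0.5 * z))
  pr <- as.integer(stats::runif(n) < stats::plogis(1.4 - 0.5 * z))
  her2 <- as.integer(stats::runif(n) < 0.15)
  ck56 <- as.integer(stats::runif(n) < 0.13)
  tnp <- as.integer(er == 0L & pr == 0L & her2 == 0L)

  clinical <- data.frame(
    sample_id = sample_ids, age = age, tumour_diameter_cm = diameter,
    grade = grade, er_status = er, pr_status = pr, her2_status = her2,
    ck56_status = ck56, tnp_status = tnp, mai = mai, ki67 = ki67,
    pph3 = pph3, follow_up_months = round(time_obs, 1),
    dmfs_event = event, stringsAsFactors = FALSE)

  ## ---- expression ----
  onco <- oncotype_signature()
  prolif_genes <- onco$symbols[onco$roles == "proliferation"]
  other_onco <- setdiff(onco$symbols, prolif_genes)
  mp <- mammaprint_signature()
  sig_genes <- setdiff(utils::head(mp$symbols, cfg$n_signature_genes),
                       onco$symbols)
  n_module_extra <- cfg$module_size - length(prolif_genes)
  module_extra <- sprintf("PROLIF_%03d", seq_len(n_module_extra))
  n_noise <- cfg$n_genes - length(prolif_genes) - length(other_onco) -
    length(sig_genes) - n_module_extra
  noise_genes <- sprintf("GENE_%05d", seq_len(n_noise))
  gene_ids <- c(prolif_genes, module_extra, sig_genes, other_onco,
                noise_genes)

  baseline <- stats::rnorm(cfg$n_genes, 7, 1)
  expr <- matrix(stats::rnorm(cfg$n_genes * n, sd = cfg$noise_sd),
                 nrow = cfg$n_genes, ncol = n,
                 dimnames = list(gene_ids, sample_ids))
  expr <- expr + baseline
  module_rows <- c(prolif_genes, module_extra)
  expr[module_rows, ] <- expr[module_rows, ] +
    cfg$module_loading * rep(z, each = length(module_rows))
  expr[sig_genes, ] <- expr[sig_genes, ] +
    cfg$module_loading * rep(s, each = length(sig_genes))

  truth <- data.frame(sample_id = sample_ids, prolif_score = z,
                      signature_score = s,
                      true_risk = ifelse(z >= 0, "high", "low"),
                      true_event_time = true_time,
                      stringsAsFactors = FALSE)

  structure(list(expression = expr, clinical = clinical, truth = truth,
                 config = cfg, baseline_hazard = h0),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  ec <- event_counts(x)
  cat(sprintf(
    "Synthetic cohort: %d patients, %d genes, %d DMFS events (%.0f%%)\n",
    ncol(x$expression), nrow(x$expression), ec[["events"]],
    100 * ec[["events"]] / ec[["at_risk"]]))
  invisible(x)
}

#' Count events and patients in a cohort
#'
#' @param cohort A `synthetic_cohort` (or any list with a `clinical`
#'   data frame carrying `dmfs_event`).
#' @return Named integer vector `c(events, at_risk)`.
#' @export
event_counts <- function(cohort) {
  cl <- cohort$clinical
  if (is.null(cl) || nrow(cl) == 0L) stop("empty cohort")
  c(events = sum(cl$dmfs_event == 1L), at_risk = nrow(cl))
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `expression.tsv` (genes x samples), `clinical.csv`, and
#' `truth.csv` (clearly marked as simulation ground truth, not analysis
#' input) into `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.csv"))
  utils::write.csv(cohort$truth,
                   file.path(dir, "truth.NOT_FOR_ANALYSIS.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
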