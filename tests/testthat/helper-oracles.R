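# Independent oracles, deliberately naive: each re-derives a quantity from
# first principles so package output can be checked against a second route.

# Product-limit estimator by direct accumulation.
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  list(event_times = ts, survival = surv)
}

# Two-group log-rank chi-square by hypergeometric accumulation over the
# distinct event times.
logrank_oracle <- function(time, event, group) {
  group <- as.integer(factor(group))
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1L)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  chi2 <- o_minus_e^2 / v
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

# Breslow partial log-likelihood for a single covariate.
cox_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    dead <- which(time == t & event == 1)
    at_risk <- which(time >= t)
    ll <- ll + sum(beta * x[dead]) -
      length(dead) * log(sum(exp(beta * x[at_risk])))
  }
  ll
}

cox_grid_search <- function(time, event, x, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, cox_partial_loglik, numeric(1),
               time = time, event = event, x = x)
  grid[which.max(ll)]
}

# Naive average-linkage agglomeration on a distance matrix; returns the
# two-cluster partition as an integer vector.
naive_two_clusters <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > 2L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  out <- integer(n)
  out[clusters[[1L]]] <- 1L
  out[clusters[[2L]]] <- 2L
  out
}

# Exhaustive sensitivity/specificity at a threshold ("score >= t is
# positive") for brute-force ROC checks.
brute_sens_spec <- function(scores, outcome, t) {
  c(sens = sum(scores >= t & outcome == 1) / sum(outcome == 1),
    spec = sum(scores < t & outcome == 0) / sum(outcome == 0))
}

# Small random expression matrix with dimnames.
random_matrix <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples),
         nrow = n_genes,
         dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                         sprintf("S%03d", seq_len(n_samples))))
}

# Separable two-class expression fixture: the signal genes carry mirror
# profiles (+e/2 vs -e/2 with alternating sign), so each class has a
# distinctive shape that a correlation-based centroid classifier can key
# on. A one-sided level shift would be invisible after per-sample
# centring.
planted_separable_matrix <- function(n_samples = 40, n_genes = 200,
                                     n_signal = 20, magnitude = 4,
                                     seed = 35) {
  g <- rep(c(0L, 1L), each = n_samples / 2)
  m <- random_matrix(n_genes, n_samples, seed = seed)
  effect <- rep(c(1, -1), length.out = n_signal) * magnitude *
    seq(0.8, 1.2, length.out = n_signal)
  m[seq_len(n_signal), g == 0L] <- m[seq_len(n_signal), g == 0L] - effect / 2
  m[seq_len(n_signal), g == 1L] <- m[seq_len(n_signal), g == 1L] + effect / 2
  list(matrix = m, labels = g)
}
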