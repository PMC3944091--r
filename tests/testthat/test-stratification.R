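test_that("perfectly separated scores give AUC 1 and a zero-distance cutoff", {
  scores <- c(1, 2, 3, 10, 11, 12)
  outcome <- c(0, 0, 0, 1, 1, 1)
  roc <- roc_curve(scores, outcome)
  expect_equal(roc$auc, 1)
  cut <- optimal_cutoff(roc)
  expect_true(cut > 3 && cut <= 10)
  i <- match(cut, roc$thresholds)
  expect_equal(roc$sensitivity[i], 1)
  expect_equal(roc$specificity[i], 1)
  expect_equal(second_cutoff_high_sensitivity(roc), cut)
})

test_that("single-class outcomes are rejected", {
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "both outcome classes")
})

test_that("ROC points equal exhaustive threshold enumeration on a toy set", {
  scores <- c(0.1, 0.4, 0.35, 0.8, 0.65, 0.2)
  outcome <- c(0, 0, 1, 1, 1, 0)
  roc <- roc_curve(scores, outcome)
  for (i in seq_along(roc$thresholds)) {
    bs <- brute_sens_spec(scores, outcome, roc$thresholds[i])
    expect_equal(roc$sensitivity[i], bs[["sens"]])
    expect_equal(roc$specificity[i], bs[["spec"]])
  }
  # AUC agrees with an independent implementation
  expect_equal(roc$auc,
               as.numeric(pROC::auc(outcome, scores, quiet = TRUE)))
})

test_that("null scores give chance-level AUC", {
  set.seed(21)
  scores <- rnorm(2000)
  outcome <- rbinom(2000, 1, 0.3)
  expect_lt(abs(roc_curve(scores, outcome)$auc - 0.5), 0.05)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(22)
  scores <- rnorm(50)
  outcome <- rbinom(50, 1, 0.4)
  a <- roc_curve(scores, outcome)$auc
  expect_equal(roc_curve(exp(scores), outcome)$auc, a)
  expect_equal(roc_curve(scores^3, outcome)$auc, a)
})

test_that("optimal cutoff minimizes distance to the (0,1) corner", {
  set.seed(23)
  scores <- rnorm(40)
  outcome <- rbinom(40, 1, 0.4)
  roc <- roc_curve(scores, outcome)
  cut <- optimal_cutoff(roc)
  d <- (1 - roc$specificity)^2 + (1 - roc$sensitivity)^2
  expect_equal(d[match(cut, roc$thresholds)], min(d))
  # Youden alternative maximizes sensitivity + specificity
  cy <- optimal_cutoff(roc, criterion = "youden")
  j <- roc$sensitivity + roc$specificity - 1
  expect_equal(j[match(cy, roc$thresholds)], max(j))
})

test_that("optimal cutoff ties break toward higher specificity", {
  # two operating points symmetric around the diagonal:
  # (sens .8, spec .6) and (sens .6, spec .8) are equidistant from (0,1)
  scores <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  outcome <- c(0, 1, 0, 0, 0, 1, 1, 1, 1, 0)
  roc <- roc_curve(scores, outcome)
  d <- round((1 - roc$specificity)^2 + (1 - roc$sensitivity)^2, 12)
  ties <- which(d == min(d))
  if (length(ties) > 1) {
    expect_equal(optimal_cutoff(roc),
                 roc$thresholds[ties][which.max(roc$specificity[ties])])
  }
  # explicit synthetic check of the documented rule on a known tie
  scores2 <- c(1, 2, 3, 4)
  outcome2 <- c(1, 0, 1, 0)  # symmetric operating points
  roc2 <- roc_curve(scores2, outcome2)
  d2 <- (1 - roc2$specificity)^2 + (1 - roc2$sensitivity)^2
  cut2 <- optimal_cutoff(roc2)
  i2 <- match(cut2, roc2$thresholds)
  tied <- which(abs(d2 - d2[i2]) < 1e-12)
  expect_equal(roc2$specificity[i2], max(roc2$specificity[tied]))
})

test_that("high-sensitivity cutoff equals brute-force constrained maximization", {
  set.seed(24)
  scores <- rnorm(60)
  outcome <- rbinom(60, 1, 0.35)
  roc <- roc_curve(scores, outcome)
  for (ms in c(0.8, 0.9, 1.0)) {
    cut <- second_cutoff_high_sensitivity(roc, min_sensitivity = ms)
    ok <- roc$sensitivity >= ms
    best_spec <- max(roc$specificity[ok])
    i <- match(cut, roc$thresholds)
    expect_gte(roc$sensitivity[i], ms)
    expect_equal(roc$specificity[i], best_spec)
    cand <- roc$thresholds[ok & roc$specificity == best_spec]
    expect_equal(cut, min(cand))
  }
  expect_error(second_cutoff_high_sensitivity(roc, min_sensitivity = 2),
               "lower min_sensitivity")
})

test_that("three-group assignment uses half-open interval conventions", {
  ra <- assign_three_groups(c(a = -1, b = 0.5, c = 2), 0, 1)
  expect_equal(as.character(ra$label), c("low", "medium", "high"))
  # equal cuts: medium is empty, score >= cut -> high
  ra2 <- assign_three_groups(c(x = -0.1, y = 0, z = 0.1), 0, 0)
  expect_equal(as.character(ra2$label), c("low", "high", "high"))
  expect_error(assign_three_groups(1:3, 1, 0), "cut_low")
})

test_that("percentile cuts reproduce an 18/42/34 grouping on 94 scores", {
  set.seed(25)
  scores <- rnorm(94)
  s <- sort(scores)
  ra <- assign_three_groups(scores, s[19], s[61])
  expect_equal(as.vector(table(ra$label)), c(18L, 42L, 34L))
  expect_equal(sum(table(ra$label)), 94L)
})

test_that("three-group labels partition every sample", {
  set.seed(26)
  scores <- rnorm(50)
  ra <- assign_three_groups(scores, -0.5, 0.5)
  expect_equal(nrow(ra), 50L)
  expect_false(anyNA(ra$label))
})

test_that("two-cluster risk recovers planted blocks and labels by event rate", {
  set.seed(27)
  base1 <- rnorm(30)
  base2 <- rnorm(30)
  # two blocks of mutually correlated samples
  m <- cbind(sapply(1:5, function(i) base1 + rnorm(30, sd = 0.05)),
             sapply(1:5, function(i) base2 + rnorm(30, sd = 0.05)))
  dimnames(m) <- list(paste0("G", 1:30), paste0("S", 1:10))
  sig <- signature_genes("sig", rownames(m))
  events <- c(rep(0, 5), rep(1, 4), 0)  # block 2 event-enriched
  ra <- two_cluster_risk(m, sig, "pearson", events)
  expect_equal(as.character(ra$label),
               c(rep("low", 5), rep("high", 5)))
})

test_that("two-cluster partition matches a naive average-linkage oracle", {
  m <- random_matrix(25, 12, seed = 28)
  sig <- signature_genes("sig", rownames(m))
  events <- rbinom(12, 1, 0.4)
  ra <- two_cluster_risk(m, sig, "pearson", events)
  d <- 1 - cor(m)
  oracle <- naive_two_clusters(as.dist(d))
  # same partition up to label swap
  agree <- mean((ra$score == 1) == (oracle == 1))
  expect_true(agree %in% c(0, 1))
})

test_that("degenerate clustering inputs are rejected", {
  m <- matrix(rep(c(1, 2, 3), 4), nrow = 3,
              dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
  sig <- signature_genes("sig", rownames(m))
  expect_error(two_cluster_risk(m, sig, "pearson", c(0, 1, 0, 1)),
               "identical|constant")
})
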