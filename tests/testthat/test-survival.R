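test_that("DMFS encoding follows the endpoint rules", {
  cl <- data.frame(
    sample_id = c("a", "b", "c", "d", "e"),
    last_followup_months = c(100, 80, 60, 120, 90),
    recurrence_months = c(40, NA, NA, NA, NA),
    event_type = c("distant_metastasis", "distant_metastasis",
                   "other_death", "locoregional", "alive"),
    stringsAsFactors = FALSE)
  rec <- encode_dmfs(cl)
  # metastasis with recurrence date: event at that date
  expect_equal(rec$time[1], 40)
  expect_equal(rec$event[1], 1L)
  # metastasis without recurrence date: event at last follow-up
  expect_equal(rec$time[2], 80)
  expect_equal(rec$event[2], 1L)
  # other-cause death / locoregional recurrence censor at last follow-up
  expect_equal(rec$event[3:5], c(0L, 0L, 0L))
  expect_equal(rec$time[3:5], c(60, 120, 90))

  expect_error(encode_dmfs(data.frame(sample_id = "x")), "columns")
  cl$last_followup_months[3] <- NA
  expect_error(encode_dmfs(cl), "c")
  expect_error(encode_dmfs(data.frame(
    sample_id = "x", last_followup_months = 10, event_type = "weird")),
    "weird")
})

test_that("encoded events agree with generator truth where uncensored", {
  co <- simulate_cohort(simulation_config(n_genes = 150L, seed = 13))
  rec <- encode_dmfs(co$clinical)
  ev <- rec$event == 1L
  # events occur exactly at the (rounded) true event time
  expect_true(all(abs(rec$time[ev] -
                        pmax(co$truth$true_event_time[ev], 0.5)) <= 0.06))
  # censored observations precede their true event time
  expect_true(all(rec$time[!ev] <= co$truth$true_event_time[!ev] + 0.06))
})

test_that("product-limit estimates match hand calculations", {
  rec <- data.frame(time = c(1, 2), event = c(1, 1))
  km <- km_estimate(rec)
  expect_equal(km$survival, c(0.5, 0))
  expect_equal(km$at_risk, c(2, 1))

  rec2 <- data.frame(time = c(1, 2), event = c(1, 0))
  km2 <- km_estimate(rec2)
  expect_equal(km2$event_times, 1)
  expect_equal(km2$survival, 0.5)

  expect_error(km_estimate(data.frame(time = numeric(0),
                                      event = integer(0))), "no survival")
})

test_that("KM curve equals the independent product-limit oracle", {
  set.seed(41)
  rec <- data.frame(time = sample(1:15, 20, replace = TRUE),
                    event = rbinom(20, 1, 0.6))
  km <- km_estimate(rec)
  oracle <- km_oracle(rec$time, rec$event)
  expect_equal(km$event_times, oracle$event_times)
  expect_equal(km$survival, oracle$survival, tolerance = 1e-12)
})

test_that("step-function evaluation is right-continuous", {
  rec <- data.frame(time = c(5, 10, 15), event = c(1, 1, 1))
  km <- km_estimate(rec)
  expect_equal(survival_at(km, 0), 1)
  expect_equal(survival_at(km, 4.99), 1)
  expect_equal(survival_at(km, 5), 2 / 3)
  expect_equal(survival_at(km, 1000), 0)
})

test_that("without early censoring, tail survival equals 1 - events/n", {
  set.seed(42)
  n <- 30
  times <- rexp(n, 0.02)
  event <- as.integer(times < 50)
  times[event == 0] <- 50  # administrative censoring after all events
  km <- km_estimate(data.frame(time = times, event = event))
  expect_equal(survival_at(km, 49.99), 1 - sum(event) / n, tolerance = 1e-12)
})

test_that("log-rank of identical groups is null and label-invariant", {
  rec <- data.frame(time = c(2, 4, 6, 8), event = c(1, 0, 1, 1))
  lr <- logrank_test(list(a = rec, b = rec))
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)

  set.seed(43)
  rec2 <- data.frame(time = rexp(40, 0.1), event = rbinom(40, 1, 0.7))
  g <- rep(c("x", "y"), 20)
  a <- logrank_test(rec2, g)
  b <- logrank_test(rec2, ifelse(g == "x", "y", "x"))
  expect_equal(a$chi2, b$chi2)
})

test_that("log-rank chi-square equals the hypergeometric accumulation oracle", {
  set.seed(44)
  for (rep in 1:5) {
    rec <- data.frame(time = sample(1:12, 30, replace = TRUE),
                      event = rbinom(30, 1, 0.6))
    g <- rbinom(30, 1, 0.5)
    if (length(unique(g)) < 2) next
    lr <- logrank_test(rec, g)
    oracle <- logrank_oracle(rec$time, rec$event, g)
    expect_equal(lr$chi2, oracle$chi2, tolerance = 1e-10)
    expect_equal(lr$p, oracle$p, tolerance = 1e-10)
  }
})

test_that("log-rank p-values are uniform under the null", {
  set.seed(45)
  pvals <- vapply(1:500, function(i) {
    rec <- data.frame(time = rexp(60, 0.05), event = rbinom(60, 1, 0.7))
    logrank_test(rec, rep(c(0, 1), 30))$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Cox fit is null for identical event patterns", {
  rec <- data.frame(time = rep(c(2, 5, 9, 12), 2),
                    event = rep(c(1, 0, 1, 1), 2))
  x <- rep(c(0, 1), each = 4)
  fit <- cox_fit(cbind(grp = x), rec)
  expect_equal(unname(fit$coefficients), 0, tolerance = 1e-8)
  expect_equal(unname(fit$hr), 1, tolerance = 1e-8)
  expect_gt(fit$wald_p[["grp"]], 0.99)
})

test_that("Cox coefficient matches a partial-likelihood grid search", {
  rec <- data.frame(time = c(3, 5, 7, 2, 11, 8, 14, 9),
                    event = c(1, 1, 0, 1, 1, 0, 1, 1))
  x <- c(0.5, -1.2, 0.3, 1.8, -0.7, 0.9, -1.5, 0.2)
  fit <- cox_fit(cbind(x = x), rec)
  beta_grid <- cox_grid_search(rec$time, rec$event, x)
  expect_equal(unname(fit$coefficients), beta_grid, tolerance = 1e-4)
  # CI bounds are exp(coef +/- 1.96 SE)
  expect_equal(unname(fit$ci_lower),
               exp(unname(fit$coefficients) - 1.96 * unname(fit$se)))
  expect_equal(unname(fit$ci_upper),
               exp(unname(fit$coefficients) + 1.96 * unname(fit$se)))
})

test_that("degenerate Cox inputs raise informative errors", {
  rec <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 1, 1))
  expect_error(cox_fit(cbind(k = rep(1, 4)), rec), "constant")
  expect_error(cox_fit(cbind(a = rnorm(4), b = rnorm(4), c = rnorm(4),
                             d = rnorm(4), e = rnorm(4)),
                       data.frame(time = 1:4, event = c(1, 0, 0, 0))),
               "fewer events")
  # complete separation: all events in one group, ordered times
  rec2 <- data.frame(time = c(1, 2, 3, 4, 10, 11, 12, 13),
                     event = c(1, 1, 1, 1, 0, 0, 0, 0))
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_error(cox_fit(cbind(x = x), rec2), "monotone|separation")
})

test_that("forward Wald selection keeps the strong covariate only", {
  set.seed(46)
  n <- 150
  strong <- rnorm(n)
  null1 <- rnorm(n)
  null2 <- rnorm(n)
  times <- rexp(n, 0.02 * exp(1.2 * strong))
  cens <- runif(n, 0, 60)
  rec <- data.frame(time = pmin(times, cens),
                    event = as.integer(times <= cens))
  fit <- cox_forward_wald(data.frame(strong = strong, null1 = null1,
                                     null2 = null2), rec)
  expect_true("strong" %in% fit$included)
  trace <- attr(fit, "trace")
  expect_equal(trace[[1]]$covariate, "strong")

  back <- cox_forward_wald(data.frame(strong = strong, null1 = null1,
                                      null2 = null2), rec,
                           direction = "backward")
  expect_true("strong" %in% back$included)
  expect_error(cox_forward_wald(data.frame(), rec), "empty")
})

test_that("all-null forward selection rarely admits a covariate", {
  set.seed(47)
  admitted <- vapply(1:60, function(i) {
    n <- 60
    rec <- data.frame(time = rexp(n, 0.05), event = rbinom(n, 1, 0.7))
    fit <- cox_forward_wald(data.frame(a = rnorm(n), b = rnorm(n)), rec)
    !is.null(fit)
  }, logical(1))
  # familywise null admission for two candidates at p_enter 0.05 is
  # roughly 10%; allow a generous Monte-Carlo band
  expect_lt(mean(admitted), 0.3)
})

test_that("event-free percentages round half away from zero", {
  expect_equal(event_free_percent(6, 45), 87L)
  expect_equal(event_free_percent(17, 49), 65L)
  expect_equal(event_free_percent(0, 10), 100L)
  expect_equal(event_free_percent(6, 16), 63L)  # 62.5 rounds up
  expect_error(event_free_percent(1, 0), "positive")
  expect_error(event_free_percent(5, 4), "events")
})
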