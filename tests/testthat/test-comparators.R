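test_that("univariate significance keeps strong effects always and noise at the nominal rate", {
  # power ~ 1 regime: a beta = 5 predictor is kept in every split
  d <- generate_scenario(scenario_config(n_rows = 200, n_continuous = 3,
                                         support = 1L, beta = 5,
                                         noise_sd = 1, seed = 91))
  plan <- make_splits(200, 40, 10, seed = 8)
  kept <- vapply(plan$splits, function(sp) {
    res <- significant_model(d$table, sp, d$outcome_spec, "linear")
    1L %in% res$selected
  }, logical(1))
  expect_true(all(kept))

  # type-I regime: pure noise predictors kept at about alpha.  Splits of a
  # single dataset share ~90% of their training rows, so independent
  # datasets (one split each) carry the information here.
  keep_n <- vapply(1:80, function(ds) {
    noise <- generate_scenario(scenario_config(n_rows = 500,
                                               n_continuous = 10,
                                               support = integer(0),
                                               beta = numeric(0),
                                               noise_sd = 1, seed = 9200 + ds))
    sp <- make_splits(500, 1, 10, seed = 90 + ds)$splits[[1L]]
    length(significant_model(noise$table, sp, noise$outcome_spec,
                             "linear")$selected)
  }, numeric(1))
  rate <- sum(keep_n) / (80 * 10) # 800 split-predictor trials
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)

  # alpha = 1 keeps the full predictor set
  full <- significant_model(d$table, plan$splits[[1]], d$outcome_spec,
                            "linear", alpha = 1)
  expect_identical(full$selected, 1:3)
})

test_that("stepwise forward selection is greedy but never beats the exhaustive IC oracle", {
  d <- generate_scenario(scenario_config(n_rows = 150, n_continuous = 4,
                                         support = c(1L, 3L), beta = c(2, -2),
                                         noise_sd = 1, seed = 77))
  plan <- make_splits(150, 10, 10, seed = 4)
  for (sp in plan$splits[1:5]) {
    res <- stepwise_forward_model(d$table, sp, d$outcome_spec, "linear")
    expect_true(all(c(1L, 3L) %in% res$selected))
    # exhaustive IC oracle over all subsets (brute force)
    all_sets <- c(list(integer(0)), brute_force_subsets(rep(1L, 4)))
    ics <- vapply(all_sets, function(s)
      holdoutbss:::subset_ic(d$table, s, sp$train, d$outcome_spec,
                             "linear", 2L), numeric(1))
    expect_gte(res$ic, min(ics) - 1e-8)
  }
  # single strong predictor is selected
  d1 <- generate_scenario(scenario_config(n_rows = 100, n_continuous = 1,
                                          support = 1L, beta = 4,
                                          noise_sd = 1, seed = 5))
  r1 <- stepwise_forward_model(d1$table, make_splits(100, 1, 10, 1)$splits[[1]],
                               d1$outcome_spec, "linear")
  expect_identical(r1$selected, 1L)
})

test_that("greedy AIC overselects on all-noise designs at the chi-square rate", {
  # first-step AIC gain for one noise predictor needs n*log(1 - r^2) + 2 < 0,
  # i.e. roughly a chi-square(1) statistic above 2; with 6 independent
  # candidates the per-split non-empty-selection probability is about
  # 1 - P(chisq(1) < 2)^6 = 0.64
  expected <- 1 - pchisq(2, 1)^6
  nonempty <- vapply(1:60, function(ds) {
    noise <- generate_scenario(scenario_config(n_rows = 500,
                                               n_continuous = 6,
                                               support = integer(0),
                                               beta = numeric(0),
                                               seed = 5500 + ds))
    sp <- make_splits(500, 1, 10, seed = 140 + ds)$splits[[1L]]
    length(stepwise_forward_model(noise$table, sp, noise$outcome_spec,
                                  "linear")$selected) > 0L
  }, logical(1))
  expect_lt(abs(mean(nonempty) - expected), 0.2)
})

test_that("the lasso path hits its limits: intercept-only at large lambda, OLS at zero", {
  d <- tiny_linear(seed = 33, n = 200)
  plan <- make_splits(200, 8, 10, seed = 3)
  big <- l1_path_model(d$table, plan, d$outcome_spec, "linear",
                       lambda = c(1e6, 1e-8))
  # at lambda -> Inf the fit is the training mean: empirical baseline error
  emp <- mean(sapply(plan$splits, function(sp)
    mean(abs(d$outcome[sp$test] - mean(d$outcome[sp$train])))))
  per_lambda <- big$per_lambda_test
  expect_equal(per_lambda[1L], emp, tolerance = 1e-6)
  # at lambda ~ 0 it matches the unpenalised full fit
  ols <- mean(sapply(plan$splits, function(sp) {
    fit <- fit_subset(d$table$design[sp$train, ], d$outcome[sp$train], "linear")
    mean(abs(d$outcome[sp$test] -
               predict_linear(fit, d$table$design[sp$test, ])))
  }))
  expect_equal(per_lambda[2L], ols, tolerance = 1e-3)
})

test_that("the chosen lasso penalty recovers sparse supports on strong signal", {
  hits <- 0L
  for (s in 1:10) {
    d <- generate_scenario(scenario_config(n_rows = 400, n_continuous = 10,
                                           support = c(2L, 7L), beta = c(3, 3),
                                           noise_sd = 1, seed = 400 + s))
    plan <- make_splits(400, 10, 10, seed = s)
    res <- l1_path_model(d$table, plan, d$outcome_spec, "linear")
    ok <- vapply(res$supports, function(su)
      !is.null(su) && all(c(2L, 7L) %in% su), logical(1))
    if (all(ok)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("comparators share the engine's exact split plan", {
  d <- tiny_linear(seed = 44, n = 120)
  fit <- holdout_select(d$table, d$outcome_spec, mode = "linear",
                        crv = 12, seed = 19)
  plan <- make_splits(fit$N, fit$crv, fit$part, fit$seed)
  cmp <- compare_methods(d$table, d$outcome_spec, mode = "linear",
                         splits = plan, methods = c("significant", "stepwise"))
  expect_identical(cmp$plan, plan) # hash-equal split plans
  expect_true(is.finite(cmp$methods$significant$test))
  expect_true(is.finite(cmp$methods$stepwise$test))
})

test_that("selected sets vary across splits on heterogeneous data", {
  # mixture of two coefficient regimes: the screen's picks are unstable
  set.seed(66)
  n <- 240
  X <- matrix(rnorm(n * 4), n, 4)
  colnames(X) <- paste0("x", 1:4)
  regime <- rep(c(0, 1), each = n / 2)
  # borderline marginal effects (t-statistics near the alpha threshold)
  y <- ifelse(regime == 0, 0.45 * X[, 1], 0.45 * X[, 2]) + rnorm(n, sd = 1.5)
  tab <- predictor_table(as.data.frame(X))
  sp_y <- encode_outcome(y, "linear")
  plan <- make_splits(n, 100, 10, seed = 77)
  sets <- lapply(plan$splits, function(sp)
    significant_model(tab, sp, sp_y, "linear")$selected)
  expect_gte(length(unique(vapply(sets, paste, "", collapse = ","))), 2L)
})

test_that("the overfitting measure is the relative generalisation gap", {
  expect_equal(overfitting_measure(1, 1, "error"), 0)
  expect_equal(overfitting_measure(1.1, 1.0, "error"), 0.1 / 1.1)
  expect_equal(overfitting_measure(0.76, 0.8, "accuracy"), 0.05)
  expect_equal(overfitting_measure(0.8, 0.8, "auroc"), 0)
  expect_true(is.na(overfitting_measure(0, 1, "error")))
})
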