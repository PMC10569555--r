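test_that("split plans have the stated sizes and are seed-deterministic", {
  sp <- make_splits(200, 10, part = 5, seed = 1)
  expect_length(sp$splits[[1]]$test, 40L)
  expect_length(sp$splits[[1]]$train, 160L)
  sp47 <- make_splits(47, 5, part = 10, seed = 2)
  expect_length(sp47$splits[[1]]$test, 4L)
  expect_length(sp47$splits[[1]]$train, 43L)
  expect_identical(make_splits(100, 20, 10, seed = 9)$splits,
                   make_splits(100, 20, 10, seed = 9)$splits)
  # disjoint, exhaustive
  s1 <- sp$splits[[3]]
  expect_length(intersect(s1$train, s1$test), 0L)
  expect_identical(sort(c(s1$train, s1$test)), 1:200)
  expect_error(make_splits(5, 2, part = 10, seed = 1))
})

test_that("reported averages are exactly recomputable from the per-model table", {
  d <- tiny_linear()
  fit <- holdout_select(d$table, d$outcome_spec, mode = "linear",
                        crv = 40, seed = 5)
  pm <- fit$per_model
  eligible <- pm$coverage >= 0.5 & !is.na(pm$test_abs)
  expect_equal(fit$header[["test_abs"]], min(pm$test_abs[eligible]))
  expect_equal(fit$header[["test_rel"]], min(pm$test_rel[eligible]))
  best_lab <- vapply(fit$best$abs, paste, "", collapse = ",")
  expect_true(all(pm$test_abs[pm$model %in% best_lab] ==
                    fit$header[["test_abs"]]))
  expect_equal(fit$header[["train_abs"]],
               pm$train_abs[pm$model == best_lab[1L]])
  # empirical baseline is averaged over the same splits
  plan <- make_splits(fit$N, fit$crv, fit$part, fit$seed)
  emp <- sapply(plan$splits, function(s)
    mean(abs(d$outcome[s$test] - mean(d$outcome[s$train]))))
  expect_equal(fit$header[["emp_abs"]], mean(emp), tolerance = 1e-12)
})

test_that("high-signal data beats the empirical baseline and recovers the support", {
  d <- tiny_linear(seed = 21, n = 200)
  fit <- holdout_select(d$table, d$outcome_spec, mode = "linear",
                        crv = 60, seed = 13)
  expect_lt(fit$header[["test_abs"]], fit$header[["emp_abs"]])
  expect_identical(fit$best$abs[[1L]], c(1L, 2L))
})

test_that("per-split EPV feasibility drives the candidate set for categorical outcomes", {
  p <- pima_like()
  # weight-6 models need >= 60 training events (rule 10); with 160-row
  # training sets that happens in only ~2.6% of splits
  fit <- holdout_select(p$table, p$outcome_spec, mode = "binary",
                        crv = 30, part = 5, maxw = 6, seed = 17,
                        min_coverage = 0.5)
  pm <- fit$per_model
  w6 <- pm$weight == 6
  expect_true(any(w6))
  expect_true(all(pm$coverage[w6] < 0.5))
  expect_gt(fit$skip_reasons[["EPV"]], 0L)
  # the coverage floor keeps those rarely-assessed models out of the ranking
  best_lab <- vapply(fit$best$acc, paste, "", collapse = ",")
  expect_true(all(pm$weight[pm$model %in% best_lab] <= 5))
})

test_that("Riley-gated candidate sets are subsets of the EPV-only sets on every split", {
  p <- pima_like()
  base <- holdout_select(p$table, p$outcome_spec, mode = "binary",
                         crv = 15, part = 5, maxw = 3, seed = 23)
  gated <- holdout_select(p$table, p$outcome_spec, mode = "binary",
                          crv = 15, part = 5, maxw = 3, seed = 23,
                          Rsq = TRUE)
  expect_gte(gated$skip_reasons[["Riley"]], 0L)
  pm_b <- base$per_model
  pm_g <- gated$per_model
  expect_identical(pm_b$model, pm_g$model)
  expect_true(all(pm_g$n_eval <= pm_b$n_eval))
})

test_that("serial and parallel runs with the same seed are bit-identical", {
  d <- tiny_linear(seed = 3, n = 100)
  fs <- holdout_select(d$table, d$outcome_spec, mode = "linear",
                       crv = 24, seed = 7, parallel = FALSE)
  fp <- holdout_select(d$table, d$outcome_spec, mode = "linear",
                       crv = 24, seed = 7, parallel = TRUE, cores = 2)
  expect_identical(fs$header, fp$header)
  expect_identical(fs$best, fp$best)
  expect_identical(fs$per_model, fp$per_model)
})

test_that("margins gate can empty the feasible set while the empirical entry survives", {
  d <- swiss_like()
  fit <- holdout_select(d$table, d$outcome_spec, mode = "linear",
                        crv = 20, seed = 31, Rsq = TRUE, marg = 0.01)
  expect_true(is.na(fit$header[["test_abs"]]))
  expect_true(is.na(fit$header[["test_rel"]]))
  expect_false(is.na(fit$header[["emp_abs"]]))
  expect_length(fit$best$abs, 0L)
})

test_that("the AUROC objective drops the empirical entry and degenerate test splits", {
  p <- pima_like()
  fit <- holdout_select(p$table, p$outcome_spec, mode = "binary",
                        crv = 20, part = 5, maxw = 4, objfun = "roc",
                        seed = 41)
  expect_named(fit$header, c("test_auroc", "train_auroc"))
  expect_null(fit$empirical)
  expect_true(fit$header[["test_auroc"]] > 0.5)
})

test_that("forced terms, correlation bound and expansion flow through the engine", {
  d <- tiny_linear(seed = 10, n = 150)
  fit <- holdout_select(d$table, d$outcome_spec, mode = "linear",
                        crv = 10, seed = 2, fixed = 3L, maxx = 3)
  expect_true(all(vapply(fit$candidates, function(s) 3L %in% s, logical(1))))
  expect_true(all(lengths(fit$candidates) <= 3L))
  # a duplicated predictor is removed by any correlation bound below 1
  dd <- cbind(d$predictors, dup = d$predictors$x1)
  fit2 <- holdout_select(dd, d$outcome, mode = "linear", crv = 5,
                         seed = 2, corr = 0.99)
  expect_false(any(vapply(fit2$candidates,
                          function(s) all(c(1L, 5L) %in% s), logical(1))))
  # quadratic expansion: candidate indices address expanded columns
  fq <- holdout_select(d$predictors[, 1:2], d$outcome, mode = "linear",
                       crv = 10, seed = 2, expand = "quadr")
  expect_identical(ncol(fq$table$design), 5L)
  expect_identical(fq$expansion$order, 2L)
  # configuration conflicts surface before computation
  expect_error(suppressWarnings(
    holdout_select(d$table, d$outcome_spec, mode = "linear",
                   crv = 5, seed = 1, fixed = 1:4, maxw = 2)),
    "no admissible|forced")
})

test_that("S3 methods expose coefficients, predictions and residuals of the refitted best model", {
  d <- tiny_linear(seed = 12, n = 150)
  fit <- holdout_select(d$table, d$outcome_spec, mode = "linear",
                        crv = 30, seed = 6)
  co <- coef(fit)
  expect_named(co, c("(Intercept)", "x1", "x2"))
  expect_equal(unname(co[2:3]), c(3, -2), tolerance = 0.3)
  pr <- predict(fit, newdata = d$predictors)
  expect_length(pr, 150L)
  expect_equal(residuals(fit), d$outcome - pr, tolerance = 1e-12)
  expect_output(print(fit), "best by abs")
  expect_output(print(summary(fit)), "Top models")

  p <- pima_like()
  fb <- holdout_select(p$table, p$outcome_spec, mode = "binary",
                       crv = 10, part = 5, maxw = 4, seed = 3)
  probs <- predict(fb, type = "probs")
  expect_equal(rowSums(probs), rep(1, 200), tolerance = 1e-12)
  cls <- predict(fb, newdata = p$predictors)
  expect_true(all(cls %in% 0:1))
})
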