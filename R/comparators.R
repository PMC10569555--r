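# Comparator selection strategies evaluated inside the identical hold-out
# framework: univariate-significance selection, stepwise forward selection
# by AIC, and L1-penalised (lasso) regression with a shared penalty grid.
# All three consume the same split plan as the main engine, so predictive
# power is directly comparable, and each records its per-split selected
# variable sets -- instability of those sets across splits is itself a
# diagnostic.

# univariate p-value of predictor j on the training rows
univariate_pvalue <- function(table, j, rows, y, mode, L) {
  X <- subset_design(table, j, rows)
  yv <- y$encoded[rows]
  d <- ncol(X)
  if (d == 0L) return(1)
  if (mode == "linear") {
    fit <- fit_subset(X, yv, "linear")
    if (is.null(fit)) return(1)
    n <- length(yv)
    if (n - d - 1L < 1L) return(1)
    R2 <- fit$R2_app
    if (R2 >= 1) return(0)
    Fstat <- (R2 / d) / ((1 - R2) / (n - d - 1L))
    stats::pf(Fstat, d, n - d - 1L, lower.tail = FALSE)
  } else {
    fit <- fit_subset(X, yv, mode, L = L)
    if (is.null(fit)) return(1)
    LR <- 2 * (fit$logLm - fit$logL0)
    stats::pchisq(max(LR, 0), df = d * (L - 1L), lower.tail = FALSE)
  }
}

# score a fitted subset (possibly empty -> empirical prediction) on one split
score_subset <- function(table, subset, sp, y, mode, L, objfun, cutoff) {
  train <- sp$train
  test <- sp$test
  ytr <- y$encoded[train]
  yte <- y$encoded[test]
  if (length(subset) == 0L) {
    if (mode == "linear") {
      te <- abs_rel_error(yte, rep(mean(ytr), length(yte)))
      tr <- abs_rel_error(ytr, rep(mean(ytr), length(ytr)))
      return(list(test = c(te$abs, te$rel), train = c(tr$abs, tr$rel)))
    }
    if (objfun == "roc")
      return(list(test = auroc(yte, rep(0.5, length(yte))),
                  train = auroc(ytr, rep(0.5, length(ytr)))))
    return(list(test = accuracy(yte, rep(0L, length(yte))),
                train = accuracy(ytr, rep(0L, length(ytr)))))
  }
  Xtr <- subset_design(table, subset, train)
  Xte <- subset_design(table, subset, test)
  fit <- fit_subset(Xtr, ytr, mode, L = L)
  if (is.null(fit)) return(NULL)
  if (mode == "linear") {
    te <- abs_rel_error(yte, predict_linear(fit, Xte))
    tr <- abs_rel_error(ytr, predict_linear(fit, Xtr))
    list(test = c(te$abs, te$rel), train = c(tr$abs, tr$rel))
  } else if (objfun == "roc") {
    list(test = auroc(yte, categorical_probs(fit, Xte)[, 2L]),
         train = auroc(ytr, categorical_probs(fit, Xtr)[, 2L]))
  } else {
    list(test = accuracy(yte, classify(categorical_probs(fit, Xte), mode, cutoff)),
         train = accuracy(ytr, classify(categorical_probs(fit, Xtr), mode, cutoff)))
  }
}

#' Significance-based model on one split
#'
#' Fits a univariate regression of the outcome on each predictor over the
#' training rows, keeps the predictors significant at level `alpha`
#' (linear: F-test; categorical: likelihood-ratio test against the null),
#' fits the joint model on the kept set and scores it on the test rows.  An
#' empty kept set falls back to the empirical prediction for that split.
#'
#' @param table a `"predictor_table"`.
#' @param sp one split, `list(train, test)`.
#' @param y an `"outcome_spec"`.
#' @param mode,objfun,cutoff as in [holdout_select()].
#' @param alpha significance level (default 0.05).
#' @return list with `selected` (indices), `test`, `train` metric values, or
#'   `NULL` on fit failure.
#' @export
significant_model <- function(table, sp, y, mode, alpha = 0.05,
                              objfun = "acc", cutoff = 0.5) {
  L <- if (mode == "linear") 2L else length(y$levels)
  cand <- which(table$weights > 0L)
  pv <- vapply(cand, univariate_pvalue, numeric(1),
               table = table, rows = sp$train, y = y, mode = mode, L = L)
  keep <- cand[pv < alpha]
  sc <- score_subset(table, keep, sp, y, mode, L, objfun, cutoff)
  if (is.null(sc)) return(NULL)
  c(list(selected = keep), sc)
}

# information criterion -2 logL + 2 k of a subset on the training rows
subset_ic <- function(table, subset, rows, y, mode, L) {
  X <- subset_design(table, subset, rows)
  yv <- y$encoded[rows]
  n <- length(yv)
  d <- ncol(X)
  if (mode == "linear") {
    fit <- fit_subset(X, yv, "linear")
    if (is.null(fit)) return(Inf)
    rss <- sum((yv - predict_linear(fit, X))^2)
    sig2 <- rss / n
    if (sig2 <= 0) return(-Inf)
    logL <- -n / 2 * (log(2 * pi * sig2) + 1)
    -2 * logL + 2 * (d + 2L) # + intercept and variance parameters
  } else {
    fit <- fit_subset(X, yv, mode, L = L)
    if (is.null(fit)) return(Inf)
    -2 * fit$logLm + 2 * (d + 1L) * (L - 1L)
  }
}

#' Stepwise forward model on one split
#'
#' Greedy forward selection from the empty model, adding at each step the
#' predictor that most reduces `-2 logL + 2 k` (AIC) on the training rows,
#' stopping when no addition reduces it.  The selected model is scored on
#' the test rows.
#'
#' @inheritParams significant_model
#' @return as [significant_model()].
#' @export
stepwise_forward_model <- function(table, sp, y, mode,
                                   objfun = "acc", cutoff = 0.5) {
  L <- if (mode == "linear") 2L else length(y$levels)
  cand <- which(table$weights > 0L)
  current <- integer(0)
  ic <- subset_ic(table, current, sp$train, y, mode, L)
  repeat {
    remaining <- setdiff(cand, current)
    if (!length(remaining)) break
    trial <- vapply(remaining, function(j)
      subset_ic(table, sort(c(current, j)), sp$train, y, mode, L),
      numeric(1))
    best <- which.min(trial)
    if (trial[best] < ic - 1e-8) {
      current <- sort(c(current, remaining[best]))
      ic <- trial[best]
    } else break
  }
  sc <- score_subset(table, current, sp, y, mode, L, objfun, cutoff)
  if (is.null(sc)) return(NULL)
  c(list(selected = current, ic = ic), sc)
}

#' L1-penalised (lasso) comparator over a shared penalty grid
#'
#' Fits an L1-penalised regression on every training set over a penalty grid
#' fixed across all hold-outs, scores each penalty on the test sets, and
#' reports the penalty with the best average test metric.  The default grid
#' is the glmnet path computed once on the full data (about 50 values,
#' log-spaced over four decades below the smallest all-zeroing penalty).
#'
#' @param table a `"predictor_table"`.
#' @param plan a `"split_plan"` shared with the main engine.
#' @param y an `"outcome_spec"`.
#' @param mode,objfun,cutoff as in [holdout_select()].
#' @param lambda optional penalty grid (decreasing).
#' @return list with `lambda` (grid), `chosen_lambda`, `test`, `train`
#'   (averages at the chosen penalty), `per_lambda_test` and `supports`
#'   (per-split selected design-column sets at the chosen penalty).
#' @export
l1_path_model <- function(table, plan, y, mode, objfun = "acc",
                          cutoff = 0.5, lambda = NULL) {
  X <- table$design
  family <- switch(mode, linear = "gaussian", binary = "binomial",
                   multin = "multinomial")
  yv <- if (mode == "linear") y$encoded else factor(y$encoded)
  if (is.null(lambda)) {
    full <- glmnet::glmnet(X, yv, family = family, nlambda = 50,
                           lambda.min.ratio = 1e-4)
    lambda <- full$lambda
  }
  nl <- length(lambda)
  crv <- plan$crv
  minimise <- mode == "linear"
  test_mat <- matrix(NA_real_, crv, nl)  # absolute error / acc / auroc
  train_mat <- matrix(NA_real_, crv, nl)
  support_list <- vector("list", crv)

  for (i in seq_len(crv)) {
    sp <- plan$splits[[i]]
    ytr <- y$encoded[sp$train]
    yte <- y$encoded[sp$test]
    ytr_f <- if (mode == "linear") ytr else factor(ytr, levels = sort(unique(y$encoded)))
    if (mode != "linear" && length(unique(ytr)) < length(levels(ytr_f))) next
    fit <- tryCatch(
      glmnet::glmnet(X[sp$train, , drop = FALSE], ytr_f, family = family,
                     lambda = lambda),
      error = function(e) NULL)
    if (is.null(fit)) next
    Xte <- X[sp$test, , drop = FALSE]
    Xtr <- X[sp$train, , drop = FALSE]
    if (mode == "linear") {
      pte <- stats::predict(fit, Xte)
      ptr <- stats::predict(fit, Xtr)
      for (k in seq_len(ncol(pte))) {
        test_mat[i, k] <- mean(abs(yte - pte[, k]))
        train_mat[i, k] <- mean(abs(ytr - ptr[, k]))
      }
    } else if (mode == "binary") {
      pte <- stats::predict(fit, Xte, type = "response")
      ptr <- stats::predict(fit, Xtr, type = "response")
      for (k in seq_len(ncol(pte))) {
        if (objfun == "roc") {
          test_mat[i, k] <- auroc(yte, pte[, k])
          train_mat[i, k] <- auroc(ytr, ptr[, k])
        } else {
          test_mat[i, k] <- accuracy(yte, as.integer(pte[, k] >= cutoff))
          train_mat[i, k] <- accuracy(ytr, as.integer(ptr[, k] >= cutoff))
        }
      }
    } else {
      pte <- stats::predict(fit, Xte, type = "response")
      ptr <- stats::predict(fit, Xtr, type = "response")
      codes <- as.integer(dimnames(pte)[[2L]])
      for (k in seq_len(dim(pte)[3L])) {
        cte <- codes[max.col(pte[, , k], ties.method = "first")]
        ctr <- codes[max.col(ptr[, , k], ties.method = "first")]
        test_mat[i, k] <- accuracy(yte, cte)
        train_mat[i, k] <- accuracy(ytr, ctr)
      }
    }
    support_list[[i]] <- fit
  }

  per_lambda <- colMeans(test_mat, na.rm = TRUE)
  per_lambda[!is.finite(per_lambda)] <- NA_real_
  k_best <- if (minimise) which.min(per_lambda) else which.max(per_lambda)
  supports <- lapply(support_list, function(fit) {
    if (is.null(fit)) return(NULL)
    b <- stats::coef(fit, s = lambda[k_best])
    if (is.list(b)) { # multinomial: union of per-category supports
      nz <- sort(unique(unlist(lapply(b, function(m) which(m[-1L, 1L] != 0)))))
    } else {
      nz <- which(b[-1L, 1L] != 0)
    }
    sort(unique(table$design_map[nz]))
  })
  list(lambda = lambda, chosen_lambda = lambda[k_best],
       test = mean(test_mat[, k_best], na.rm = TRUE),
       train = mean(train_mat[, k_best], na.rm = TRUE),
       per_lambda_test = per_lambda, supports = supports)
}

#' Relative generalisation gap (overfitting measure)
#'
#' For error metrics, `(test - train) / test`; for accuracy/AUROC,
#' `(train - test) / train`.  Zero when test and training performance agree;
#' larger values indicate overfitting.
#'
#' @param test_metric,train_metric average test and training metric values.
#' @param metric one of `"error"`, `"accuracy"`, `"auroc"`.
#' @export
overfitting_measure <- function(test_metric, train_metric,
                                metric = c("error", "accuracy", "auroc")) {
  metric <- match.arg(metric)
  if (metric == "error") {
    if (test_metric == 0) return(NA_real_)
    (test_metric - train_metric) / test_metric
  } else {
    if (train_metric == 0) return(NA_real_)
    (train_metric - test_metric) / train_metric
  }
}

#' Run the comparator methods on the engine's splits
#'
#' Evaluates the significance-based, stepwise-forward and lasso comparators
#' on exactly the split plan used by a [holdout_select()] run (or a fresh
#' plan built from `crv`/`part`/`seed`), so their average predictive power
#' is directly comparable with the exhaustive search.
#'
#' @param x predictors (data frame or `"predictor_table"`).
#' @param y outcome vector or `"outcome_spec"`.
#' @param mode outcome mode.
#' @param splits a `"split_plan"`; built from `crv`, `part`, `seed` when
#'   missing.
#' @param crv,part,seed split parameters when `splits` is missing.
#' @param methods subset of `c("significant", "stepwise", "lasso")`.
#' @param alpha significance level of the univariate screen.
#' @param objfun,cutoff as in [holdout_select()].
#' @param lambda optional lasso penalty grid.
#' @return object of class `"holdout_comparison"`: per-method average test
#'   and train metric, overfitting measure, per-split selected sets, and
#'   the lasso penalty diagnostics.
#' @export
compare_methods <- function(x, y, mode = c("linear", "binary", "multin"),
                            splits = NULL, crv = 100L, part = 10L,
                            seed = 1L,
                            methods = c("significant", "stepwise", "lasso"),
                            alpha = 0.05, objfun = c("acc", "roc"),
                            cutoff = 0.5, lambda = NULL) {
  mode <- match.arg(mode)
  objfun <- match.arg(objfun)
  methods <- match.arg(methods, several.ok = TRUE)
  y <- if (inherits(y, "outcome_spec")) y else encode_outcome(y, mode)
  table <- if (inherits(x, "predictor_table")) x else predictor_table(x)
  N <- nrow(table$data)
  plan <- if (is.null(splits)) make_splits(N, crv, part, seed) else splits
  stopifnot(inherits(plan, "split_plan"), plan$N == N)
  metric <- if (mode == "linear") "error"
            else if (objfun == "roc") "auroc" else "accuracy"

  run_per_split <- function(fun) {
    res <- lapply(plan$splits, function(sp)
      fun(table, sp, y, mode))
    ok <- !vapply(res, is.null, logical(1))
    te <- vapply(res[ok], function(r) r$test[1L], numeric(1))
    tr <- vapply(res[ok], function(r) r$train[1L], numeric(1))
    list(test = agg_mean(te, metric == "auroc"),
         train = agg_mean(tr, metric == "auroc"),
         selected = lapply(res[ok], `[[`, "selected"),
         n_eval = sum(ok))
  }

  out <- list(mode = mode, objfun = objfun, metric = metric, plan = plan,
              methods = list())
  if ("significant" %in% methods)
    out$methods$significant <- run_per_split(function(tb, sp, yy, md)
      significant_model(tb, sp, yy, md, alpha = alpha,
                        objfun = objfun, cutoff = cutoff))
  if ("stepwise" %in% methods)
    out$methods$stepwise <- run_per_split(function(tb, sp, yy, md)
      stepwise_forward_model(tb, sp, yy, md, objfun = objfun,
                             cutoff = cutoff))
  if ("lasso" %in% methods) {
    l1 <- l1_path_model(table, plan, y, mode, objfun = objfun,
                        cutoff = cutoff, lambda = lambda)
    out$methods$lasso <- list(test = l1$test, train = l1$train,
                              selected = l1$supports,
                              lambda = l1$lambda,
                              chosen_lambda = l1$chosen_lambda,
                              per_lambda_test = l1$per_lambda_test,
                              n_eval = sum(!vapply(l1$supports, is.null,
                                                   logical(1))))
  }
  for (m in names(out$methods)) {
    mm <- out$methods[[m]]
    out$methods[[m]]$overfitting <-
      if (is.na(mm$test) || is.na(mm$train)) NA_real_
      else overfitting_measure(mm$test, mm$train, metric)
  }
  class(out) <- "holdout_comparison"
  out
}

#' @export
print.holdout_comparison <- function(x, ...) {
  cat("Comparator methods on", x$plan$crv, "shared hold-outs (metric =",
      x$metric, ")\n")
  for (m in names(x$methods)) {
    mm <- x$methods[[m]]
    cat(sprintf("  %-12s test %.5f  train %.5f  overfit %.4f  (n_eval %d)\n",
                m, mm$test, mm$train, mm$overfitting, mm$n_eval))
  }
  invisible(x)
}
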