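# The hold-out engine: random train/test splits, per-split feasibility +
# fitting + scoring of every admissible subset, aggregation across splits
# and ranking by average predictive power.

# reason codes for a (model, split) cell that carries no metric value
.reasons <- c(evaluated = 0L, EPV = 1L, Rsq = 2L, Riley = 3L, margin = 4L,
              fit_failure = 5L, degenerate_test = 6L, absent_category = 7L,
              correlation = 8L, degenerate_mean = 9L)

# deterministic per-split RNG substream; independent of worker scheduling
split_seed <- function(seed, i) {
  as.integer((as.double(seed %% 2147483647L) * 48271 + i * 30269) %% 2147483647)
}

#' Build a reproducible plan of random hold-out splits
#'
#' Each of the `crv` splits draws `floor(N / part)` test rows uniformly
#' without replacement; the remaining rows form the training set.  The RNG
#' substream of split `i` is derived from `(seed, i)`, so the plan -- and
#' everything downstream -- is identical whether splits are evaluated
#' serially or in parallel.
#'
#' @param N number of rows.
#' @param crv number of hold-outs.
#' @param part split parameter: the test set is `1/part` of the data and the
#'   training set `(part-1)/part`.
#' @param seed integer seed.
#' @return object of class `"split_plan"`: list with `N`, `crv`, `part`,
#'   `seed` and `splits` (list of `list(train, test)` index vectors).
#' @examples
#' sp <- make_splits(200, 5, part = 5, seed = 1)
#' lengths(sp$splits[[1]]) # train 160, test 40
#' @export
make_splits <- function(N, crv, part, seed) {
  stopifnot(N >= part, part >= 2, crv >= 1)
  m <- N %/% part
  if (m < 1L) stop("floor(N / part) must be at least 1")
  splits <- lapply(seq_len(crv), function(i) {
    set.seed(split_seed(seed, i))
    test <- sort(sample.int(N, m))
    list(train = setdiff(seq_len(N), test), test = test)
  })
  out <- list(N = N, crv = crv, part = part, seed = seed, splits = splits)
  class(out) <- "split_plan"
  out
}

# evaluate every candidate on one split; returns per-candidate metric
# columns plus the empirical baseline for the split
eval_one_split <- function(i, plan, table, y, mode, candidates, cand_weights,
                           config) {
  sp <- plan$splits[[i]]
  train <- sp$train
  test <- sp$test
  ytr <- y$encoded[train]
  yte <- y$encoded[test]
  n_tr <- length(train)
  M <- length(candidates)
  L <- if (mode == "linear") 2L else length(y$levels)
  objfun <- config$objfun

  k_metrics <- if (mode == "linear") 2L else 1L
  test_m <- matrix(NA_real_, M, k_metrics)
  train_m <- matrix(NA_real_, M, k_metrics)
  reason <- rep(.reasons[["evaluated"]], M)

  # training events and split-level gates
  if (mode == "linear") {
    events <- n_tr
    split_block <- 0L
  } else {
    counts <- tabulate(ytr + 1L, nbins = L)
    events <- min(counts)
    split_block <- if (any(counts == 0L)) .reasons[["absent_category"]] else 0L
    if (split_block == 0L && mode == "binary" && !is.null(config$marg)) {
      phi <- mean(ytr == 1L)
      if (proportion_margin(phi, n_tr) > config$marg)
        split_block <- .reasons[["margin"]]
    }
  }
  wmax <- floor(events / config$rule)

  corr_split <- NULL
  if (isTRUE(config$per_split_correlation) && config$corr < 1) {
    corr_split <- suppressWarnings(stats::cor(table$numeric[train, , drop = FALSE]))
    corr_split[is.na(corr_split)] <- 0
    diag(corr_split) <- 1
  }

  emp <- if (objfun != "roc") empirical_baseline(ytr, yte, mode) else NULL

  if (split_block != 0L) {
    reason[] <- split_block
    return(list(test = test_m, train = train_m, reason = reason, emp = emp))
  }

  for (mi in seq_len(M)) {
    subset <- candidates[[mi]]
    if (cand_weights[mi] > wmax) {
      reason[mi] <- .reasons[["EPV"]]
      next
    }
    if (!is.null(corr_split) &&
        !passes_correlation(subset, corr_split, config$corr)) {
      reason[mi] <- .reasons[["correlation"]]
      next
    }
    Xtr <- subset_design(table, subset, train)
    fit <- fit_subset(Xtr, ytr, mode, L = L)
    if (is.null(fit)) {
      reason[mi] <- .reasons[["fit_failure"]]
      next
    }
    if (mode == "linear") {
      if (isTRUE(config$Rsq) &&
          !rsq_gate_linear(fit$R2_app, cand_weights[mi], n_tr,
                           shrink_fn = config$shrink_fn)) {
        reason[mi] <- .reasons[["Rsq"]]
        next
      }
      if (!is.null(config$marg)) {
        mg <- margins_linear(n_tr, cand_weights[mi], fit$sigma_hat, fit$mean_hat)
        if (is.na(mg$Mo)) {
          reason[mi] <- .reasons[["degenerate_mean"]]
          next
        }
        if (max(mg$Mv - 1, mg$Mo) > config$marg) {
          reason[mi] <- .reasons[["margin"]]
          next
        }
      }
    } else if (mode == "binary" && isTRUE(config$Rsq)) {
      if (!riley_gate_binary(fit$logL0, fit$logLm, fit$p, n_tr)) {
        reason[mi] <- .reasons[["Riley"]]
        next
      }
    }

    Xte <- subset_design(table, subset, test)
    if (mode == "linear") {
      ete <- abs_rel_error(yte, predict_linear(fit, Xte))
      etr <- abs_rel_error(ytr, predict_linear(fit, Xtr))
      test_m[mi, ] <- c(ete$abs, ete$rel)
      train_m[mi, ] <- c(etr$abs, etr$rel)
    } else if (objfun == "roc") {
      ste <- categorical_probs(fit, Xte)[, 2L]
      str <- categorical_probs(fit, Xtr)[, 2L]
      a_te <- auroc(yte, ste)
      if (is.na(a_te)) reason[mi] <- .reasons[["degenerate_test"]]
      test_m[mi, 1L] <- a_te
      train_m[mi, 1L] <- auroc(ytr, str)
    } else {
      cte <- classify(categorical_probs(fit, Xte), mode, config$cutoff)
      ctr <- classify(categorical_probs(fit, Xtr), mode, config$cutoff)
      test_m[mi, 1L] <- accuracy(yte, cte)
      train_m[mi, 1L] <- accuracy(ytr, ctr)
    }
  }
  list(test = test_m, train = train_m, reason = reason, emp = emp)
}

# column-wise mean respecting the NA conventions: relative error propagates
# NA, AUROC drops degenerate splits
agg_mean <- function(v, na_drop) {
  ok <- !is.na(v)
  if (na_drop) {
    if (!any(ok)) NA_real_ else mean(v[ok])
  } else {
    if (length(v) == 0L) NA_real_ else mean(v)
  }
}

#' Aggregate per-split records and rank candidate models
#'
#' Per-model averages are taken over the splits where the model was actually
#' evaluated; `feasible_count` and the coverage fraction are always
#' reported.  A model may only be declared best if its coverage is at least
#' `min_coverage` (rarely-feasible models would otherwise win on a handful
#' of lucky splits).  All ties are returned.
#'
#' @param records list as produced internally by [holdout_select()]:
#'   `test`/`train` are (models x splits) matrices per metric, `reason` the
#'   reason-code matrix.
#' @param candidates list of candidate index vectors.
#' @param mode,objfun run mode and objective.
#' @param min_coverage coverage floor in `[0, 1]`.
#' @return list with `header`, `best`, `per_model`, `skip_reasons`,
#'   `empirical`.
#' @keywords internal
aggregate_and_rank <- function(records, candidates, mode, objfun,
                               min_coverage = 0.5) {
  M <- length(candidates)
  crv <- ncol(records$reason)
  evaluated <- records$reason == .reasons[["evaluated"]] |
    records$reason == .reasons[["degenerate_test"]]
  feasible_count <- rowSums(evaluated)
  coverage <- feasible_count / crv

  # means over evaluated splits
  mean_over <- function(mat, na_drop) {
    vapply(seq_len(M), function(mi) {
      v <- mat[mi, evaluated[mi, ], drop = TRUE]
      agg_mean(v, na_drop)
    }, numeric(1))
  }
  na_drop <- objfun == "roc" # degenerate one-class test sets are excluded
  if (mode == "linear") {
    m_te_abs <- mean_over(records$test_abs, FALSE)
    m_te_rel <- mean_over(records$test_rel, FALSE)
    m_tr_abs <- mean_over(records$train_abs, FALSE)
    m_tr_rel <- mean_over(records$train_rel, FALSE)
  } else {
    m_te <- mean_over(records$test1, na_drop)
    m_tr <- mean_over(records$train1, na_drop)
  }

  eligible <- coverage >= min_coverage & feasible_count > 0L
  pick <- function(value, minimise) {
    ok <- eligible & !is.na(value)
    if (!any(ok)) return(list(best = integer(0), value = NA_real_))
    opt <- if (minimise) min(value[ok]) else max(value[ok])
    list(best = which(ok & value == opt), value = opt)
  }

  model_label <- vapply(candidates, paste, "", collapse = ",")
  skip <- table(factor(records$reason[records$reason != 0L],
                       levels = .reasons[-1L],
                       labels = names(.reasons)[-1L]))
  skip <- stats::setNames(as.integer(skip), names(skip))

  emp <- records$emp
  if (mode == "linear") {
    ba <- pick(m_te_abs, TRUE)
    br <- pick(m_te_rel, TRUE)
    header <- c(
      test_abs = ba$value,
      test_rel = br$value,
      train_abs = if (length(ba$best)) m_tr_abs[ba$best[1L]] else NA_real_,
      train_rel = if (length(br$best)) m_tr_rel[br$best[1L]] else NA_real_,
      emp_abs = emp$abs, emp_rel = emp$rel)
    best <- list(abs = candidates[ba$best], rel = candidates[br$best])
    per_model <- data.frame(
      model = model_label, weight = records$cand_weights,
      test_abs = m_te_abs, test_rel = m_te_rel,
      train_abs = m_tr_abs, train_rel = m_tr_rel,
      n_eval = feasible_count, coverage = coverage,
      stringsAsFactors = FALSE)
  } else if (objfun == "roc") {
    bb <- pick(m_te, FALSE)
    header <- c(test_auroc = bb$value,
                train_auroc = if (length(bb$best)) m_tr[bb$best[1L]] else NA_real_)
    best <- list(auroc = candidates[bb$best])
    per_model <- data.frame(
      model = model_label, weight = records$cand_weights,
      test_auroc = m_te, train_auroc = m_tr,
      n_eval = feasible_count, coverage = coverage,
      stringsAsFactors = FALSE)
  } else {
    bb <- pick(m_te, FALSE)
    header <- c(test_acc = bb$value,
                train_acc = if (length(bb$best)) m_tr[bb$best[1L]] else NA_real_,
                emp_acc = emp$acc)
    best <- list(acc = candidates[bb$best])
    per_model <- data.frame(
      model = model_label, weight = records$cand_weights,
      test_acc = m_te, train_acc = m_tr,
      n_eval = feasible_count, coverage = coverage,
      stringsAsFactors = FALSE)
  }
  list(header = header, best = best, per_model = per_model,
       skip_reasons = skip, empirical = emp)
}

#' Best-subset regression ranked by hold-out predictive power
#'
#' The main engine.  Enumerates every admissible subset of predictors
#' (events-per-variable rule, forced terms, size/weight/correlation bounds),
#' fits each candidate on `crv` random training sets, scores it on the
#' corresponding test sets, and ranks candidates by average predictive
#' power: absolute and relative error for continuous outcomes, accuracy or
#' AUROC for categorical ones.  Feasibility is re-decided per split --
#' categorical event counts, the R-squared / shrinkage gates and the error
#' margins all depend on the training rows -- so a model may be assessed in
#' some hold-outs and skipped in others; averages are taken over the splits
#' where a model was evaluated and a coverage floor keeps rarely-feasible
#' models from being declared best.
#'
#' @param x data frame (or matrix) of predictors, or a `"predictor_table"`.
#' @param y outcome vector, or an `"outcome_spec"`.
#' @param mode `"linear"`, `"binary"` or `"multin"`.
#' @param crv number of hold-outs.
#' @param part split parameter: test sets hold `floor(N / part)` rows.
#' @param rule EPV rule constant `r` (default 10, the one-in-ten rule).
#' @param minx,maxx minimum / maximum number of predictors per model.
#' @param maxw maximum model weight (`Inf` = only the EPV bound applies).
#' @param fixed indices of predictors forced into every model.
#' @param corr highest allowed pairwise correlation between predictors in a
#'   model (inclusive bound; default 1 accepts everything).
#' @param cutoff binary classification threshold.
#' @param objfun objective for categorical outcomes: `"acc"` (accuracy,
#'   default) or `"roc"` (AUROC; no empirical baseline is reported).
#' @param Rsq apply the R-squared/shrinkage sample-size gates (linear and
#'   binary modes).
#' @param marg optional error margin: linear models must keep
#'   `max(Mv - 1, Mo)` within `marg` ([margins_linear()]); binary runs
#'   require the training outcome-proportion margin within `marg`.
#' @param expand interaction expansion applied to a fully numeric predictor
#'   block before enumeration: `"none"`, `"quadr"` or `"cub"`.
#' @param types per-column type overrides, see [predictor_table()].
#' @param seed integer seed driving every split (drawn from the session RNG
#'   when omitted, so `set.seed()` beforehand also fixes the run).
#' @param parallel,cores evaluate hold-outs in parallel via forked workers;
#'   results are bit-identical to the serial run.
#' @param min_coverage coverage floor below which a model cannot be declared
#'   best (default 0.5).
#' @param per_split_correlation recompute the correlation filter on each
#'   training set instead of once on the full data (default off).
#' @param shrink_fn threshold function for the linear R-squared gate, see
#'   [rsq_gate_linear()].
#' @param splits optionally a precomputed `"split_plan"` (overrides `crv`,
#'   `part`, `seed`); used to share identical splits with the comparator
#'   methods.
#' @return An object of class `"holdout_select"`; see
#'   [print.holdout_select()], [summary.holdout_select()],
#'   [coef.holdout_select()], [predict.holdout_select()].  Key fields:
#'   `header` (the metric array: linear mode best-test-abs, best-test-rel,
#'   the same models' training errors, and the empirical baseline errors;
#'   accuracy mode best-test, best-train, empirical; AUROC mode best-test,
#'   best-train), `best` (lists of tied best index sets per criterion, 1-
#'   based relative to the supplied predictor block), `per_model` (averages,
#'   `n_eval`, coverage), `skip_reasons`, `empirical`.
#' @examples
#' dat <- generate_scenario(scenario_config(n_rows = 120, n_continuous = 4,
#'   support = c(1, 2), beta = c(3, -2), noise_sd = 1, seed = 11))
#' fit <- holdout_select(dat$predictors, dat$outcome, mode = "linear",
#'                       crv = 50, seed = 1)
#' fit
#' @export
holdout_select <- function(x, y, mode = c("linear", "binary", "multin"),
                           crv = 1000L, part = 10L, rule = 10,
                           minx = 1L, maxx = Inf, maxw = Inf,
                           fixed = integer(0), corr = 1, cutoff = 0.5,
                           objfun = c("acc", "roc"), Rsq = FALSE,
                           marg = NULL,
                           expand = c("none", "quadr", "cub"),
                           types = NULL, seed = NULL,
                           parallel = FALSE, cores = 2L,
                           min_coverage = 0.5,
                           per_split_correlation = FALSE,
                           shrink_fn = rsq_shrink_threshold,
                           splits = NULL) {
  mode <- match.arg(mode)
  objfun <- match.arg(objfun)
  expand <- match.arg(expand)
  cl <- match.call()
  if (objfun == "roc" && mode == "multin")
    stop("objfun = 'roc' is defined for binary outcomes only")
  seed <- if (is.null(seed)) sample.int(2147483646L, 1L) else as.integer(seed)

  y <- if (inherits(y, "outcome_spec")) y else encode_outcome(y, mode)
  if (y$mode != mode) stop("outcome_spec mode does not match 'mode'")

  expansion_info <- NULL
  if (inherits(x, "predictor_table")) {
    if (expand != "none")
      stop("pass the raw predictor block when using 'expand'")
    table <- x
  } else {
    xdf <- as.data.frame(x)
    if (expand != "none") {
      base_tab <- predictor_table(xdf, types = types)
      kinds <- vapply(base_tab$columns, `[[`, "", "kind")
      if (!all(kinds %in% c("continuous", "binary")))
        stop("interaction expansion requires numeric (continuous or binary) predictors")
      Xexp <- expand_design(as.matrix(base_tab$numeric),
                            if (expand == "quadr") 2L else 3L)
      expansion_info <- list(order = attr(Xexp, "order"),
                             base_count = attr(Xexp, "base_count"),
                             base_names = names(xdf))
      xdf <- as.data.frame(Xexp)
      types <- stats::setNames(rep("continuous", ncol(xdf)), names(xdf))
    }
    table <- predictor_table(xdf, types = types)
  }
  N <- nrow(table$data)
  if (length(y$encoded) != N) stop("predictors and outcome differ in length")

  if (!is.null(splits)) {
    stopifnot(inherits(splits, "split_plan"), splits$N == N)
    plan <- splits
    crv <- plan$crv
    part <- plan$part
    seed <- plan$seed
  } else {
    plan <- make_splits(N, crv, part, seed)
  }
  n_tr <- N - N %/% part

  # search-space bound: per-split events never exceed min(n_tr, full events)
  events_cap <- if (mode == "linear") n_tr
                else min(n_tr, min(y$category_counts))
  cap_w <- epv_max_weight(events_cap, rule)
  candidates <- enumerate_subsets(
    table$weights, min_vars = minx, max_vars = maxx, max_weight = maxw,
    forced = fixed, max_total_weight = cap_w,
    correlation = if (per_split_correlation) NULL else table$correlation,
    max_correlation = corr)
  if (length(candidates) == 0L)
    stop("no admissible candidate subsets under the given constraints")
  cand_weights <- vapply(candidates, subset_weight, numeric(1),
                         weights = table$weights)

  config <- list(rule = rule, cutoff = cutoff, objfun = objfun, Rsq = Rsq,
                 marg = marg, corr = corr,
                 per_split_correlation = per_split_correlation,
                 shrink_fn = shrink_fn)

  worker <- function(i) eval_one_split(i, plan, table, y, mode, candidates,
                                       cand_weights, config)
  per_split <- if (isTRUE(parallel)) {
    parallel::mclapply(seq_len(crv), worker, mc.cores = cores,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(crv), worker)
  }

  M <- length(candidates)
  records <- list(reason = vapply(per_split, `[[`, integer(M), "reason"),
                  cand_weights = cand_weights)
  dim(records$reason) <- c(M, crv)
  grab <- function(field, col) {
    m <- vapply(per_split, function(s) s[[field]][, col], numeric(M))
    dim(m) <- c(M, crv)
    m
  }
  if (mode == "linear") {
    records$test_abs <- grab("test", 1L)
    records$test_rel <- grab("test", 2L)
    records$train_abs <- grab("train", 1L)
    records$train_rel <- grab("train", 2L)
    ea <- vapply(per_split, function(s) s$emp$abs, numeric(1))
    er <- vapply(per_split, function(s) s$emp$rel, numeric(1))
    records$emp <- list(abs = mean(ea), rel = mean(er))
  } else {
    records$test1 <- grab("test", 1L)
    records$train1 <- grab("train", 1L)
    records$emp <- if (objfun != "roc")
      list(acc = mean(vapply(per_split, function(s) s$emp$acc, numeric(1))))
    else NULL
  }

  agg <- aggregate_and_rank(records, candidates, mode, objfun, min_coverage)

  out <- list(call = cl, mode = mode, objective =
                if (mode == "linear") "error" else objfun,
              header = agg$header, best = agg$best,
              per_model = agg$per_model, skip_reasons = agg$skip_reasons,
              empirical = agg$empirical,
              candidates = candidates, cand_weights = cand_weights,
              table = table, outcome = y, expansion = expansion_info,
              N = N, crv = crv, part = part, seed = seed,
              config = c(config[setdiff(names(config), "shrink_fn")],
                         list(minx = minx, maxx = maxx, maxw = maxw,
                              fixed = fixed, part = part, crv = crv,
                              seed = seed, mode = mode, expand = expand,
                              min_coverage = min_coverage)))
  class(out) <- "holdout_select"
  out
}
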