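# Seeded synthetic-data generator: correlated Gaussian continuous
# predictors, multinomial categorical predictors, and linear / logistic /
# multinomial-softmax outcomes with controllable sparse true effects.  Gives
# every stage of the engine a download-free, statistically controlled test
# bed.

#' Describe a synthetic-data scenario
#'
#' @param n_rows number of rows.
#' @param n_continuous number of continuous predictors, drawn from a
#'   correlated standard Gaussian.
#' @param n_categorical number of categorical predictors.
#' @param cat_levels levels per categorical predictor (recycled).
#' @param correlation either a scalar exchangeable correlation for the
#'   continuous block or a full correlation matrix (must be positive
#'   definite).
#' @param support indices (into the numeric-encoded predictor block) of the
#'   predictors with true effects.
#' @param beta effect sizes: a vector matching `support` (linear/binary), or
#'   an (L-1) x length(support) matrix of per-category effects (multin).
#' @param intercept intercept of the linear predictor; for binary outcomes
#'   it is re-solved when `event_target` is given.
#' @param noise_sd residual standard deviation (linear mode).
#' @param mode outcome mode.
#' @param n_categories number of outcome categories (multin).
#' @param event_target target event proportion for binary outcomes; the
#'   intercept is solved on the drawn design so the expected proportion
#'   matches it.
#' @param seed integer seed; identical config + seed gives identical data.
#' @return list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_rows = 500L, n_continuous = 6L,
                            n_categorical = 0L, cat_levels = 3L,
                            correlation = 0, support = integer(0),
                            beta = numeric(0), intercept = 0,
                            noise_sd = 1, mode = "linear",
                            n_categories = 2L, event_target = NULL,
                            seed = 1L) {
  cfg <- list(n_rows = as.integer(n_rows),
              n_continuous = as.integer(n_continuous),
              n_categorical = as.integer(n_categorical),
              cat_levels = as.integer(cat_levels),
              correlation = correlation, support = as.integer(support),
              beta = beta, intercept = intercept, noise_sd = noise_sd,
              mode = mode, n_categories = as.integer(n_categories),
              event_target = event_target, seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  cfg
}

# exchangeable or user-supplied correlation matrix, checked PD via chol
scenario_corr <- function(k, correlation) {
  R <- if (is.matrix(correlation)) {
    correlation
  } else {
    (1 - correlation) * diag(k) + correlation
  }
  if (!isTRUE(all.equal(R, t(R)))) stop("correlation matrix must be symmetric")
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) stop("requested correlation matrix is not positive definite")
  ch
}

#' Generate a synthetic predictor table and outcome
#'
#' Continuous predictors are drawn from a correlated standard Gaussian with
#' the requested correlation, categorical predictors from a uniform
#' multinomial over their levels.  The linear predictor
#' `eta = intercept + X[, support] %*% beta` (on the numeric-encoded
#' columns) drives the outcome: `y = eta + noise` for linear mode, a
#' Bernoulli draw from `plogis(eta)` for binary mode, and a draw from the
#' reference-category softmax for multinomial mode.
#'
#' @param config a [scenario_config()].
#' @return list with `predictors` (data frame), `outcome` (raw outcome
#'   vector), `table` ([predictor_table()]), `outcome_spec`
#'   ([encode_outcome()]) and `config`.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n <- config$n_rows
  kc <- config$n_continuous
  kq <- config$n_categorical

  Xc <- NULL
  if (kc > 0L) {
    ch <- scenario_corr(kc, config$correlation)
    Xc <- matrix(stats::rnorm(n * kc), n, kc) %*% ch
    colnames(Xc) <- paste0("x", seq_len(kc))
  }
  Xq <- NULL
  if (kq > 0L) {
    levs <- rep_len(config$cat_levels, kq)
    Xq <- as.data.frame(lapply(seq_len(kq), function(j) {
      sample(LETTERS[seq_len(levs[j])], n, replace = TRUE)
    }))
    names(Xq) <- paste0("c", seq_len(kq))
  }
  predictors <- if (is.null(Xq)) as.data.frame(Xc)
                else if (is.null(Xc)) Xq
                else cbind(as.data.frame(Xc), Xq)

  table <- predictor_table(predictors)
  Z <- table$numeric # numeric-encoded columns carry the true effects

  s <- config$support
  if (length(s) && (min(s) < 1L || max(s) > ncol(Z)))
    stop("support indices out of range")

  if (config$mode == "linear") {
    beta <- as.numeric(config$beta)
    stopifnot(length(beta) == length(s))
    eta <- config$intercept +
      if (length(s)) drop(Z[, s, drop = FALSE] %*% beta) else 0
    y <- eta + stats::rnorm(n, sd = config$noise_sd)
  } else if (config$mode == "binary") {
    beta <- as.numeric(config$beta)
    stopifnot(length(beta) == length(s))
    lin <- if (length(s)) drop(Z[, s, drop = FALSE] %*% beta) else rep(0, n)
    a <- config$intercept
    if (!is.null(config$event_target)) {
      a <- stats::uniroot(function(b) mean(stats::plogis(b + lin)) -
                            config$event_target,
                          interval = c(-50, 50))$root
    }
    y <- stats::rbinom(n, 1L, stats::plogis(a + lin))
  } else { # multin
    L <- config$n_categories
    B <- config$beta
    if (is.null(dim(B))) B <- matrix(B, nrow = L - 1L, ncol = length(s),
                                     byrow = TRUE)
    stopifnot(nrow(B) == L - 1L, ncol(B) == length(s))
    eta <- matrix(rep(config$intercept, length.out = L - 1L),
                  n, L - 1L, byrow = TRUE)
    if (length(s)) eta <- eta + Z[, s, drop = FALSE] %*% t(B)
    den <- 1 + rowSums(exp(eta))
    probs <- cbind(exp(eta), 1) / den # categories 1..L-1, reference last
    y <- apply(probs, 1L, function(p) sample.int(L, 1L, prob = p)) - 1L
  }
  list(predictors = predictors, outcome = y, table = table,
       outcome_spec = encode_outcome(y, config$mode), config = config)
}

#' Bundled linear integration fixture (47 x 5, continuous outcome)
#'
#' A fixed-seed synthetic table shaped like a small socio-economic survey:
#' 47 rows, 5 continuous predictors, a continuous outcome driven by three of
#' them.  With the default EPV rule of 10 all models of weight up to 4 are
#' feasible on the full sample.
#'
#' @return as [generate_scenario()].
#' @export
swiss_like <- function() {
  generate_scenario(scenario_config(
    n_rows = 47L, n_continuous = 5L, correlation = 0.2,
    support = c(1L, 3L, 4L), beta = c(4, -6, 3), intercept = 70,
    noise_sd = 6, mode = "linear", seed = 4707L))
}

#' Bundled binary integration fixture (200 x 7, exactly 68 events)
#'
#' A fixed-seed synthetic cohort: 200 rows, 7 continuous predictors, a
#' binary outcome with exactly 68 events (the least frequent category, coded
#' 1).  Events are assigned to the 68 rows with the largest latent risk
#' (linear predictor plus logistic noise), which pins the event count while
#' keeping the signal recoverable.  Always predicting the non-event class
#' is 132/200 = 0.66 accurate on the full table.
#'
#' @return as [generate_scenario()], with exactly 68 events.
#' @export
pima_like <- function() {
  set.seed(20068L)
  n <- 200L
  X <- matrix(stats::rnorm(n * 7L), n, 7L)
  colnames(X) <- paste0("x", 1:7)
  eta <- -1 + 1.2 * X[, 2L] + 0.8 * X[, 6L] + 0.6 * X[, 7L]
  risk <- eta + stats::rlogis(n)
  y <- integer(n)
  y[order(risk, decreasing = TRUE)[1:68]] <- 1L
  predictors <- as.data.frame(X)
  list(predictors = predictors, outcome = y,
       table = predictor_table(predictors),
       outcome_spec = encode_outcome(y, "binary"))
}

#' Read a scenario configuration file
#'
#' Flat `key = value` format (the same dialect as the command-line
#' configuration): one pair per line, `#` comments allowed.  Recognised keys
#' are the arguments of [scenario_config()]; `support` and `beta` accept
#' comma-separated lists.
#'
#' @param path file path.
#' @return a [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  kv <- read_config_file(path)
  num <- function(key, default) {
    if (is.null(kv[[key]])) default
    else as.numeric(strsplit(kv[[key]], ",")[[1L]])
  }
  chr <- function(key, default) if (is.null(kv[[key]])) default else kv[[key]]
  scenario_config(
    n_rows = num("n_rows", 500), n_continuous = num("n_continuous", 6),
    n_categorical = num("n_categorical", 0),
    cat_levels = num("cat_levels", 3),
    correlation = num("correlation", 0),
    support = num("support", integer(0)), beta = num("beta", numeric(0)),
    intercept = num("intercept", 0), noise_sd = num("noise_sd", 1),
    mode = chr("mode", "linear"),
    n_categories = num("n_categories", 2),
    event_target = if (is.null(kv[["event_target"]])) NULL
                   else as.numeric(kv[["event_target"]]),
    seed = num("seed", 1))
}
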