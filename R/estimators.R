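# Model fitting and prediction.
#
# Linear mode uses ordinary least squares; binary and multinomial modes use
# a maximum-likelihood multinomial logit (nnet::multinom) with the highest
# outcome code -- the least frequent category -- as the reference.  Fit
# failures (singular design, non-convergence, a category absent from the
# training set) mark the candidate infeasible for the current hold-out
# rather than aborting the sweep.

# null log-likelihood of a categorical outcome from category counts
null_loglik <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  sum(counts * log(counts / n))
}

#' Fit one candidate model on a training design
#'
#' @param X numeric training design matrix (0 columns = intercept-only).
#' @param y encoded outcome on the training rows: reals (linear) or integer
#'   codes `0..L-1` (categorical modes).
#' @param mode `"linear"`, `"binary"` or `"multin"`.
#' @param L number of outcome categories (categorical modes).
#' @param maxit,reltol convergence controls of the multinomial fit.
#' @return `NULL` on failure; otherwise a list (class `"subset_fit"`) with
#'   `mode`, `coefficients` (linear: vector; categorical: (L-1) x (d+1)
#'   matrix, row k = equation of category code k-1 against the reference)
#'   and, per mode, `R2_app`, `sigma_hat`, `mean_hat`, `fitted` (linear) or
#'   `logL0`, `logLm`, `p` (categorical).
#' @export
fit_subset <- function(X, y, mode, L = 2L, maxit = 100L, reltol = 1e-8) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n && ncol(X) > 0) stop("design/outcome length mismatch")
  d <- ncol(X)
  if (mode == "linear") {
    if (n < d + 2L) return(NULL)
    Xi <- cbind(`(Intercept)` = 1, X)
    fit <- tryCatch(stats::lm.fit(Xi, y), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) return(NULL)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    R2 <- if (tss > 0) 1 - rss / tss else as.numeric(rss <= 1e-12)
    out <- list(mode = mode, coefficients = fit$coefficients,
                R2_app = R2,
                sigma_hat = sqrt(rss / max(1L, n - d - 1L)),
                mean_hat = mean(y), p = d)
    class(out) <- "subset_fit"
    return(out)
  }
  # categorical: every category must be present on the training rows
  counts <- tabulate(y + 1L, nbins = L)
  if (any(counts == 0L)) return(NULL)
  if (n < d + 2L) return(NULL)
  # reference (code L-1) first so multinom's baseline is the reference
  f <- factor(y, levels = c(L - 1L, seq_len(L - 1L) - 1L))
  dat <- as.data.frame(X)
  names(dat) <- if (d > 0) paste0("V", seq_len(d)) else character(0)
  dat$.y <- f
  fit <- tryCatch(
    suppressMessages(nnet::multinom(.y ~ ., data = dat, trace = FALSE,
                                    maxit = maxit, reltol = reltol)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) return(NULL)
  if (!is.null(fit$convergence) && fit$convergence != 0) return(NULL)
  B <- stats::coef(fit)
  if (L == 2L) B <- matrix(B, nrow = 1L, dimnames = list(NULL, names(B)))
  if (anyNA(B)) return(NULL)
  logLm <- as.numeric(stats::logLik(fit))
  logL0 <- null_loglik(counts)
  out <- list(mode = mode, coefficients = B, L = L,
              logL0 = logL0, logLm = max(logLm, logL0),
              p = d * (L - 1L))
  class(out) <- "subset_fit"
  out
}

#' Category probabilities of a fitted categorical model
#'
#' Reference-category multinomial logit: with linear predictors
#' `eta_k = b_k0 + x' b_k` for non-reference codes `k = 0..L-2`,
#' `P(Y = k) = exp(eta_k) / (1 + sum_l exp(eta_l))` and the reference code
#' `L-1` gets `1 / (1 + sum_l exp(eta_l))`.  Evaluated via log-sum-exp so
#' large linear predictors cannot overflow.
#'
#' @param model a categorical `"subset_fit"`.
#' @param X numeric matrix of predictor rows (same columns as the training
#'   design).
#' @return matrix of probabilities, one row per input row, columns in code
#'   order `0..L-1`; rows sum to 1.
#' @export
categorical_probs <- function(model, X) {
  stopifnot(inherits(model, "subset_fit"), model$mode %in% c("binary", "multin"))
  X <- as.matrix(X)
  B <- model$coefficients
  eta <- cbind(1, X) %*% t(B)            # n x (L-1), column k -> code k-1
  m <- pmax(apply(eta, 1L, max), 0)      # include the reference's 0 logit
  ex <- exp(eta - m)
  ref <- exp(-m)
  den <- ref + rowSums(ex)
  probs <- cbind(ex, ref) / den          # codes 0..L-2, then reference L-1
  colnames(probs) <- as.character(seq_len(ncol(probs)) - 1L)
  probs
}

#' Deterministic classification from category probabilities
#'
#' Multinomial mode predicts the arg-max category (ties broken towards the
#' lowest code); binary mode predicts code 1 iff `P(code 1) >= cutoff`.
#'
#' @param probs probability matrix from [categorical_probs()] (or a single
#'   row as a vector).
#' @param mode `"binary"` or `"multin"`.
#' @param cutoff binary decision threshold in `(0, 1)`.
#' @return integer vector of predicted codes.
#' @export
classify <- function(probs, mode, cutoff = 0.5) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  if (mode == "binary") {
    as.integer(probs[, 2L] >= cutoff)
  } else {
    max.col(probs, ties.method = "first") - 1L
  }
}

# linear prediction for a subset_fit
predict_linear <- function(model, X) {
  drop(cbind(1, as.matrix(X)) %*% model$coefficients)
}
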