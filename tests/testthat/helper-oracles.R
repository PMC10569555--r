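# Independent oracles used to cross-check the implementation.

# AUROC by explicit trapezoidal integration of the ROC curve
trapezoid_auroc <- function(y, scores) {
  if (length(unique(y)) < 2L) return(NA_real_)
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & y == 1L) / n1, 0), 1)
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & y == 0L) / n0, 0), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# every admissible subset by brute force over the power set
brute_force_subsets <- function(weights, min_vars = 1, max_vars = Inf,
                                max_weight = Inf, forced = integer(0),
                                max_total_weight = Inf,
                                correlation = NULL, max_correlation = 1) {
  n <- length(weights)
  bound <- min(max_weight, max_total_weight)
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    s <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(forced) && !all(forced %in% s)) next
    if (any(weights[s] == 0)) next
    if (length(s) < min_vars || length(s) > max_vars) next
    if (sum(weights[s]) > bound) next
    if (!is.null(correlation) && length(s) > 1L) {
      sub <- abs(correlation[s, s, drop = FALSE])
      diag(sub) <- 0
      if (max(sub) > max_correlation) next
    }
    out[[length(out) + 1L]] <- s
  }
  out
}

# least-squares coefficients from the normal equations
normal_equations <- function(X, y) {
  Xi <- cbind(1, X)
  drop(solve(crossprod(Xi), crossprod(Xi, y)))
}

# canonical string form of a list of index sets, order-free comparison
subset_key <- function(sets) {
  sort(vapply(sets, function(s) paste(sort(s), collapse = ","), ""))
}

# small deterministic linear scenario used by several tests
tiny_linear <- function(seed = 7L, n = 120L) {
  generate_scenario(scenario_config(
    n_rows = n, n_continuous = 4L, support = c(1L, 2L),
    beta = c(3, -2), noise_sd = 1, seed = seed))
}
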