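# Exhaustive enumeration of admissible predictor subsets.
#
# The search space is every non-empty subset of predictors subject to:
# forced terms, min/max variable counts, a model-weight bound (the binding
# one of the user's max_weight and the EPV-derived bound), and a pairwise
# correlation bound.  Enumeration is depth-first in ascending index order,
# which yields lexicographic output and allows pruning on weight and size.

#' Count the subsets admitted by a weight bound
#'
#' Number of non-empty subsets of `n` unit-weight predictors with at most
#' `w` members: `sum_{i=1..w} choose(n, i)`.
#'
#' @param n number of predictors.
#' @param w weight bound, `0 <= w <= n`.
#' @export
count_subsets <- function(n, w) {
  stopifnot(w >= 0, w <= n)
  if (w == 0) return(0)
  sum(choose(n, seq_len(w)))
}

#' Correlation admissibility of a subset
#'
#' @param subset integer vector of predictor indices.
#' @param correlation symmetric correlation matrix with unit diagonal.
#' @param c bound in `(0, 1]`; inclusive (`<= c`); `c = 1` accepts every
#'   subset.
#' @return logical.
#' @export
passes_correlation <- function(subset, correlation, c = 1) {
  if (c >= 1 || length(subset) < 2L) return(TRUE)
  sub <- abs(correlation[subset, subset, drop = FALSE])
  diag(sub) <- 0
  max(sub) <= c
}

#' Enumerate admissible predictor subsets
#'
#' Emits exactly the subsets `S` with `forced` a subset of `S`,
#' `min_vars <= |S| <= max_vars`, total weight at most
#' `min(max_weight, max_total_weight)`, and (optionally) all pairwise
#' correlations within `max_correlation`.  Zero-weight (constant) predictors
#' are never candidates.  Output order is lexicographic by indices and
#' contains no duplicates.
#'
#' @param weights positive integer weight per predictor (0 marks an excluded
#'   constant column).
#' @param min_vars,max_vars bounds on the number of member predictors.
#' @param max_weight user bound on total model weight (`Inf` = unbounded).
#' @param forced integer indices required in every subset.
#' @param max_total_weight additional weight bound (e.g. the EPV bound from
#'   the full sample); the binding bound is the smaller of the two.
#' @param correlation optional correlation matrix for the correlation filter.
#' @param max_correlation bound `c` in `(0, 1]`, inclusive.
#' @return list of sorted integer vectors; empty (with a warning) when the
#'   forced set itself violates the weight bound.
#' @examples
#' length(enumerate_subsets(rep(1, 5), max_total_weight = 4)) # 30
#' @export
enumerate_subsets <- function(weights, min_vars = 1L, max_vars = Inf,
                              max_weight = Inf, forced = integer(0),
                              max_total_weight = Inf,
                              correlation = NULL, max_correlation = 1) {
  n <- length(weights)
  forced <- sort(unique(as.integer(forced)))
  if (length(forced) && (min(forced) < 1L || max(forced) > n))
    stop("forced indices out of range 1..", n)
  if (any(weights[forced] == 0))
    stop("forced predictor(s) ", paste(forced[weights[forced] == 0], collapse = ", "),
         " are constant columns")
  bound <- min(max_weight, max_total_weight)
  if (min_vars > max_vars) stop("min_vars exceeds max_vars")
  forced_w <- sum(weights[forced])
  if (forced_w > bound || length(forced) > max_vars) {
    warning("forced set alone violates the weight/size bound; no admissible subsets")
    return(list())
  }
  free <- setdiff(which(weights > 0), forced)
  out <- vector("list", 0L)
  emit <- function(s) {
    if (length(s) < min_vars) return()
    if (!is.null(correlation) &&
        !passes_correlation(s, correlation, max_correlation)) return()
    out[[length(out) + 1L]] <<- s
  }
  # depth-first over free indices (ascending); each partial set includes forced
  recurse <- function(pos, current, cur_w) {
    emit(sort(c(forced, current)))
    if (length(forced) + length(current) >= max_vars) return()
    for (idx in seq_along(free)) {
      if (idx < pos) next
      w <- weights[free[idx]]
      if (cur_w + w > bound) next
      recurse(idx + 1L, c(current, free[idx]), cur_w + w)
    }
  }
  recurse(1L, integer(0), forced_w)
  # depth-first emission is not lexicographic across sizes; normalise
  if (length(out) > 1L) {
    keys <- vapply(out, function(s)
      paste(sprintf("%06d", s), collapse = ","), "")
    out <- out[order(keys)]
  }
  out
}

# total weight of a subset
subset_weight <- function(subset, weights) sum(weights[subset])
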