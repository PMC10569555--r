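# Quadratic / cubic interaction expansion of numeric designs.
#
# Column ordering of the quadratic expansion of (a_1, ..., a_k):
#   a_1, ..., a_k, a_11, ..., a_1k, a_22, ..., a_2k, ..., a_kk
# i.e. the k linear terms followed, for i = 1..k, by the block
# a_ii, a_i,i+1, ..., a_ik.  The cubic expansion appends, for i = 1..k,
# the blocks a_ijl over i <= j <= l <= k in ascending (j, l) order, giving
# choose(k + 2, 3) cubic columns in total.

# column position -> sorted tuple of base indices, for the given order
expansion_map <- function(k, order = 2L) {
  stopifnot(k >= 1, order %in% c(2L, 3L))
  map <- as.list(seq_len(k))
  for (i in seq_len(k))
    for (j in i:k)
      map[[length(map) + 1L]] <- c(i, j)
  if (order == 3L)
    for (i in seq_len(k))
      for (j in i:k)
        for (l in j:k)
          map[[length(map) + 1L]] <- c(i, j, l)
  map
}

expand_design <- function(base, order) {
  X <- as.matrix(base)
  if (!is.numeric(X))
    stop("interaction expansion is not well-defined for non-numeric variables")
  if (anyNA(X)) stop("expansion input contains missing values")
  k <- ncol(X)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(k))
  map <- expansion_map(k, order)
  out <- vapply(map, function(idx) {
    col <- X[, idx[1L]]
    for (i in idx[-1L]) col <- col * X[, i]
    col
  }, numeric(nrow(X)))
  out <- matrix(out, nrow = nrow(X))
  colnames(out) <- vapply(map, function(idx) paste(nm[idx], collapse = "."), "")
  attr(out, "base_count") <- k
  attr(out, "order") <- order
  attr(out, "index_map") <- map
  out
}

#' Quadratic expansion of a numeric design
#'
#' Appends all squares and pairwise products to the `k` base columns, in the
#' order `a_1..a_k, a_11..a_1k, a_22..a_2k, ..., a_kk`, giving
#' `k + k(k+1)/2` columns.  Binary (0/1) columns are allowed (their square
#' duplicates them; the correlation bound removes such duplicates from the
#' search if desired).
#'
#' @param base numeric matrix or data frame with `k` columns (continuous or
#'   binary only; categorical columns are rejected).
#' @return numeric matrix with attributes `base_count`, `order` and
#'   `index_map` (column position -> sorted tuple of base indices).
#' @examples
#' q <- quadr(cbind(a = 1:4, b = c(2, 0, 1, 1), c = 4:1))
#' ncol(q)          # 9
#' find_int(6, 3)   # column 6 is the a*c interaction: 1 3
#' @export
quadr <- function(base) expand_design(base, 2L)

#' Cubic expansion of a numeric design
#'
#' [quadr()]'s columns followed, for `i = 1..k`, by the third-order products
#' `a_ijl` over `i <= j <= l <= k` in ascending `(j, l)` order:
#' `choose(k + 2, 3)` cubic columns, `k + k(k+1)/2 + choose(k+2, 3)` in
#' total.
#'
#' @inheritParams quadr
#' @return as [quadr()].
#' @export
cub <- function(base) expand_design(base, 3L)

#' Decode an expanded-design column index
#'
#' Maps a flattened column position of the quadratic or cubic expansion of
#' `k` base variables back to the sorted tuple of base-variable indices whose
#' elementwise product that column equals (length 1 for linear terms).
#'
#' @param ind column position, `1 <= ind <=` column count of the expansion.
#' @param k number of base variables.
#' @param order expansion order, 2 (quadratic, default) or 3 (cubic).
#' @return integer vector of base indices.
#' @examples
#' find_int(6, 3)            # 1 3
#' find_int(2, 3)            # 2
#' find_int(19, 3, order = 3) # 3 3 3
#' @export
find_int <- function(ind, k, order = 2L) {
  map <- expansion_map(k, as.integer(order))
  if (ind < 1L || ind > length(map))
    stop("index ", ind, " out of range: expansion of ", k,
         " variables at order ", order, " has ", length(map), " columns")
  as.integer(map[[ind]])
}

# closed-form column counts, used for validation
expansion_ncol <- function(k, order = 2L) {
  n <- k + k * (k + 1) / 2
  if (order == 3L) n <- n + choose(k + 2, 3)
  as.integer(n)
}
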