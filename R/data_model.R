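# Typed representation of predictors and outcomes.
#
# Encoding conventions used throughout the package:
#   * categorical outcomes are coded 0..L-1 with frequency non-increasing in
#     the code, so the least frequent category gets the highest code and is
#     the multinomial reference category;
#   * predictor columns carry an EPV weight: 1 for continuous and binary
#     columns, (levels - 1) for categorical ones;
#   * a numeric predictor with five or more distinct values is treated as
#     continuous, with fewer as categorical.

#' Encode an outcome vector
#'
#' Converts a raw outcome into the internal representation used by the
#' hold-out engine.  In `"linear"` mode values are passed through as reals.
#' In the categorical modes (`"binary"`, `"multin"`) the distinct values are
#' ranked by decreasing frequency and coded `0..L-1`, so that the least
#' frequent category receives the highest code and becomes the reference
#' category of the multinomial logit.  Frequency ties are broken by sorted
#' value order (numeric order for numeric outcomes), which makes the encoding
#' deterministic and invariant to row permutation.
#'
#' @param raw vector of outcome values (numeric, character or factor).
#' @param mode one of `"linear"`, `"binary"`, `"multin"`.
#' @return An object of class `"outcome_spec"`: a list with elements `mode`,
#'   `raw`, `encoded` (reals for linear, integer codes otherwise), `levels`
#'   (labels ordered by code), `category_counts` and `reference_category`
#'   (always `L - 1`).
#' @examples
#' sp <- encode_outcome(c(rep("no", 150), rep("yes", 50)), "binary")
#' sp$levels              # "no" -> 0, "yes" -> 1
#' sp$reference_category  # 1
#' @export
encode_outcome <- function(raw, mode = c("linear", "binary", "multin")) {
  mode <- match.arg(mode)
  if (length(raw) == 0L) stop("outcome is empty")
  if (is.factor(raw)) raw <- as.character(raw)
  if (anyNA(raw)) stop("outcome contains missing values; remove or impute before modelling")
  if (mode == "linear") {
    y <- suppressWarnings(as.numeric(raw))
    if (anyNA(y)) stop("linear mode requires a numeric outcome")
    out <- list(mode = mode, raw = raw, encoded = y, levels = NULL,
                category_counts = NULL, reference_category = NULL)
    class(out) <- "outcome_spec"
    return(out)
  }
  vals <- as.character(raw)
  tab <- table(vals)
  lev <- names(tab)
  # tie-break by sorted raw-value order; numeric outcomes sort numerically
  key <- suppressWarnings(as.numeric(lev))
  tie_rank <- if (!anyNA(key)) rank(key) else rank(lev)
  ord <- order(-as.integer(tab), tie_rank)
  lev <- lev[ord]
  L <- length(lev)
  if (L < 2L) stop("categorical outcome needs at least two distinct values")
  if (mode == "binary" && L != 2L)
    stop("binary mode requires exactly two outcome categories, got ", L)
  enc <- match(vals, lev) - 1L
  counts <- as.integer(tab[lev])
  names(counts) <- lev
  out <- list(mode = mode, raw = raw, encoded = enc, levels = lev,
              category_counts = counts, reference_category = L - 1L)
  class(out) <- "outcome_spec"
  out
}

#' Decode encoded outcome values back to their original labels
#'
#' @param spec an `"outcome_spec"` from [encode_outcome()].
#' @param codes integer codes to decode; defaults to `spec$encoded`.
#' @return The original labels (character) for categorical modes, the numeric
#'   values for linear mode.
#' @export
decode_outcome <- function(spec, codes = spec$encoded) {
  stopifnot(inherits(spec, "outcome_spec"))
  if (spec$mode == "linear") return(codes)
  spec$levels[codes + 1L]
}

#' Classify a predictor column and compute its EPV weight
#'
#' A numeric column with five or more distinct values is continuous
#' (weight 1); a numeric column with exactly two distinct values is binary
#' (weight 1); other numeric columns and all string columns are categorical
#' with weight `levels - 1`.  A constant column gets weight 0 and is flagged
#' so enumeration excludes it.
#'
#' @param values the raw column (no missing values allowed).
#' @param name column label.
#' @param force optional override, `"continuous"` or `"categorical"`.
#' @return A list (class `"predictor_column"`) with `name`, `kind` (one of
#'   `"continuous"`, `"binary"`, `"categorical"`, `"constant"`), `levels`
#'   (categorical only, ordered by decreasing frequency) and integer
#'   `weight`.
#' @export
column_weight <- function(values, name = "x", force = NULL) {
  if (length(values) == 0L) stop("empty column '", name, "'")
  if (is.factor(values)) values <- as.character(values)
  if (anyNA(values)) stop("column '", name, "' contains missing values")
  distinct <- unique(values)
  nd <- length(distinct)
  numeric_col <- is.numeric(values)
  if (!is.null(force)) {
    force <- match.arg(force, c("continuous", "categorical"))
    if (force == "continuous" && !numeric_col)
      stop("column '", name, "' cannot be forced continuous: not numeric")
  }
  if (nd == 1L) {
    col <- list(name = name, kind = "constant", levels = character(0), weight = 0L)
  } else if (identical(force, "continuous") ||
             (is.null(force) && numeric_col && nd >= 5L)) {
    col <- list(name = name, kind = "continuous", levels = character(0), weight = 1L)
  } else if (is.null(force) && numeric_col && nd == 2L) {
    col <- list(name = name, kind = "binary", levels = character(0), weight = 1L)
  } else {
    lev <- names(sort(table(as.character(values)), decreasing = TRUE))
    col <- list(name = name, kind = "categorical", levels = lev,
                weight = as.integer(nd - 1L))
  }
  class(col) <- "predictor_column"
  col
}

#' Build a predictor table from a data frame
#'
#' Types every column via [column_weight()], expands categorical predictors
#' into indicator (dummy) columns -- the most frequent level is the dropped
#' reference -- and computes the pairwise correlation matrix of the
#' numeric-encoded predictors used by the correlation bound.
#'
#' @param df data frame of predictors (no missing cells).
#' @param types optional named character vector of per-column overrides,
#'   values in `{"continuous","categorical"}`.
#' @return An object of class `"predictor_table"`: list with `columns`
#'   (per-predictor `"predictor_column"` specs), `weights` (integer vector),
#'   `design` (N x d numeric design matrix with dummies expanded),
#'   `design_map` (predictor index owning each design column), `numeric`
#'   (N x n numeric-encoded matrix used for correlations) and `correlation`.
#' @export
predictor_table <- function(df, types = NULL) {
  df <- as.data.frame(df)
  if (nrow(df) < 2L) stop("need at least two rows")
  if (ncol(df) < 1L) stop("need at least one predictor column")
  if (anyNA(df)) stop("predictor table contains missing cells")
  nm <- names(df)
  cols <- vector("list", ncol(df))
  for (j in seq_along(df)) {
    force <- if (!is.null(types) && nm[j] %in% names(types)) types[[nm[j]]] else NULL
    cols[[j]] <- column_weight(df[[j]], name = nm[j], force = force)
  }
  weights <- vapply(cols, function(cl) cl$weight, integer(1))

  design_list <- vector("list", ncol(df))
  numeric_enc <- matrix(0, nrow(df), ncol(df), dimnames = list(NULL, nm))
  for (j in seq_along(df)) {
    cl <- cols[[j]]
    v <- df[[j]]
    if (is.factor(v)) v <- as.character(v)
    if (cl$kind %in% c("continuous", "binary")) {
      m <- matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, cl$name))
      numeric_enc[, j] <- as.numeric(v)
    } else if (cl$kind == "categorical") {
      lev <- cl$levels
      # drop the most frequent level (first) as reference
      m <- vapply(lev[-1L], function(l) as.numeric(as.character(v) == l),
                  numeric(nrow(df)))
      m <- matrix(m, nrow = nrow(df),
                  dimnames = list(NULL, paste0(cl$name, ".", lev[-1L])))
      numeric_enc[, j] <- match(as.character(v), lev) - 1
    } else { # constant
      m <- matrix(numeric(0), nrow = nrow(df), ncol = 0)
      numeric_enc[, j] <- if (is.numeric(v)) as.numeric(v) else 0
    }
    design_list[[j]] <- m
  }
  design <- do.call(cbind, design_list)
  design_map <- rep.int(seq_along(df),
                        vapply(design_list, ncol, integer(1)))
  corr <- suppressWarnings(stats::cor(numeric_enc))
  corr[is.na(corr)] <- 0 # constant columns have undefined correlation
  diag(corr) <- 1
  out <- list(columns = cols, weights = weights, data = df,
              design = design, design_map = design_map,
              numeric = numeric_enc, correlation = corr)
  class(out) <- "predictor_table"
  out
}

#' @export
print.predictor_table <- function(x, ...) {
  cat("predictor_table:", nrow(x$data), "rows,", length(x$columns),
      "predictors (total weight", sum(x$weights), ")\n")
  info <- data.frame(
    name = vapply(x$columns, `[[`, "", "name"),
    kind = vapply(x$columns, `[[`, "", "kind"),
    weight = x$weights)
  print(info, row.names = FALSE)
  invisible(x)
}

# design columns belonging to a subset of predictor indices
subset_design <- function(table, subset, rows = NULL) {
  keep <- table$design_map %in% subset
  X <- table$design[, keep, drop = FALSE]
  if (!is.null(rows)) X <- X[rows, , drop = FALSE]
  X
}

#' Read a predictor table and outcome from a CSV file
#'
#' The file must have a header row.  All columns except `outcome` become
#' predictors.
#'
#' @param path CSV file path (RFC-4180, header required).
#' @param outcome name of the outcome column.
#' @param mode outcome mode passed to [encode_outcome()].
#' @param types optional per-column type overrides, see [predictor_table()].
#' @return list with `table` (a `"predictor_table"`) and `outcome`
#'   (an `"outcome_spec"`).
#' @export
read_predictor_csv <- function(path, outcome, mode, types = NULL) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  if (!outcome %in% names(df))
    stop("outcome column '", outcome, "' not found in ", path)
  y <- df[[outcome]]
  df[[outcome]] <- NULL
  list(table = predictor_table(df, types = types),
       outcome = encode_outcome(y, mode))
}
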