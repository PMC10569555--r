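# S3 methods for "holdout_select" objects.

# first best subset under the object's primary criterion
primary_best <- function(object, which = NULL) {
  if (is.null(which)) which <- names(object$best)[1L]
  b <- object$best[[which]]
  if (length(b) == 0L)
    stop("no model was feasible under criterion '", which, "'")
  b[[1L]]
}

#' @export
print.holdout_select <- function(x, digits = 7, ...) {
  cat("Best-subset selection over", x$crv, "hold-outs (mode =", x$mode,
      if (x$mode != "linear") paste0(", objective = ", x$config$objfun), ")\n")
  cat("candidates:", length(x$candidates), " N =", x$N,
      " test size =", x$N %/% x$part, "\n\n")
  print(round(unname(x$header), digits))
  for (crit in names(x$best)) {
    b <- x$best[[crit]]
    cat("\nbest by", crit, ":",
        if (length(b) == 0L) "none feasible"
        else paste(vapply(b, paste, "", collapse = " "), collapse = " | "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.holdout_select <- function(object, n_top = 10L, ...) {
  pm <- object$per_model
  metric <- names(pm)[3L] # first test metric
  ord <- order(if (object$objective == "error") pm[[metric]] else -pm[[metric]])
  structure(list(object = object,
                 top = utils::head(pm[ord, , drop = FALSE], n_top)),
            class = "summary.holdout_select")
}

#' @export
print.summary.holdout_select <- function(x, ...) {
  print(x$object)
  cat("\nTop models by average test performance:\n")
  print(x$top, row.names = FALSE, digits = 4)
  sk <- x$object$skip_reasons
  sk <- sk[sk > 0L]
  if (length(sk)) {
    cat("\nSkipped (model, split) evaluations by reason:\n")
    print(sk)
  }
  invisible(x)
}

# refit a chosen subset on the full data
refit_full <- function(object, subset) {
  X <- subset_design(object$table, subset)
  L <- if (object$mode == "linear") 2L else length(object$outcome$levels)
  fit <- fit_subset(X, object$outcome$encoded, object$mode, L = L)
  if (is.null(fit)) stop("full-data refit failed for subset ",
                         paste(subset, collapse = ","))
  colnames_X <- colnames(X)
  list(fit = fit, subset = subset, colnames = colnames_X)
}

#' Coefficients of the best model refitted on the full data
#'
#' @param object a `"holdout_select"` fit.
#' @param which criterion whose best model to use (e.g. `"abs"`, `"rel"`,
#'   `"acc"`, `"auroc"`); defaults to the object's primary criterion.  Ties
#'   are broken towards the lexicographically first subset.
#' @param ... ignored.
#' @return named coefficient vector (linear) or matrix with one row per
#'   non-reference outcome category.
#' @export
coef.holdout_select <- function(object, which = NULL, ...) {
  rf <- refit_full(object, primary_best(object, which))
  co <- rf$fit$coefficients
  if (is.matrix(co)) {
    colnames(co) <- c("(Intercept)", rf$colnames)
    rownames(co) <- object$outcome$levels[seq_len(nrow(co))]
  }
  co
}

# rebuild a design block for new data using the stored column specs
design_for_newdata <- function(table, newdata, subset) {
  df <- as.data.frame(newdata)
  cols <- table$columns[subset]
  blocks <- lapply(cols, function(cl) {
    if (!cl$name %in% names(df))
      stop("newdata lacks predictor '", cl$name, "'")
    v <- df[[cl$name]]
    if (is.factor(v)) v <- as.character(v)
    if (cl$kind %in% c("continuous", "binary")) {
      matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, cl$name))
    } else {
      lev <- cl$levels
      unknown <- setdiff(unique(as.character(v)), lev)
      if (length(unknown))
        stop("unknown level(s) in '", cl$name, "': ",
             paste(unknown, collapse = ", "))
      m <- vapply(lev[-1L], function(l) as.numeric(as.character(v) == l),
                  numeric(nrow(df)))
      matrix(m, nrow = nrow(df),
             dimnames = list(NULL, paste0(cl$name, ".", lev[-1L])))
    }
  })
  do.call(cbind, blocks)
}

#' Predict from the best model refitted on the full data
#'
#' @param object a `"holdout_select"` fit.
#' @param newdata data frame with the original predictor columns (the base
#'   columns when an interaction expansion was used -- the expansion is
#'   re-applied automatically).  Defaults to the training data.
#' @param which criterion whose best model to use, see
#'   [coef.holdout_select()].
#' @param type `"response"` (linear predictions / predicted category codes)
#'   or `"probs"` (categorical modes: category-probability matrix).
#' @param cutoff binary decision threshold; defaults to the run's cutoff.
#' @param ... ignored.
#' @export
predict.holdout_select <- function(object, newdata = NULL, which = NULL,
                                   type = c("response", "probs"),
                                   cutoff = NULL, ...) {
  type <- match.arg(type)
  subset <- primary_best(object, which)
  rf <- refit_full(object, subset)
  if (is.null(newdata)) {
    X <- subset_design(object$table, subset)
  } else {
    nd <- as.data.frame(newdata)
    if (!is.null(object$expansion)) {
      base <- nd[, object$expansion$base_names, drop = FALSE]
      nd <- as.data.frame(expand_design(as.matrix(base),
                                        object$expansion$order))
    }
    X <- design_for_newdata(object$table, nd, subset)
  }
  if (object$mode == "linear") {
    if (type == "probs") stop("type = 'probs' applies to categorical modes")
    return(predict_linear(rf$fit, X))
  }
  probs <- categorical_probs(rf$fit, X)
  if (type == "probs") {
    colnames(probs) <- object$outcome$levels
    return(probs)
  }
  classify(probs, object$mode,
           if (is.null(cutoff)) object$config$cutoff else cutoff)
}

#' Residuals of the best model refitted on the full data (linear mode)
#'
#' @param object a `"holdout_select"` fit in linear mode.
#' @param which see [coef.holdout_select()].
#' @param ... ignored.
#' @export
residuals.holdout_select <- function(object, which = NULL, ...) {
  if (object$mode != "linear")
    stop("residuals are defined for linear mode")
  object$outcome$encoded - predict(object, which = which)
}

#' Plot the distribution of average test performance across candidates
#'
#' Histogram of per-model average test metric, with the best model and (where
#' reported) the empirical baseline marked.
#'
#' @param x a `"holdout_select"` fit.
#' @param ... passed to [graphics::hist()].
#' @export
plot.holdout_select <- function(x, ...) {
  pm <- x$per_model
  metric <- names(pm)[3L]
  v <- pm[[metric]][!is.na(pm[[metric]])]
  if (!length(v)) stop("no evaluated models to plot")
  graphics::hist(v, main = "Average test performance across candidate models",
                 xlab = metric, ...)
  best <- x$header[[1L]]
  if (!is.na(best)) graphics::abline(v = best, col = "red3", lwd = 2)
  if (!is.null(x$empirical)) {
    e <- x$empirical[[1L]]
    if (!is.na(e)) graphics::abline(v = e, col = "grey40", lty = 2, lwd = 2)
  }
  invisible(x)
}
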