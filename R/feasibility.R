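# Sample-size feasibility gates.
#
# Two families of criteria decide whether a candidate model may be fitted on
# a given training set:
#   * the events-per-variable (EPV) rule: r * weight(model) <= events, where
#     events is the training size for continuous outcomes and the count of
#     the least likely outcome category for categorical ones;
#   * shrinkage / R-squared sample-size criteria adapted to the hold-out
#     setting: instead of solving for a prospective n, each criterion is
#     evaluated on the current training fit and failing models are declared
#     infeasible for that hold-out only.

#' Largest admissible model weight under an EPV rule
#'
#' @param events number of events (training size for linear outcomes, least
#'   likely category count for categorical ones).
#' @param r the EPV rule constant (default 10, the "one in ten" rule).
#' @return `floor(events / r)`, the largest model weight satisfying the rule.
#' @examples
#' epv_max_weight(47, 10) # 4
#' @export
epv_max_weight <- function(events, r = 10) {
  stopifnot(events >= 0, r > 0)
  as.integer(floor(events / r))
}

#' EPV feasibility of a model weight
#'
#' @param model_weight sum of the weights of the model's predictors.
#' @param events see [epv_max_weight()].
#' @param r the EPV rule constant.
#' @return `TRUE` iff `r * model_weight <= events`.
#' @export
epv_feasible <- function(model_weight, events, r = 10) {
  stopifnot(model_weight >= 0)
  r * model_weight <= events
}

#' Shrinkage-factor threshold for the linear R-squared gate
#'
#' The first argument of the apparent-R2 condition: the minimum apparent R2
#' for which the anticipated global shrinkage stays above 0.9 at the given
#' model weight and training size, `0.9 * (1 - exp(-p / (0.1 * n_tr)))`.
#' Exposed so an alternative threshold can be injected into
#' [rsq_gate_linear()] without touching callers.
#'
#' @param p model weight (fitted parameters excluding intercept).
#' @param n_tr training-set size.
#' @export
rsq_shrink_threshold <- function(p, n_tr) 0.9 * (1 - exp(-p / (0.1 * n_tr)))

#' R-squared sample-size gate for linear models
#'
#' A linear candidate passes iff its apparent R2 on the training set exceeds
#' both the shrinkage-factor threshold ([rsq_shrink_threshold()] by default)
#' and the apparent-vs-adjusted criterion
#' `1 - 0.05 * (n_tr - 1 - p) / p`, which keeps the optimism
#' (apparent minus adjusted R2) below 0.05.
#'
#' @param R2_app apparent coefficient of determination on the training set.
#' @param p model weight.
#' @param n_tr training-set size (`n_tr > p + 1`).
#' @param shrink_fn threshold function `f(p, n_tr)` for the shrinkage term.
#' @return logical; `p = 0` (intercept-only) passes vacuously.
#' @export
rsq_gate_linear <- function(R2_app, p, n_tr, shrink_fn = rsq_shrink_threshold) {
  if (p == 0L) return(TRUE)
  stopifnot(n_tr > p + 1)
  t_adj <- 1 - 0.05 * (n_tr - 1 - p) / p
  t_shrink <- shrink_fn(p, n_tr)
  isTRUE(R2_app > max(t_shrink, t_adj))
}

#' Error margins of residual variance and mean outcome (linear mode)
#'
#' Confidence-interval half-width style margins evaluated on the training
#' fit, with `nu = n_tr - p - 1` residual degrees of freedom:
#' `Mv = max(chisq(0.975, nu)/nu, nu/chisq(0.025, nu))` is the multiplicative
#' 95% margin of the residual variance estimate, and
#' `Mo = t(0.975, nu) * sigma_hat / (sqrt(n_tr) * |mean_hat|)` is the 95%
#' margin of the mean outcome on the relative scale, so both are unitless and
#' comparable.  A model is margin-feasible iff `max(Mv - 1, Mo) <= marg`.
#'
#' @param n_tr training-set size.
#' @param p model weight.
#' @param sigma_hat residual standard deviation estimate.
#' @param mean_hat training-outcome mean; `Mo` is undefined when it is 0.
#' @return list with `Mv`, `Mo` (NA when undefined).
#' @export
margins_linear <- function(n_tr, p, sigma_hat, mean_hat) {
  nu <- n_tr - p - 1
  stopifnot(nu >= 1, sigma_hat >= 0)
  Mv <- max(stats::qchisq(0.975, nu) / nu, nu / stats::qchisq(0.025, nu))
  Mo <- if (sigma_hat == 0) 0
        else if (mean_hat == 0) NA_real_
        else stats::qt(0.975, nu) * sigma_hat / (sqrt(n_tr) * abs(mean_hat))
  list(Mv = Mv, Mo = Mo)
}

#' Van Houwelingen shrinkage gate for binary models
#'
#' With likelihood-ratio statistic `LR = 2 * (logLm - logL0)`, the gate
#' requires the global shrinkage factor `S_VH = 1 - p / LR` to exceed 0.9
#' and the absolute optimism
#' `(R2_CS / R2_CS,max) * (1 - S_VH)` to stay below 0.05, where
#' `R2_CS = 1 - exp(-LR / n_tr)` is the Cox-Snell R-squared and
#' `R2_CS,max = 1 - exp(2 * logL0 / n_tr)` its attainable maximum.
#'
#' @param logL0,logLm log-likelihoods of the null (intercept-only) and
#'   candidate model on the training set.
#' @param p number of fitted parameters excluding the intercept.
#' @param n_tr training-set size.
#' @return logical; `LR = 0` returns `FALSE` (no information, shrinkage
#'   undefined).
#' @export
riley_gate_binary <- function(logL0, logLm, p, n_tr) {
  stopifnot(logLm >= logL0 - 1e-8)
  LR <- max(0, 2 * (logLm - logL0))
  if (LR == 0) return(FALSE)
  S_VH <- 1 - p / LR
  if (!(S_VH > 0.9)) return(FALSE)
  R2_cs <- 1 - exp(-LR / n_tr)
  R2_max <- 1 - exp(2 * logL0 / n_tr)
  if (R2_max <= 0) return(FALSE)
  (R2_cs / R2_max) * (1 - S_VH) < 0.05
}

#' Error margin of an outcome proportion
#'
#' 95% normal-approximation margin `1.96 * sqrt(phi * (1 - phi) / n)` of the
#' outcome proportion estimated on a training set of size `n`.
#'
#' @param phi_hat estimated outcome proportion in `[0, 1]`.
#' @param n training-set size.
#' @export
proportion_margin <- function(phi_hat, n) {
  stopifnot(phi_hat >= 0, phi_hat <= 1, n >= 1)
  1.96 * sqrt(phi_hat * (1 - phi_hat) / n)
}

#' Probability that a random training subset contains enough events
#'
#' Exact hypergeometric tail probability that a uniformly random training
#' subset of `n_train` of the `N` rows contains at least `min_events` of the
#' cohort's `events` events.  Useful for judging how often a heavy model will
#' be EPV-feasible across random hold-out splits.
#'
#' @param N cohort size.
#' @param events number of events in the cohort.
#' @param n_train training subset size.
#' @param min_events event count of interest.
#' @return `P(X >= min_events)` with `X` hypergeometric.
#' @examples
#' # 68 events among 200 rows; training sets of 160 rows:
#' training_event_tail(200, 68, 160, 60) # about 0.026
#' @export
training_event_tail <- function(N, events, n_train, min_events) {
  stopifnot(events <= N, n_train <= N, min_events >= 0)
  stats::phyper(min_events - 1, events, N - events, n_train, lower.tail = FALSE)
}
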