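---
title: "Best-subset regression under EPV rules with repeated hold-out validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Best-subset regression under EPV rules with repeated hold-out validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holdoutbss)
```

## The problem

In moderate-sample clinical and epidemiological studies the question is
rarely "which coefficients are significant" but "which small model predicts
best, given that the sample cannot support a large one".  `holdoutbss`
answers it by exhaustive search: every admissible subset of candidate
predictors is fitted and ranked by its *average out-of-sample predictive
power* over many random hold-out splits.  Admissibility encodes sample-size
discipline — events-per-variable (EPV) rules and shrinkage-based
R² criteria — together with expert constraints (forced terms, bounds on
model size, weight and collinearity).

## The model and its feasibility rules

A candidate model is a subset $S$ of predictors fitted with the link
appropriate to the outcome: identity (ordinary least squares) for
continuous outcomes, a reference-category multinomial logit for binary and
multi-category outcomes.  Each predictor carries an integer *weight*: 1 for
continuous and binary columns, $l-1$ for a categorical column with $l$
levels (its dummy block); a numeric column with five or more distinct
values is treated as continuous.  The model weight is the sum of its
members' weights.

**EPV rule.** With rule constant $r$ (default 10, the classical one-in-ten
rule) a model of weight $w$ is feasible when $r\,w \le N_{ev}$, where
$N_{ev}$ is the training-set size for continuous outcomes and the count of
the *least likely* outcome category in the training set for categorical
ones.  Because event counts vary across random splits, feasibility is
re-decided per hold-out: a heavy model can be assessable on a lucky split
and not on the next.

**R²/shrinkage gates (optional, `Rsq = TRUE`).** For linear models the
apparent training R² must exceed both
$1 - 0.05\,(n_{tr}-1-p)/p$ (which caps the apparent-minus-adjusted R²
optimism at 0.05) and a shrinkage threshold, by default
$0.9\,(1-e^{-p/(0.1\,n_{tr})})$, keeping the anticipated global shrinkage
above 0.9.  The printed source for the first threshold is typographically
ambiguous, so the function is an injectable parameter (`shrink_fn`) rather
than a hard-wired formula.  For binary models the Van Houwelingen
shrinkage factor $S_{VH} = 1 - p/LR$ must exceed 0.9 and the absolute
optimism $(R^2_{CS}/R^2_{CS,max})(1-S_{VH})$ must stay below 0.05, with
$LR = 2(\log L_m - \log L_0)$ and the Cox–Snell
$R^2_{CS} = 1 - e^{-LR/n_{tr}}$.  We take $LR \ge 0$ by definition of the
likelihood ratio; models with $LR = 0$ carry no information and fail the
gate.

**Error margins (optional, `marg`).** Linear models must keep the 95%
margins of the residual-variance estimate ($M_v - 1$, a chi-square ratio)
and of the mean outcome ($M_o$, a t-margin divided by $|\bar y|$ so it is
unitless and comparable to $M_v - 1$) within `marg`; binary runs require
the training outcome-proportion margin $1.96\sqrt{\hat\phi(1-\hat\phi)/n}$
within `marg`.  The mean-outcome margin is undefined when $\bar y = 0$;
such models are skipped for that hold-out with a logged reason rather than
scored on an ill-defined scale.

## The hold-out engine

Each of `crv` hold-outs draws $\lfloor N/\mathtt{part}\rfloor$ test rows
uniformly without replacement (default `part = 10`: 90% training, 10%
test).  Every admissible candidate is fitted on the training rows and
scored on the test rows: mean absolute and mean relative error for
continuous outcomes, accuracy or AUROC (rank form, half-credit for ties)
for categorical ones.  The relative error is reported `NA` as soon as a
zero outcome occurs — flagging is preferable to silently dropping points.
One-class test sets make AUROC undefined; such splits are excluded from
that model's AUROC average and counted.

Per-model averages are taken over the splits where the model was actually
evaluated, and every model carries its *coverage* (fraction of splits where
it was assessed).  Averaging over evaluated splits alone would favour heavy
models that sneak through on a few event-rich splits, so a model may only
be declared best when its coverage reaches `min_coverage` (default 0.5).
All ties are returned.  The empirical baseline — training mean for
continuous outcomes, the constant most-frequent class for categorical ones
— is scored on the same splits; it is omitted under the AUROC objective,
where a constant score has no discrimination to measure.

Reproducibility: the RNG substream of split $i$ is derived from
`(seed, i)`, so serial and parallel executions (forked workers via the
`parallel` package) are bit-identical and independent of scheduling.

## Encoding conventions

Categorical outcomes are coded $0..L-1$ with frequency non-increasing in
the code; the least frequent category gets the highest code and is the
multinomial reference.  Frequency ties are broken by sorted value order —
deterministic and permutation-invariant.  Categorical *predictors* are
expanded to indicator columns with the most frequent level as the dropped
reference; any fixed convention spans the same fitted subspace, so this
choice affects coefficient labels, never predictions.  Binary
classification predicts the event class (code 1) when its probability
reaches `cutoff` (inclusive, default 0.5); multinomial prediction is the
arg-max with ties towards the lowest code.  Missing cells are rejected at
load time; imputation is out of scope.

## Interaction expansion

`quadr()` maps $(a_1,\dots,a_k)$ to the $k + k(k+1)/2$ columns
$a_1,\dots,a_k, a_{11},\dots,a_{1k}, a_{22},\dots,a_{kk}$; `cub()` appends
the $\binom{k+2}{3}$ third-order products $a_{ijl}$, $i\le j\le l$, in
ascending order.  `find_int(ind, k, order)` decodes a flattened column
position back to its base-variable tuple (the quadratic decode reproduces
the original tool's indexing; the `order` argument extends it to the cubic
layout, whose published description states a block count inconsistent with
its own formula — we follow the formula).  Expansion is defined for
numeric columns only; expanded columns are treated as continuous
regressors of weight 1.

## Search-space constraints

Enumeration is exhaustive by design (that is the method), lexicographic
and deterministic, with forced terms, `minx`/`maxx` size bounds, a weight
bound (the binding one of `maxw` and the EPV cap implied by the largest
possible training event count) and an inclusive pairwise-correlation bound
`corr`.  The correlation matrix is computed once on the full data: the
filter is a search-space reduction, and making the candidate set
split-dependent beyond what event counting already requires would blur
what "the same model across splits" means.  A
`per_split_correlation = TRUE` switch restores the stricter per-training-set
behaviour for users who want it.

## Comparator methods

Three selection strategies widely used in practice run on the *identical*
split plan: univariate-significance selection (keep predictors with
univariate $p < \alpha$, default 0.05; F-test for linear, likelihood-ratio
test for categorical outcomes), greedy forward selection by
$-2\log L + 2k$ (AIC), and lasso regression over a penalty grid fixed
across hold-outs (default: the glmnet path on the full data, ~50 values
spanning four decades), choosing the penalty with the best average test
metric.  Each records its per-split selected sets — instability of those
sets across splits is a heterogeneity diagnostic in itself.  The
overfitting measure is the relative generalisation gap:
$(\text{test}-\text{train})/\text{test}$ for errors,
$(\text{train}-\text{test})/\text{train}$ for accuracy/AUROC; the raw
test/train pair is always retained so an absolute difference can be formed
as well.

## The synthetic-data generator

`generate_scenario()` draws continuous predictors from a correlated
standard Gaussian (Cholesky factor of the requested correlation, which must
be positive definite), categorical predictors uniformly over their levels,
and outcomes from the model itself: $y = \eta + \varepsilon$,
Bernoulli$(\text{logit}^{-1}\eta)$, or the reference-category softmax.  For
binary outcomes the intercept can be solved so the expected event
proportion hits a target.  The bundled fixtures are fixed-seed calls:
`swiss_like()` (47 rows, 5 continuous predictors, continuous outcome — the
regime where the rule of ten admits models up to weight 4) and
`pima_like()` (200 rows, 7 predictors, *exactly* 68 events, assigned to the
68 largest latent risks so the count is pinned; the majority-class baseline
is exactly 0.66).

What the generator does *not* emulate: missing data, measurement error,
outcome-dependent sampling, non-Gaussian predictor tails, and real-world
collinearity structure beyond an exchangeable or user-supplied correlation
matrix.  Passing tests therefore demonstrate correctness of the machinery
and calibration under the generative model, not performance on any
particular clinical dataset.

## Numerical choices and degenerate inputs

* Least squares via `lm.fit`; singular designs are per-split skips, never
  aborts.  Multinomial fits via `nnet::multinom` (relative log-likelihood
  tolerance $10^{-8}$, 100 iterations); non-convergence and
  absent-from-training categories are skips with logged reasons.
* Softmax probabilities are evaluated with log-sum-exp, so extreme linear
  predictors cannot overflow; rows sum to 1 within $10^{-12}$.
* AUROC uses midranks (Mann–Whitney form), giving tied scores half credit.
* Constant predictor columns get weight 0 and are excluded from
  enumeration rather than erroring.
* All seeds derived internally stay below $2^{31}$.

## Known limitations

* **Internal validation cannot separate the true support from supersets.**
  Training and test rows are subsets of the same finite sample, so a noise
  predictor whose chance correlation with the realised error term is
  $O(1/\sqrt N)$ *genuinely* improves hold-out test error about half the
  time; the best-ranked set then strictly contains the generating support.
  This is a property of repeated hold-outs on fixed data, not of the
  implementation — exact support recovery claims require fresh external
  data.  In our simulations at $n = 300$ with two strong effects among six
  predictors, the winning set always contained the true support but
  equalled it only in roughly half the generator seeds.
* Keep-rate and calibration properties of the comparators must be judged
  across independent datasets: hold-out splits of one dataset share ~90%
  of their training rows and are nearly perfectly correlated.
* The multinomial mode applies the EPV rule and (optionally) the
  proportion margin, but the shrinkage gate is defined for linear and
  binary outcomes only.
* Exhaustive search is exponential in the weight bound; the EPV cap and
  the `maxw`/`corr` constraints are what keep it tractable.

## Problem sizes used in the test suite

The suite exercises the engine at deliberately modest scale — hundreds of
rows, up to ten predictors, tens to two hundred hold-outs, and 20-seed
replication for recovery properties — which is where the statistical
phenomena of interest (per-split feasibility, coverage effects, type-I
calibration) already appear clearly.

## A worked run

```{r example}
d <- swiss_like()
fit <- holdout_select(d$table, d$outcome_spec, mode = "linear",
                      crv = 200, seed = 3)
fit
```

The printed array is: average absolute and relative error of the best
models on the test sets, the same models' training errors (their gap is the
overfitting read-out), and the empirical baseline's errors.  The index sets
below it are the tied best models, 1-based in the supplied predictor block.

```{r comparators}
plan <- make_splits(fit$N, 50, fit$part, fit$seed)
compare_methods(d$table, d$outcome_spec, mode = "linear", splits = plan)
```
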