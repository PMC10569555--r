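test_that("linear fits interpolate noiseless data and match the normal equations", {
  x <- seq(-2, 2, length.out = 20)
  fit <- fit_subset(matrix(x, ncol = 1), 2 + 3 * x, "linear")
  expect_equal(unname(fit$coefficients), c(2, 3), tolerance = 1e-10)
  expect_equal(fit$R2_app, 1, tolerance = 1e-12)

  set.seed(12)
  X <- matrix(rnorm(150), 50, 3)
  y <- 1 + X %*% c(0.5, -1, 2) + rnorm(50)
  fit2 <- fit_subset(X, drop(y), "linear")
  expect_lt(max(abs(fit2$coefficients - normal_equations(X, drop(y)))), 1e-8)
  expect_equal(fit2$mean_hat, mean(y))

  # singular design is a skip, not an abort
  Xs <- cbind(X, X[, 1])
  expect_null(fit_subset(Xs, drop(y), "linear"))
})

test_that("intercept-only categorical fit reproduces the event fraction and null likelihood", {
  y <- rep(c(0L, 1L), c(30, 30))
  fit <- fit_subset(matrix(numeric(0), 60, 0), y, "binary", L = 2L)
  probs <- categorical_probs(fit, matrix(numeric(0), 1, 0))
  expect_equal(unname(probs[1, ]), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(fit$logLm, fit$logL0, tolerance = 1e-6)
  # a category absent from training marks the fit infeasible
  expect_null(fit_subset(matrix(rnorm(10)), rep(0L, 10), "binary", L = 2L))
})

test_that("softmax probabilities follow the reference-category logit and sum to one", {
  fit <- structure(list(mode = "binary",
                        coefficients = matrix(c(0, 0), 1, 2), L = 2L),
                   class = "subset_fit")
  p <- categorical_probs(fit, matrix(0, 1, 1))
  expect_equal(unname(p[1, ]), c(0.5, 0.5))

  fit3 <- structure(list(mode = "multin",
                         coefficients = matrix(0, 2, 2), L = 3L),
                    class = "subset_fit")
  p3 <- categorical_probs(fit3, matrix(0, 1, 1))
  expect_equal(unname(p3[1, ]), rep(1 / 3, 3))

  # eta = ln 2 for the single non-reference category -> P = 2/3
  fit_l <- structure(list(mode = "binary",
                          coefficients = matrix(c(log(2), 0), 1, 2), L = 2L),
                     class = "subset_fit")
  expect_equal(categorical_probs(fit_l, matrix(0, 1, 1))[1, 1], 2 / 3,
               ignore_attr = TRUE)

  # extreme linear predictors stay finite via log-sum-exp
  fit_big <- structure(list(mode = "multin",
                            coefficients = cbind(c(2000, -2000), c(1, 1)),
                            L = 3L), class = "subset_fit")
  pb <- categorical_probs(fit_big, matrix(1, 5, 1))
  expect_true(all(is.finite(pb)))
  expect_equal(rowSums(pb), rep(1, 5), tolerance = 1e-12)
})

test_that("classification applies the cutoff and argmax tie-break conventions", {
  expect_identical(classify(c(0.4, 0.6), "binary", 0.5), 1L)
  expect_identical(classify(c(0.4, 0.6), "binary", 0.7), 0L)
  expect_identical(classify(c(0.4, 0.6), "binary", 0.6), 1L) # inclusive
  expect_identical(classify(c(0.2, 0.5, 0.3), "multin"), 1L)
  expect_identical(classify(c(0.4, 0.4, 0.2), "multin"), 0L) # lowest code wins
})

test_that("multinomial fits agree with the reference-category logit on recoverable data", {
  set.seed(77)
  n <- 600
  x <- rnorm(n)
  eta <- cbind(1.5 * x, -1 * x)
  probs <- cbind(exp(eta), 1) / (1 + rowSums(exp(eta)))
  y <- apply(probs, 1, function(p) sample.int(3, 1, prob = p)) - 1L
  sp <- encode_outcome(y, "multin")
  fit <- fit_subset(matrix(x), sp$encoded, "multin", L = 3L)
  expect_false(is.null(fit))
  expect_gte(fit$logLm, fit$logL0)
  P <- categorical_probs(fit, matrix(x))
  expect_equal(rowSums(P), rep(1, n), tolerance = 1e-12)
  # predicted categories beat chance comfortably
  expect_gt(accuracy(sp$encoded, classify(P, "multin")), 0.45)
})

test_that("prediction is invariant to affine rescaling of predictors on noiseless data", {
  x <- seq(1, 5, length.out = 30)
  y <- 4 - 2 * x
  f1 <- fit_subset(matrix(x), y, "linear")
  f2 <- fit_subset(matrix(10 * x + 3), y, "linear")
  expect_equal(predict_linear(f1, matrix(x)),
               predict_linear(f2, matrix(10 * x + 3)), tolerance = 1e-9)
})

test_that("fitted slope sign matches the generating sign on strong logistic signal", {
  hits <- 0L
  for (s in 1:50) {
    set.seed(1000 + s)
    x <- rnorm(2000)
    y <- rbinom(2000, 1, plogis(-1 + 2 * x)) # events the rarer class
    sp <- encode_outcome(y, "binary")
    fit <- fit_subset(matrix(x), sp$encoded, "binary", L = 2L)
    # the single fitted equation is code 0 vs the event reference (code 1):
    # its slope is minus the generating slope, so the event-class logit
    # log(P(1)/P(0)) recovers the generating sign
    if (!is.null(fit) && -fit$coefficients[1, 2] > 0) hits <- hits + 1L
  }
  expect_identical(hits, 50L)
})
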