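test_that("keepX = p reduces sparse PLS to ordinary PLS regression", {
  library(mixOmics)
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20; p <- 30; q <- 2
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", 1:p)))
    Y <- matrix(rnorm(n * q), n, q)
    mine <- fit_spls(X, Y, n_components = 3, keepX = p)
    ref <- mixOmics::pls(X, Y, ncomp = 3, mode = "regression")
    expect_equal(predict(mine, X),
                 unname(predict(ref, X)$predict[, , 3]),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # VIP agrees with the independent implementation on the dense model
    expect_equal(unname(compute_vip(mine)),
                 unname(mixOmics::vip(ref)[, 3]), tolerance = 1e-8)
  }
})

test_that("first-component weight is proportional to X'y for univariate y", {
  set.seed(6)
  X <- matrix(rnorm(18 * 25), 18, 25)
  y <- rnorm(18)
  fit <- fit_spls(X, y, n_components = 1, keepX = 25)
  w <- fit$x_weights[, 1]
  ref <- drop(crossprod(scale(X), scale(y)))
  ref <- ref / sqrt(sum(ref^2))
  expect_lt(min(max(abs(w - ref)), max(abs(w + ref))), 1e-10)
})

test_that("a response equal to one predictor is found by keepX = 1", {
  set.seed(12)
  X <- matrix(rnorm(20 * 10), 20, 10,
              dimnames = list(NULL, paste0("V", 1:10)))
  y <- X[, 4]
  fit <- fit_spls(X, y, n_components = 1, keepX = 1)
  expect_equal(fit$selected_features[[1]], "V4")
  pred <- predict(fit, X)
  expect_equal(drop(pred), y, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("sparsity pattern and deflation invariants hold", {
  set.seed(13)
  X <- matrix(rnorm(24 * 40), 24, 40)
  Y <- matrix(rnorm(24 * 3), 24, 3)
  fit <- fit_spls(X, Y, n_components = 3, keepX = 7)
  expect_equal(unname(colSums(fit$x_weights != 0)), rep(7L, 3))
  expect_equal(unname(colSums(fit$x_weights^2)), rep(1, 3), tolerance = 1e-9)
  g <- crossprod(fit$x_scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
})

test_that("VIP has its closed form and exact normalization", {
  # weights (1, 0, 0) on one component: VIP = (sqrt(3), 0, 0)
  set.seed(14)
  X <- matrix(rnorm(15 * 3), 15, 3)
  y <- X[, 1]
  fit <- fit_spls(X, y, n_components = 1, keepX = 1)
  expect_equal(unname(fit$x_weights[, 1]), c(1, 0, 0))
  expect_equal(unname(fit$vip), c(sqrt(3), 0, 0))
  # mean squared VIP is exactly 1 for any fitted model
  for (keepX in c(5, 20, 40)) {
    m <- fit_spls(matrix(rnorm(20 * 40), 20, 40),
                  matrix(rnorm(20 * 2), 20, 2),
                  n_components = 2, keepX = keepX)
    expect_equal(mean(m$vip^2), 1, tolerance = 1e-8)
    expect_true(all(m$vip >= 0))
  }
})

test_that("VIP equals a brute-force evaluation of its formula", {
  set.seed(15)
  X <- matrix(rnorm(18 * 10), 18, 10)
  Y <- matrix(rnorm(18 * 2), 18, 2)
  fit <- fit_spls(X, Y, n_components = 2, keepX = 4)
  p <- 10
  ssy <- vapply(1:2, function(a) {
    sum(fit$y_loadings[, a]^2) * sum(fit$x_scores[, a]^2)
  }, numeric(1))
  brute <- vapply(seq_len(p), function(j) {
    num <- sum(vapply(1:2, function(a) {
      w <- fit$x_weights[, a]
      ssy[a] * (w[j] / sqrt(sum(w^2)))^2
    }, numeric(1)))
    sqrt(p * num / sum(ssy))
  }, numeric(1))
  expect_equal(unname(fit$vip), brute, tolerance = 1e-10)
})

test_that("discriminant fit separates linearly separable classes", {
  set.seed(16)
  X <- matrix(rnorm(20 * 8), 20, 8)
  cls <- rep(c("a", "b"), each = 10)
  X[, 3] <- ifelse(cls == "a", 5, -5) + rnorm(20, 0, 0.1)
  fit <- fit_splsda(X, cls, n_components = 1, keepX = 1)
  expect_equal(predict(fit, X, type = "class"), cls)
  expect_equal(fit$selected_features[[1]], "X3")
})

test_that("invalid sparse PLS inputs are rejected", {
  X <- matrix(rnorm(12 * 5), 12, 5)
  y <- rnorm(12)
  expect_error(fit_spls(X, y, n_components = 1, keepX = 6), "keepX")
  expect_error(fit_spls(X, y, n_components = 8, keepX = 2), "n_components")
  expect_error(fit_spls(cbind(X, 1), y, n_components = 1, keepX = 2),
               "zero-variance")
  expect_error(fit_splsda(X, rep("a", 12), 1, 1), "2 classes")
  expect_error(fit_splsda(X, c("b", rep("a", 11)), 1, 1), "at least 2 samples")
})

test_that("residual missing X entries are median-imputed with a message", {
  set.seed(17)
  X <- matrix(rnorm(20 * 10), 20, 10)
  X[sample(length(X), 10)] <- NA
  expect_message(fit <- fit_spls(X, rnorm(20), n_components = 1, keepX = 5),
                 "imputing")
  expect_false(anyNA(fit$x_scores))
})
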