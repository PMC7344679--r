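make_cls_data <- function(seed = 20, n_per = 12, p = 40, sep = 2) {
  set.seed(seed)
  cls <- rep(c("a", "b", "c"), each = n_per)
  X <- matrix(rnorm(3 * n_per * p), 3 * n_per, p)
  X[, 1] <- X[, 1] + sep * (cls == "a")
  X[, 2] <- X[, 2] + sep * (cls == "b")
  list(X = X, cls = cls)
}

test_that("the same seed reproduces the whole grid and the best pair", {
  d <- make_cls_data()
  a <- grid_search(d$X, d$cls, kind = "splsda", comp_grid = 1:2,
                   keepX_grid = c(5, 10), n_repeats = 3, seed = 42)
  b <- grid_search(d$X, d$cls, kind = "splsda", comp_grid = 1:2,
                   keepX_grid = c(5, 10), n_repeats = 3, seed = 42)
  expect_identical(a$grid, b$grid)
  expect_identical(a$best_pair, b$best_pair)
  c <- grid_search(d$X, d$cls, kind = "splsda", comp_grid = 1:2,
                   keepX_grid = c(5, 10), n_repeats = 3, seed = 43)
  expect_false(identical(a$grid$criterion, c$grid$criterion))
})

test_that("a single-point grid is its own best pair", {
  d <- make_cls_data()
  cv <- grid_search(d$X, d$cls, kind = "splsda", comp_grid = 2,
                    keepX_grid = 10, n_repeats = 2, seed = 1)
  expect_equal(unname(cv$best_pair), c(2L, 10L))
  expect_equal(nrow(cv$grid), 1L)
})

test_that("the best pair attains the criterion optimum over the grid", {
  d <- make_cls_data()
  cv <- grid_search(d$X, d$cls, kind = "splsda", comp_grid = 1:2,
                    keepX_grid = c(2, 10, 40), n_repeats = 3, seed = 2)
  best <- cv$grid$criterion[cv$grid$n_components == cv$best_pair[[1]] &
                              cv$grid$keepX == cv$best_pair[[2]]]
  expect_equal(best, min(cv$grid$criterion))
  set.seed(3)
  y <- d$X[, 1] + rnorm(nrow(d$X), 0, 0.5)
  cvq <- grid_search(d$X, y, kind = "spls", comp_grid = 1:2,
                     keepX_grid = c(2, 10), n_repeats = 3, seed = 4)
  bestq <- cvq$grid$criterion[cvq$grid$n_components == cvq$best_pair[[1]] &
                                cvq$grid$keepX == cvq$best_pair[[2]]]
  expect_equal(bestq, max(cvq$grid$criterion))
  expect_equal(cvq$criterion_kind, "q2")
  # a strongly predictive response yields a high held-out Q2
  expect_gt(bestq, 0.7)
})

test_that("keepX values above the feature count are clamped with a warning", {
  d <- make_cls_data(p = 20)
  expect_warning(
    cv <- grid_search(d$X, d$cls, kind = "splsda", comp_grid = 1,
                      keepX_grid = c(10, 1000), n_repeats = 2, seed = 5),
    "clamped")
  expect_setequal(cv$grid$keepX, c(10L, 20L))
})

test_that("fold construction is guarded", {
  d <- make_cls_data(n_per = 3)
  expect_error(grid_search(d$X, d$cls, kind = "splsda", comp_grid = 1,
                           keepX_grid = 5, n_repeats = 2, k = 5, seed = 1),
               "smallest class")
  expect_error(grid_search(d$X, d$cls, kind = "splsda", comp_grid = integer(0),
                           keepX_grid = 5, seed = 1), "empty grid")
})

test_that("separable classes reach near-zero CV error; permuted labels do not", {
  d <- make_cls_data(sep = 6)
  cv <- grid_search(d$X, d$cls, kind = "splsda", comp_grid = 2,
                    keepX_grid = c(2, 10), n_repeats = 5, seed = 6)
  expect_lt(min(cv$grid$criterion), 0.1)
  set.seed(7)
  null_cv <- grid_search(d$X, sample(d$cls), kind = "splsda", comp_grid = 1,
                         keepX_grid = 10, n_repeats = 10, seed = 8)
  # 3 balanced classes under the null: error near 2/3
  expect_lt(abs(null_cv$grid$criterion - 2 / 3), 0.15)
})
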