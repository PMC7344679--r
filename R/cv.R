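# Repeated k-fold cross-validated grid search over (n_components, keepX).
#
# For every keepX value, one model is fitted per fold at the largest
# requested component number; because sparse PLS components are nested
# (component h does not depend on later components), held-out predictions
# for every smaller component count come from the same fit, which keeps the
# full grid affordable.

# k roughly equal folds; stratified by class when `classes` is given.
make_folds <- function(n, k, classes = NULL) {
  fold <- integer(n)
  if (is.null(classes)) {
    fold <- sample(rep_len(seq_len(k), n))
  } else {
    for (cl in unique(classes)) {
      idx <- which(classes == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  }
  fold
}

#' Cross-validated hyperparameter grid search for sparse PLS (and -DA)
#'
#' Searches the grid spanned by component counts (default 1-12 for sPLS,
#' 1-3 for sPLS-DA) and the number of selected variables per component
#' (default 50, 100, 200, 300, 500, 1000). Each grid point is evaluated by
#' `n_repeats` random `k`-fold cross-validation rounds (stratified by class
#' for the discriminant variant). The criterion is the mean held-out
#' misclassification rate (sPLS-DA, minimized) or the mean held-out Q²
#' (sPLS, maximized); the optimal pair attains the criterion optimum, with
#' ties broken toward fewer components, then smaller keepX.
#'
#' @param X samples x features matrix or `feature_table`.
#' @param Y quantitative response (sPLS) or class labels (sPLS-DA).
#' @param kind `"spls"` or `"splsda"`.
#' @param comp_grid integer vector of component counts; `NULL` for the
#'   defaults above.
#' @param keepX_grid integer vector of keepX values; values above the feature
#'   count are clamped to it with a warning.
#' @param n_repeats cross-validation repeats per grid point (default 100).
#' @param k folds (default 5); for sPLS-DA, `k` must not exceed the smallest
#'   class size.
#' @param seed integer seed making folds, hence the whole search,
#'   reproducible.
#' @return a `cv_result`: `grid` (data.frame `n_components`, `keepX`,
#'   `criterion`), `criterion_kind`, `best_pair`, `n_repeats`, `k_folds`,
#'   `seed`.
#' @export
grid_search <- function(X, Y, kind = c("spls", "splsda"), comp_grid = NULL,
                        keepX_grid = c(50L, 100L, 200L, 300L, 500L, 1000L),
                        n_repeats = 100L, k = 5L, seed = 1L) {
  kind <- match.arg(kind)
  if (inherits(X, "feature_table")) X <- t(X$intensities)
  X <- as.matrix(X)
  if (anyNA(X)) {  # impute once, so every fold sees the same complete matrix
    message("imputing ", sum(is.na(X)),
            " missing X entries with per-feature medians before CV")
    for (j in which(colSums(is.na(X)) > 0L))
      X[is.na(X[, j]), j] <- stats::median(X[, j], na.rm = TRUE)
  }
  n <- nrow(X); p <- ncol(X)
  if (is.null(comp_grid)) comp_grid <- if (kind == "spls") 1:12 else 1:3
  comp_grid <- sort(unique(as.integer(comp_grid)))
  if (!length(comp_grid) || !length(keepX_grid)) stop("empty grid")
  if (any(keepX_grid > p)) {
    warning("keepX values above n_features (", p, ") clamped")
    keepX_grid <- pmin(as.integer(keepX_grid), p)
  }
  keepX_grid <- sort(unique(as.integer(keepX_grid)))
  classes <- NULL
  if (kind == "splsda") {
    classes <- factor(Y)
    if (k > min(table(classes)))
      stop("k exceeds the smallest class size (", min(table(classes)), ")")
  } else {
    Y <- as.matrix(Y)
  }
  hmax <- max(comp_grid)
  # n_train = n - largest fold; components must fit in every training split
  if (hmax > min(n - ceiling(n / k) - 1L, p))
    stop("comp_grid exceeds what the training folds can support")
  set.seed(seed)
  acc <- array(0, dim = c(length(comp_grid), length(keepX_grid), n_repeats))
  for (r in seq_len(n_repeats)) {
    fold <- make_folds(n, k, classes)
    err <- matrix(0, length(comp_grid), length(keepX_grid))
    press <- matrix(0, length(comp_grid), length(keepX_grid))
    tss <- matrix(0, length(comp_grid), length(keepX_grid))
    for (f in seq_len(k)) {
      test <- fold == f
      Xtr <- X[!test, , drop = FALSE]; Xte <- X[test, , drop = FALSE]
      for (j in seq_along(keepX_grid)) {
        if (kind == "splsda") {
          fit <- fit_splsda(Xtr, classes[!test], n_components = hmax,
                            keepX = keepX_grid[j])
          for (i in seq_along(comp_grid)) {
            pred <- predict(fit, Xte, n_components = comp_grid[i],
                            type = "class")
            err[i, j] <- err[i, j] + sum(pred != as.character(classes[test]))
          }
        } else {
          Ytr <- Y[!test, , drop = FALSE]; Yte <- Y[test, , drop = FALSE]
          fit <- fit_spls(Xtr, Ytr, n_components = hmax, keepX = keepX_grid[j])
          base <- matrix(colMeans(Ytr), nrow(Yte), ncol(Y), byrow = TRUE)
          for (i in seq_along(comp_grid)) {
            pred <- predict(fit, Xte, n_components = comp_grid[i])
            press[i, j] <- press[i, j] + sum((Yte - pred)^2)
            tss[i, j] <- tss[i, j] + sum((Yte - base)^2)
          }
        }
      }
    }
    acc[, , r] <- if (kind == "splsda") err / n else 1 - press / tss
  }
  grid_mean <- apply(acc, c(1, 2), mean)
  grid <- expand.grid(n_components = comp_grid, keepX = keepX_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$criterion <- as.vector(grid_mean)
  best_idx <- if (kind == "splsda") which.min(grid$criterion)
              else which.max(grid$criterion)
  structure(list(
    grid = grid,
    criterion_kind = if (kind == "splsda") "classification_error" else "q2",
    best_pair = c(n_components = grid$n_components[best_idx],
                  keepX = grid$keepX[best_idx]),
    n_repeats = n_repeats, k_folds = k, seed = seed),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result (%s): best n_components = %d, keepX = %d (%s = %.4f)\n",
              x$criterion_kind, x$best_pair[["n_components"]],
              x$best_pair[["keepX"]],
              x$criterion_kind,
              x$grid$criterion[x$grid$n_components == x$best_pair[["n_components"]] &
                                 x$grid$keepX == x$best_pair[["keepX"]]]))
  cat(sprintf("  grid: %d points, %d repeats of %d-fold CV, seed %d\n",
              nrow(x$grid), x$n_repeats, x$k_folds, x$seed))
  invisible(x)
}
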