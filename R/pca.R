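#' Principal component analysis by NIPALS, tolerant of missing values
#'
#' Unsupervised overview of a processed feature table. Observations are
#' samples, variables are features; variables are mean-centered and scaled to
#' unit variance over their observed entries. Components are extracted one at
#' a time by the NIPALS algorithm, with each regression step restricted to
#' observed entries, so moderate missingness (up to the 30% surviving the
#' missingness filter) is handled without imputation. On complete data the
#' result coincides with the singular value decomposition of the scaled
#' matrix (up to column signs).
#'
#' Per-component explained variance is the drop in residual sum of squares
#' over observed entries, as a fraction of the total sum of squares of the
#' scaled data. The sign of each component is fixed so that its
#' largest-magnitude loading is positive, and the starting score vector is
#' the column of maximal variance, making runs reproducible.
#'
#' @param x a `feature_table` (features x samples; transposed internally) or
#'   a numeric samples x variables matrix with optional `NA`s.
#' @param n_components number of components (default 5); must not exceed
#'   `min(n_samples - 1, n_variables)`.
#' @param center mean-center variables (default `TRUE`).
#' @param scale scale variables to unit variance (default `TRUE`); a
#'   zero-variance variable is an error.
#' @param tol convergence tolerance on the relative score change
#'   (default 1e-13; tight enough for near-degenerate components).
#' @param max_iter maximum NIPALS iterations per component (default 20000;
#'   generous because components with close variances converge slowly).
#' @return a `pca_result`: `scores` (samples x components), `loadings`
#'   (variables x components, unit norm), `r2_per_component`,
#'   `n_components`, `scaling`, `centering`.
#' @export
fit_pca <- function(x, n_components = 5L, center = TRUE, scale = TRUE,
                    tol = 1e-13, max_iter = 20000L) {
  X <- if (inherits(x, "feature_table")) t(x$intensities) else as.matrix(x)
  n <- nrow(X); p <- ncol(X)
  kmax <- min(if (center) n - 1L else n, p)
  if (n_components > kmax)
    stop("n_components must not exceed min(n_samples - 1, n_features) = ", kmax)
  obs <- !is.na(X)
  if (any(colSums(obs) < 2L)) stop("a variable has fewer than 2 observed values")
  mu <- if (center) colMeans(X, na.rm = TRUE) else rep(0, p)
  sdv <- if (scale) apply(X, 2L, stats::sd, na.rm = TRUE) else rep(1, p)
  if (scale && any(sdv == 0))
    stop("zero-variance variable cannot be unit-scaled: ",
         colnames(X)[which(sdv == 0)[1L]])
  Xs <- sweep(sweep(X, 2L, mu, "-"), 2L, sdv, "/")
  X0 <- Xs; X0[!obs] <- 0            # zero-filled copy; obs masks the holes
  W <- obs * 1
  tss <- sum(X0^2)
  scores <- matrix(0, n, n_components)
  loadings <- matrix(0, p, n_components)
  r2 <- numeric(n_components)
  ss_prev <- tss
  for (a in seq_len(n_components)) {
    t_vec <- X0[, which.max(apply(X0, 2L, stats::var))]
    for (it in seq_len(max_iter)) {
      pl <- drop(crossprod(X0, t_vec)) / drop(crossprod(W, t_vec^2))
      pl <- pl / sqrt(sum(pl^2))
      t_new <- drop(X0 %*% pl) / drop(W %*% pl^2)
      if (sqrt(sum((t_new - t_vec)^2)) < tol * sqrt(sum(t_new^2))) {
        t_vec <- t_new
        break
      }
      t_vec <- t_new
    }
    if (pl[which.max(abs(pl))] < 0) { pl <- -pl; t_vec <- -t_vec }
    X0 <- X0 - (t_vec %*% t(pl)) * W
    ss <- sum(X0^2)
    r2[a] <- (ss_prev - ss) / tss
    ss_prev <- ss
    scores[, a] <- t_vec
    loadings[, a] <- pl
  }
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(n_components)))
  dimnames(loadings) <- list(colnames(X), colnames(scores))
  structure(list(scores = scores, loadings = loadings,
                 r2_per_component = r2, n_components = n_components,
                 scaling = if (scale) "unit_variance" else "none",
                 centering = center, center = mu, scale = sdv),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d components over %d samples x %d variables\n",
              x$n_components, nrow(x$scores), nrow(x$loadings)))
  cat("  R2 per component:",
      paste(sprintf("%.3f", x$r2_per_component), collapse = " "), "\n")
  invisible(x)
}
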