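# Sparse partial least squares (regression mode) with soft-thresholded
# X-weights, its discriminant-analysis variant, VIP coefficients, and
# repeated cross-validated grid search over (components, keepX).

# Soft-threshold a weight vector so that exactly `keep` entries are nonzero.
# The threshold is the (keep+1)-th largest |u|; ties at the boundary are
# broken by feature order (lowest index kept) and kept entries are bumped to
# a sign-preserving epsilon if shrinkage would zero them exactly.
soft_keep <- function(u, keep) {
  p <- length(u)
  if (keep >= p) return(u)
  ord <- order(-abs(u), seq_len(p))
  sel <- ord[seq_len(keep)]
  lambda <- abs(u[ord[keep + 1L]])
  shr <- abs(u[sel]) - lambda
  shr <- pmax(shr, .Machine$double.eps * max(abs(u)))
  out <- numeric(p)
  out[sel] <- sign(u[sel]) * shr
  out
}

center_scale <- function(M, what) {
  mu <- colMeans(M)
  sdv <- apply(M, 2L, stats::sd)
  if (any(sdv == 0))
    stop("zero-variance column in ", what, ": ",
         paste(utils::head(colnames(M)[sdv == 0], 3L), collapse = ", "))
  list(x = sweep(sweep(M, 2L, mu, "-"), 2L, sdv, "/"), center = mu, scale = sdv)
}

#' Fit a sparse PLS regression model
#'
#' Sparse partial least squares in regression mode: predictors (metabolite
#' intensities) and responses are column-centered and unit-variance scaled;
#' for each component the dominant singular pair of the current
#' cross-covariance matrix \eqn{X_d^T Y_d} is found iteratively, the X-weight
#' is soft-thresholded so that exactly `keepX` entries are nonzero, and both
#' \eqn{X_d} and \eqn{Y_d} are deflated on the X-score (regression-mode
#' deflation). The VIP coefficient vector is computed on the fitted model.
#'
#' Residual missing values in `X` (the preprocessing chain tolerates up to
#' 30% missingness per feature) are imputed with the per-feature median
#' before fitting, with a message.
#'
#' @param X samples x features numeric matrix, or a `feature_table`
#'   (transposed internally).
#' @param Y numeric response vector or samples x responses matrix
#'   (e.g. one sensory attribute).
#' @param n_components number of latent components; must not exceed
#'   `min(n_samples - 1, n_features)`.
#' @param keepX number of features retained per component; a scalar (applied
#'   to every component, the default grid semantics) or a vector of length
#'   `n_components`. Must be `<= n_features`.
#' @param scale unit-variance scale X and Y (default `TRUE`).
#' @param tol,max_iter convergence control of the per-component iteration.
#' @return an `spls_model` with `x_weights` (features x components, unit
#'   norm, `keepX` nonzeros per column), `x_scores`, `x_loadings`,
#'   `y_loadings`, `selected_features` (per-component id lists), `vip`, and
#'   the centering/scaling parameters used.
#' @export
fit_spls <- function(X, Y, n_components = 2L, keepX = NULL, scale = TRUE,
                     tol = 1e-9, max_iter = 500L) {
  if (inherits(X, "feature_table")) X <- t(X$intensities)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("Y", seq_len(ncol(Y)))
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y disagree on sample count")
  if (n < 2L) stop("at least 2 samples required")
  if (any(!is.finite(Y))) stop("Y must be finite")
  if (is.null(keepX)) keepX <- p
  keepX <- as.integer(round(keepX))
  if (length(keepX) == 1L) keepX <- rep(keepX, n_components)
  if (length(keepX) != n_components)
    stop("keepX must be scalar or of length n_components")
  if (any(keepX < 1L) || any(keepX > p))
    stop("keepX must be between 1 and n_features (", p, ")")
  if (n_components > min(n - 1L, p))
    stop("n_components exceeds min(n_samples - 1, n_features)")
  x_impute <- apply(X, 2L, stats::median, na.rm = TRUE)
  if (anyNA(X)) {
    message("imputing ", sum(is.na(X)),
            " missing X entries with per-feature medians")
    if (any(!is.finite(x_impute)))
      stop("feature ", colnames(X)[which(!is.finite(x_impute))[1L]],
           " is entirely missing")
    for (j in which(colSums(is.na(X)) > 0L))
      X[is.na(X[, j]), j] <- x_impute[j]
  }
  xs <- if (scale) center_scale(X, "X") else
    list(x = scale(X, scale = FALSE), center = colMeans(X), scale = rep(1, p))
  ys <- if (scale) center_scale(Y, "Y") else
    list(x = scale(Y, scale = FALSE), center = colMeans(Y), scale = rep(1, q))
  Xd <- xs$x; Yd <- ys$x
  W <- matrix(0, p, n_components, dimnames = list(colnames(X), NULL))
  Tm <- matrix(0, n, n_components, dimnames = list(rownames(X), NULL))
  P <- matrix(0, p, n_components, dimnames = list(colnames(X), NULL))
  Q <- matrix(0, q, n_components, dimnames = list(colnames(Y), NULL))
  tt <- numeric(n_components)
  selected <- vector("list", n_components)
  for (a in seq_len(n_components)) {
    M <- crossprod(Xd, Yd)
    if (max(abs(M)) < 1e-12)
      stop("X has no remaining covariance with Y at component ", a,
           " (rank exceeded)")
    if (q == 1L) {
      u <- soft_keep(drop(M), keepX[a])
      u <- u / sqrt(sum(u^2))
    } else {
      sv <- svd(M, nu = 0L, nv = 1L)
      v <- sv$v[, 1L]
      u <- numeric(p)
      for (it in seq_len(max_iter)) {
        u_new <- soft_keep(drop(M %*% v), keepX[a])
        u_new <- u_new / sqrt(sum(u_new^2))
        v <- drop(crossprod(M, u_new))
        v <- v / sqrt(sum(v^2))
        if (sqrt(sum((u_new - u)^2)) < tol) { u <- u_new; break }
        u <- u_new
      }
    }
    imax <- which.max(abs(u))
    if (u[imax] < 0) u <- -u
    t_vec <- drop(Xd %*% u)
    ss_t <- sum(t_vec^2)
    if (ss_t < 1e-12) stop("degenerate score at component ", a)
    c_vec <- drop(crossprod(Xd, t_vec)) / ss_t
    d_vec <- drop(crossprod(Yd, t_vec)) / ss_t
    Xd <- Xd - tcrossprod(t_vec, c_vec)
    Yd <- Yd - tcrossprod(t_vec, d_vec)
    W[, a] <- u; Tm[, a] <- t_vec; P[, a] <- c_vec; Q[, a] <- d_vec
    tt[a] <- ss_t
    selected[[a]] <- colnames(X)[u != 0]
  }
  model <- structure(list(
    x_weights = W, x_scores = Tm, x_loadings = P, y_loadings = Q,
    selected_features = selected, keepX = keepX,
    n_components = n_components, mode = "regression",
    score_ss = tt,
    x_impute = x_impute,
    x_center = xs$center, x_scale = xs$scale,
    y_center = ys$center, y_scale = ys$scale,
    feature_ids = colnames(X), response_names = colnames(Y)),
    class = "spls_model")
  model$vip <- compute_vip(model)
  model
}

#' @export
print.spls_model <- function(x, ...) {
  cat(sprintf("spls_model (%s): %d component(s), keepX = %s, %d features\n",
              if (is.null(x$classes)) "regression" else "discriminant",
              x$n_components, paste(x$keepX, collapse = "/"),
              length(x$feature_ids)))
  invisible(x)
}

#' Predict from a sparse PLS model
#'
#' @param object an `spls_model` (or `splsda_model`).
#' @param newdata samples x features matrix over the training feature set.
#' @param n_components number of components to use (default: all fitted;
#'   models are nested, so fewer components reproduce the smaller model).
#' @param type for discriminant models, `"class"` (default) returns predicted
#'   class labels by the maximum predicted class indicator; `"response"`
#'   returns the numeric predictions.
#' @param ... unused.
#' @return numeric matrix samples x responses, or a character vector of
#'   classes.
#' @export
predict.spls_model <- function(object, newdata, n_components = NULL,
                               type = c("class", "response"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_table")) newdata <- t(newdata$intensities)
  newdata <- as.matrix(newdata)
  if (anyNA(newdata)) {   # training per-feature medians fill residual holes
    for (j in which(colSums(is.na(newdata)) > 0L))
      newdata[is.na(newdata[, j]), j] <- object$x_impute[j]
  }
  h <- if (is.null(n_components)) object$n_components else as.integer(n_components)
  if (h < 1L || h > object$n_components) stop("invalid n_components")
  Xs <- sweep(sweep(newdata, 2L, object$x_center, "-"), 2L, object$x_scale, "/")
  W <- object$x_weights[, seq_len(h), drop = FALSE]
  P <- object$x_loadings[, seq_len(h), drop = FALSE]
  Q <- object$y_loadings[, seq_len(h), drop = FALSE]
  B <- W %*% solve(crossprod(P, W), t(Q))
  pred <- Xs %*% B
  pred <- sweep(sweep(pred, 2L, object$y_scale, "*"), 2L, object$y_center, "+")
  colnames(pred) <- object$response_names
  if (!is.null(object$classes) && type == "class") {
    object$classes[max.col(pred, ties.method = "first")]
  } else pred
}

#' Fit a sparse PLS discriminant model
#'
#' Encodes the class labels (e.g. season or grape cluster type) as a
#' one-column-per-class indicator matrix and fits [fit_spls()] on it.
#' Prediction assigns the class with the largest predicted indicator value.
#'
#' @param X samples x features matrix or `feature_table`.
#' @param classes factor or character vector of class labels, one per sample;
#'   at least 2 classes with at least 2 samples each.
#' @inheritParams fit_spls
#' @return an `spls_model` that also carries `classes` (the class levels).
#' @export
fit_splsda <- function(X, classes, n_components = 2L, keepX = NULL,
                       scale = TRUE, tol = 1e-9, max_iter = 500L) {
  classes <- factor(classes)
  counts <- table(classes)
  if (nlevels(classes) < 2L) stop("at least 2 classes required")
  if (any(counts < 2L))
    stop("every class needs at least 2 samples; short: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  Y <- stats::model.matrix(~ classes - 1)
  colnames(Y) <- levels(classes)
  model <- fit_spls(X, Y, n_components = n_components, keepX = keepX,
                    scale = scale, tol = tol, max_iter = max_iter)
  model$classes <- levels(classes)
  model
}

#' Variable importance in projection
#'
#' The VIP coefficient of feature j over A components is
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{aj}/\|w_a\|)^2 / \sum_a SSY_a}}
#' where p is the number of features, \eqn{w_a} the component-a X-weights and
#' \eqn{SSY_a = \|q_a\|^2 t_a^T t_a} the response sum of squares explained by
#' component a. The mean of the squared VIPs over features is exactly 1, so
#' VIP > 1 flags features of above-average importance.
#'
#' @param model a fitted `spls_model`.
#' @return named numeric vector of nonnegative VIP coefficients, one per
#'   feature.
#' @export
compute_vip <- function(model) {
  if (!inherits(model, "spls_model")) stop("compute_vip needs a fitted spls_model")
  W <- model$x_weights
  wn <- sqrt(colSums(W^2))
  ssy <- colSums(model$y_loadings^2) * model$score_ss
  vip <- sqrt(nrow(W) * drop(sweep(W, 2L, wn, "/")^2 %*% ssy) / sum(ssy))
  stats::setNames(vip, model$feature_ids)
}
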