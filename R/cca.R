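# Canonical correlation analysis, classical and ridge-regularized.

# Symmetric inverse square root of a covariance matrix; errors when the
# smallest eigenvalue is at or below tol (singular covariance).
inv_sqrt <- function(s, tol = 1e-10, context = "covariance") {
  e <- eigen(s, symmetric = TRUE)
  if (any(e$values <= tol * max(abs(e$values), 1))) {
    stop(sprintf("singular %s matrix; use rcca() with positive penalties",
                 context), call. = FALSE)
  }
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

cca_engine <- function(x, y, lambda1, lambda2, n_dims) {
  x <- as_numeric_matrix(x, "x")
  y <- as_numeric_matrix(y, "y")
  if (nrow(x) != nrow(y)) stop("x and y must have the same rows",
                               call. = FALSE)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  xc <- center_cols(x)
  yc <- center_cols(y)
  sxx <- crossprod(xc) / (n - 1) + diag(lambda1, ncol(x))
  syy <- crossprod(yc) / (n - 1) + diag(lambda2, ncol(y))
  sxy <- crossprod(xc, yc) / (n - 1)
  wx <- inv_sqrt(sxx, context = "X covariance")
  wy <- inv_sqrt(syy, context = "Y covariance")
  k <- wx %*% sxy %*% wy
  sv <- svd(k)
  d_max <- min(ncol(x), ncol(y))
  if (n_dims > d_max) {
    stop(sprintf("n_dims must be <= min(p, q) = %d", d_max), call. = FALSE)
  }
  a <- wx %*% sv$u[, seq_len(n_dims), drop = FALSE]
  b <- wy %*% sv$v[, seq_len(n_dims), drop = FALSE]
  a <- apply(a, 2L, l2_normalize)
  b <- apply(b, 2L, l2_normalize)
  a <- matrix(a, ncol = n_dims)
  b <- matrix(b, ncol = n_dims)
  # deterministic orientation: largest-|a| entry positive, then b oriented so
  # the training score correlation is non-negative
  for (d in seq_len(n_dims)) {
    if (a[which.max(abs(a[, d])), d] < 0) a[, d] <- -a[, d]
    if (stats::cor(xc %*% a[, d], yc %*% b[, d]) < 0) b[, d] <- -b[, d]
  }
  xs <- xc %*% a
  ys <- yc %*% b
  rho <- vapply(seq_len(n_dims),
                function(d) stats::cor(xs[, d], ys[, d]), numeric(1))
  rho <- pmin(pmax(rho, 0), 1)
  dimnames(a) <- list(colnames(x), paste0("dim", seq_len(n_dims)))
  dimnames(b) <- list(colnames(y), paste0("dim", seq_len(n_dims)))
  structure(list(canonical_correlations = rho,
                 x_weights = a, y_weights = b,
                 x_scores = xs, y_scores = ys,
                 lambda1 = lambda1, lambda2 = lambda2,
                 x_center = colMeans(x), y_center = colMeans(y),
                 x = x, y = y, n_dims = n_dims),
            class = "cca_model")
}

#' Classical canonical correlation analysis
#'
#' Extracts pairs of unit-norm weight vectors whose scores (linear combinations
#' of the X and Y columns) have maximal correlation, solving the classical
#' generalized eigenproblem via whitened cross-covariance SVD. Requires more
#' samples than total features and nonsingular covariance matrices; for
#' high-dimensional data use [rcca()].
#'
#' @param x,y numeric matrices with the same rows (samples).
#' @param n_dims number of canonical dimensions (<= `min(ncol(x), ncol(y))`).
#' @return An object of class `cca_model` with `canonical_correlations`
#'   (training correlations of paired scores, non-increasing), `x_weights`,
#'   `y_weights` (unit norm), and `x_scores`, `y_scores`.
#' @export
cca <- function(x, y, n_dims = min(ncol(x), ncol(y))) {
  if (nrow(as_numeric_matrix(x, "x")) <= ncol(x) + ncol(y)) {
    stop("classical CCA needs n > p + q; use rcca() instead", call. = FALSE)
  }
  cca_engine(x, y, 0, 0, n_dims)
}

#' Regularized canonical correlation analysis
#'
#' CCA with ridge penalties added to the two block covariance matrices,
#' well-defined when features outnumber samples. With both penalties at zero
#' (and nonsingular covariances) it reduces to [cca()]; as the penalties grow
#' the weight directions converge to the singular vectors of the
#' cross-covariance matrix (the PLS limit).
#'
#' @param x,y numeric matrices with the same rows.
#' @param lambda1,lambda2 non-negative ridge penalties added to the diagonals
#'   of Cov(X) and Cov(Y).
#' @param n_dims number of canonical dimensions.
#' @return An object of class `cca_model`; see [cca()].
#' @examples
#' x <- matrix(rnorm(200), 20)  # n = 20 < p = 10
#' y <- matrix(rnorm(100), 20)
#' rcca(x, y, 0.1, 0.1, n_dims = 2)$canonical_correlations
#' @export
rcca <- function(x, y, lambda1, lambda2, n_dims = min(ncol(x), ncol(y))) {
  if (lambda1 < 0 || lambda2 < 0) stop("penalties must be >= 0",
                                       call. = FALSE)
  cca_engine(x, y, lambda1, lambda2, n_dims)
}

#' @export
print.cca_model <- function(x, ...) {
  reg <- x$lambda1 > 0 || x$lambda2 > 0
  cat(sprintf("%s canonical correlation analysis (%d dimension%s)\n",
              if (reg) "Regularized" else "Classical", x$n_dims,
              if (x$n_dims > 1) "s" else ""))
  if (reg) cat(sprintf("  penalties: lambda1 = %g, lambda2 = %g\n",
                       x$lambda1, x$lambda2))
  cat("  canonical correlations:",
      paste(sprintf("%.4f", x$canonical_correlations), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.cca_model <- function(object, ...) {
  print(object)
  cat("  top X weights (dim 1):\n")
  w <- sort(abs(object$x_weights[, 1]), decreasing = TRUE)
  print(round(utils::head(w, 5), 4))
  invisible(object)
}

#' Tune the ridge penalties of regularized CCA by cross-validation
#'
#' Grid search over penalty pairs, scoring each by the cross-validated first
#' canonical correlation: per fold the model is fitted on the training
#' samples and the held-out samples are projected on the first weight pair;
#' the score is the correlation of the held-out score pairs averaged over
#' folds. Ties are broken towards the smallest `lambda1 + lambda2`.
#'
#' @param x,y numeric matrices with the same rows.
#' @param lambda_grid numeric vector of candidate penalties (used for both
#'   blocks), or a two-column matrix/data frame of (lambda1, lambda2) pairs.
#' @param folds number of cross-validation folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @return list with `lambda1`, `lambda2`, and `surface` (a data frame of
#'   grid points and their CV scores).
#' @export
tune_rcc <- function(x, y, lambda_grid = 10^seq(-4, 0, length.out = 5),
                     folds = 5, seed = 1L) {
  x <- as_numeric_matrix(x, "x")
  y <- as_numeric_matrix(y, "y")
  if (is.null(dim(lambda_grid))) {
    if (!length(lambda_grid)) stop("empty penalty grid", call. = FALSE)
    grid <- expand.grid(lambda1 = lambda_grid, lambda2 = lambda_grid)
  } else {
    grid <- as.data.frame(lambda_grid)
    names(grid) <- c("lambda1", "lambda2")
  }
  stop_if_not_count(folds, "folds", min = 2L)
  n <- nrow(x)
  if (floor(n / folds) < 3L) {
    stop("each fold needs at least 3 samples; reduce `folds`", call. = FALSE)
  }
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  score_one <- function(l1, l2) {
    cors <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- rcca(x[tr, , drop = FALSE], y[tr, , drop = FALSE], l1, l2,
                  n_dims = 1)
      xs <- sweep(x[!tr, , drop = FALSE], 2L, fit$x_center, "-") %*%
        fit$x_weights[, 1]
      ys <- sweep(y[!tr, , drop = FALSE], 2L, fit$y_center, "-") %*%
        fit$y_weights[, 1]
      if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(0)
      stats::cor(xs, ys)[1, 1]
    }, numeric(1))
    mean(cors)
  }
  grid$score <- mapply(score_one, grid$lambda1, grid$lambda2)
  best <- which(grid$score == max(grid$score))
  if (length(best) > 1L) {
    best <- best[which.min(grid$lambda1[best] + grid$lambda2[best])]
  }
  list(lambda1 = grid$lambda1[best], lambda2 = grid$lambda2[best],
       surface = grid)
}

#' Feature-feature similarity matrix from a fitted CCA model
#'
#' The association between X feature j and Y feature k displayed on
#' cross-correlation heatmaps: the sum over the first `n_dims` dimensions of
#' the product of each feature's correlation with the consensus score of that
#' dimension (the average of the paired X and Y scores).
#'
#' @param model a fitted `cca_model`.
#' @param n_dims number of dimensions to accumulate (>= 1, <= fitted).
#' @return X-features x Y-features matrix with entries in `[-1, 1]`.
#' @export
similarity_matrix <- function(model, n_dims = model$n_dims) {
  if (!inherits(model, "cca_model")) stop("`model` must be a cca_model",
                                          call. = FALSE)
  if (!is.numeric(n_dims) || length(n_dims) != 1L || n_dims < 1L) {
    stop("`n_dims` must be a positive count", call. = FALSE)
  }
  if (n_dims > model$n_dims) stop("n_dims exceeds fitted dimensions",
                                  call. = FALSE)
  dims <- seq_len(n_dims)
  m <- (model$x_scores[, dims, drop = FALSE] +
          model$y_scores[, dims, drop = FALSE]) / 2
  cx <- stats::cor(model$x, m)
  cy <- stats::cor(model$y, m)
  cx %*% t(cy)
}
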