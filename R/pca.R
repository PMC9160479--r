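#' Principal component analysis
#'
#' Singular-value decomposition of the column-centered (and optionally
#' standardized) data matrix. Loadings are the leading right singular
#' vectors; each loading vector is oriented so its largest-magnitude entry is
#' positive, making runs bit-reproducible.
#'
#' @param x numeric matrix (observations x features), at least 2 rows.
#' @param scale standardize columns to unit variance first (zero-variance
#'   columns are dropped, see [scale_columns()]).
#' @param n_components number of components to retain; default
#'   `min(nrow - 1, ncol)`.
#' @return An object of class `pca_model` with elements `loadings`
#'   (features x components, orthonormal), `scores` (observations x
#'   components, column means 0), `sdev`, `explained_variance_ratio`
#'   (computed over the full spectrum, so ratios of a truncated model sum to
#'   less than 1), `center`, and `scaled`.
#' @examples
#' fit <- pca(matrix(rnorm(40), 10, 4))
#' fit$explained_variance_ratio
#' @export
pca <- function(x, scale = FALSE, n_components = NULL) {
  x <- as_numeric_matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows", call. = FALSE)
  if (scale) x <- scale_columns(x)
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr, "-")
  k_max <- min(nrow(x) - 1L, ncol(x))
  if (is.null(n_components)) n_components <- k_max
  stop_if_not_count(n_components, "n_components", min = 1L)
  if (n_components > k_max) {
    stop(sprintf("n_components must be <= min(nrow - 1, ncol) = %d", k_max),
         call. = FALSE)
  }
  sv <- svd(xc)
  d <- sv$d
  evr_all <- d^2 / sum(d^2)
  k <- n_components
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  flip <- apply(loadings, 2L, function(v) if (v[which.max(abs(v))] < 0) -1 else 1)
  loadings <- sweep(loadings, 2L, flip, "*")
  scores <- xc %*% loadings
  rownames(loadings) <- colnames(x)
  rownames(scores) <- rownames(x)
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(loadings = loadings, scores = scores,
                 sdev = d[seq_len(k)] / sqrt(max(nrow(x) - 1L, 1L)),
                 explained_variance_ratio = evr_all[seq_len(k)],
                 center = ctr, scaled = scale),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA: %d components over %d features\n",
              ncol(x$loadings), nrow(x$loadings)))
  cat("  explained variance ratio:",
      paste(sprintf("%.3f", x$explained_variance_ratio), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.pca_model <- function(object, ...) {
  tab <- rbind(`Std. deviation` = object$sdev,
               `Variance ratio` = object$explained_variance_ratio,
               `Cumulative ratio` = cumsum(object$explained_variance_ratio))
  colnames(tab) <- colnames(object$loadings)
  cat("Principal component analysis\n")
  print(round(tab, 4))
  invisible(tab)
}

#' @export
predict.pca_model <- function(object, newdata, ...) {
  newdata <- as_numeric_matrix(newdata, "newdata")
  sweep(newdata, 2L, object$center, "-") %*% object$loadings
}
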