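# Sparse multiblock partial least squares and its discriminant variant.

#' Sparse top-k selection of a weight vector
#'
#' The sparsity operator used on every block weight update: entries outside
#' the `keep` largest absolute values are zeroed, the survivors are
#' soft-thresholded by the largest excluded absolute value
#' (`sign(v) * (|v| - tau)+`), and the result is L2-normalized. Ties at the
#' selection boundary are broken towards the lowest feature index. When every
#' surviving entry is thresholded exactly to zero (all survivors tied with
#' the threshold), the survivors keep their original magnitudes before
#' normalization so the direction remains defined.
#'
#' @param v numeric vector.
#' @param keep number of entries to retain (>= 1). Values larger than
#'   `length(v)` are truncated with a warning (dense limit, no thresholding).
#' @return unit-norm vector with at most `keep` nonzeros.
#' @examples
#' soft_select(c(3, -1, 2), keep = 2)
#' @export
soft_select <- function(v, keep) {
  if (!is.numeric(v) || !length(v)) stop("`v` must be a numeric vector",
                                         call. = FALSE)
  stop_if_not_count(keep, "keep", min = 1L)
  p <- length(v)
  if (keep > p) {
    warning("`keep` exceeds length(v); keeping all entries")
    keep <- p
  }
  ord <- order(-abs(v), seq_along(v))
  sel <- ord[seq_len(keep)]
  tau <- if (keep < p) abs(v[ord[keep + 1L]]) else 0
  out <- numeric(p)
  shrunk <- pmax(abs(v[sel]) - tau, 0)
  if (all(shrunk == 0)) shrunk <- abs(v[sel])  # boundary ties: keep direction
  out[sel] <- sign(v[sel]) * shrunk
  l2_normalize(out)
}

default_design <- function(n_blocks, block_block = 0.1, y_weight = 1) {
  d <- matrix(block_block, n_blocks + 1L, n_blocks + 1L)
  diag(d) <- 0
  d[n_blocks + 1L, seq_len(n_blocks)] <- y_weight
  d[seq_len(n_blocks), n_blocks + 1L] <- y_weight
  d
}

check_design <- function(design, n_blocks) {
  if (is.null(design)) return(default_design(n_blocks))
  design <- as_numeric_matrix(design, "design")
  if (nrow(design) != n_blocks + 1L || ncol(design) != n_blocks + 1L) {
    stop(sprintf("`design` must be %d x %d (blocks + outcome)",
                 n_blocks + 1L, n_blocks + 1L), call. = FALSE)
  }
  if (any(design < 0) || any(abs(design - t(design)) > 1e-12)) {
    stop("`design` must be symmetric and non-negative", call. = FALSE)
  }
  design
}

# Deterministic initial score for a matrix: leading left singular direction,
# oriented by the sign convention on the corresponding right vector.
init_score <- function(m) {
  sv <- svd(m, nu = 1L, nv = 1L)
  v <- sign_fix(sv$v[, 1])
  m %*% v
}

#' Sparse multiblock partial least squares (regression mode)
#'
#' Joint latent-component decomposition of several feature blocks against an
#' outcome matrix. Per component, each block's weight vector is iteratively
#' updated as the [soft_select()] of the design-weighted sum of covariances
#' between the block and the current scores of the connected blocks (the
#' outcome is carried as an extra, densely weighted block), until the scores
#' stabilize. Blocks are then deflated on their own scores and the outcome on
#' its regression onto the consensus score (the average of the block scores),
#' and the next component is extracted.
#'
#' All block and outcome columns are centered internally; inputs are expected
#' on a common scale (see [scale_columns()]).
#'
#' @param blocks named list of numeric matrices with identical rows
#'   (substances).
#' @param y outcome matrix (or vector) with the same rows.
#' @param keepX integer vector (recycled over blocks): maximum nonzero
#'   weights per block and component.
#' @param n_comp number of components.
#' @param design optional `(B+1) x (B+1)` symmetric non-negative connection
#'   matrix over the blocks plus outcome (outcome last). Default: outcome
#'   connected to every block with weight 1, block-block weight 0.1.
#' @param tol convergence tolerance on the L2 change of any block score
#'   between successive iterations.
#' @param max_iter maximum inner iterations per component; non-convergence is
#'   an error (of class `adjuscreen_no_convergence`) carrying the last
#'   iterate in its `model` field.
#' @return An object of class `block_spls`: weights, scores, selected
#'   features per block and component, outcome weights and scores, the design
#'   matrix, and convergence information. Weight vectors have unit norm and
#'   at most `keepX` nonzeros; all scores are centered.
#' @export
block_spls <- function(blocks, y, keepX, n_comp = 1, design = NULL,
                       tol = 1e-6, max_iter = 500) {
  if (!is.list(blocks) || !length(blocks)) {
    stop("`blocks` must be a non-empty list of matrices", call. = FALSE)
  }
  bn <- names(blocks)
  blocks <- lapply(seq_along(blocks), function(i)
    as_numeric_matrix(blocks[[i]], paste0("blocks[[", i, "]]")))
  names(blocks) <- bn
  nb <- length(blocks)
  if (is.null(names(blocks)) || any(!nzchar(names(blocks)))) {
    names(blocks) <- paste0("block", seq_len(nb))
  }
  if (is.vector(y)) y <- matrix(y, ncol = 1L, dimnames = list(NULL, "y"))
  y <- as_numeric_matrix(y, "y")
  n <- nrow(y)
  if (any(vapply(blocks, nrow, 1L) != n)) {
    stop("all blocks and y must have the same number of rows", call. = FALSE)
  }
  keepX <- rep_len(as.integer(keepX), nb)
  p <- vapply(blocks, ncol, 1L)
  if (any(keepX < 1L) || any(keepX > p)) {
    stop("each keepX must be in 1..ncol(block)", call. = FALSE)
  }
  stop_if_not_count(n_comp, "n_comp", min = 1L)
  design <- check_design(design, nb)

  xb <- lapply(blocks, center_cols)
  yc <- center_cols(y)
  w <- lapply(p, function(pi) matrix(0, pi, n_comp))
  tt <- lapply(seq_len(nb), function(i) matrix(0, n, n_comp))
  wy <- matrix(0, ncol(y), n_comp)
  ty <- matrix(0, n, n_comp)
  defl <- lapply(p, function(pi) matrix(0, pi, n_comp))  # deflation loadings
  selected <- lapply(seq_len(nb), function(i) vector("list", n_comp))
  iters <- integer(n_comp)

  for (h in seq_len(n_comp)) {
    t_cur <- lapply(xb, init_score)
    t_y <- init_score(yc)
    w_h <- vector("list", nb)
    w_yh <- NULL
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      t_prev <- t_cur
      ty_prev <- t_y
      for (b in seq_len(nb)) {
        grad <- numeric(nrow(w[[b]]))
        acc <- matrix(0, n, 1L)
        for (k in seq_len(nb)) {
          if (k != b && design[b, k] > 0) acc <- acc + design[b, k] * t_cur[[k]]
        }
        if (design[b, nb + 1L] > 0) acc <- acc + design[b, nb + 1L] * t_y
        grad <- crossprod(xb[[b]], acc)[, 1]
        w_h[[b]] <- soft_select(grad, keepX[b])
        t_cur[[b]] <- xb[[b]] %*% w_h[[b]]
      }
      accy <- matrix(0, n, 1L)
      for (k in seq_len(nb)) {
        if (design[nb + 1L, k] > 0) accy <- accy + design[nb + 1L, k] * t_cur[[k]]
      }
      w_yh <- l2_normalize(crossprod(yc, accy)[, 1])
      t_y <- yc %*% w_yh
      delta <- max(c(vapply(seq_len(nb), function(b)
        sqrt(sum((t_cur[[b]] - t_prev[[b]])^2)), numeric(1)),
        sqrt(sum((t_y - ty_prev)^2))))
      if (delta < tol) { converged <- TRUE; iters[h] <- it; break }
    }
    if (!converged) {
      cond <- structure(class = c("adjuscreen_no_convergence", "error",
                                  "condition"),
                        list(message = sprintf(
                          "component %d did not converge in %d iterations", h,
                          max_iter), call = sys.call(-1),
                          model = list(weights = w_h, y_weights = w_yh)))
      stop(cond)
    }
    # deflation with the converged (un-standardized) scores
    consensus <- Reduce(`+`, t_cur) / nb
    for (b in seq_len(nb)) {
      tb <- t_cur[[b]]
      ss <- sum(tb^2)
      cb <- if (ss > 0) crossprod(xb[[b]], tb)[, 1] / ss else
        numeric(ncol(xb[[b]]))
      defl[[b]][, h] <- cb
      xb[[b]] <- xb[[b]] - tb %*% t(cb)
    }
    ssc <- sum(consensus^2)
    if (ssc > 0) yc <- yc - consensus %*% (crossprod(yc, consensus)[, 1] / ssc)
    # store with the deterministic orientation convention
    for (b in seq_len(nb)) {
      flip <- if (w_h[[b]][which.max(abs(w_h[[b]]))] < 0) -1 else 1
      w[[b]][, h] <- flip * w_h[[b]]
      tt[[b]][, h] <- flip * t_cur[[b]]
      selected[[b]][[h]] <- which(w_h[[b]] != 0)
    }
    flip_y <- if (w_yh[which.max(abs(w_yh))] < 0) -1 else 1
    wy[, h] <- flip_y * w_yh
    ty[, h] <- flip_y * t_y
  }

  for (b in seq_len(nb)) {
    rownames(w[[b]]) <- rownames(defl[[b]]) <- colnames(blocks[[b]])
    colnames(w[[b]]) <- colnames(tt[[b]]) <- paste0("comp", seq_len(n_comp))
    rownames(tt[[b]]) <- rownames(blocks[[b]])
    selected[[b]] <- lapply(selected[[b]], function(ix) {
      if (!is.null(colnames(blocks[[b]]))) {
        stats::setNames(ix, colnames(blocks[[b]])[ix])
      } else ix
    })
  }
  names(w) <- names(tt) <- names(selected) <- names(defl) <- names(blocks)
  rownames(wy) <- colnames(y)
  structure(list(weights = w, scores = tt, y_weights = wy, y_scores = ty,
                 selected = selected, keepX = stats::setNames(keepX,
                                                              names(blocks)),
                 n_comp = n_comp, design = design, mode = "regression",
                 deflation_loadings = defl, iterations = iters,
                 block_centers = lapply(blocks, colMeans),
                 block_names = names(blocks), tol = tol,
                 max_iter = max_iter),
            class = "block_spls")
}

#' @export
print.block_spls <- function(x, ...) {
  cat(sprintf("Sparse multiblock PLS (%s mode): %d block(s), %d component(s)\n",
              x$mode, length(x$weights), x$n_comp))
  for (b in names(x$weights)) {
    cat(sprintf("  %s: keepX = %d, selected on comp 1: %s\n", b, x$keepX[b],
                paste(names(x$selected[[b]][[1]]), collapse = ", ")))
  }
  invisible(x)
}

#' @export
coef.block_spls <- function(object, ...) object$weights

#' Selected features of a sparse multiblock model
#'
#' @param model a `block_spls` / `block_splsda` fit.
#' @param component component number.
#' @return data frame of block, feature, weight (and dominant class for
#'   discriminant fits).
#' @export
selected_features <- function(model, component = 1) {
  stopifnot(inherits(model, "block_spls"))
  rows <- lapply(names(model$weights), function(b) {
    ix <- model$selected[[b]][[component]]
    if (!length(ix)) return(NULL)
    fn <- if (!is.null(names(ix))) names(ix) else as.character(ix)
    df <- data.frame(block = b, feature = fn,
                     weight = model$weights[[b]][ix, component],
                     row.names = NULL)
    if (!is.null(model$dominant)) {
      df$dominant_class <- model$dominant[[b]][[component]]
    }
    df
  })
  do.call(rbind, rows)
}

#' Dichotomize a continuous outcome at its mean
#'
#' Substances with outcome strictly above the cohort mean are labelled
#' `"high"`, the rest `"low"` (a value exactly at the mean goes to `"low"`).
#' A non-constant input guarantees both classes are non-empty.
#'
#' @param outcome_values numeric vector with at least 2 distinct values.
#' @return factor with levels `low`, `high`.
#' @export
dichotomize <- function(outcome_values) {
  if (length(outcome_values) < 2L || length(unique(outcome_values)) < 2L) {
    stop("outcome must contain at least 2 distinct values", call. = FALSE)
  }
  m <- mean(outcome_values)
  factor(ifelse(outcome_values > m, "high", "low"), levels = c("low", "high"))
}

#' Sparse multiblock PLS discriminant analysis
#'
#' Discriminant variant of [block_spls()]: the outcome block is the centered
#' class-indicator (dummy) matrix of a two-class label. For every selected
#' feature the dominant class is recorded: the class with the larger
#' within-class mean of that feature, i.e. the group in which the feature is
#' predominantly observed.
#'
#' @param blocks named list of numeric matrices (common rows).
#' @param class_labels factor (or vector) with exactly two levels, each
#'   represented at least twice.
#' @param keepX,n_comp,design,tol,max_iter as in [block_spls()].
#' @return An object of class `block_splsda` (inheriting `block_spls`) with
#'   additional fields `class_labels`, `dominant` (per block/component
#'   character vectors of dominant classes for the selected features), and
#'   `centroids` (class centroids in averaged component-score space, used by
#'   `predict`).
#' @export
block_splsda <- function(blocks, class_labels, keepX, n_comp = 1,
                         design = NULL, tol = 1e-6, max_iter = 500) {
  cl <- factor(class_labels)
  if (nlevels(cl) != 2L) stop("exactly two classes are required",
                              call. = FALSE)
  if (any(table(cl) < 2L)) stop("each class needs at least 2 members",
                                call. = FALSE)
  yd <- stats::model.matrix(~ cl - 1)
  colnames(yd) <- levels(cl)
  fit <- block_spls(blocks, center_cols(yd), keepX = keepX, n_comp = n_comp,
                    design = design, tol = tol, max_iter = max_iter)
  fit$mode <- "discriminant"
  fit$class_labels <- cl
  fit$dominant <- lapply(names(fit$weights), function(b) {
    lapply(seq_len(n_comp), function(h) {
      ix <- fit$selected[[b]][[h]]
      bm <- as_numeric_matrix(blocks[[b]])
      vapply(ix, function(j) {
        means <- tapply(bm[, j], cl, mean)
        names(means)[which.max(means)]
      }, character(1))
    })
  })
  names(fit$dominant) <- names(fit$weights)
  avg <- Reduce(`+`, fit$scores) / length(fit$scores)
  fit$centroids <- apply(avg, 2L, function(s) tapply(s, cl, mean))
  fit$centroids <- matrix(fit$centroids, nrow = 2L,
                          dimnames = list(levels(cl),
                                          paste0("comp", seq_len(n_comp))))
  class(fit) <- c("block_splsda", "block_spls")
  fit
}

#' @export
print.block_splsda <- function(x, ...) {
  cat(sprintf("Sparse multiblock PLS-DA: %d block(s), %d component(s), classes %s\n",
              length(x$weights), x$n_comp,
              paste(levels(x$class_labels), collapse = "/")))
  sf <- selected_features(x, 1)
  for (b in names(x$weights)) {
    sub <- sf[sf$block == b, , drop = FALSE]
    cat(sprintf("  %s: %s\n", b,
                paste(sprintf("%s(%s)", sub$feature, sub$dominant_class),
                      collapse = " ")))
  }
  invisible(x)
}

# Project new blocks through the fitted (deflated) weight sequence, returning
# per-block scores averaged across blocks.
project_blocks <- function(model, new_blocks) {
  nb <- length(model$weights)
  xs <- lapply(seq_len(nb), function(b) {
    m <- as_numeric_matrix(new_blocks[[model$block_names[b]]])
    sweep(m, 2L, model$block_centers[[b]], "-")
  })
  n <- nrow(xs[[1]])
  scores <- lapply(seq_len(nb), function(b) matrix(0, n, model$n_comp))
  for (h in seq_len(model$n_comp)) {
    for (b in seq_len(nb)) {
      t_new <- xs[[b]] %*% model$weights[[b]][, h]
      scores[[b]][, h] <- t_new
      xs[[b]] <- xs[[b]] - t_new %*% t(model$deflation_loadings[[b]][, h])
    }
  }
  Reduce(`+`, scores) / nb
}

#' @export
predict.block_splsda <- function(object, new_blocks, ...) {
  avg <- project_blocks(object, new_blocks)
  cents <- object$centroids
  d2 <- sapply(rownames(cents), function(cl)
    rowSums(sweep(avg, 2L, cents[cl, ], "-")^2))
  d2 <- matrix(d2, ncol = nrow(cents),
               dimnames = list(NULL, rownames(cents)))
  cls <- factor(rownames(cents)[max.col(-d2, ties.method = "first")],
                levels = levels(object$class_labels))
  list(class = cls, scores = avg, distances = d2)
}

#' Tune keepX for multiblock sparse PLS-DA by repeated cross-validation
#'
#' For every candidate keepX, runs `repeats` rounds of stratified `folds`-fold
#' cross-validation (default 3 x 5-fold). Training folds are standardized and
#' the same centering/scaling is applied to the held-out samples, which are
#' classified by nearest class centroid in averaged component-score space.
#' The candidate minimizing the mean balanced error rate is returned; ties go
#' to the sparsest candidate (smallest total keepX).
#'
#' @param blocks named list of matrices (unscaled; scaling happens per fold).
#' @param class_labels two-class factor.
#' @param keepX_grid numeric vector of candidates (each recycled over blocks
#'   and capped at the block width), or a list of keepX vectors.
#' @param folds,repeats cross-validation layout (default 5-fold, 3 repeats).
#' @param n_comp,design passed to [block_splsda()].
#' @param seed integer seed for fold assignment.
#' @return list with `keepX` (chosen vector), `error_table` (candidate x
#'   mean balanced error rate), and the CV layout.
#' @export
tune_block_splsda <- function(blocks, class_labels, keepX_grid, folds = 5,
                              repeats = 3, n_comp = 1, design = NULL,
                              seed = 1L) {
  cl <- factor(class_labels)
  if (nlevels(cl) != 2L) stop("exactly two classes are required",
                              call. = FALSE)
  stop_if_not_count(folds, "folds", min = 2L)
  stop_if_not_count(repeats, "repeats", min = 1L)
  if (any(table(cl) < folds)) {
    stop("each class needs at least `folds` members for stratified folds",
         call. = FALSE)
  }
  blocks <- lapply(blocks, as_numeric_matrix)
  p <- vapply(blocks, ncol, 1L)
  if (is.list(keepX_grid)) {
    cands <- lapply(keepX_grid, function(k) pmin(rep_len(as.integer(k),
                                                         length(blocks)), p))
  } else {
    if (!length(keepX_grid)) stop("empty keepX grid", call. = FALSE)
    cands <- lapply(as.integer(keepX_grid), function(k)
      pmin(rep_len(k, length(blocks)), p))
  }
  n <- length(cl)
  fold_plan <- with_seed(seed, {
    lapply(seq_len(repeats), function(r) {
      id <- integer(n)
      for (lev in levels(cl)) {
        ix <- which(cl == lev)
        id[ix] <- sample(rep_len(seq_len(folds), length(ix)))
      }
      id
    })
  })
  ber_one <- function(keepX) {
    errs <- c()
    for (r in seq_len(repeats)) {
      id <- fold_plan[[r]]
      for (f in seq_len(folds)) {
        tr <- id != f
        tr_blocks <- lapply(blocks, function(b) b[tr, , drop = FALSE])
        te_blocks <- lapply(blocks, function(b) b[!tr, , drop = FALSE])
        sc <- lapply(tr_blocks, function(b) {
          mu <- colMeans(b); sdv <- apply(b, 2L, stats::sd)
          keep <- sdv > 1e-12
          list(mu = mu, sd = sdv, keep = keep)
        })
        std <- function(bl, s) {
          b <- sweep(bl[, s$keep, drop = FALSE], 2L, s$mu[s$keep], "-")
          sweep(b, 2L, s$sd[s$keep], "/")
        }
        tr_s <- Map(std, tr_blocks, sc)
        te_s <- Map(std, te_blocks, sc)
        kx <- pmin(keepX, vapply(tr_s, ncol, 1L))
        fit <- block_splsda(tr_s, cl[tr], keepX = kx, n_comp = n_comp,
                            design = design)
        pred <- predict(fit, te_s)$class
        truth <- cl[!tr]
        per_class <- vapply(levels(cl), function(lev) {
          ix <- truth == lev
          if (!any(ix)) return(NA_real_)
          mean(pred[ix] != lev)
        }, numeric(1))
        errs <- c(errs, mean(per_class, na.rm = TRUE))
      }
    }
    mean(errs)
  }
  ber <- vapply(cands, ber_one, numeric(1))
  lab <- vapply(cands, function(k) paste(k, collapse = "/"), character(1))
  best <- which(ber == min(ber))
  if (length(best) > 1L) {
    best <- best[which.min(vapply(cands[best], sum, numeric(1)))]
  }
  list(keepX = cands[[best]],
       error_table = data.frame(keepX = lab, balanced_error = ber),
       folds = folds, repeats = repeats, seed = seed)
}
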