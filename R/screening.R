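# One-step and two-step threshold screens, separation statistics, and PCA
# discrimination.

#' Threshold screen on a single parameter
#'
#' Screens substances on one in vitro parameter. With `threshold = "auto"`
#' the threshold is the arithmetic mean of the parameter over all substances
#' (extracts and controls jointly). A positive-direction screen passes values
#' at or above the threshold; a negative-direction screen passes values
#' strictly below it, so a substance exactly at a negative threshold is
#' rejected (the conservative choice).
#'
#' @param values numeric parameter vector (length >= 2).
#' @param threshold `"auto"` (mean of `values`) or an explicit number.
#' @param direction `"positive"` (pass on `>=`) or `"negative"` (pass on
#'   `<`).
#' @return list with `mask` (logical pass flags), `threshold`, `direction`.
#' @export
threshold_screen <- function(values, threshold = "auto",
                             direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (length(values) < 2L || any(!is.finite(values))) {
    stop("`values` must be >= 2 finite numbers", call. = FALSE)
  }
  if (identical(threshold, "auto")) {
    if (length(unique(values)) == 1L) {
      stop("constant values: auto-mean threshold is degenerate",
           call. = FALSE)
    }
    threshold <- mean(values)
  } else if (!is.numeric(threshold) || length(threshold) != 1L) {
    stop('`threshold` must be "auto" or a single number', call. = FALSE)
  }
  mask <- if (direction == "positive") values >= threshold else
    values < threshold
  list(mask = mask, threshold = threshold, direction = direction)
}

#' Two-step screen: negative parameter first, positive parameter second
#'
#' First rejects substances at or above the negative-parameter threshold
#' (e.g. the percentage of the smallest-particle population), then keeps, of
#' the survivors, those at or above the positive-parameter threshold (e.g. an
#' in vitro cytokine level). Auto thresholds are means over all substances.
#' The final mask is the logical AND of the two rules, so it is always a
#' subset of the negative-step survivors.
#'
#' @param neg_values,pos_values aligned parameter vectors.
#' @param neg_threshold,pos_threshold `"auto"` or explicit numbers.
#' @return list with `mask`, the per-step masks and thresholds, and survivor
#'   counts after each step.
#' @export
two_step_screen <- function(neg_values, pos_values, neg_threshold = "auto",
                            pos_threshold = "auto") {
  if (length(neg_values) != length(pos_values)) {
    stop("parameter vectors must be aligned (equal length)", call. = FALSE)
  }
  step1 <- threshold_screen(neg_values, neg_threshold, "negative")
  step2 <- threshold_screen(pos_values, pos_threshold, "positive")
  mask <- step1$mask & step2$mask
  list(mask = mask,
       neg = step1, pos = step2,
       survivors = c(after_negative_step = sum(step1$mask),
                     after_positive_step = sum(mask)))
}

#' Degree of separation between screened and non-screened groups
#'
#' Two-sample t test (pooled-variance Student's t by default, matching an
#' unpaired t test with homogeneous variances; Welch's correction available
#' behind the `welch` flag) of the outcome between the substances passing and
#' failing a screen.
#'
#' @param outcome_values numeric outcome (e.g. fold-change total IgG).
#' @param mask logical pass flags of the same length; both groups need at
#'   least 2 members.
#' @param welch use Welch's unequal-variance t test instead of the pooled
#'   test.
#' @return An object of class `screening_result`: mask, group sizes and
#'   means, `t_statistic`, `degrees_of_freedom`, two-tailed `p_value`.
#' @examples
#' separation_test(c(5, 6, 7, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
#' @export
separation_test <- function(outcome_values, mask, welch = FALSE) {
  if (length(outcome_values) != length(mask) || !is.logical(mask)) {
    stop("`mask` must be a logical vector aligned with the outcome",
         call. = FALSE)
  }
  g1 <- outcome_values[mask]
  g2 <- outcome_values[!mask]
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("both screened and non-screened groups need >= 2 members ",
         "(consider the `welch` flag only for unequal variances, ",
         "not for singleton groups)", call. = FALSE)
  }
  tt <- stats::t.test(g1, g2, var.equal = !welch)
  structure(list(mask = mask,
                 group_sizes = c(screened = length(g1),
                                 non_screened = length(g2)),
                 group_means = c(screened = mean(g1),
                                 non_screened = mean(g2)),
                 t_statistic = unname(tt$statistic),
                 degrees_of_freedom = unname(tt$parameter),
                 p_value = tt$p.value,
                 method = if (welch) "welch" else "pooled"),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("Screen separation: %d screened (mean %.3f) vs %d non-screened (mean %.3f)\n",
              x$group_sizes[1], x$group_means[1],
              x$group_sizes[2], x$group_means[2]))
  cat(sprintf("  %s t = %.3f, df = %.4g, two-tailed p = %.4g\n",
              if (x$method == "pooled") "Student" else "Welch",
              x$t_statistic, x$degrees_of_freedom, x$p_value))
  invisible(x)
}

#' Pearson correlation between a screening parameter and an outcome
#'
#' @param parameter_values,outcome_values aligned numeric vectors (n >= 3,
#'   both non-constant).
#' @return list with `r` (Pearson correlation) and `p` (t-based two-tailed
#'   p value).
#' @export
correlate <- function(parameter_values, outcome_values) {
  if (length(parameter_values) != length(outcome_values) ||
      length(parameter_values) < 3L) {
    stop("need aligned vectors with n >= 3", call. = FALSE)
  }
  if (stats::sd(parameter_values) == 0 || stats::sd(outcome_values) == 0) {
    stop("zero variance in an input vector", call. = FALSE)
  }
  ct <- stats::cor.test(parameter_values, outcome_values, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Screen substances by PCA discrimination
#'
#' Runs a standardized PCA on a substances x parameters matrix and splits the
#' substances at the mean of the component-1 scores (zero under centering;
#' the mean is used for robustness). Because a principal component's sign is
#' arbitrary, component 1 is oriented so that the side with the higher mean
#' level of the designated positive parameters is the screened group; the
#' split is then scored with [separation_test()] against the outcome.
#'
#' @param parameter_matrix substances x parameters matrix (>= 3 substances,
#'   >= 2 parameters).
#' @param outcome_fold_changes outcome vector aligned with the rows.
#' @param positive_parameter_names column names of the parameters expected to
#'   increase with adjuvanticity (used only to orient component 1).
#' @param welch passed to [separation_test()].
#' @return An object of classes `pca_screen` and `screening_result`, with
#'   additional fields `scores` (component scores), `loadings`, and
#'   `explained_variance_ratio`.
#' @export
pca_discriminate <- function(parameter_matrix, outcome_fold_changes,
                             positive_parameter_names, welch = FALSE) {
  x <- as_numeric_matrix(parameter_matrix, "parameter_matrix")
  if (nrow(x) < 3L || ncol(x) < 2L) {
    stop("need >= 3 substances and >= 2 parameters", call. = FALSE)
  }
  if (length(outcome_fold_changes) != nrow(x)) {
    stop("outcome must align with the parameter matrix rows", call. = FALSE)
  }
  if (is.null(colnames(x)) ||
      !all(positive_parameter_names %in% colnames(x))) {
    stop("positive_parameter_names must name columns of the matrix",
         call. = FALSE)
  }
  fit <- pca(x, scale = TRUE, n_components = min(nrow(x) - 1L, ncol(x), 2L))
  s1 <- fit$scores[, 1]
  xs <- scale_columns(x)
  pos_mean_by_side <- function(mask) {
    mean(xs[mask, positive_parameter_names, drop = FALSE])
  }
  mask <- s1 >= mean(s1)
  if (all(mask) || !any(mask)) {
    stop("all substances fall on one side of the component-1 threshold",
         call. = FALSE)
  }
  if (pos_mean_by_side(mask) < pos_mean_by_side(!mask)) {
    s1 <- -s1
    fit$scores[, 1] <- s1
    fit$loadings[, 1] <- -fit$loadings[, 1]
    mask <- s1 >= mean(s1)
  }
  res <- separation_test(outcome_fold_changes, mask, welch = welch)
  res$scores <- fit$scores
  res$loadings <- fit$loadings
  res$explained_variance_ratio <- fit$explained_variance_ratio
  class(res) <- c("pca_screen", "screening_result")
  res
}

#' End-to-end screening report across all endpoints
#'
#' For every adjuvanticity endpoint: dichotomizes the endpoint at its mean,
#' fits a sparse multiblock PLS-DA on the (standardized) blocks, tabulates
#' the selected parameters with their dominant class and their Pearson
#' correlation with the endpoint, and applies the screening battery — the
#' single positive-parameter screen, the two-step negative-then-positive
#' screen, and PCA discrimination on the positive selected parameters, all at
#' auto-mean thresholds. The positive screening parameter is the selected
#' high-dominant feature with the largest absolute weight in the cytokine
#' blocks; the negative parameter is the low-dominant particle feature with
#' the largest absolute weight. Endpoints with no high-dominant selected
#' parameter are marked not applicable rather than screened.
#'
#' @param blocks named list of raw feature matrices (`human`, `mouse`,
#'   `particle`).
#' @param outcomes data frame of endpoint values (one column per endpoint).
#' @param keepX,n_comp,design passed to [block_splsda()].
#' @param models optional named list of pre-fitted `block_splsda` models, one
#'   per endpoint; fitted internally when omitted.
#' @return An object of class `screening_report`: per endpoint a list with
#'   the fitted model's selected-feature table, correlation table, screening
#'   results (`single_step`, `two_step`, `pca`), and the parameters used.
#' @export
screening_report <- function(blocks, outcomes, keepX = 10, n_comp = 1,
                             design = NULL, models = NULL) {
  blocks <- lapply(blocks, as_numeric_matrix)
  endpoints <- colnames(outcomes)
  cyto_blocks <- intersect(c("human", "mouse"), names(blocks))
  if (!length(cyto_blocks)) cyto_blocks <- setdiff(names(blocks), "particle")
  scaled <- lapply(blocks, scale_columns)
  report <- lapply(endpoints, function(ep) {
    y <- outcomes[[ep]]
    fit <- if (!is.null(models) && !is.null(models[[ep]])) models[[ep]] else
      block_splsda(scaled, dichotomize(y),
                   keepX = pmin(keepX, vapply(scaled, ncol, 1L)),
                   n_comp = n_comp, design = design)
    sf <- selected_features(fit, 1)
    sf$r <- NA_real_
    sf$p <- NA_real_
    for (i in seq_len(nrow(sf))) {
      cc <- correlate(blocks[[sf$block[i]]][, sf$feature[i]], y)
      sf$r[i] <- cc$r
      sf$p[i] <- cc$p
    }
    pos <- sf[sf$dominant_class == "high" & sf$block %in% cyto_blocks, ]
    neg <- sf[sf$dominant_class == "low" & sf$block == "particle", ]
    section <- list(endpoint = ep, selected = sf,
                    applicable = nrow(pos) > 0)
    if (nrow(pos) > 0) {
      pos_best <- pos[which.max(abs(pos$weight)), ]
      pos_values <- blocks[[pos_best$block]][, pos_best$feature]
      section$positive_parameter <- pos_best$feature
      single <- threshold_screen(pos_values, "auto", "positive")
      section$single_step <- separation_test(y, single$mask)
      section$single_step$threshold <- single$threshold
      if (nrow(neg) > 0) {
        neg_best <- neg[which.max(abs(neg$weight)), ]
        neg_values <- blocks$particle[, neg_best$feature]
        section$negative_parameter <- neg_best$feature
        ts <- two_step_screen(neg_values, pos_values)
        section$two_step <- tryCatch(separation_test(y, ts$mask),
                                     error = function(e) e$message)
        section$two_step_survivors <- ts$survivors
      }
      pos_all <- unique(pos$feature)
      if (length(pos_all) >= 2) {
        pm <- do.call(cbind, lapply(seq_len(nrow(pos)), function(i)
          blocks[[pos$block[i]]][, pos$feature[i]]))
        colnames(pm) <- pos$feature
        section$pca <- tryCatch(
          pca_discriminate(pm, y, positive_parameter_names = pos$feature),
          error = function(e) e$message)
      }
    }
    section
  })
  names(report) <- endpoints
  structure(report, class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  for (sec in x) {
    cat(sprintf("== %s ==\n", sec$endpoint))
    if (!sec$applicable) {
      cat("  no positive-direction selected parameter; screening not applicable\n")
      next
    }
    cat(sprintf("  positive parameter: %s", sec$positive_parameter))
    if (!is.null(sec$negative_parameter)) {
      cat(sprintf("; negative parameter: %s", sec$negative_parameter))
    }
    cat("\n  single-step: ")
    cat(sprintf("p = %.4g", sec$single_step$p_value))
    if (!is.null(sec$two_step) && inherits(sec$two_step, "screening_result")) {
      cat(sprintf("; two-step: p = %.4g", sec$two_step$p_value))
    }
    if (!is.null(sec$pca) && inherits(sec$pca, "screening_result")) {
      cat(sprintf("; PCA screen: p = %.4g", sec$pca$p_value))
    }
    cat("\n")
  }
  invisible(x)
}
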