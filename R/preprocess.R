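#' Endpoint antibody titer by log-linear interpolation
#'
#' The endpoint titer is the reciprocal plasma dilution at which the ELISA
#' absorbance curve crosses the cutoff (OD450 of 0.2 by default), obtained by
#' piecewise linear interpolation in (log10 dilution, OD) between the two
#' measured points bracketing the cutoff. Series that never reach the cutoff
#' are censored: if even the lowest dilution is below the cutoff the titer is
#' censored low at the smallest dilution; if the highest dilution is still
#' above the cutoff it is censored high at the largest dilution.
#'
#' @param series a `dilution_series` object, or a numeric vector of strictly
#'   increasing reciprocal dilutions.
#' @param od absorbances, one per dilution (ignored when `series` is a
#'   `dilution_series`).
#' @param cutoff cutoff absorbance (default 0.2).
#' @return list with `titer` (reciprocal dilution) and `censored`, one of
#'   `"none"`, `"low"`, `"high"`. With a non-monotone series crossing the
#'   cutoff more than once, the first crossing from the low-dilution end is
#'   used and a warning is emitted.
#' @examples
#' titer_from_od(c(100, 400, 1600), c(0.8, 0.35, 0.1))
#' @export
titer_from_od <- function(series, od = NULL, cutoff = 0.2) {
  if (inherits(series, "dilution_series")) {
    dil <- series$dilutions
    od <- series$od
  } else {
    dil <- series
  }
  if (length(dil) == 0L) stop("empty dilution series", call. = FALSE)
  if (length(dil) != length(od) || length(dil) < 2L) {
    stop("need >= 2 dilutions with matching OD values", call. = FALSE)
  }
  if (any(dil <= 0) || any(diff(dil) <= 0)) {
    stop("dilutions must be positive and strictly increasing", call. = FALSE)
  }
  n <- length(dil)
  if (od[1] < cutoff) {
    return(list(titer = dil[1], censored = "low"))
  }
  if (od[n] > cutoff) {
    return(list(titer = dil[n], censored = "high"))
  }
  # multiple sign changes indicate a non-monotone series; first crossing wins
  # (exact hits contribute no sign change of their own)
  s <- sign(od - cutoff)
  s <- s[s != 0]
  if (length(s) > 1L && sum(diff(s) != 0) > 1L) {
    warning("OD series crosses the cutoff more than once; using the first ",
            "crossing from the low-dilution end")
  }
  hit <- which(od == cutoff)
  below <- which(od < cutoff)
  j <- if (length(hit) && (!length(below) || hit[1] < below[1])) hit[1] else
    below[1]
  if (od[j] == cutoff) {
    return(list(titer = dil[j], censored = "none"))
  }
  i <- j - 1L
  frac <- (od[i] - cutoff) / (od[i] - od[j])
  lt <- log10(dil[i]) + frac * (log10(dil[j]) - log10(dil[i]))
  list(titer = 10^lt, censored = "none")
}

#' Fold change of a treatment group against a reference group
#'
#' Ratio of the arithmetic mean of the group's values (e.g. endpoint titers)
#' to the arithmetic mean of the reference group (e.g. the antigen-alone
#' group).
#'
#' @param group_values,reference_values non-empty numeric vectors.
#' @return a single fold change.
#' @export
fold_change <- function(group_values, reference_values) {
  if (!length(group_values) || !length(reference_values)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ref <- mean(reference_values)
  if (!is.finite(ref) || ref <= 0) {
    stop("reference mean must be positive (fold change undefined)",
         call. = FALSE)
  }
  mean(group_values) / ref
}

#' Background-subtracted group concentration
#'
#' Mean concentration of the stimulated group minus the mean of the background
#' group (non-stimulated medium, or antigen-alone, depending on the assay),
#' floored at zero: downstream feature blocks assume non-negative
#' concentrations.
#'
#' @param values,background_values non-empty numeric vectors of raw
#'   concentrations (must be non-negative).
#' @return adjusted concentration (>= 0).
#' @export
background_subtract <- function(values, background_values) {
  if (!length(values) || !length(background_values)) {
    stop("both inputs must be non-empty", call. = FALSE)
  }
  if (any(values < 0) || any(background_values < 0)) {
    stop("raw concentrations must be non-negative (check upstream units)",
         call. = FALSE)
  }
  max(mean(values) - mean(background_values), 0)
}

#' Assemble aligned feature blocks and an outcome table
#'
#' Aligns the three in vitro blocks and the in vivo outcome table on a common
#' canonical substance order (sorted ids) and validates the block invariants:
#' no missing substances, no missing values, non-negative cytokine entries,
#' and particle rows summing to 100.
#'
#' @param human,mouse,particle numeric matrices (substances x features) with
#'   substance ids as row names.
#' @param outcomes data frame or matrix of endpoint values with substance ids
#'   as row names.
#' @return list with `blocks` (named list of aligned matrices) and `outcomes`
#'   (aligned data frame).
#' @export
assemble_blocks <- function(human, mouse, particle, outcomes) {
  blocks <- list(human = as_numeric_matrix(human, "human"),
                 mouse = as_numeric_matrix(mouse, "mouse"),
                 particle = as_numeric_matrix(particle, "particle"))
  out <- outcomes
  if (is.matrix(out)) out <- as.data.frame(out)
  tables <- c(blocks, list(outcomes = as.matrix(out)))
  ids_per <- lapply(tables, rownames)
  if (any(vapply(ids_per, is.null, logical(1)))) {
    stop("all tables must carry substance ids as row names", call. = FALSE)
  }
  all_ids <- sort(unique(unlist(ids_per)))
  for (nm in names(tables)) {
    missing <- setdiff(all_ids, ids_per[[nm]])
    if (length(missing)) {
      stop(sprintf("substances missing from '%s': %s", nm,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    if (anyNA(tables[[nm]]) || any(!is.finite(tables[[nm]]))) {
      stop(sprintf("missing or non-finite values in '%s'", nm), call. = FALSE)
    }
  }
  blocks <- lapply(blocks, function(b) b[all_ids, , drop = FALSE])
  out <- out[all_ids, , drop = FALSE]
  if (any(blocks$human < 0) || any(blocks$mouse < 0)) {
    stop("cytokine blocks must be non-negative", call. = FALSE)
  }
  bad <- which(abs(rowSums(blocks$particle) - 100) > 1e-6)
  if (length(bad)) {
    stop(sprintf("particle rows not summing to 100: %s",
                 paste(rownames(blocks$particle)[bad], collapse = ", ")),
         call. = FALSE)
  }
  list(blocks = blocks, outcomes = out)
}

#' Standardize matrix columns
#'
#' Centers each column to mean 0 and scales to sample standard deviation 1
#' (n - 1 denominator). Columns with zero variance cannot be standardized;
#' they are dropped with a warning and reported in the `"dropped"` attribute.
#'
#' @param x numeric matrix with at least 2 rows.
#' @return standardized matrix; attribute `dropped` holds names (or indices)
#'   of removed zero-variance columns.
#' @export
scale_columns <- function(x) {
  x <- as_numeric_matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows to standardize", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  zero <- !is.finite(sds) | sds < 1e-12
  if (all(zero)) stop("all columns have zero variance", call. = FALSE)
  dropped <- if (is.null(colnames(x))) which(zero) else colnames(x)[zero]
  if (any(zero)) {
    warning(sprintf("dropping %d zero-variance column(s): %s", sum(zero),
                    paste(dropped, collapse = ", ")))
    x <- x[, !zero, drop = FALSE]
    sds <- sds[!zero]
  }
  out <- sweep(sweep(x, 2L, colMeans(x), "-"), 2L, sds, "/")
  attr(out, "dropped") <- if (any(zero)) dropped else
    if (is.null(colnames(x))) integer(0) else character(0)
  out
}
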