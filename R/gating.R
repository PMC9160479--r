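#' Define the 4 x 4 FSC/SSC gating grid
#'
#' Nano-sized particles acquired on a 4-decade logarithmic scatter scale are
#' categorized into 16 populations, labelled A to P, by a 4 x 4 grid on
#' (log10 FSC, log10 SSC). Labels are row-major with rows ordered by
#' descending SSC and columns by ascending FSC: the top row (highest SSC) is
#' A-D, and the bottom row (lowest SSC) is M-P, so population A is
#' FSC-low/SSC-high, D is FSC-high/SSC-high, M is FSC-low/SSC-low (the
#' smallest, least dense particles) and P is FSC-high/SSC-low.
#'
#' @param fsc_edges,ssc_edges five strictly increasing bin boundaries per axis
#'   in log10 intensity units; the default `0:4` carves the 4-decade
#'   instrument range into equal decades.
#' @return An object of class `gate_grid`.
#' @export
gate_grid <- function(fsc_edges = 0:4, ssc_edges = 0:4) {
  check_edges <- function(e, name) {
    if (length(e) != 5L || any(!is.finite(e)) || any(diff(e) <= 0)) {
      stop(sprintf("`%s` must be 5 strictly increasing finite values", name),
           call. = FALSE)
    }
    as.numeric(e)
  }
  fsc_edges <- check_edges(fsc_edges, "fsc_edges")
  ssc_edges <- check_edges(ssc_edges, "ssc_edges")
  layout <- matrix(LETTERS[1:16], nrow = 4, ncol = 4, byrow = TRUE)
  dimnames(layout) <- list(ssc_row = paste0("ssc", 4:1),
                           fsc_col = paste0("fsc", 1:4))
  structure(list(fsc_edges = fsc_edges, ssc_edges = ssc_edges,
                 layout = layout), class = "gate_grid")
}

#' @export
print.gate_grid <- function(x, ...) {
  cat("4 x 4 FSC/SSC gate grid (log10 edges)\n")
  cat("  FSC:", paste(x$fsc_edges, collapse = " "), "\n")
  cat("  SSC:", paste(x$ssc_edges, collapse = " "), "\n")
  cat("  layout (rows = SSC high to low, cols = FSC low to high):\n")
  for (r in 1:4) cat("   ", paste(x$layout[r, ], collapse = " "), "\n")
  invisible(x)
}

# log10 cell bounds per population letter, in A..P order
grid_cells <- function(grid) {
  letters16 <- as.vector(t(grid$layout))  # row-major A..P
  row_of <- rep(1:4, each = 4)            # 1 = top (highest SSC)
  col_of <- rep(1:4, times = 4)
  ssc_bin <- 5L - row_of                  # bin index on the ssc axis
  ord <- match(LETTERS[1:16], letters16)
  data.frame(letter = LETTERS[1:16],
             fsc_lo = grid$fsc_edges[col_of[ord]],
             fsc_hi = grid$fsc_edges[col_of[ord] + 1L],
             ssc_lo = grid$ssc_edges[ssc_bin[ord]],
             ssc_hi = grid$ssc_edges[ssc_bin[ord] + 1L])
}

#' Assign scatter events to gate populations
#'
#' Maps each (FSC, SSC) intensity pair to the letter of the grid cell
#' containing (log10 FSC, log10 SSC). Cells are half-open `[low, high)` on
#' both axes with the top edge closed, so an event exactly on an interior
#' boundary belongs to the higher bin. Events outside the grid are returned
#' as `NA` (out of range), not clipped.
#'
#' @param fsc,ssc positive intensity vectors of equal length.
#' @param grid a [gate_grid()].
#' @return character vector of population letters, `NA` for out-of-range
#'   events.
#' @export
assign_population <- function(fsc, ssc, grid) {
  if (!inherits(grid, "gate_grid")) stop("`grid` must be a gate_grid",
                                         call. = FALSE)
  if (length(fsc) != length(ssc)) stop("fsc and ssc lengths differ",
                                       call. = FALSE)
  if (length(fsc) == 0L) return(character(0))
  if (any(!is.finite(fsc)) || any(!is.finite(ssc)) ||
      any(fsc <= 0) || any(ssc <= 0)) {
    stop("intensities must be positive and finite", call. = FALSE)
  }
  col <- findInterval(log10(fsc), grid$fsc_edges, rightmost.closed = TRUE)
  sbin <- findInterval(log10(ssc), grid$ssc_edges, rightmost.closed = TRUE)
  ok <- col >= 1L & col <= 4L & sbin >= 1L & sbin <= 4L
  out <- rep(NA_character_, length(fsc))
  row <- 5L - sbin[ok]   # row 1 = highest SSC
  out[ok] <- grid$layout[cbind(row, col[ok])]
  out
}

#' Count events per gate population
#'
#' @param events data frame with columns `fsc` and `ssc` (one row per event);
#'   an empty table yields all-zero counts.
#' @param grid a [gate_grid()].
#' @return list with `counts` (named integer vector, A..P) and `out_of_range`
#'   (number of events falling outside the grid).
#' @export
population_counts <- function(events, grid) {
  if (!is.data.frame(events) || !all(c("fsc", "ssc") %in% names(events))) {
    stop("`events` must be a data frame with columns fsc and ssc",
         call. = FALSE)
  }
  letters <- assign_population(events$fsc, events$ssc, grid)
  counts <- table(factor(letters, levels = LETTERS[1:16]))
  counts <- stats::setNames(as.integer(counts), LETTERS[1:16])
  list(counts = counts, out_of_range = sum(is.na(letters)))
}

#' Subtract blank (buffer-only) counts from sample counts
#'
#' Sample and blank must be acquired at the same flow rate for the same
#' duration so counts are directly comparable. Per-population differences
#' below zero are clamped to zero: corrected counts are event numbers and
#' cannot be negative.
#'
#' @param sample_counts,blank_counts length-16 non-negative count vectors.
#' @return corrected length-16 count vector.
#' @export
blank_correct <- function(sample_counts, blank_counts) {
  if (length(sample_counts) != 16L || length(blank_counts) != 16L) {
    stop("count vectors must have length 16", call. = FALSE)
  }
  if (any(sample_counts < 0) || any(blank_counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  out <- pmax(sample_counts - blank_counts, 0)
  if (is.null(names(out))) names(out) <- LETTERS[1:16]
  out
}

#' Convert corrected counts to a population percentage profile
#'
#' Percentages are taken over the sum of the 16 blank-corrected gate counts
#' (the profile is a composition over the gates, not over raw acquired
#' events). An all-zero input yields an all-zero profile with
#' `total_corrected_events = 0`.
#'
#' @param corrected_counts length-16 non-negative vector.
#' @return An object of class `population_profile`: list with `percent`
#'   (named A..P, summing to 100 when any events remain) and
#'   `total_corrected_events`.
#' @export
population_percentages <- function(corrected_counts) {
  if (length(corrected_counts) != 16L) {
    stop("`corrected_counts` must have length 16", call. = FALSE)
  }
  if (any(corrected_counts < 0)) {
    stop("corrected counts must be non-negative", call. = FALSE)
  }
  total <- sum(corrected_counts)
  pct <- if (total > 0) 100 * corrected_counts / total else
    rep(0, 16L)
  names(pct) <- if (!is.null(names(corrected_counts)))
    names(corrected_counts) else LETTERS[1:16]
  structure(list(percent = pct, total_corrected_events = total),
            class = "population_profile")
}

#' @export
print.population_profile <- function(x, ...) {
  cat(sprintf("Population profile (%s corrected events)\n",
              format(x$total_corrected_events)))
  m <- matrix(sprintf("%s %5.1f%%", names(x$percent), x$percent),
              nrow = 4, byrow = TRUE)
  for (r in 1:4) cat(" ", paste(m[r, ], collapse = "  "), "\n")
  invisible(x)
}

#' Gate one sample end to end
#'
#' Convenience wrapper: counts sample and blank events, blank-corrects, and
#' returns the percentage profile.
#'
#' @param sample_events,blank_events event data frames (columns `fsc`, `ssc`);
#'   `blank_events` may be `NULL` for no blank correction.
#' @param grid a [gate_grid()].
#' @return a [population_percentages()] profile.
#' @export
gate_sample <- function(sample_events, blank_events = NULL, grid = gate_grid()) {
  sc <- population_counts(sample_events, grid)$counts
  bc <- if (is.null(blank_events)) stats::setNames(integer(16L), LETTERS[1:16])
        else population_counts(blank_events, grid)$counts
  population_percentages(blank_correct(sc, bc))
}
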