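#' Configuration for a synthetic adjuvant-screening cohort
#'
#' Describes the statistical structure of a simulated screening cohort: a
#' library of candidate extracts plus a handful of control adjuvants, each
#' profiled on three in vitro feature blocks (human cytokines, mouse cytokines,
#' nanoparticle population percentages) and six in vivo adjuvanticity
#' endpoints. Two independent standard-normal latent factors drive the data:
#' a positive factor `z_pos` (innate stimulation capacity) that loads on the
#' planted cytokine features and raises every endpoint, and a negative factor
#' `z_neg` that raises the log-abundance of one particle population while
#' lowering the endpoints. The factors are independent so that a negative
#' particle parameter carries screening information not available from the
#' cytokine block.
#'
#' @param n_extracts number of library extracts (default 73).
#' @param n_controls number of control adjuvants (default 7). Controls are
#'   drawn from the same model with `control_shift` added to `z_pos`,
#'   emulating their potent adjuvanticity.
#' @param n_human,n_mouse,n_particle features per block (defaults 18, 23, 16).
#' @param informative_pos list with elements `human` and `mouse`: indices of
#'   the planted positive-signal cytokines in each block. The default plants
#'   five per block, on the columns named hGCSF, hGMCSF, hMIP1b, hIL4, hIL5
#'   (human) and mRANTES, mMIP1b, mGMCSF, mIL4, mIL5 (mouse).
#' @param informative_neg index (1..`n_particle`) of the particle population
#'   carrying the negative signal. The default, 13, is population M in the
#'   row-major A-P layout: the lowest-FSC, lowest-SSC gate.
#' @param effect_pos,effect_neg loading magnitudes of the latent factors on
#'   their informative features, in standardized (log-scale) units; must be
#'   positive.
#' @param noise_sd residual standard deviation on the log scale; must be
#'   positive.
#' @param control_shift mean shift of `z_pos` for control adjuvants.
#' @param w_pos,w_neg weights of the two latent factors on the log of each
#'   outcome endpoint; scalars are recycled across the six endpoints.
#' @param seed integer seed; all randomness in [generate_cohort()] flows from
#'   it.
#'
#' @return An object of class `sim_config`.
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_extracts = 73, n_controls = 7,
                       n_human = 18, n_mouse = 23, n_particle = 16,
                       informative_pos = NULL,
                       informative_neg = 13,
                       effect_pos = 1, effect_neg = 1,
                       noise_sd = 0.5,
                       control_shift = 1,
                       w_pos = 1, w_neg = 0.5,
                       seed = 1L) {
  stop_if_not_count(n_extracts, "n_extracts", min = 2L)
  stop_if_not_count(n_controls, "n_controls", min = 0L)
  stop_if_not_count(n_human, "n_human", min = 2L)
  stop_if_not_count(n_mouse, "n_mouse", min = 2L)
  stop_if_not_count(n_particle, "n_particle", min = 2L)
  if (is.null(informative_pos)) {
    # defaults named after the growth factor / chemokine candidates the
    # screen is designed around, falling back to leading columns for
    # non-default block widths
    hum <- match(c("hGCSF", "hGMCSF", "hMIP1b", "hIL4", "hIL5"),
                 human_cytokine_names(n_human))
    mou <- match(c("mRANTES", "mMIP1b", "mGMCSF", "mIL4", "mIL5"),
                 mouse_cytokine_names(n_mouse))
    hum <- hum[!is.na(hum)]
    mou <- mou[!is.na(mou)]
    if (length(hum) < min(5L, n_human)) hum <- seq_len(min(5L, n_human))
    if (length(mou) < min(5L, n_mouse)) mou <- seq_len(min(5L, n_mouse))
    informative_pos <- list(human = hum, mouse = mou)
  }
  if (!is.list(informative_pos) ||
      !all(c("human", "mouse") %in% names(informative_pos))) {
    stop("`informative_pos` must be a list with elements 'human' and 'mouse'",
         call. = FALSE)
  }
  if (any(informative_pos$human < 1 | informative_pos$human > n_human) ||
      any(informative_pos$mouse < 1 | informative_pos$mouse > n_mouse)) {
    stop("informative_pos indices out of feature range", call. = FALSE)
  }
  if (length(informative_neg) != 1L || informative_neg < 1 ||
      informative_neg > n_particle) {
    stop("`informative_neg` must be a single index in 1..n_particle",
         call. = FALSE)
  }
  if (effect_pos <= 0 || effect_neg <= 0) {
    stop("effect sizes must be positive", call. = FALSE)
  }
  if (noise_sd <= 0) stop("`noise_sd` must be positive", call. = FALSE)
  endpoints <- c("totalIgG_fc", "igg1_fc", "igg2c_fc",
                 "ige_delta", "il13_delta", "ifng_delta")
  link <- data.frame(endpoint = endpoints,
                     w_pos = rep_len(w_pos, 6L),
                     w_neg = rep_len(w_neg, 6L))
  structure(list(n_extracts = as.integer(n_extracts),
                 n_controls = as.integer(n_controls),
                 n_features = c(human = as.integer(n_human),
                                mouse = as.integer(n_mouse),
                                particle = as.integer(n_particle)),
                 informative_pos = lapply(informative_pos, as.integer),
                 informative_neg = as.integer(informative_neg),
                 effect_pos = effect_pos, effect_neg = effect_neg,
                 noise_sd = noise_sd, control_shift = control_shift,
                 outcome_link = link, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  substances: %d extracts + %d controls\n",
              x$n_extracts, x$n_controls))
  cat(sprintf("  features:   %d human, %d mouse cytokines; %d particle populations\n",
              x$n_features["human"], x$n_features["mouse"],
              x$n_features["particle"]))
  cat(sprintf("  planted:    %d + %d positive cytokines; negative population index %d\n",
              length(x$informative_pos$human), length(x$informative_pos$mouse),
              x$informative_neg))
  cat(sprintf("  effects:    pos %.2f, neg %.2f; noise sd %.2f; seed %d\n",
              x$effect_pos, x$effect_neg, x$noise_sd, x$seed))
  invisible(x)
}

human_cytokine_names <- function(n) {
  base <- c("hIL1b", "hIL2", "hIL4", "hIL5", "hIL6", "hIL7", "hIL8", "hIL10",
            "hIL12p70", "hIL13", "hIL17", "hGCSF", "hGMCSF", "hIFNg", "hMCP1",
            "hMIP1b", "hTNFa", "hIFNa")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("hCK%02d", seq_len(n - length(base))))
}

mouse_cytokine_names <- function(n) {
  base <- c("mIL1a", "mIL1b", "mIL2", "mIL3", "mIL4", "mIL5", "mIL6", "mIL9",
            "mIL10", "mIL12p40", "mIL12p70", "mIL13", "mIL17A", "mEotaxin",
            "mGCSF", "mGMCSF", "mIFNg", "mKC", "mMCP1", "mMIP1a", "mMIP1b",
            "mRANTES", "mTNFa")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("mCK%02d", seq_len(n - length(base))))
}

particle_population_names <- function(n) {
  if (n <= 26L) LETTERS[seq_len(n)] else sprintf("P%02d", seq_len(n))
}

#' Generate a synthetic screening cohort
#'
#' Draws one cohort from the latent-factor model described in [sim_config()].
#' Cytokine concentrations are log-normal: informative features carry
#' `effect_pos * z_pos` on the log scale plus Gaussian noise, the rest are pure
#' noise, and the block is exponentiated so all entries are positive. The
#' particle block is compositional: Gaussian log-abundances (the negative
#' population's raised by `effect_neg * z_neg`) are passed through a softmax
#' and scaled to percentages summing to 100. Outcome endpoints are
#' `exp(w_pos * z_pos - w_neg * z_neg + noise)`, so fold changes are positive
#' and decrease with the negative factor.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `sim_cohort`: a list with
#'   \item{blocks}{named list of `human`, `mouse`, `particle` matrices
#'     (substances x features; particle rows sum to 100);}
#'   \item{outcomes}{data frame of the six endpoints;}
#'   \item{truth}{the planted signal: `z_pos`, `z_neg`, informative feature
#'     indices per block, and the noise-free outcome means.}
#' @examples
#' coh <- generate_cohort(sim_config(seed = 7))
#' rowSums(coh$blocks$particle)[1:3]
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be created with sim_config()", call. = FALSE)
  }
  n <- config$n_extracts + config$n_controls
  ids <- c(sprintf("EXT%03d", seq_len(config$n_extracts)),
           if (config$n_controls > 0) sprintf("ADJ%02d", seq_len(config$n_controls)))
  is_control <- c(rep(FALSE, config$n_extracts), rep(TRUE, config$n_controls))
  with_seed(config$seed, {
    z_pos <- stats::rnorm(n) + config$control_shift * is_control
    z_neg <- stats::rnorm(n)

    make_cyto <- function(p, inf, namer) {
      m <- matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
      m[, inf] <- m[, inf] + config$effect_pos * z_pos
      m <- exp(m)
      dimnames(m) <- list(ids, namer(p))
      m
    }
    human <- make_cyto(config$n_features["human"], config$informative_pos$human,
                       human_cytokine_names)
    mouse <- make_cyto(config$n_features["mouse"], config$informative_pos$mouse,
                       mouse_cytokine_names)

    pp <- config$n_features["particle"]
    la <- matrix(stats::rnorm(n * pp, sd = config$noise_sd), n, pp)
    la[, config$informative_neg] <- la[, config$informative_neg] +
      config$effect_neg * z_neg
    ela <- exp(la)
    particle <- 100 * ela / rowSums(ela)
    dimnames(particle) <- list(ids, particle_population_names(pp))

    link <- config$outcome_link
    out <- sapply(seq_len(nrow(link)), function(i) {
      exp(link$w_pos[i] * z_pos - link$w_neg[i] * z_neg +
            stats::rnorm(n, sd = config$noise_sd))
    })
    colnames(out) <- link$endpoint
    rownames(out) <- ids
    true_means <- sapply(seq_len(nrow(link)), function(i) {
      exp(link$w_pos[i] * z_pos - link$w_neg[i] * z_neg)
    })
    colnames(true_means) <- link$endpoint

    structure(list(
      blocks = list(human = human, mouse = mouse, particle = particle),
      outcomes = as.data.frame(out),
      truth = list(z_pos = z_pos, z_neg = z_neg,
                   informative = list(human = config$informative_pos$human,
                                      mouse = config$informative_pos$mouse,
                                      particle = config$informative_neg),
                   is_control = is_control,
                   true_outcome_means = true_means),
      config = config), class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d substances (%d extracts + %d controls)\n",
              nrow(x$blocks$human), x$config$n_extracts, x$config$n_controls))
  cat(sprintf("  blocks: human %df, mouse %df, particle %df; 6 endpoints\n",
              ncol(x$blocks$human), ncol(x$blocks$mouse),
              ncol(x$blocks$particle)))
  invisible(x)
}

#' Simulate raw flow-cytometry scatter events for one sample
#'
#' Draws `n_events` events from a multinomial over the 16 grid populations and
#' places each uniformly (on the log10 scale) inside its gate cell, so that
#' re-gating through [population_counts()] recovers the multinomial draw
#' exactly. A paired blank (buffer-only acquisition, same flow rate and
#' duration) is produced with a Poisson number of events per population.
#'
#' @param grid a [gate_grid()].
#' @param population_probs length-16 probability vector (A..P order), summing
#'   to 1.
#' @param n_events number of sample events to draw.
#' @param blank_rate expected blank events per population (Poisson mean).
#' @param seed integer seed.
#' @return list with `sample` and `blank` event data frames (columns `fsc`,
#'   `ssc`), and the generating `sample_counts` / `blank_counts` (named A..P).
#' @export
generate_event_table <- function(grid, population_probs, n_events,
                                 blank_rate = 0, seed = 1L) {
  if (!inherits(grid, "gate_grid")) stop("`grid` must be a gate_grid object",
                                         call. = FALSE)
  if (length(population_probs) != 16L) {
    stop("`population_probs` must have length 16", call. = FALSE)
  }
  if (any(population_probs < 0) || any(!is.finite(population_probs))) {
    stop("`population_probs` must be non-negative and finite", call. = FALSE)
  }
  if (abs(sum(population_probs) - 1) > 1e-8) {
    stop("`population_probs` must sum to 1", call. = FALSE)
  }
  stop_if_not_count(n_events, "n_events", min = 1L)
  if (blank_rate < 0) stop("`blank_rate` must be >= 0", call. = FALSE)

  cells <- grid_cells(grid)  # per letter: log10 bounds of the cell
  draw_events <- function(counts) {
    pops <- rep(seq_len(16L), counts)
    kn <- sum(counts)
    if (kn == 0L) {
      return(data.frame(fsc = numeric(0), ssc = numeric(0)))
    }
    lf <- stats::runif(kn, cells$fsc_lo[pops], cells$fsc_hi[pops])
    ls <- stats::runif(kn, cells$ssc_lo[pops], cells$ssc_hi[pops])
    data.frame(fsc = 10^lf, ssc = 10^ls)
  }
  with_seed(seed, {
    pop_draw <- sample.int(16L, n_events, replace = TRUE,
                           prob = population_probs)
    sample_counts <- tabulate(pop_draw, nbins = 16L)
    blank_counts <- if (blank_rate > 0) stats::rpois(16L, blank_rate) else
      integer(16L)
    names(sample_counts) <- names(blank_counts) <- LETTERS[1:16]
    list(sample = draw_events(sample_counts),
         blank = draw_events(blank_counts),
         sample_counts = sample_counts,
         blank_counts = blank_counts)
  })
}

#' Simulate an ELISA endpoint-titer dilution series
#'
#' Builds a serial-dilution OD450 curve whose piecewise log-linear
#' interpolation crosses the cutoff absorbance exactly at `true_titer`: the
#' two dilution points bracketing `true_titer` lie on a line in
#' (log10 dilution, OD) through (log10 `true_titer`, `cutoff`), and the curve
#' is extended outward strictly monotonically towards `od_max` and `od_floor`.
#' [titer_from_od()] therefore recovers `true_titer` exactly; series whose
#' true titer falls outside the dilution range are flagged for censoring
#' tests.
#'
#' @param true_titer reciprocal dilution at which the curve crosses the
#'   cutoff.
#' @param dilution_start smallest reciprocal dilution.
#' @param dilution_factor serial dilution factor (> 1).
#' @param n_points number of dilution points (>= 2).
#' @param od_max,od_floor asymptotic OD bounds of the generated curve.
#' @param cutoff cutoff absorbance the curve crosses at `true_titer`.
#' @param seed integer seed.
#' @return An object of class `dilution_series`: list with `dilutions`,
#'   `od`, `true_titer`, and `flagged` (TRUE when `true_titer` is outside the
#'   dilution range).
#' @export
generate_dilution_series <- function(true_titer, dilution_start = 100,
                                     dilution_factor = 4, n_points = 8,
                                     od_max = 3, od_floor = 0.05,
                                     cutoff = 0.2, seed = 1L) {
  stop_if_not_count(n_points, "n_points", min = 2L)
  if (dilution_start <= 0 || dilution_factor <= 1) {
    stop("dilution_start must be > 0 and dilution_factor > 1", call. = FALSE)
  }
  if (!(od_floor < cutoff && cutoff < od_max)) {
    stop("need od_floor < cutoff < od_max", call. = FALSE)
  }
  if (true_titer <= 0) stop("`true_titer` must be positive", call. = FALSE)
  d <- dilution_start * dilution_factor^(0:(n_points - 1L))
  ld <- log10(d)
  lt <- log10(true_titer)
  flagged <- true_titer < d[1] || true_titer > d[n_points]

  with_seed(seed, {
    od <- numeric(n_points)
    if (!flagged) {
      # local log-linear segment through (log10 true_titer, cutoff)
      gap <- log10(dilution_factor)
      slope_ub <- 0.9 * min(od_max - cutoff, cutoff - od_floor) / gap
      slope <- stats::runif(1, min(0.1, slope_ub / 2), slope_ub)
      k <- findInterval(lt, ld, rightmost.closed = TRUE)
      od[k] <- cutoff + slope * (lt - ld[k])
      if (k < n_points) od[k + 1L] <- cutoff - slope * (ld[k + 1L] - lt)
      hi <- if (k < n_points) k + 1L else k
      for (i in rev(seq_len(k - 1L))) {
        od[i] <- od[i + 1L] + stats::runif(1, 0.3, 0.7) * (od_max - od[i + 1L])
      }
      if (hi < n_points) {
        for (i in (hi + 1L):n_points) {
          od[i] <- od[i - 1L] - stats::runif(1, 0.3, 0.7) * (od[i - 1L] - od_floor)
        }
      }
    } else if (true_titer < d[1]) {
      # whole curve below cutoff
      od[1] <- od_floor + stats::runif(1, 0.5, 0.9) * (cutoff - od_floor)
      if (n_points > 1) for (i in 2:n_points) {
        od[i] <- od[i - 1L] - stats::runif(1, 0.3, 0.7) * (od[i - 1L] - od_floor)
      }
    } else {
      # whole curve above cutoff
      od[n_points] <- cutoff + stats::runif(1, 0.1, 0.5) * (od_max - cutoff)
      if (n_points > 1) for (i in rev(seq_len(n_points - 1L))) {
        od[i] <- od[i + 1L] + stats::runif(1, 0.3, 0.7) * (od_max - od[i + 1L])
      }
    }
    structure(list(dilutions = d, od = od, true_titer = true_titer,
                   cutoff = cutoff, flagged = flagged),
              class = "dilution_series")
  })
}

#' @export
print.dilution_series <- function(x, ...) {
  cat(sprintf("Dilution series: %d points, 1/%g .. 1/%g%s\n",
              length(x$dilutions), x$dilutions[1],
              x$dilutions[length(x$dilutions)],
              if (x$flagged) " [true titer outside range]" else ""))
  print(data.frame(dilution = x$dilutions, od = round(x$od, 4)))
  invisible(x)
}
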