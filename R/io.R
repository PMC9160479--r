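# Delimited-text readers/writers, run manifests, and the pipeline driver.

delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") "," else "\t"
}

#' Read a feature block from delimited text
#'
#' Expects a header row of feature names and a first column of substance ids;
#' the delimiter is sniffed from the extension (`.csv` comma, anything else
#' tab). Duplicate substance ids, non-numeric cells, and empty files are
#' errors.
#'
#' @param path file path.
#' @return numeric matrix with substance ids as row names.
#' @export
read_block <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop(sprintf("empty or malformed block file: %s", path), call. = FALSE)
  }
  ids <- df[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("duplicate substance id(s) in %s: %s", path,
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  vals <- df[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(ids, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    x <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(x) & !is.na(vals[[j]]))
    if (length(bad) || anyNA(vals[[j]])) {
      r <- if (length(bad)) bad[1] else which(is.na(vals[[j]]))[1]
      stop(sprintf("non-numeric or missing cell in %s at row %d, column '%s'",
                   path, r, colnames(vals)[j]), call. = FALSE)
    }
    m[, j] <- x
  }
  m
}

#' Write a feature block as delimited text
#'
#' @param block numeric matrix with substance-id row names.
#' @param path output path (`.csv` comma, otherwise tab).
#' @param id_name header of the substance-id column.
#' @export
write_block <- function(block, path, id_name = "substance") {
  block <- as_numeric_matrix(block, "block")
  if (is.null(rownames(block))) stop("block must have substance-id row names",
                                     call. = FALSE)
  df <- data.frame(rownames(block), block, check.names = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read raw scatter events from CSV
#'
#' @param path CSV with columns `fsc`, `ssc` (one row per event).
#' @return event data frame.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("fsc", "ssc") %in% names(df))) {
    stop(sprintf("%s must have columns fsc and ssc", path), call. = FALSE)
  }
  df[, c("fsc", "ssc")]
}

#' Write raw scatter events to CSV
#'
#' @param events data frame with `fsc`, `ssc`.
#' @param path output path.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events[, c("fsc", "ssc")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records tool version, input digests, hyperparameters and seeds as
#' `key: value` lines so a run can be reproduced bit-identically.
#'
#' @param params named list of scalar parameters; list-valued entries are
#'   collapsed with commas.
#' @param path output path.
#' @param inputs character vector of input file paths to digest (md5).
#' @export
write_manifest <- function(params, path, inputs = character(0)) {
  lines <- c(sprintf("tool_version: %s",
                     as.character(utils::packageVersion("adjuscreen"))),
             sprintf("timestamp: %s",
                     format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  for (f in inputs) {
    lines <- c(lines, sprintf("input_md5 %s: %s", basename(f),
                              unname(tools::md5sum(f))))
  }
  for (nm in names(params)) {
    lines <- c(lines, sprintf("%s: %s", nm,
                              paste(format(params[[nm]]), collapse = ",")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a run manifest back into a named character list
#'
#' @param path manifest path.
#' @return named list of character values.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  kv <- regmatches(lines, regexpr(": ", lines), invert = TRUE)
  out <- lapply(kv, function(x) if (length(x) == 2) x[2] else NA_character_)
  names(out) <- vapply(kv, `[[`, character(1), 1L)
  out
}

#' Run the full screening pipeline
#'
#' Generates (or reads) a cohort, fits the discriminant multiblock model per
#' endpoint, applies the screening battery, and writes every artifact as
#' delimited text plus a run manifest into `out_dir`: the three block TSVs,
#' the outcome TSV, a selected-features table, a screening-statistics table,
#' a plain-text report, and `manifest.txt`.
#'
#' @param config list with either `sim` (a [sim_config()]) or `inputs`
#'   (named paths `human`, `mouse`, `particle`, `outcomes`); optional
#'   `keepX` (default 10) and `n_comp` (default 1).
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, the `screening_report`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  keepX <- config$keepX %||% 10
  n_comp <- config$n_comp %||% 1

  stage <- "input"
  result <- tryCatch({
    if (!is.null(config$sim)) {
      stage <- "simulate"
      coh <- generate_cohort(config$sim)
      blocks <- coh$blocks
      outcomes <- coh$outcomes
      say("[simulate] %d substances, blocks %s", nrow(blocks$human),
          paste(vapply(blocks, ncol, 1L), collapse = "/"))
      inputs <- character(0)
    } else {
      stage <- "read"
      paths <- config$inputs
      need <- c("human", "mouse", "particle", "outcomes")
      if (is.null(paths) || !all(need %in% names(paths))) {
        stop("config$inputs must name human, mouse, particle, outcomes files")
      }
      blocks <- lapply(paths[c("human", "mouse", "particle")], read_block)
      outcomes <- as.data.frame(read_block(paths[["outcomes"]]))
      inputs <- unlist(paths[need])
      say("[read] %d substances", nrow(blocks$human))
    }
    stage <- "assemble"
    asm <- assemble_blocks(blocks$human, blocks$mouse, blocks$particle,
                           outcomes)
    say("[assemble] canonical order over %d substances", nrow(asm$outcomes))
    for (b in names(asm$blocks)) {
      write_block(asm$blocks[[b]], file.path(out_dir, paste0(b, "_block.tsv")))
    }
    write_block(as.matrix(asm$outcomes), file.path(out_dir, "outcomes.tsv"))
    stage <- "integrate+screen"
    rep <- screening_report(asm$blocks, asm$outcomes, keepX = keepX,
                            n_comp = n_comp)
    say("[screen] %d endpoint sections", length(rep))
    sel <- do.call(rbind, lapply(rep, function(s) {
      cbind(endpoint = s$endpoint, s$selected)
    }))
    utils::write.table(sel, file.path(out_dir, "selected_features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stats_tab <- do.call(rbind, lapply(rep, function(s) {
      data.frame(endpoint = s$endpoint,
                 applicable = s$applicable,
                 positive_parameter = s$positive_parameter %||% NA,
                 negative_parameter = s$negative_parameter %||% NA,
                 single_step_p = if (!is.null(s$single_step))
                   s$single_step$p_value else NA,
                 two_step_p = if (inherits(s$two_step, "screening_result"))
                   s$two_step$p_value else NA,
                 pca_p = if (inherits(s$pca, "screening_result"))
                   s$pca$p_value else NA)
    }))
    utils::write.table(stats_tab, file.path(out_dir, "screening_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    txt <- utils::capture.output(print(rep))
    writeLines(txt, file.path(out_dir, "report.txt"))
    write_manifest(list(keepX = keepX, n_comp = n_comp,
                        seed = if (!is.null(config$sim)) config$sim$seed else NA,
                        n_substances = nrow(asm$outcomes)),
                   file.path(out_dir, "manifest.txt"), inputs = inputs)
    rep
  }, error = function(e) {
    writeLines(sprintf("FAILED at stage '%s': %s", stage,
                       conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
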