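# Internal helpers shared across modules.

# Evaluate expr with a local RNG state seeded at `seed`, restoring the caller's
# state afterwards. seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_if_not_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a whole number >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

as_numeric_matrix <- function(x, name = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  x
}

# Column-center a matrix (no scaling).
center_cols <- function(x) sweep(x, 2L, colMeans(x), "-")

# Unit L2 normalization; zero vectors are returned unchanged.
l2_normalize <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv > 0) v / nv else v
}

# Flip the sign of a vector so its largest-magnitude entry is positive
# (deterministic orientation convention used throughout the package).
sign_fix <- function(v) {
  i <- which.max(abs(v))
  if (length(i) && v[i] < 0) -v else v
}
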