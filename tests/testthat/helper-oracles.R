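# Independent reference implementations used as oracles. These deliberately
# take different computational routes than the package code they check.

# Classical CCA via the generalized eigenproblem on Sxx^-1 Sxy Syy^-1 Syx,
# solved with plain solve()/eigen() (no whitening, no SVD).
oracle_cca_correlations <- function(x, y) {
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  n <- nrow(x)
  sxx <- crossprod(xc) / (n - 1)
  syy <- crossprod(yc) / (n - 1)
  sxy <- crossprod(xc, yc) / (n - 1)
  m <- solve(sxx) %*% sxy %*% solve(syy) %*% t(sxy)
  ev <- sort(Re(eigen(m)$values), decreasing = TRUE)
  sqrt(pmax(pmin(ev[seq_len(min(ncol(x), ncol(y)))], 1), 0))
}

# Textbook NIPALS PLS2 (regression mode): w from X'u, t = Xw, q from Y't,
# u = Yq; X deflated on t, Y deflated on its regression onto t.
oracle_nipals_pls2 <- function(x, y, n_comp, tol = 1e-12, max_iter = 1000) {
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  p <- ncol(x)
  w_out <- matrix(0, p, n_comp)
  for (h in seq_len(n_comp)) {
    u <- yc[, which.max(apply(yc, 2, var)), drop = FALSE]
    w <- NULL
    for (i in seq_len(max_iter)) {
      w_new <- crossprod(xc, u)
      w_new <- w_new / sqrt(sum(w_new^2))
      t_ <- xc %*% w_new
      q <- crossprod(yc, t_)
      q <- q / sqrt(sum(q^2))
      u_new <- yc %*% q
      if (!is.null(w) && sqrt(sum((w_new - w)^2)) < tol) {
        w <- w_new
        break
      }
      w <- w_new
      u <- u_new
    }
    t_ <- xc %*% w
    w_out[, h] <- w
    cvec <- crossprod(xc, t_) / sum(t_^2)
    xc <- xc - t_ %*% t(cvec)
    yc <- yc - t_ %*% t(crossprod(yc, t_) / sum(t_^2))
  }
  w_out
}

# Exhaustive permutation two-sample pooled-t p-value (Monte Carlo).
oracle_permutation_p <- function(values, mask, n_perm = 4000, seed = 1) {
  obs <- abs(pooled_t(values, mask))
  n <- length(values)
  k <- sum(mask)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    pm <- logical(n)
    pm[sample.int(n, k)] <- TRUE
    if (abs(pooled_t(values, pm)) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

pooled_t <- function(values, mask) {
  a <- values[mask]
  b <- values[!mask]
  n1 <- length(a)
  n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Fine-grid evaluation of the log-linear titer interpolation: linear
# interpolation of OD against log10 dilution on a dense grid, first grid
# point at/below the cutoff.
oracle_titer_grid <- function(dilutions, od, cutoff = 0.2, n_grid = 2e5) {
  lg <- seq(log10(dilutions[1]), log10(dilutions[length(dilutions)]),
            length.out = n_grid)
  og <- approx(log10(dilutions), od, xout = lg)$y
  10^lg[which(og <= cutoff)[1]]
}

# Small aligned synthetic block set with row names, for io/assembly tests.
make_named_blocks <- function(n = 6, seed = 1) {
  set.seed(seed)
  ids <- sprintf("S%02d", seq_len(n))
  hum <- matrix(rexp(n * 4), n, 4, dimnames = list(ids, paste0("h", 1:4)))
  mou <- matrix(rexp(n * 3), n, 3, dimnames = list(ids, paste0("m", 1:3)))
  raw <- matrix(rexp(n * 16), n, 16,
                dimnames = list(ids, LETTERS[1:16]))
  par <- 100 * raw / rowSums(raw)
  out <- data.frame(totalIgG_fc = rexp(n), igg1_fc = rexp(n),
                    row.names = ids)
  list(human = hum, mouse = mou, particle = par, outcomes = out)
}
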