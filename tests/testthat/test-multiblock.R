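test_that("soft_select thresholds by the largest excluded magnitude", {
  out <- soft_select(c(3, -1, 2), keep = 2)
  expect_equal(which(out != 0), c(1L, 3L))
  expect_equal(out, c(2, 0, 1) / sqrt(5))
  # dense limit preserves direction
  v <- c(0.3, -2, 1.1)
  expect_equal(soft_select(v, 3), v / sqrt(sum(v^2)))
  expect_warning(kept <- soft_select(v, 10), "exceeds")
  expect_equal(kept, v / sqrt(sum(v^2)))
  # boundary tie: lowest index survives
  tie <- soft_select(c(2, -2), keep = 1)
  expect_equal(tie, c(1, 0))
})

test_that("dense single-block PLS1 weight equals X'y normalized", {
  set.seed(1)
  x <- scale(matrix(rnorm(200), 20, 10))
  y <- rnorm(20)
  fit <- block_spls(list(x = x), y, keepX = 10, n_comp = 1)
  ref <- crossprod(scale(x, scale = FALSE), y - mean(y))[, 1]
  ref <- ref / sqrt(sum(ref^2))
  if (ref[which.max(abs(ref))] < 0) ref <- -ref
  expect_equal(unname(fit$weights$x[, 1]), unname(ref), tolerance = 1e-8)
})

test_that("keepX = 1 picks the feature with maximal |covariance| with y", {
  for (s in 1:5) {
    set.seed(s)
    x <- scale(matrix(rnorm(30 * 8), 30, 8))
    y <- rnorm(30)
    fit <- block_spls(list(x = x), y, keepX = 1, n_comp = 1)
    brute <- which.max(abs(cov(x, y)))
    expect_equal(unname(fit$selected$x[[1]]), brute)
  }
})

test_that("dense single-block fits reproduce NIPALS PLS2 weights up to sign", {
  set.seed(2)
  x <- scale(matrix(rnorm(25 * 6), 25, 6))
  y <- scale(matrix(rnorm(25 * 3), 25, 3))
  fit <- block_spls(list(x = x), y, keepX = 6, n_comp = 2, tol = 1e-11)
  ref <- oracle_nipals_pls2(x, y, n_comp = 2)
  for (h in 1:2) {
    w <- fit$weights$x[, h]
    r <- ref[, h]
    expect_lt(min(max(abs(w - r)), max(abs(w + r))), 1e-8)
  }
})

test_that("weight and score invariants hold on random fits", {
  set.seed(3)
  blocks <- list(a = scale(matrix(rnorm(40 * 7), 40, 7)),
                 b = scale(matrix(rnorm(40 * 5), 40, 5)))
  y <- scale(matrix(rnorm(80), 40, 2))
  fit <- block_spls(blocks, y, keepX = c(3, 2), n_comp = 2)
  for (b in names(blocks)) {
    for (h in 1:2) {
      w <- fit$weights[[b]][, h]
      expect_equal(sum(w^2), 1, tolerance = 1e-10)
      expect_lte(sum(w != 0), fit$keepX[b])
      expect_lt(abs(mean(fit$scores[[b]][, h])), 1e-10)
    }
  }
})

test_that("dichotomize splits at the mean with ties going low", {
  lab <- dichotomize(c(1, 2, 3, 4))
  expect_equal(as.character(lab), c("low", "low", "high", "high"))
  # value exactly at the mean goes low
  lab2 <- dichotomize(c(0, 2, 4))  # mean 2
  expect_equal(as.character(lab2)[2], "low")
  expect_error(dichotomize(c(3, 3, 3)), "distinct")
  # both classes always populated
  set.seed(4)
  for (s in 1:10) {
    v <- rexp(15)
    expect_equal(nlevels(droplevels(dichotomize(v))), 2)
  }
})

test_that("splsda recovers planted separating features with dominant class high", {
  set.seed(5)
  n <- 40
  cl <- rep(c("low", "high"), each = n / 2)
  x <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  x[cl == "high", 1:3] <- x[cl == "high", 1:3] + 5
  fit <- block_splsda(list(x = scale(x)), cl, keepX = 3)
  sel <- selected_features(fit)
  expect_setequal(sel$feature, c("f1", "f2", "f3"))
  expect_true(all(sel$dominant_class == "high"))

  # label swap keeps the selection, swaps the dominant classes
  swapped <- ifelse(cl == "high", "low", "high")
  fit2 <- block_splsda(list(x = scale(x)), swapped, keepX = 3)
  sel2 <- selected_features(fit2)
  expect_setequal(sel2$feature, sel$feature)
  expect_true(all(sel2$dominant_class == "low"))
})

test_that("splsda is invariant to joint row permutation", {
  coh <- generate_cohort(sim_config(seed = 9))
  sc <- lapply(coh$blocks, scale_columns)
  cl <- dichotomize(coh$outcomes$totalIgG_fc)
  fit <- block_splsda(sc, cl, keepX = 10)
  set.seed(6)
  perm <- sample(length(cl))
  fit_p <- block_splsda(lapply(sc, function(b) b[perm, ]), cl[perm],
                        keepX = 10)
  for (b in names(fit$weights)) {
    expect_equal(fit_p$weights[[b]], fit$weights[[b]], tolerance = 1e-6)
  }
})

test_that("keepX = 10 yields ten selected features per block on component 1", {
  coh <- generate_cohort(sim_config(seed = 2))
  sc <- lapply(coh$blocks, scale_columns)
  fit <- block_splsda(sc, dichotomize(coh$outcomes$totalIgG_fc), keepX = 10)
  for (b in names(fit$selected)) {
    expect_length(fit$selected[[b]][[1]], 10)
  }
  expect_error(block_splsda(sc, rep("high", nrow(sc$human)), keepX = 10),
               "two classes")
})

test_that("tuning reaches zero CV error on separable classes and keeps ties sparse", {
  set.seed(7)
  n <- 40
  cl <- rep(c("low", "high"), each = n / 2)
  x <- matrix(rnorm(n * 6), n, 6)
  x[cl == "high", 1:2] <- x[cl == "high", 1:2] + 6
  res <- tune_block_splsda(list(x = x), cl, keepX_grid = c(1, 2, 4),
                           folds = 5, repeats = 3, seed = 1)
  expect_equal(min(res$error_table$balanced_error), 0)
  expect_equal(res$keepX, 1)  # tie broken towards sparsity
  single <- tune_block_splsda(list(x = x), cl, keepX_grid = 2,
                              folds = 5, repeats = 2, seed = 1)
  expect_equal(single$keepX, 2)
  expect_equal(nrow(single$error_table), 1)
  small <- rep(c("low", "high"), 3)
  expect_error(tune_block_splsda(list(x = x[1:6, ]), small, 2, folds = 5),
               "folds")
})

test_that("non-convergence raises a condition carrying the last iterate", {
  set.seed(8)
  x <- scale(matrix(rnorm(100), 20, 5))
  y <- rnorm(20)
  err <- tryCatch(block_spls(list(x = x), y, keepX = 3, max_iter = 1,
                             tol = 1e-300),
                  adjuscreen_no_convergence = function(e) e)
  expect_s3_class(err, "adjuscreen_no_convergence")
  expect_true(!is.null(err$model))
})
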