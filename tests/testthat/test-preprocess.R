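test_that("titer interpolation matches the fine-grid oracle and handles exact hits", {
  # cutoff falls exactly on a measured point
  res <- titer_from_od(c(400, 800), c(0.35, 0.2))
  expect_equal(res$titer, 800)
  expect_equal(res$censored, "none")

  # interior crossing: compare with dense-grid evaluation of the same rule
  d <- c(100, 400, 1600)
  od <- c(0.8, 0.35, 0.1)
  res <- titer_from_od(d, od)
  expect_equal(res$titer, 400 * 4^((0.35 - 0.2) / (0.35 - 0.1)),
               tolerance = 1e-10)
  expect_equal(res$titer, oracle_titer_grid(d, od), tolerance = 1e-3)

  # censoring rules
  low <- titer_from_od(c(100, 400), c(0.15, 0.05))
  expect_equal(low$censored, "low")
  expect_equal(low$titer, 100)
  high <- titer_from_od(c(100, 400), c(1.5, 0.9))
  expect_equal(high$censored, "high")
  expect_equal(high$titer, 400)
})

test_that("titer interpolation is invariant to redundant collinear points", {
  d <- c(100, 400, 1600)
  od <- c(0.8, 0.35, 0.1)
  base <- titer_from_od(d, od)$titer
  # insert a point on the segment between the bracketing pair (log-linear)
  lmid <- (log10(400) + log10(1600)) / 2
  omid <- 0.35 + (0.1 - 0.35) * 0.5
  res <- titer_from_od(c(100, 400, 10^lmid, 1600), c(0.8, 0.35, omid, 0.1))
  expect_equal(res$titer, base, tolerance = 1e-10)
})

test_that("non-monotone series warn and use the first crossing", {
  expect_warning(
    res <- titer_from_od(c(100, 400, 1600, 6400), c(0.5, 0.1, 0.4, 0.1)),
    "more than once")
  expect_lt(res$titer, 400)
  expect_error(titer_from_od(numeric(0), numeric(0)), "empty|>= 2")
})

test_that("fold change is the ratio of group means and is scale invariant", {
  expect_equal(fold_change(c(5000, 5000), 1000), 5)
  expect_equal(fold_change(c(2, 4), c(2, 4)), 1)
  expect_equal(fold_change(c(100, 300), c(50, 150)), 2)
  g <- rexp(5) + 1
  r <- rexp(3) + 1
  expect_equal(fold_change(7 * g, 7 * r), fold_change(g, r))
  expect_error(fold_change(c(1, 2), c(0, 0)), "positive")
  expect_error(fold_change(numeric(0), 1), "non-empty")
})

test_that("background subtraction floors at zero and rejects negative input", {
  expect_equal(background_subtract(120, 20), 100)
  expect_equal(background_subtract(10, 25), 0)
  expect_equal(background_subtract(c(5, 7), c(2, 4)), 3)
  expect_error(background_subtract(c(-1, 3), 1), "non-negative")
  for (s in 1:10) {
    set.seed(s)
    expect_gte(background_subtract(rexp(4), rexp(4) * 3), 0)
  }
})

test_that("assemble_blocks aligns shuffled tables to one canonical order", {
  tb <- make_named_blocks(n = 5, seed = 3)
  shuffle <- function(m) m[sample(nrow(m)), , drop = FALSE]
  set.seed(1)
  asm <- assemble_blocks(shuffle(tb$human), shuffle(tb$mouse),
                         shuffle(tb$particle), tb$outcomes[sample(5), ])
  ids <- rownames(asm$blocks$human)
  expect_identical(ids, sort(rownames(tb$human)))
  expect_identical(rownames(asm$blocks$mouse), ids)
  expect_identical(rownames(asm$blocks$particle), ids)
  expect_identical(rownames(asm$outcomes), ids)
  expect_equal(asm$blocks$human[ids, ], tb$human[ids, ])
})

test_that("assemble_blocks reports offending substances and bad rows", {
  tb <- make_named_blocks(n = 4, seed = 2)
  expect_error(assemble_blocks(tb$human, tb$mouse[-2, ], tb$particle,
                               tb$outcomes), "S02")
  bad <- tb$particle
  bad[1, 1] <- bad[1, 1] + 3  # row no longer sums to 100
  expect_error(assemble_blocks(tb$human, tb$mouse, bad, tb$outcomes),
               "not summing to 100")
  nan <- tb$human
  nan[2, 2] <- NaN
  expect_error(assemble_blocks(nan, tb$mouse, tb$particle, tb$outcomes),
               "non-finite|missing")
})

test_that("scale_columns standardizes and drops zero-variance columns", {
  expect_equal(as.vector(scale_columns(matrix(c(1, 2, 3), ncol = 1))),
               c(-1, 0, 1))
  x <- cbind(a = rnorm(5), b = rep(2, 5), c = rnorm(5))
  expect_warning(s <- scale_columns(x), "zero-variance")
  expect_identical(attr(s, "dropped"), "b")
  expect_equal(ncol(s), 2)
  set.seed(8)
  m <- matrix(rnorm(15), 5, 3)
  sm <- scale_columns(m)
  expect_true(all(abs(colMeans(sm)) < 1e-12))
  expect_true(all(abs(apply(sm, 2, sd) - 1) < 1e-12))
  expect_error(scale_columns(matrix(1, 3, 2)), "zero variance")
})
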