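test_that("threshold screens pass the documented masks", {
  # hG-CSF-style positive screen at an explicit threshold
  res <- threshold_screen(c(0.5, 0.2, 1.0), threshold = 0.39,
                          direction = "positive")
  expect_equal(res$mask, c(TRUE, FALSE, TRUE))
  # population-M-style negative screen
  res <- threshold_screen(c(1.0, 3.0), threshold = 1.98,
                          direction = "negative")
  expect_equal(res$mask, c(TRUE, FALSE))
  # auto-mean threshold
  res <- threshold_screen(c(1, 3), direction = "positive")
  expect_equal(res$threshold, 2)
  expect_equal(res$mask, c(FALSE, TRUE))
  expect_error(threshold_screen(c(2, 2, 2)), "degenerate|constant")
})

test_that("the two-step screen is the AND of its steps and reports survivors", {
  res <- two_step_screen(neg_values = c(1.0, 1.0, 3.0),
                         pos_values = c(0.5, 0.1, 0.9),
                         neg_threshold = 1.98, pos_threshold = 0.39)
  expect_equal(res$mask, c(TRUE, FALSE, FALSE))
  expect_equal(unname(res$survivors), c(2, 1))
  # with an always-passing positive threshold it reduces to the negative step
  res2 <- two_step_screen(c(1, 3, 2), c(5, 6, 7), neg_threshold = 2.5,
                          pos_threshold = 0)
  expect_equal(res2$mask, res2$neg$mask)
  # subset relation holds on random screens
  set.seed(1)
  for (s in 1:10) {
    nv <- rexp(20)
    pv <- rexp(20)
    r <- two_step_screen(nv, pv)
    expect_true(all(r$mask[r$mask] %in% r$neg$mask[r$mask]))
    expect_true(all(!r$mask | r$neg$mask))
  }
  expect_error(two_step_screen(1:3, 1:4), "aligned")
})

test_that("separation_test reproduces the closed-form pooled t", {
  res <- separation_test(c(5, 6, 7, 1, 2, 3),
                         c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$t_statistic, 4.899, tolerance = 1e-3)
  expect_equal(res$degrees_of_freedom, 4)
  expect_equal(res$p_value, 0.0080, tolerance = 1e-2)
  # identical groups
  same <- separation_test(rep(c(1, 2), 4), rep(c(TRUE, FALSE), each = 4))
  expect_equal(same$p_value, 1)
  expect_equal(same$t_statistic, 0)
  # swapping labels flips t, keeps p
  m <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  v <- c(5, 4, 1, 2, 6, 1.5)
  a <- separation_test(v, m)
  b <- separation_test(v, !m)
  expect_equal(a$t_statistic, -b$t_statistic)
  expect_equal(a$p_value, b$p_value)
  expect_error(separation_test(v, c(TRUE, rep(FALSE, 5))), ">= 2")
})

test_that("parametric separation p agrees with a permutation oracle", {
  set.seed(2)
  for (s in 1:10) {
    v <- rnorm(12)
    m <- rep(FALSE, 12)
    m[sample(12, 6)] <- TRUE
    p_param <- separation_test(v, m)$p_value
    p_perm <- oracle_permutation_p(v, m, n_perm = 4000, seed = s)
    mc_se <- sqrt(p_perm * (1 - p_perm) / 4000)
    expect_lt(abs(p_param - p_perm), 0.05 + 3 * mc_se)
  }
})

test_that("correlate matches hand-computed Pearson cases", {
  x <- 1:5
  expect_equal(correlate(x, 2 * x + 1)$r, 1)
  expect_equal(correlate(c(1, 2, 3), c(6, 4, 2))$r, -1)
  expect_equal(correlate(c(1, 2, 3, 4), c(2, 1, 4, 3))$r, 0.6)
  expect_error(correlate(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(correlate(1:2, 1:2), "n >= 3")
})

test_that("PCA discrimination screens planted clusters and ignores column order", {
  set.seed(3)
  n <- 8
  x <- matrix(rnorm(n * 3, sd = 0.3), n, 3,
              dimnames = list(NULL, c("p1", "p2", "p3")))
  x[1:4, ] <- x[1:4, ] + 3  # high cluster on all positive parameters
  outcome <- c(rexp(4) + 5, rexp(4))
  res <- pca_discriminate(x, outcome, positive_parameter_names = c("p1", "p2", "p3"))
  expect_equal(which(res$mask), 1:4)
  expect_lt(abs(mean(res$scores[, 1])), 1e-12)
  # column order invariance
  res2 <- pca_discriminate(x[, c(3, 1, 2)], outcome,
                           positive_parameter_names = c("p1", "p2", "p3"))
  expect_equal(res2$mask, res$mask)
  # global negation preserves the partition, and the orientation rule keeps
  # the screened group anchored to whoever is high on the positive parameters
  # (after negation that is the other cluster)
  res3 <- pca_discriminate(-x, outcome,
                           positive_parameter_names = c("p1", "p2", "p3"))
  expect_equal(res3$mask, !res$mask)
})

test_that("screening_report emits one section per endpoint with the battery", {
  coh <- generate_cohort(sim_config(seed = 13))
  rep1 <- screening_report(coh$blocks, coh$outcomes)
  expect_s3_class(rep1, "screening_report")
  expect_length(rep1, 6)
  expect_named(rep1, colnames(coh$outcomes))
  sec <- rep1$totalIgG_fc
  expect_true(sec$applicable)
  expect_s3_class(sec$single_step, "screening_result")
  expect_true(is.finite(sec$single_step$p_value))
  expect_equal(nrow(sec$selected), 30)  # 10 per block
  # determinism
  rep2 <- screening_report(coh$blocks, coh$outcomes)
  expect_equal(rep1, rep2)
})

test_that("endpoints without positive selected parameters are flagged not applicable", {
  # every cytokine feature carries the positive signal; an inverted endpoint
  # then selects only low-dominant cytokines, so no positive screen exists
  cfg <- sim_config(informative_pos = list(human = 1:18, mouse = 1:23),
                    effect_pos = 2, noise_sd = 0.3, seed = 13)
  coh <- generate_cohort(cfg)
  inverted <- data.frame(ige_delta = 1 / coh$outcomes$totalIgG_fc,
                         row.names = rownames(coh$blocks$human))
  rep1 <- screening_report(coh$blocks, inverted)
  sec <- rep1$ige_delta
  expect_false(sec$applicable)
  expect_null(sec$single_step)
  expect_true(all(sec$selected$dominant_class[
    sec$selected$block %in% c("human", "mouse")] == "low"))
})
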