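test_that("cohort generation is deterministic and structurally valid", {
  cfg <- sim_config(seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  expect_equal(nrow(a$blocks$human), 80)
  expect_equal(ncol(a$blocks$human), 18)
  expect_equal(ncol(a$blocks$mouse), 23)
  expect_equal(ncol(a$blocks$particle), 16)
  expect_true(all(a$blocks$human > 0))
  expect_true(all(a$blocks$mouse > 0))
  expect_true(all(a$outcomes > 0))
  # compositional closure
  expect_true(all(abs(rowSums(a$blocks$particle) - 100) < 1e-9))
})

test_that("noise-free limit makes the outcome a monotone function of z_pos", {
  cfg <- sim_config(noise_sd = 1e-9, w_pos = 1, w_neg = 0, seed = 5)
  coh <- generate_cohort(cfg)
  expect_equal(cor(coh$outcomes$totalIgG_fc, coh$truth$z_pos,
                   method = "spearman"), 1)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(effect_pos = 0), "positive")
  expect_error(sim_config(effect_neg = -1), "positive")
  expect_error(sim_config(informative_neg = 17), "1..n_particle")
  expect_error(sim_config(noise_sd = 0), "positive")
  expect_error(sim_config(informative_pos = list(human = 25, mouse = 1)),
               "range")
})

test_that("the planted negative population correlates negatively with total IgG", {
  signs <- vapply(1:20, function(s) {
    coh <- generate_cohort(sim_config(seed = s))
    neg <- coh$truth$informative$particle
    cor(coh$blocks$particle[, neg], coh$outcomes$totalIgG_fc) < 0
  }, logical(1))
  expect_gte(sum(signs), 18)
})

test_that("the two latent factors are independent", {
  coh <- generate_cohort(sim_config(n_extracts = 9993, n_controls = 7,
                                    seed = 99))
  expect_lt(abs(cor(coh$truth$z_pos, coh$truth$z_neg)), 0.05)
})

test_that("doubling effect_pos strengthens feature-outcome correlations", {
  mean_abs_cor <- function(effect, seed) {
    coh <- generate_cohort(sim_config(effect_pos = effect, seed = seed))
    inf <- coh$truth$informative$human
    mean(abs(cor(coh$blocks$human[, inf], coh$outcomes$totalIgG_fc)))
  }
  lo <- vapply(1:20, function(s) mean_abs_cor(0.5, s), numeric(1))
  hi <- vapply(1:20, function(s) mean_abs_cor(1.0, s), numeric(1))
  expect_gt(mean(hi), mean(lo))
})

test_that("event tables land inside their cells and are reproducible", {
  g <- gate_grid()
  probs <- rep(1 / 16, 16)
  a <- generate_event_table(g, probs, 500, blank_rate = 2, seed = 7)
  b <- generate_event_table(g, probs, 500, blank_rate = 2, seed = 7)
  expect_identical(a, b)
  expect_equal(sum(a$sample_counts), 500)
  expect_equal(nrow(a$blank), sum(a$blank_counts))

  # degenerate multinomial: all mass on one population
  one <- rep(0, 16)
  one[13] <- 1  # population M
  ev <- generate_event_table(g, one, 200, blank_rate = 0, seed = 1)
  prof <- gate_sample(ev$sample, grid = g)
  expect_equal(unname(prof$percent["M"]), 100)

  expect_error(generate_event_table(g, rep(1 / 8, 8), 10), "length 16")
  expect_error(generate_event_table(g, c(-1, rep(2 / 15, 15)) / sum(c(-1, rep(2 / 15, 15)))),
               "non-negative")
})

test_that("uniform sampling recovers ~6.25% per population", {
  g <- gate_grid()
  ev <- generate_event_table(g, rep(1 / 16, 16), 10000, blank_rate = 0,
                             seed = 3)
  prof <- gate_sample(ev$sample, grid = g)
  # 3 SD of a multinomial proportion at p = 1/16, n = 10000 (in percent)
  tol <- 3 * sqrt((1 / 16) * (15 / 16) / 10000) * 100
  expect_true(all(abs(prof$percent - 6.25) < tol))
})

test_that("dilution series cross the cutoff at the true titer", {
  s <- generate_dilution_series(919, seed = 2)
  expect_false(s$flagged)
  expect_true(all(diff(s$od) < 0))
  res <- titer_from_od(s)
  expect_equal(res$censored, "none")
  expect_equal(res$titer, 919, tolerance = 1e-8)

  # titer on a measured dilution point gives OD exactly at the cutoff
  s2 <- generate_dilution_series(1600, dilution_start = 100,
                                 dilution_factor = 4, seed = 9)
  expect_equal(s2$od[s2$dilutions == 1600], 0.2)

  # out-of-range titers are flagged and the whole curve avoids the cutoff
  lo <- generate_dilution_series(10, seed = 4)
  hi <- generate_dilution_series(1e9, seed = 4)
  expect_true(lo$flagged)
  expect_true(hi$flagged)
  expect_true(all(lo$od < 0.2))
  expect_true(all(hi$od > 0.2))
})

test_that("dilution series are monotone for many seeds", {
  for (s in 1:25) {
    ser <- generate_dilution_series(5000, seed = s)
    expect_true(all(diff(ser$od) < 0))
  }
})
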