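test_that("the overlap confidence level follows the equal-SE calibration", {
  expect_equal(overlap_level(0.05), 2 * pnorm(qnorm(0.975) / sqrt(2)) - 1)
  expect_equal(overlap_level(0.05), 0.8342, tolerance = 1e-4)
  expect_true(overlap_level(0.05) > 0.83 && overlap_level(0.05) < 0.84)
  # z = 1 case and the alpha -> 1 limit
  expect_equal(overlap_level(2 * pnorm(-1)), 2 * pnorm(1 / sqrt(2)) - 1, tolerance = 1e-10)
  expect_equal(overlap_level(2 * pnorm(-1)), 0.5205, tolerance = 1e-4)
  expect_lt(overlap_level(0.999), 0.002)
  expect_error(overlap_level(0), "0, 1")
})

test_that("saturated arm means equal observed cells, with in-range intervals", {
  withr::local_seed(9)
  tr <- cell_trial(runif(16, 0.15, 0.9), k = 54, seed = 10)
  fit <- fit_factorial(tr, "y", family = "binomial", max_order = 4)
  am <- arm_means(fit, level = 0.95)
  obs <- as.numeric(tapply(tr$y, tr$arm, mean))
  expect_equal(am$estimate, obs, tolerance = 1e-7)
  expect_true(all(am$ci_low >= 0 & am$ci_high <= 1))
  expect_true(all(am$ci_low <= am$estimate & am$estimate <= am$ci_high))
  # 51/54 events in an arm: ~94.4% point estimate
  tr2 <- tr
  tr2$y[tr2$arm == 16] <- rep(c(1, 0), c(51, 3))
  am2 <- arm_means(fit_factorial(tr2, "y", family = "binomial", max_order = 4))
  expect_equal(am2$estimate[16], 51 / 54, tolerance = 1e-7)
  expect_equal(round(100 * am2$estimate[16]), 94)
  # the non-saturated fit is rejected with instructions
  expect_error(arm_means(fit_factorial(tr, "y", family = "binomial", max_order = 2)),
               "saturated")
})

test_that("degenerate cells are flagged and given continuity-adjusted intervals", {
  tr <- cell_trial(rep(0.5, 16), k = 20, seed = 12)
  tr$y[tr$arm == 1] <- 0L   # all-zero arm
  w <- capture_warnings(fit <- fit_factorial(tr, "y", family = "binomial", max_order = 4))
  am <- arm_means(fit, level = 0.95)
  expect_true(am$degenerate[1])
  expect_false(any(am$degenerate[-1]))
  expect_equal(am$estimate[1], 0, tolerance = 1e-6)
  expect_true(is.finite(am$ci_low[1]) && is.finite(am$ci_high[1]))
  expect_gt(am$ci_high[1], 0)
})

test_that("pairwise overlap verdicts are symmetric negations of significance", {
  tr <- cell_trial(seq(0.1, 0.85, length.out = 16), k = 40, seed = 13)
  am <- arm_means(fit_factorial(tr, "y", family = "binomial", max_order = 4),
                  level = overlap_level(0.05))
  v <- pairwise_overlap(am)
  expect_equal(nrow(v), 120)
  expect_equal(v$significant, !v$overlap)
  # trivial geometry: identical and disjoint intervals
  fake <- am
  fake$ci_low <- rep(0.1, 16); fake$ci_high <- rep(0.2, 16)
  expect_true(all(pairwise_overlap(fake)$overlap))
  fake$ci_low <- seq(0.1, 4.6, by = 0.3); fake$ci_high <- fake$ci_low + 0.1
  expect_true(all(pairwise_overlap(fake)$significant))
})

test_that("overlap verdicts agree with the two-sample z-test in the equal-SE regime", {
  withr::local_seed(16)
  n_pairs <- 1e4
  se <- 0.05
  gamma <- overlap_level(0.05)
  z_g <- qnorm((1 + gamma) / 2)
  m1 <- rnorm(n_pairs, 0.5, se); m2 <- rnorm(n_pairs, 0.5 + runif(n_pairs, 0, 0.3), se)
  nonoverlap <- abs(m1 - m2) > 2 * z_g * se
  ztest <- abs(m1 - m2) / (se * sqrt(2)) > qnorm(0.975)
  expect_gte(mean(nonoverlap == ztest), 0.99)
})

test_that("arm ranking identifies the top set correctly", {
  tr <- cell_trial(c(rep(0.2, 14), 0.5, 0.9), k = 50, seed = 18)
  am <- arm_means(fit_factorial(tr, "y", family = "binomial", max_order = 4),
                  level = overlap_level(0.05))
  rk <- rank_arms(am)
  expect_equal(rk$rank, 1:16)
  expect_true(all(diff(rk$estimate) <= 0))
  expect_true(rk$in_top_set[1])
  # all-identical intervals -> every arm in the top set
  same <- am
  same$estimate <- rep(0.4, 16); same$ci_low <- rep(0.3, 16); same$ci_high <- rep(0.5, 16)
  expect_true(all(rank_arms(same)$in_top_set))
})

test_that("arm contrasts apply the SMD formulas with sign symmetry", {
  tr <- cell_trial(rep(0.5, 16), k = 30, seed = 19)
  am <- arm_means(fit_factorial(tr, "y", family = "binomial", max_order = 4))
  am$estimate[1] <- 0.03; am$estimate[16] <- 0.30
  expect_equal(round(arm_contrast_smd(am, 16, 1), 2), 0.55)
  expect_equal(arm_contrast_smd(am, 1, 16), -arm_contrast_smd(am, 16, 1))
  am$estimate[16] <- am$estimate[1]
  expect_equal(arm_contrast_smd(am, 16, 1), 0)
  expect_error(arm_contrast_smd(am, 16, 42), "not present")
  # count scale uses the dispersion-scaled formula
  trc <- tiny_trial(320, seed = 20)
  amc <- arm_means(fit_factorial(trc, "feature_count", max_order = 4))
  expect_equal(arm_contrast_smd(amc, 16, 1),
               smd_count(amc$estimate[16], amc$estimate[1],
                         attr(amc, "dispersion")))
})
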