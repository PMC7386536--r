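test_that("the binary SMD formula matches hand evaluation and its properties", {
  expect_equal(smd_binary(0.466, 0.279),
               (0.466 - 0.279) / sqrt(0.466 * 0.534 + 0.279 * 0.721))
  expect_equal(round(smd_binary(0.466, 0.279), 2), 0.28)
  # antisymmetry and zero at equality, over random proportions
  withr::local_seed(2)
  p <- runif(50, 0.01, 0.99); q <- runif(50, 0.01, 0.99)
  expect_equal(smd_binary(p, q), -smd_binary(q, p))
  expect_equal(smd_binary(p, p), rep(0, 50))
  expect_true(all(sign(smd_binary(p, q)) == sign(p - q)))
  expect_error(smd_binary(0, 0.5), class = "mostscreen_degenerate_proportion")
  expect_error(smd_binary(0.5, 1), class = "mostscreen_degenerate_proportion")
})

test_that("the count SMD formula matches hand evaluation and scales with phi", {
  expect_equal(smd_count(2.59, 2.22, 1), 0.37 / sqrt(4.81))
  expect_equal(round(smd_count(2.59, 2.22, 1), 3), 0.169)
  expect_equal(smd_count(3, 3, 2.5), 0)
  # halving phi multiplies d by sqrt(2)
  expect_equal(smd_count(2.5, 2.0, 0.5), sqrt(2) * smd_count(2.5, 2.0, 1))
  expect_error(smd_count(0, 0, 1), class = "mostscreen_degenerate_proportion")
  expect_error(smd_count(1, 2, 0), "phi")
})

test_that("published binary SMDs are reproduced from the published marginals", {
  grid <- published_binary_grid()
  d <- smd_binary(grid$on / 100, grid$off / 100)
  # every cell agrees with the printed SMD to within one unit in the second
  # decimal place: the tables print marginals rounded to 0.1 percent, so
  # trailing digits can differ where the published SMDs used unrounded data
  expect_true(all(abs(d - grid$smd) <= 0.011))
  # the strongest-factor block is reproduced exactly at printed precision
  ig <- grid[grid$factor == "integration" & grid$table == 1, ]
  expect_equal(round(smd_binary(ig$on / 100, ig$off / 100), 2), ig$smd)
})

test_that("marginal means equal raw subgroup means for the saturated balanced fit", {
  withr::local_seed(6)
  tr <- cell_trial(runif(16, 0.2, 0.8), k = 10, seed = 8)
  fit <- fit_factorial(tr, "y", family = "binomial", max_order = 4)
  for (f in most_factors()) {
    mm <- marginal_means(fit, f)
    expect_equal(mm$mean_on, mean(tr$y[tr[[f]] == 1]), tolerance = 1e-7)
    expect_equal(mm$mean_off, mean(tr$y[tr[[f]] == 0]), tolerance = 1e-7)
  }
  expect_error(marginal_means(fit, "dose"), "not in the design")
})

test_that("standardization recovers known on/off rates from simulation", {
  sc <- default_scenario(
    latent_loading = 0,
    features = c(set_quit_date = 0.858, track_triggers = 0.554,
                 choose_aid = 0.279, visit_community = 0.334,
                 beat_triggers = 0.153, build_support = 0.127),
    main_effects = list(integration = c(choose_aid = qlogis(0.466) - qlogis(0.279)))
  )
  withr::local_seed(14)
  mm <- purrr::map_dfr(1:40, function(i) {
    fit <- fit_factorial(simulate_trial(864, sc), "feature_choose_aid", max_order = 1)
    marginal_means(fit, "integration")
  })
  expect_equal(mean(mm$mean_on), 0.466, tolerance = 0.01)
  expect_equal(mean(mm$mean_off), 0.279, tolerance = 0.01)
  # raw difference on the percent scale: the headline 18.7-point effect
  expect_equal(round(46.6 - 27.9, 1), 18.7)
})

test_that("percentile bootstrap matches the normal closed form on a toy model", {
  # identity-link toy: functional is a single coefficient, so the percentile
  # interval should approach the Wald interval
  toy <- structure(list(
    coefficients = c(`(Intercept)` = 1, slope = 2),
    vcov = matrix(c(0.04, 0.01, 0.01, 0.09), 2, 2,
                  dimnames = list(c("(Intercept)", "slope"),
                                  c("(Intercept)", "slope")))
  ), class = "factorial_fit")
  ci <- parametric_bootstrap_ci(toy, function(b) b[2], B = 1e5, level = 0.95, seed = 4)
  se <- 0.3
  expect_equal(ci$point, 2)
  expect_lt(abs(ci$ci_low - (2 - qnorm(0.975) * se)), 0.02 * se)
  expect_lt(abs(ci$ci_high - (2 + qnorm(0.975) * se)), 0.02 * se)
  # level 0 degenerates to the median draw
  ci0 <- parametric_bootstrap_ci(toy, function(b) b[2], B = 1000, level = 0, seed = 4)
  expect_equal(ci0$ci_low, ci0$ci_high)
  expect_error(parametric_bootstrap_ci(toy, function(b) b[2], B = 50), "at least 100")
})

test_that("bootstrap draws with undefined functionals are rejected and resampled", {
  toy <- structure(list(
    coefficients = c(a = 0.5), vcov = matrix(4, dimnames = list("a", "a"))
  ), class = "factorial_fit")
  # SMD against a fixed 0.5 is undefined whenever a draw leaves (0,1)
  expect_warning(
    ci <- parametric_bootstrap_ci(toy, function(b) smd_binary(b[1], 0.5),
                                  B = 200, seed = 5),
    "rejected"
  )
  expect_true(ci$rejected > 0)
})

test_that("marginal_effects returns coherent tables with percentile intervals", {
  tr <- tiny_trial(320, seed = 44)
  fit <- fit_factorial(tr, "feature_track_triggers", max_order = 2)
  me <- marginal_effects(fit, B = 2000, seed = 3)
  expect_equal(nrow(me), 4)
  expect_true(all(me$smd_low <= me$smd & me$smd <= me$smd_high))
  expect_true(all(me$raw_difference_low <= me$raw_difference))
  expect_equal(me$raw_difference, me$mean_on - me$mean_off)
  expect_equal(me$smd, smd_binary(me$mean_on, me$mean_off))
  # determinism given the seed
  me2 <- marginal_effects(fit, B = 2000, seed = 3)
  expect_identical(me, me2)
  # count outcome uses the dispersion-scaled formula
  fitc <- fit_factorial(tr, "feature_count", max_order = 2)
  mec <- marginal_effects(fitc, factors = "integration", B = 500, seed = 6)
  expect_equal(mec$smd, smd_count(mec$mean_on, mec$mean_off, fitc$dispersion))
})
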