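test_that("arm assignment is balanced within strata and overall", {
  asg <- assign_arms(864, mobile_fraction = 0.834, seed = 1)
  expect_equal(unname(table(asg$arm)), rep(54L, 16), ignore_attr = TRUE)
  # within-stratum balance for assorted n and seeds
  for (n in c(16, 61, 200, 864)) {
    for (seed in c(2, 3)) {
      a <- assign_arms(n, 0.6, seed = seed)
      for (s in unique(a$stratum)) {
        cnt <- tabulate(a$arm[a$stratum == s], 16)
        expect_lte(max(cnt) - min(cnt), 1)
      }
      cnt_all <- tabulate(a$arm, 16)
      expect_lte(max(cnt_all) - min(cnt_all), 1)
    }
  }
})

test_that("n = 16 gives one full block; invalid inputs are rejected", {
  a <- assign_arms(16, 0.99, seed = 5)
  expect_equal(sort(a$arm), 1:16)
  expect_error(assign_arms(15), "16")
  expect_error(assign_arms(100, mobile_fraction = 1.2), "0, 1")
})

test_that("arm id is the stated bijection of factor levels", {
  a <- assign_arms(160, seed = 8)
  expect_equal(a$arm, 1L + 8L * a$personalization + 4L * a$integration +
                 2L * a$tailoring + a$intensity)
  one <- dplyr::filter(a, arm == 1)[1, ]
  expect_equal(unlist(one[most_factors()]), c(personalization = 0, integration = 0,
                                              tailoring = 0, intensity = 0))
})

test_that("the mobile stratum matches the enrollment fraction", {
  frac <- replicate(20, mean(assign_arms(864, 0.834)$stratum == "mobile"))
  expect_equal(mean(frac), 721 / 864, tolerance = 0.01)
})

test_that("simulation is deterministic given the seed", {
  t1 <- simulate_trial(200, seed = 99)
  t2 <- simulate_trial(200, seed = 99)
  expect_identical(t1, t2)
  t3 <- simulate_trial(200, seed = 100)
  expect_false(identical(t1, t3))
})

test_that("null-scenario pooled feature rates match the scenario baselines", {
  withr::local_seed(21)
  rates <- rowMeans(replicate(30, {
    tr <- simulate_trial(864)
    colMeans(tr[paste0("feature_", most_features())])
  }))
  expect_lt(abs(rates[["feature_set_quit_date"]] - 0.858), 0.01)
  expect_lt(abs(rates[["feature_build_support"]] - 0.127), 0.01)
})

test_that("default scenario hits the feature-count moments", {
  withr::local_seed(31)
  mom <- replicate(50, {
    tr <- simulate_trial(864)
    c(mean(tr$feature_count), sd(tr$feature_count))
  })
  expect_lt(abs(mean(mom[1, ]) - 2.40), 0.1)
  expect_lt(abs(mean(mom[2, ]) - 1.41), 0.1)
})

test_that("a logit shift on one factor is recovered in the marginal rates", {
  # shift chosen by inverting the logit at the baseline: 27.9% off -> 46.6% on
  sc <- default_scenario(
    features = c(set_quit_date = 0.858, track_triggers = 0.554,
                 choose_aid = 0.279, visit_community = 0.334,
                 beat_triggers = 0.153, build_support = 0.127),
    main_effects = list(integration = c(choose_aid = qlogis(0.466) - qlogis(0.279)))
  )
  withr::local_seed(41)
  rates <- replicate(200, {
    tr <- simulate_trial(432, scenario = sc)
    c(on = mean(tr$feature_choose_aid[tr$integration == 1]),
      off = mean(tr$feature_choose_aid[tr$integration == 0]))
  })
  # Monte-Carlo error of the mean over 200 replicates of n=216/level
  mc_se <- sqrt(0.466 * 0.534 / (216 * 200))
  expect_lt(abs(mean(rates["on", ]) - 0.466), 4 * mc_se + 0.002)
  expect_lt(abs(mean(rates["off", ]) - 0.279), 4 * mc_se + 0.002)
})

test_that("degenerate implied probabilities are rejected naming the arm", {
  sc <- default_scenario(
    main_effects = list(integration = c(choose_aid = 60))
  )
  asg <- assign_arms(64, seed = 3)
  expect_error(simulate_outcomes(asg, sc), "choose_aid.*arm|arm")
})

test_that("trial CSV round-trips and invalid files are rejected by row", {
  tr <- simulate_trial(64, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(tr, path)
  back <- read_trial(path)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12)

  # empty set -> header-only file, read back empty
  empty <- tr[0, ]
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_trial(empty, p2)
  expect_equal(nrow(read_trial(p2)), 0)

  # negative minutes named by row
  bad <- tr
  bad$minutes_on_site[3] <- -1
  p3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, p3)
  expect_error(read_trial(p3), "minutes_on_site.*3")

  # unknown and missing columns
  extra <- dplyr::mutate(tr, bogus = 1)
  p4 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(extra, p4)
  expect_error(read_trial(p4), "unknown columns")
  expect_error(write_trial(tr[, setdiff(names(tr), "arm")], p4), "missing required")
})
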