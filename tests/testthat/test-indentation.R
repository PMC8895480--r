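test_that("line fit recovers an exact slope and flags degenerate records", {
  d <- seq(0, 2, length.out = 50)
  fit <- fit_stiffness(d, 1.2 * d)
  expect_equal(fit$k_measured, 1.2, tolerance = 1e-12)
  expect_equal(fit$residual_rms_n, 0, tolerance = 1e-12)
  expect_error(fit_stiffness(rep(1, 50), 1.2 * d)[], "zero displacement")
  expect_error(fit_stiffness(d[1:5], d[1:5]), "at least")
})

test_that("noisy slope is recovered within three standard errors", {
  set.seed(123)
  d <- seq(0, 2, length.out = 200)
  reps <- replicate(50, {
    f <- 0.9 * d + rnorm(200, 0, 0.02)
    fit_stiffness(d, f)$k_measured
  })
  se <- 0.02 / (sd(d) * sqrt(199))
  expect_true(mean(abs(reps - 0.9) < 3 * se) > 0.95)
})

test_that("fit uses the loading segment of a load-unload record", {
  d_load <- seq(0, 2, length.out = 100)
  d_unload <- seq(1.98, 1.2, length.out = 15)
  d <- c(d_load, d_unload)
  f <- c(1.1 * d_load, 0.3 * d_unload)      # different unloading behaviour
  fit <- fit_stiffness(d, f)
  expect_equal(fit$k_measured, 1.1, tolerance = 1e-9)
  expect_equal(fit$n_used, 100)
})

test_that("indenter-compliance correction inverts the series spring", {
  expect_equal(correct_for_indenter(0.7728, 2.67), 1.0876, tolerance = 1e-3)
  expect_equal(correct_for_indenter(0.5, 1e8), 0.5, tolerance = 1e-6)
  expect_error(correct_for_indenter(2.67, 2.67), "saturated")
  expect_error(correct_for_indenter(3, 2.67), "saturated")
  # round trip and monotonicity
  set.seed(9)
  km <- sort(runif(40, 0.1, 2.5))
  kd <- correct_for_indenter(km, 2.67)
  expect_equal(series_elastic(kd, 2.67), km, tolerance = 1e-12)
  expect_true(all(kd > km))
  expect_true(all(diff(kd) > 0))
})

test_that("map summaries aggregate regions and locations correctly", {
  df <- data.frame(location_id = rep(c("MC2_p1", "IM_p1"), each = 3),
                   repetition = rep(1:3, 2),
                   k_measured = rep(0.7, 6))
  m <- stiffness_map(df)
  expect_identical(unique(m$region[m$location_id == "IM_p1"]), "inter_bone")
  s <- summarize_map(m)
  expect_equal(s$overall$sd_n_mm, 0)
  expect_equal(s$overall$mean_n_mm, correct_for_indenter(0.7, 2.67))
  # single-location map: overall equals that location's mean
  one <- stiffness_map(df[df$location_id == "MC2_p1", ])
  expect_warning(s1 <- summarize_map(one), "inter_bone")
  expect_equal(s1$overall$mean_n_mm,
               s1$by_location$mean_n_mm[1])
})

test_that("synthetic generator is seed-deterministic and respects bounds", {
  d1 <- generate_synthetic_indentation(seed = 42)
  d2 <- generate_synthetic_indentation(seed = 42)
  expect_identical(d1, d2)
  d3 <- generate_synthetic_indentation(seed = 43)
  expect_false(identical(d1$force_n, d3$force_n))
  truth <- attr(d1, "truth")
  expect_equal(nrow(truth), 15)
  expect_true(all(truth$k_true >= 0.54 & truth$k_true <= 1.59))
  expect_error(generate_synthetic_indentation(
    truth = data.frame(location_id = "a", k_true = 3), seed = 1),
    "infeasible")
  expect_error(generate_synthetic_indentation(), "seed")
})

test_that("noise-free generation recovers the truth exactly", {
  truth <- data.frame(location_id = c("MC2_p1", "IM_p1"),
                      region = c("over_bone", "inter_bone"),
                      k_true = c(1.0, 1.2))
  dat <- generate_synthetic_indentation(truth, n_reps = 2, noise_sd_n = 0,
                                        rep_jitter_sd = 0, seed = 1)
  res <- analyze_indentation(dat)
  m <- merge(res$summary$by_location, truth, by = "location_id")
  expect_equal(m$mean_n_mm, m$k_true, tolerance = 1e-9)
})

test_that("grasp force raises the generated stiffness", {
  truth <- synthetic_truth_map(seed = 2)
  d0 <- generate_synthetic_indentation(truth, noise_sd_n = 0,
                                       rep_jitter_sd = 0, grasp_force_n = 0,
                                       seed = 2)
  d5 <- generate_synthetic_indentation(truth, noise_sd_n = 0,
                                       rep_jitter_sd = 0, grasp_force_n = 5,
                                       seed = 2)
  k0 <- analyze_indentation(d0)$summary$overall$mean_n_mm
  k5 <- analyze_indentation(d5)$summary$overall$mean_n_mm
  expect_gt(k5, k0)
})

test_that("pipeline recovers regional structure from a seeded map", {
  dat <- generate_synthetic_indentation(seed = 7)
  res <- analyze_indentation(dat)
  br <- res$summary$by_region
  expect_setequal(br$region, c("over_bone", "inter_bone"))
  truth <- attr(dat, "truth")
  m <- merge(res$summary$by_location, truth, by = "location_id")
  expect_lt(median(abs(m$mean_n_mm - m$k_true) / m$k_true), 0.05)
})
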