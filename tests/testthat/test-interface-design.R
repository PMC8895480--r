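test_that("peak pressure cost is the maximum of the profile", {
  p <- pressure_profile(c(-0.01, 0, 0.01), c(100, 100, 100))
  expect_equal(peak_pressure_cost(p), 100)
  two <- pressure_profile(c(-0.01, 0.01), c(50, 120))
  expect_equal(peak_pressure_cost(two), 120)
  set.seed(1)
  pr <- runif(50, 0, 500)
  expect_equal(peak_pressure_cost(pressure_profile(seq_len(50), pr)), max(pr))
})

test_that("analytic optimum reproduces the two-region closed form", {
  cs <- plate_load_case(10, 0.5, 30, 0.05)
  ao <- analytic_optimum(cs)
  x <- 0.5 / 40
  expect_equal(x, 0.0125)
  expect_equal(ao$peak, 40 / (0.05 - 2 * x))    # 1600 N/m
  expect_equal(ao$peak, 1600)
  # force and moment balance of the exact block
  w <- cs$L - 2 * x
  expect_equal(ao$peak * w, 40)
  expect_equal(ao$peak * w * x, 0.5)
  # high-region centre sits at x
  expect_equal(mean(c(ao$region_boundary, cs$L / 2)), x)
})

test_that("zero moment degenerates to uniform pressure; negation mirrors", {
  cs0 <- plate_load_case(10, 0, 30, 0.05)
  ao0 <- analytic_optimum(cs0)
  expect_equal(ao0$peak, 40 / 0.05)
  expect_true(all(abs(ao0$pressures - 800) < 1e-9))
  cw <- analytic_optimum(plate_load_case(10, -0.5, 30, 0.05))
  ccw <- analytic_optimum(plate_load_case(10, 0.5, 30, 0.05))
  expect_equal(cw$pressures, rev(ccw$pressures))
  expect_equal(cw$region_boundary, -ccw$region_boundary)
  expect_error(analytic_optimum(plate_load_case(1, 0.5, 0, 0.05)),
               "bias force")
})

test_that("LP oracle confirms the analytic minimum peak pressure", {
  skip_if_not_installed("boot")
  for (M in c(0.1, 0.3, 0.5)) {
    cs <- plate_load_case(10, M, 30, 0.05)
    ao <- analytic_optimum(cs)
    lp <- lp_min_peak(40, M, 0.05, n = 15)
    cell <- ao$peak * (0.05 / 15) / (0.05 - 2 * M / 40)
    expect_lt(abs(lp - ao$peak), cell)
  }
})

test_that("optimal bias force follows the closed form and the grid search", {
  expect_equal(optimal_bias_force(10, 0.5, 0.05), 30)
  expect_equal(optimal_bias_force(10, 0, 0.05), 0)
  expect_equal(optimal_bias_force(50, 0.1, 0.05), 0)   # clamped
  Fbs <- seq(0, 60, by = 0.25)
  pk <- vapply(Fbs, function(Fb) tryCatch(
    analytic_optimum(plate_load_case(10, 0.5, Fb, 0.05))$peak,
    error = function(e) Inf), numeric(1))
  expect_lt(abs(Fbs[which.min(pk)] - 30), 0.25 + 1e-12)
  # at the optimal bias the low region is exactly zero and the block covers
  # half the plate
  ao <- analytic_optimum(plate_load_case(10, 0.5, 30, 0.05))
  expect_equal(ao$region_boundary, 0, tolerance = 1e-12)
})

test_that("discrete interface: uniform springs give the parallel closed form", {
  L <- 0.05; n <- 15; k <- 1.0876
  sp <- stiffness_profile(k, 0, L, n)
  cs <- plate_load_case(10, 0, 30, L)
  eq <- simulate_discrete_interface(sp, cs)
  expect_equal(eq$tilt, 0, tolerance = 1e-12)
  expect_equal(eq$relative_displacement, 40 / (n * k * 1e3), tolerance = 1e-9)
  expect_true(all(abs(eq$forces - 40 / n) < 1e-9))
})

test_that("two-spring toy: moment splits into a 2M/s force difference", {
  L <- 0.04; s <- L / 2
  sp <- stiffness_profile_from_points(c(-s / 2, s / 2), c(1, 1), L = L)
  M <- 0.02
  eq <- simulate_discrete_interface(sp, plate_load_case(5, M, 0, L))
  expect_equal(eq$forces[2] - eq$forces[1], 2 * M / s, tolerance = 1e-9)
  expect_equal(sum(eq$forces), 5, tolerance = 1e-9)
})

test_that("discrete equilibria satisfy force and moment balance exactly", {
  set.seed(21)
  for (i in 1:20) {
    k_mean <- runif(1, 0.5, 3)
    g <- runif(1, 0, 0.9) * 4 * k_mean / 0.05
    Fb <- runif(1, 5, 50)
    # keep the moment within what a rigid plate of this length can balance
    M <- runif(1, -1, 1) * 0.4 * (10 + Fb) * 0.05 / 2
    sp <- stiffness_profile(k_mean, g, 0.05, 15)
    cs <- plate_load_case(10, M, Fb, 0.05)
    eq <- simulate_discrete_interface(sp, cs)
    Ft <- 10 + Fb
    expect_lt(abs(sum(eq$forces) - Ft) / Ft, 1e-9)
    expect_lt(abs(sum(eq$forces * sp$positions) - M) / max(abs(M), 1e-3),
              1e-9)
    expect_true(all(eq$profile$pressures >= 0))
  }
})

test_that("design sweep reproduces the comfort/accuracy trade-off", {
  grads <- seq(0, 80, by = 10)
  sw0 <- design_sweep(30, grads, plate_load_case(10, 0, 30, 0.05))
  # zero moment: pressure tracks the stiffness profile, so the flat profile
  # (gradient 0, uniform pressure) is the optimum and displacement is flat
  expect_equal(which.min(sw0$peak_pressure_n_m), 1L)
  expect_true(all(diff(sw0$peak_pressure_n_m) > 0))
  expect_lt(diff(range(sw0$relative_displacement_mm)) /
              mean(sw0$relative_displacement_mm), 0.02)
  argmins <- c()
  for (M in c(0.2, 0.35, 0.5)) {
    sw <- design_sweep(30, grads, plate_load_case(10, M, 30, 0.05))
    i <- which.min(sw$peak_pressure_n_m)
    expect_gt(i, 1)                       # interior minimum
    expect_lt(i, length(grads))
    argmins <- c(argmins, grads[i])
    expect_true(all(diff(sw$relative_displacement_mm) > 0))
    expect_true(all(sw$force_balance_rel_err < 1e-9))
    expect_true(all(sw$moment_balance_rel_err < 1e-9))
  }
  expect_true(all(diff(argmins) >= 0))    # argmin grows with the moment
  # peak pressure grows with the applied moment at fixed bias and gradient
  peaks_at_g20 <- vapply(c(0.2, 0.35, 0.5), function(M)
    design_sweep(30, 20, plate_load_case(10, M, 30, 0.05))$peak_pressure_n_m,
    numeric(1))
  expect_true(all(diff(peaks_at_g20) > 0))
})

test_that("padding stiffness inverts the series coupling", {
  expect_equal(padding_stiffness(0.5, 1), 1)
  expect_equal(padding_stiffness(1, 1e7), 1, tolerance = 1e-6)
  set.seed(5)
  for (i in 1:50) {
    kd <- runif(1, 0.5, 3)
    ke <- runif(1, 0.05, 0.95) * kd
    kp <- padding_stiffness(ke, kd)
    expect_equal(series_elastic(kp, kd), ke, tolerance = 1e-12)
  }
  expect_error(padding_stiffness(1.2, 1.0), "infeasible")
  expect_error(padding_stiffness(1.0, 1.0), "infeasible")
})

test_that("stiffness profile taper is symmetric with the stated mid/edge", {
  sp <- stiffness_profile(1, 20, 0.05, 15)
  expect_equal(sp$k_mid, 1 + 20 * 0.05 / 4)
  expect_equal(sp$k_edge, 1 - 20 * 0.05 / 4)
  expect_equal(sp$k_eff, rev(sp$k_eff))
  expect_error(stiffness_profile(1, 100, 0.05, 15), "gradient too steep")
  expect_error(stiffness_profile(1, 10, 0.05, 2), "3 contact points")
})
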