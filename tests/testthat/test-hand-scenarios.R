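test_that("default hand build matches the two-plate network layout", {
  sys <- build_hand_system()
  expect_gte(nrow(sys$nodes), 6)
  expect_length(sys$bodies, 2)
  expect_equal(nrow(sys$inelastic), 6)
  labels <- vapply(sys$phrii_units, `[[`, character(1), "label")
  contacting <- !vapply(sys$phrii_units, `[[`, logical(1), "inert")
  expect_gte(sum(contacting & labels %in% sys$meta$dorsal_units), 4)
  # the two apex points carry zero viscoelastic properties
  expect_true(all(vapply(sys$phrii_units[match(c("mc_apex", "ph_apex"),
                                               labels)],
                         `[[`, logical(1), "inert")))
  expect_length(sys$meta$strap_loops, 2)
  err <- validate_system(sys)
  expect_length(err, 0)
})

test_that("zero pretension, zero moment: steady state is the built state", {
  sys <- build_hand_system(pretension = 0)
  ss <- settle(sys, NULL)
  q0 <- c(t(as.matrix(sys$nodes[, c("x", "y")])))
  expect_lt(max(abs(ss$state$q - q0)), 1e-7)
})

test_that("MCP angle poses the phalanx ground frame kinematically", {
  d_th <- 0.3
  g <- hand_geometry(mcp_angle = d_th)
  sys <- build_hand_system(g)
  p0 <- hand_geometry()
  sys0 <- build_hand_system(p0)
  # phalanx plate end nodes rotate about the MCP by exactly d_th
  R <- matrix(c(cos(d_th), sin(d_th), -sin(d_th), cos(d_th)), 2, 2)
  for (id in sys$meta$plate_nodes$phalanx) {
    i <- match(id, sys$nodes$id)
    p_rot <- as.numeric(R %*% c(sys0$nodes$x[i], sys0$nodes$y[i]))
    expect_equal(c(sys$nodes$x[i], sys$nodes$y[i]), p_rot, tolerance = 1e-12)
  }
  # metacarpal side unchanged
  i <- match(1, sys$nodes$id)
  expect_equal(sys$nodes$x[i], sys0$nodes$x[i])
})

test_that("strap pretension calibration hits the nominal loop tension", {
  sys <- test_hand_system(pretension = 8)
  ss <- settle(sys, NULL)
  loop_t <- vapply(sys$meta$strap_loops, function(ix) sum(ss$link_tension[ix]),
                   numeric(1))
  expect_equal(unname(loop_t), c(8, 8), tolerance = 0.05)
})

test_that("moment study reproduces the displacement and pressure trends", {
  sys <- build_hand_system()
  study <- run_isometric_moment_study(sys, moment_grid = c(0, 0.25, 0.5),
                                      pretension_grid = c(2, 14),
                                      rtol = 1e-4, atol = 1e-7)
  expect_equal(nrow(study), 6)
  for (P in c(2, 14)) {
    s <- study[study$pretension_n == P, ]
    expect_lt(abs(s$angle_deg[s$moment_nm == 0]), 1e-3)
    expect_true(all(diff(abs(s$angle_deg)) > 0))       # grows with moment
  }
  for (M in c(0.25, 0.5)) {
    s <- study[study$moment_nm == M, ]
    expect_true(all(diff(abs(s$angle_deg)) < 0))       # falls with pretension
  }
  # pressure redistribution on the metacarpal plate under extension:
  # the unit nearer the MCP loads up, the farther one unloads
  s14 <- study[study$pretension_n == 14, ]
  base <- s14[s14$moment_nm == 0, ]
  loaded <- s14[s14$moment_nm == 0.5, ]
  expect_gt(loaded$p_mc_near, base$p_mc_near)
  expect_lt(loaded$p_mc_far, base$p_mc_far)
})

test_that("lift-off pattern: extension lifts near-MCP, flexion mirrors it", {
  sys <- test_hand_system(pretension = 2)
  ext <- settle(sys, hand_moment_load(sys, 0.3))
  expect_identical(detect_liftoff_pattern(ext, sys)$which_end_lifted,
                   "near_mcp")
  expect_gt(detect_liftoff_pattern(ext, sys)$gap, 0)
  flx <- settle(sys, hand_moment_load(sys, -0.3))
  expect_identical(detect_liftoff_pattern(flx, sys)$which_end_lifted,
                   "far_mcp")
  # mirror symmetry of the dorsal pressure pattern within each plate
  labels <- vapply(sys$phrii_units, `[[`, character(1), "label")
  ex <- ext$normal_force[match(c("ph_near", "ph_far"), labels)]
  fl <- flx$normal_force[match(c("ph_far", "ph_near"), labels)]
  expect_equal(ex, fl, tolerance = 0.02)
})

test_that("high pretension suppresses lift-off at moderate moment", {
  sys_hi <- test_hand_system(pretension = 14)
  hi <- settle(sys_hi, hand_moment_load(sys_hi, 0.1))
  expect_identical(detect_liftoff_pattern(hi, sys_hi)$which_end_lifted, "none")
  sys_lo <- test_hand_system(pretension = 2)
  lo <- settle(sys_lo, hand_moment_load(sys_lo, 0.1))
  expect_identical(detect_liftoff_pattern(lo, sys_lo)$which_end_lifted,
                   "near_mcp")
})

test_that("strap stiffness: monotone without bulge, interior optimum with", {
  grid <- c(2, 5, 20, 50)
  flat <- strap_stiffness_study(grid, cocontraction_bulge = 0, moment = 0.3,
                                pretension = 8, rtol = 1e-4, atol = 1e-7)
  # without co-contraction the stiffest strap is never worse on either metric
  expect_true(all(diff(flat$peak_pressure_n_m) < 1e-6))
  expect_true(all(diff(flat$rel_disp_mm) < 0))
  bulged <- strap_stiffness_study(grid, cocontraction_bulge = 0.1,
                                  moment = 0.3, pretension = 8,
                                  rtol = 1e-4, atol = 1e-7)
  i <- which.min(bulged$peak_pressure_n_m)
  expect_gt(i, 1)
  expect_lt(i, length(grid))
  # displacement still degrades as straps soften
  expect_true(all(diff(bulged$rel_disp_mm) < 0))
})
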