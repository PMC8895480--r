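pendulum_system <- function(theta0 = pi / 3, L = 1, m = 0.2) {
  sys <- system_model(gravity = TRUE)
  sys <- add_node(sys, 1, c(L * sin(theta0), -L * cos(theta0)), mass = m)
  add_ground_constraint(sys, 1, c(0, 0))
}

test_that("constraint assembly matches hand-differentiated rows", {
  sys <- pendulum_system(theta0 = pi / 4)
  q <- c(sys$nodes$x, sys$nodes$y)
  v <- c(0.3, -0.1)
  con <- assemble_constraints(sys, q, v, baumgarte = c(0, 0))
  expect_equal(dim(con$A), c(1, 2))
  expect_equal(as.vector(con$A), 2 * q)          # 2 (p - g), g at origin
  expect_equal(con$b, -2 * sum(v^2))
  # no constraints -> zero rows
  free <- system_model()
  free <- add_node(free, 1, c(0, 0))
  con0 <- assemble_constraints(free, c(0, 0), c(0, 0))
  expect_equal(nrow(con0$A), 0)
  # rigid triangle -> rank 3
  tri <- system_model()
  tri <- add_node(tri, 1, c(0, 0))
  tri <- add_node(tri, 2, c(0.01, 0))
  tri <- add_node(tri, 3, c(0.005, 0.008))
  tri <- add_rigid_body(tri, 1:3)
  ct <- assemble_constraints(tri, c(t(as.matrix(tri$nodes[, c("x", "y")]))),
                             rep(0, 6))
  expect_equal(qr(ct$A)$rank, 3)
})

test_that("unconstrained acceleration is M^-1 Q (free fall)", {
  qdd <- uk_acceleration(c(0.3, 0.3), c(0, -0.3 * 9.81),
                         matrix(0, 0, 2), numeric(0))
  expect_equal(qdd, c(0, -9.81))
})

test_that("pendulum acceleration matches the closed-form oracle", {
  th <- pi / 5; L <- 0.7; m <- 0.4; g <- 9.81
  sys <- pendulum_system(th, L, m)
  q <- c(L * sin(th), -L * cos(th))
  con <- assemble_constraints(sys, q, c(0, 0), baumgarte = c(0, 0))
  qdd <- uk_acceleration(rep(m, 2), c(0, -m * g), con$A, con$b)
  tang <- c(cos(th), sin(th))
  radial <- q / L
  expect_equal(sum(qdd * tang), -g * sin(th), tolerance = 1e-10)
  expect_equal(sum(qdd * radial), 0, tolerance = 1e-10)   # at rest: no v^2/L
})

test_that("duplicated constraint rows do not change the acceleration", {
  th <- pi / 6; sys <- pendulum_system(th)
  q <- c(sin(th), -cos(th)); v <- c(0.2, 0.1)
  con <- assemble_constraints(sys, q, v, baumgarte = c(0, 0))
  qdd1 <- uk_acceleration(rep(0.2, 2), c(0, -0.2 * 9.81), con$A, con$b)
  A2 <- rbind(con$A, con$A); b2 <- c(con$b, con$b)
  qdd2 <- uk_acceleration(rep(0.2, 2), c(0, -0.2 * 9.81), A2, b2)
  expect_equal(qdd1, qdd2, tolerance = 1e-10)
  # also agrees with the Lagrange-multiplier oracle
  qdd_lm <- lm_acceleration(rep(0.2, 2), c(0, -0.2 * 9.81), con$A, con$b)
  expect_equal(qdd1, qdd_lm, tolerance = 1e-10)
})

test_that("inconsistent constraints raise an error naming the residual", {
  A <- rbind(c(1, 0), c(1, 0))
  b <- c(1, 2)                       # contradictory
  expect_error(uk_acceleration(c(1, 1), c(0, 0), A, b), "inconsistent")
})

test_that("a free undamped mass keeps constant velocity", {
  sys <- system_model()
  sys <- add_node(sys, 1, c(0, 0), velocity = c(0.1, -0.05), mass = 0.01)
  tr <- integrate_system(sys, t_span = c(0, 1), solver_policy = "explicit",
                         n_out = 11)
  expect_equal(tr$states[11, 1:2], c(0.1, -0.05), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(tr$states[, 3], rep(0.1, 11), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("a damped contact unit settles to the 1-DOF series equilibrium", {
  k <- 0.8  # N/mm per layer
  cv <- function() stiffness_curve(0, k * 0.005 * 1e3, smoothing_halfwidth = 0)
  el <- function() viscoelastic_element(cv(), cv(), 3, 3, 0.005)
  sys <- system_model()
  sys <- add_node(sys, 1, c(0, 0.01), mass = 0.01)
  sys <- add_phrii_unit(sys, 1, c(0, 0), el(), el())
  Fdown <- 0.6
  ld <- load_case(node_forces = list(
    list(node = 1, force = function(t) c(0, -Fdown))))
  ss <- steady_state(sys, ld, rtol = 1e-8, atol = 1e-11)
  k_series <- series_elastic(k, k) * 1e3          # N/m
  expect_equal(ss$normal_force[1], Fdown, tolerance = 1e-6)
  expect_equal(-ss$gap[1], Fdown / k_series, tolerance = 1e-6)
})

test_that("implicit policy needs far fewer steps than explicit on stiff laws", {
  # stiff contact held in compression by a constant load: the explicit pair
  # is stability-limited to tiny steps while BDF coasts after the transient
  scale <- 1e4
  cv <- function() stiffness_curve(0, scale * 0.8 * 0.005 * 1e3,
                                   smoothing_halfwidth = 0)
  d <- critical_damping(scale * 0.8 * 1e3 / 2, 0.01)
  el <- function() viscoelastic_element(cv(), cv(), d, d, 0.005)
  sys <- system_model()
  sys <- add_node(sys, 1, c(0, 0.0098), mass = 0.01)
  sys <- add_phrii_unit(sys, 1, c(0, 0), el(), el())
  ld <- load_case(node_forces = list(
    list(node = 1, force = function(t) c(0, -100))))
  tr_ex <- integrate_system(sys, ld, t_span = c(0, 0.5), rtol = 1e-4,
                            solver_policy = "explicit", n_out = 6)
  tr_im <- integrate_system(sys, ld, t_span = c(0, 0.5), rtol = 1e-4,
                            solver_policy = "implicit", n_out = 6)
  expect_gte(tr_ex$diagnostics$steps / tr_im$diagnostics$steps, 10)
  # auto policy picks the implicit method for the stiff variant
  tr_auto <- integrate_system(sys, ld, t_span = c(0, 0.01), n_out = 6)
  expect_identical(tr_auto$diagnostics$method, "bdf")
})

test_that("steady state: pre-tensioned antagonistic straps stay put", {
  # two opposing tension-only links anchored left and right of one node
  cv <- stiffness_curve(0, 200, smoothing_halfwidth = 0)
  sys <- system_model()
  sys <- add_node(sys, 1, c(0, 0), mass = 0.01)
  sys <- add_elastic_link(sys, 1, anchor = c(-0.05, 0), stiffness_curve = cv,
                          pretension = 2, tension_only = TRUE, damping = 1)
  sys <- add_elastic_link(sys, 1, anchor = c(0.05, 0), stiffness_curve = cv,
                          pretension = 2, tension_only = TRUE, damping = 1)
  ss <- steady_state(sys, NULL, rtol = 1e-8, atol = 1e-11)
  expect_equal(ss$link_tension, c(2, 2), tolerance = 1e-6)
  expect_equal(ss$state$q, c(0, 0), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("steady state reports non-convergence with a residual history", {
  # undamped oscillator never settles
  cv <- stiffness_curve(0, 500, smoothing_halfwidth = 0)
  sys <- system_model()
  sys <- add_node(sys, 1, c(0.01, 0), velocity = c(0.05, 0), mass = 0.01)
  sys <- add_elastic_link(sys, 1, anchor = c(-0.05, 0), stiffness_curve = cv)
  expect_error(steady_state(sys, NULL, t_max = 1), "no settling")
})
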