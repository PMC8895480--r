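make_triangle <- function(side = 0.01) {
  sys <- system_model()
  sys <- add_node(sys, 1, c(0, 0))
  sys <- add_node(sys, 2, c(side, 0))
  sys <- add_node(sys, 3, c(side / 2, side * sqrt(3) / 2))
  sys
}

test_that("rigid ternary bodies add three pairwise constraints idempotently", {
  sys <- add_rigid_body(make_triangle(), c(1, 2, 3))
  expect_equal(nrow(sys$inelastic), 3)
  expect_equal(sort(sys$inelastic$target), rep(0.01, 3), tolerance = 1e-12)
  sys2 <- add_rigid_body(sys, c(3, 1, 2))
  expect_equal(nrow(sys2$inelastic), 3)
  expect_length(sys2$bodies, 1)
})

test_that("collinear triples are rejected", {
  sys <- system_model()
  for (i in 1:3) sys <- add_node(sys, i, c(i * 0.01, 0))
  expect_error(add_rigid_body(sys, 1:3), "collinear")
})

test_that("constraints and links referencing unknown nodes fail loudly", {
  sys <- make_triangle()
  expect_error(add_inelastic_constraint(sys, 1, 9), "unknown node")
  expect_error(add_phrii_unit(sys, 99, c(0, 0), inert_element(),
                              inert_element()), "unknown node")
  expect_error(add_elastic_link(sys, 1, 42,
                                stiffness_curve = stiffness_curve(0, 1, 0)),
               "unknown node")
})

linear_unit_system <- function(k_n_mm = 1, damping = 0, mass = 0.01) {
  # one node on a series stack of two identical linear layers
  cv <- function() stiffness_curve(0, k_n_mm * 0.005 * 1e3,
                                   smoothing_halfwidth = 0)
  el <- function() viscoelastic_element(cv(), cv(), damping, damping, 0.005)
  sys <- system_model()
  sys <- add_node(sys, 1, c(0, 0.01), mass = mass)
  add_phrii_unit(sys, 1, c(0, 0), el(), el(), label = "u")
}

test_that("contact unit force: series of equal springs gives k/2 per metre", {
  sys <- linear_unit_system(k_n_mm = 1)
  u <- sys$phrii_units[[1]]
  # zero compression, zero velocity: (0, 0) at the contact boundary
  f0 <- phrii_force(u, c(0, 0.01), c(0, 0))
  expect_equal(f0$force, c(0, 0))
  expect_equal(f0$delta, 0)
  # compression delta with two springs k in series: F = (k/2) * delta
  delta <- 0.002
  f <- phrii_force(u, c(0, 0.01 - delta), c(0, 0))
  expect_true(f$in_contact)
  expect_equal(f$normal_force, 0.5 * 1e3 * delta, tolerance = 1e-9)
  expect_equal(f$force[2], f$normal_force)
})

test_that("rapid withdrawal clamps the normal force at zero and lifts", {
  sys <- linear_unit_system(k_n_mm = 1, damping = 50)
  u <- sys$phrii_units[[1]]
  # small compression, large separating velocity: viscous term would make
  # the normal force negative; the unit must lift instead
  f <- phrii_force(u, c(0, 0.0099), c(0, 1))
  expect_identical(f$normal_force, 0)
  expect_identical(f$tangential_force, 0)
  expect_false(f$in_contact)
  # same state moving inward transmits positive force
  f2 <- phrii_force(u, c(0, 0.0099), c(0, -0.01))
  expect_gt(f2$normal_force, 0)
})

test_that("zero-property units never transmit force", {
  sys <- system_model()
  sys <- add_node(sys, 1, c(0, 0.004))
  sys <- add_phrii_unit(sys, 1, c(0, 0), inert_element(0.002),
                        inert_element(0.002))
  f <- phrii_force(sys$phrii_units[[1]], c(0, -0.05), c(0, -2))
  expect_identical(f$force, c(0, 0))
  expect_false(f$in_contact)
})

test_that("trajectories are unchanged by the presence of inert units", {
  base <- system_model(gravity = TRUE)
  base <- add_node(base, 1, c(0.006, -0.008), mass = 0.02)
  base <- add_ground_constraint(base, 1, c(0, 0))
  with_inert <- add_phrii_unit(base, 1, c(0.006, -0.02), inert_element(0.004),
                               inert_element(0.004))
  t1 <- integrate_system(base, t_span = c(0, 0.5), n_out = 26,
                         solver_policy = "explicit")
  t2 <- integrate_system(with_inert, t_span = c(0, 0.5), n_out = 26,
                         solver_policy = "explicit")
  expect_equal(t1$states, t2$states, tolerance = 1e-12)
})

test_that("system serialization round-trips the full hand scenario", {
  sys <- build_hand_system()
  path <- tempfile(fileext = ".yaml")
  serialize_system(sys, path)
  back <- deserialize_system(path)
  for (field in c("nodes", "inelastic", "bodies", "gravity"))
    expect_equal(back[[field]], sys[[field]], tolerance = 1e-12)
  expect_length(back$elastic_links, length(sys$elastic_links))
  for (i in seq_along(sys$elastic_links)) {
    expect_equal(back$elastic_links[[i]]$stiffness_curve,
                 sys$elastic_links[[i]]$stiffness_curve, tolerance = 1e-12)
    expect_identical(back$elastic_links[[i]]$tension_only,
                     sys$elastic_links[[i]]$tension_only)
    expect_equal(back$elastic_links[[i]]$pretension,
                 sys$elastic_links[[i]]$pretension, tolerance = 1e-12)
  }
  for (i in seq_along(sys$phrii_units)) {
    expect_equal(back$phrii_units[[i]]$normal_curve,
                 sys$phrii_units[[i]]$normal_curve, tolerance = 1e-12)
    expect_equal(back$phrii_units[[i]]$rest_thickness,
                 sys$phrii_units[[i]]$rest_thickness, tolerance = 1e-12)
  }
})

test_that("deserialization reports a constraint naming a missing node", {
  sys <- make_triangle()
  sys <- add_rigid_body(sys, 1:3)
  path <- tempfile(fileext = ".yaml")
  serialize_system(sys, path)
  doc <- yaml::read_yaml(path)
  doc$nodes <- doc$nodes[1:2]            # drop node 3
  doc$bodies <- list()
  yaml::write_yaml(doc, path)
  expect_error(deserialize_system(path), "missing")
})

test_that("validate_system lists all violations", {
  sys <- make_triangle()
  sys <- add_rigid_body(sys, 1:3)
  sys$inelastic$node_b[1] <- 77L
  sys$nodes$mass[2] <- -1
  problems <- validate_system(sys)
  expect_gte(length(problems), 2)
  expect_true(any(grepl("77", problems)))
  expect_error(validate_system(sys, stop_on_error = TRUE))
})
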