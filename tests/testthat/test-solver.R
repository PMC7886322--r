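# Static solver verification: closed-form oracles, interface law, equilibrium.

test_that("tip-loaded bar matches FL/(EA) in the linear range", {
  bp <- bar_problem(E = 100, nu = 0.3, h = 4)
  s <- solve_static(bp$mesh, bp$materials, load_case("SOL", 10, ramp_steps = 1),
                    interface_model("bonded"))
  tip <- mean_face_displacement(s, "proximal_SOL")
  expect_equal(tip, 10 * bp$L / (bp$E * bp$A), tolerance = 0.01)
  expect_lt(max(equilibrium_residual(s)), 1e-4)
})

test_that("zero force converges immediately with zero displacement", {
  bp <- bar_problem(h = 5)
  s <- solve_static(bp$mesh, bp$materials, load_case("SOL", 0, ramp_steps = 1),
                    interface_model("bonded"))
  expect_equal(max(abs(s$u)), 0)
  expect_true(all(s$log$iter == 0))   # only the initial residual check ran
})

test_that("homogeneous large-strain extension matches the analytic uniaxial response", {
  # nu = 0 so the clamped distal face is compatible with a homogeneous state
  bp <- bar_problem(E = 100, nu = 0, w = 10, t = 10, L = 20, h = 5)
  s <- solve_static(bp$mesh, bp$materials, load_case("SOL", 1500, ramp_steps = 5),
                    interface_model("bonded"))
  stretch <- 1 + mean_face_displacement(s, "proximal_SOL") / bp$L
  expect_gt(stretch, 1.1)    # genuinely large strain
  analytic <- as.numeric(uniaxial_nominal_stress(neo_hookean_from_modulus(100, 0), stretch))
  expect_equal(1500 / bp$A, analytic, tolerance = 0.01)
})

test_that("interface force update implements the joint and Coulomb law", {
  fr <- interface_model("frictional", mu = 0.4, k_n = 1000, k_t = 1000)
  # stick: trial below the cap
  up <- interface_force_update(c(-0.01, 0.001, 0), fr, area = 1)
  expect_equal(up$normal_force, 10)
  expect_equal(up$tangential_force[1], -1)
  expect_identical(up$flag, "stick")
  # slip: trial force 10 N against cap mu*|N| = 4 N
  up2 <- interface_force_update(c(-0.01, 0.01, 0), fr, area = 1)
  expect_equal(abs(up2$tangential_force[1]), 0.4 * 10)
  expect_identical(up2$flag, "slip")
  # mu = 0 frictional is identical to frictionless in every component
  fr0 <- interface_model("frictional", mu = 0)
  fl <- interface_model("frictionless")
  for (k in 1:10) {
    d <- rnorm(3) / 50
    a <- interface_force_update(d, fr0, area = 2)
    b <- interface_force_update(d, fl, area = 2)
    expect_equal(a$normal_force, b$normal_force)
    expect_equal(a$tangential_force, b$tangential_force)
  }
  # bilateral joint: separation and interpenetration both resisted
  expect_equal(interface_force_update(c(0.02, 0, 0), fl, 1)$normal_force, -20)
  expect_equal(interface_force_update(c(-0.02, 0, 0), fl, 1)$normal_force, 20)
  expect_error(interface_force_update(c(NA, 0, 0), fl, 1), "finite")
})

test_that("converged frictional solutions satisfy the Coulomb consistency bounds", {
  m <- loft_mesh(make_archetype(3), 5)
  s <- solve_static(m, material_map(), load_case("SOL", 100, ramp_steps = 5),
                    interface_model("frictional", mu = 0.4))
  st <- s$interface_state
  cap <- 0.4 * abs(st$normal_force)
  slip <- st$flag == "slip"
  if (any(slip))
    expect_true(all(abs(abs(st$tangential_force_t1[slip]) - cap[slip]) <=
                      0.01 * pmax(cap[slip], 1e-6)))
  expect_true(all(abs(st$tangential_force_t1[!slip]) <= cap[!slip] + 1e-6))
  expect_lt(max(equilibrium_residual(s)), 1e-4)
})

test_that("the solution field is objective under a rigid rotation of the problem", {
  # rotate mesh and load by 90 degrees about z: displacements must co-rotate
  bp <- bar_problem(E = 100, nu = 0.3, w = 6, t = 5, L = 20, h = 5)
  s0 <- solve_static(bp$mesh, bp$materials, load_case("SOL", 50, ramp_steps = 2),
                     interface_model("bonded"))
  mesh_rot <- bp$mesh
  R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  mesh_rot$nodes <- bp$mesh$nodes %*% t(R)
  s1 <- solve_static(mesh_rot, bp$materials, load_case("SOL", 50, ramp_steps = 2),
                     interface_model("bonded"))
  expect_equal(s1$u, s0$u %*% t(R), tolerance = 1e-6)
})

test_that("bonded penalties reproduce the merged-node mesh within 0.5 percent", {
  g <- make_archetype(3)
  mp <- loft_mesh(g, 5)
  mm <- loft_mesh(g, 5, merge_interfaces = TRUE)
  expect_length(mm$interface_pairs$a, 0)
  lab <- load_case("SOL", 100, ramp_steps = 5)
  sp <- solve_static(mp, material_map(), lab, interface_model("bonded", k_t = 1e4, k_n = 1e4))
  sm <- solve_static(mm, material_map(), lab, interface_model("bonded"))
  dp <- mean_face_displacement(sp, "proximal_SOL")
  dm <- mean_face_displacement(sm, "proximal_SOL")
  expect_equal(dp, dm, tolerance = 0.005)
})

test_that("doubling the penalty stiffness barely moves the outcome scalars", {
  # run in the resolved regime (h = 3); at very coarse meshes the facet
  # frames add ~1 percent of extra penalty sensitivity (see vignette)
  m <- loft_mesh(make_archetype(3), 3)
  lab <- load_case("SOL", 100, ramp_steps = 5)
  s1 <- solve_static(m, material_map(), lab, interface_model("frictionless", k_n = 1000, k_t = 1000))
  s2 <- solve_static(m, material_map(), lab, interface_model("frictionless", k_n = 2000, k_t = 2000))
  d1 <- mean_face_displacement(s1); d2 <- mean_face_displacement(s2)
  expect_equal(d1, d2, tolerance = 0.01)
})

test_that("run_load_cases labels and orders the grid deterministically", {
  bp <- bar_problem(h = 5, L = 20)
  sols <- run_load_cases(bp$mesh, bp$materials,
                         interfaces = list(interface_model("bonded"),
                                           interface_model("frictionless")),
                         loads = list(load_case("SOL", 10, 1)))
  expect_length(sols, 2)
  g <- attr(sols, "grid")
  expect_equal(g$interface, c("bonded", "frictionless"))
  # identical problems solve identically (full determinism, no RNG)
  sols2 <- run_load_cases(bp$mesh, bp$materials,
                          interfaces = list(interface_model("bonded"),
                                            interface_model("frictionless")),
                          loads = list(load_case("SOL", 10, 1)))
  expect_identical(sols[[1]]$u, sols2[[1]]$u)
})
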