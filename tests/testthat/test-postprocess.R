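# Outcome measures: face averages, von Mises, normalization, rotation.

test_that("mean face displacement averages the longitudinal component", {
  bp <- bar_problem(w = 1, t = 1, L = 2, h = 0.5)
  m <- bp$mesh
  N <- nrow(m$nodes)
  # rigid 1 mm z-translation
  s <- fake_solution(m, cbind(0 * 1:N, 0 * 1:N, rep(1, N)))
  expect_equal(mean_face_displacement(s, "proximal_SOL"), 1, tolerance = 1e-12)
  # pure transverse translation
  s2 <- fake_solution(m, cbind(rep(1, N), rep(2, N), rep(0, N)))
  expect_equal(mean_face_displacement(s2, "proximal_SOL"), 0, tolerance = 1e-12)
  # linear ramp u_z = x over the unit square face: area average = 0.5
  # (x runs -0.5..0.5 here, so use x + 0.5)
  s3 <- fake_solution(m, cbind(0 * 1:N, 0 * 1:N, m$nodes[, 1] + 0.5))
  expect_equal(mean_face_displacement(s3, "proximal_SOL"), 0.5, tolerance = 1e-9)
  expect_error(mean_face_displacement(s, "no_such_face"), "empty")
})

test_that("von Mises stress follows the deviatoric invariant", {
  expect_equal(von_mises_field(matrix(c(5, 5, 5, 0, 0, 0), 1)), 0)
  expect_equal(von_mises_field(matrix(c(7, 0, 0, 0, 0, 0), 1)), 7)
  tau <- 3.2
  expect_equal(von_mises_field(matrix(c(0, 0, 0, tau, 0, 0), 1)), tau * sqrt(3))
})

test_that("stress summaries of a homogeneous bar give mean = peak = applied", {
  bp <- bar_problem(E = 100, nu = 0, w = 10, t = 10, L = 20, h = 5)
  s <- solve_static(bp$mesh, bp$materials, load_case("SOL", 200, ramp_steps = 1),
                    interface_model("bonded"))
  ss <- stress_summaries(s, exclusion_layers = 0)
  # nominal 2 MPa; Cauchy follows sigma = P / lateral_stretch^2
  stretch <- 1 + mean_face_displacement(s, "proximal_SOL") / bp$L
  lat <- attr(uniaxial_nominal_stress(neo_hookean_from_modulus(100, 0), stretch),
              "lateral_stretch")
  expect_equal(ss$mean_vm, 2 / lat^2, tolerance = 0.01)
  expect_equal(ss$peak_vm, ss$mean_vm, tolerance = 0.01)
  expect_gte(ss$peak_vm, ss$mean_vm - 1e-9)
  ss1 <- stress_summaries(s, exclusion_layers = 1)
  expect_gte(ss1$peak_vm, ss1$mean_vm * 0.99)
})

test_that("normalization divides by the frictionless row per group", {
  sweep <- tibble::tibble(
    model_id = 1, loaded = rep(c("SOL", "MG"), each = 3),
    interface = rep(c("frictionless", "frictional", "bonded"), 2),
    mu = c(NA, 0.2, NA, NA, 0.2, NA),
    soleus_face_displacement = c(2, 1, 0.5, 0.1, 0.2, 0.4),
    mean_vm = c(4, 3, 2, 1, 0.9, 0.8))
  out <- normalize_sweep(sweep)
  expect_equal(out$normalized_displacement[out$loaded == "SOL"], c(1, 0.5, 0.25))
  expect_equal(out$normalized_displacement[out$loaded == "MG"], c(1, 2, 4))
  expect_equal(out$mean_vm_normalized[out$loaded == "SOL"], c(1, 0.75, 0.5))
  # ratio property: scaling a group leaves normalized values unchanged
  sweep2 <- sweep
  sweep2$soleus_face_displacement <- sweep2$soleus_face_displacement * 7
  expect_equal(normalize_sweep(sweep2)$normalized_displacement,
               out$normalized_displacement)
  # missing reference errors
  expect_error(normalize_sweep(sweep[sweep$interface != "frictionless", ]),
               "frictionless")
})

test_that("face rotation recovers imposed transverse rotations", {
  bp <- bar_problem(w = 4, t = 2, L = 10, h = 1)
  m <- bp$mesh
  th <- 5 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  u <- cbind(m$nodes[, 1:2] %*% t(R) - m$nodes[, 1:2], 0)
  s <- fake_solution(m, u)
  expect_equal(face_rotation(s, "proximal_SOL"), 5, tolerance = 0.01 / 5)
  # pure translation gives zero
  s2 <- fake_solution(m, cbind(rep(0.3, nrow(m$nodes)), rep(-0.2, nrow(m$nodes)), 0))
  expect_equal(face_rotation(s2, "proximal_SOL"), 0, tolerance = 1e-9)
  # noisy rotation still recovered within half a degree (Monte Carlo)
  set.seed(21)
  for (k in 1:5) {
    noise <- 0.01 * max(abs(m$nodes[, 1:2])) * matrix(rnorm(2 * nrow(m$nodes)), ncol = 2)
    sn <- fake_solution(m, cbind(u[, 1:2] + noise, 0))
    expect_lt(abs(face_rotation(sn, "proximal_SOL") - 5), 0.5)
  }
})
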