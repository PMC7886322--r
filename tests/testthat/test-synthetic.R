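# Seeded generators: determinism, parameter recovery, cohort structure.

test_that("generators are pure functions of their seed", {
  c1 <- gen_test_curve(200, csa = 30, noise = 0.02, seed = 42)
  c2 <- gen_test_curve(200, csa = 30, noise = 0.02, seed = 42)
  expect_identical(c1, c2)
  expect_false(identical(c1$force, gen_test_curve(200, csa = 30, noise = 0.02, seed = 43)$force))

  g1 <- gen_geometry_params(3, jitter = 0.1, seed = 9)
  g2 <- gen_geometry_params(3, jitter = 0.1, seed = 9)
  expect_identical(g1, g2)

  t1 <- gen_cohort(n_young = 2, n_old = 2, muscles = "SOL", seed = 5)
  t2 <- gen_cohort(n_young = 2, n_old = 2, muscles = "SOL", seed = 5)
  expect_identical(t1, t2)
})

test_that("generated curves respect the stated failure kinematics", {
  cv <- gen_test_curve(300, csa = 30, failure_strain = 0.15, gauge_length = 60, noise = 0)
  imax <- which.max(cv$force)
  # displacement at max force = failure strain x gauge, toe correction < 1.5 mm
  expect_lt(abs(cv$displacement[imax] - 9), 1.5)
  # at least a 20 percent force drop after the peak
  expect_lt(min(cv$force[imax:length(cv$force)]), 0.8 * max(cv$force))
  # pull rate encoded in the time base
  expect_equal(diff(cv$displacement[1:2]) / diff(cv$time[1:2]), 0.75, tolerance = 1e-9)
})

test_that("cohort generator produces the study layout and group structure", {
  trials <- gen_cohort(seed = 1)
  expect_length(trials, 16 * 3)
  expect_equal(sum(vapply(trials, function(t) t$group == "young", logical(1))), 9 * 3)
  coh <- cohort_record(trials)
  expect_true(all(coh$normalized_displacement > 0))
  expect_equal(nrow(coh), 48)
})

test_that("a null effect leaves group means indistinguishable (law of large numbers)", {
  trials <- gen_cohort(n_young = 120, n_old = 120, d = c(LG = 0, MG = 0, SOL = 0),
                       muscles = "SOL", trace_noise = 0, seed = 7)
  coh <- cohort_record(trials)
  m <- tapply(coh$normalized_displacement, coh$group, mean)
  s <- stats::sd(coh$normalized_displacement)
  expect_lt(abs(diff(m)) / s, 0.35)   # ~2.7 SE at n = 120 per group
})

test_that("geometry jitter is unbiased, clipped and reproducible", {
  expect_identical(gen_geometry_params(3, 0)$csa, 42.3)
  expect_identical(gen_geometry_params(1, 0)$twist, 90)
  set.seed(NULL)
  csas <- vapply(1:500, function(s) gen_geometry_params(3, 0.1, seed = s)$csa, numeric(1))
  expect_equal(mean(csas), 42.3, tolerance = 0.5 / 42.3)
  # pathological jitter is clipped with a message, never negative
  expect_message(g <- gen_geometry_params(3, jitter = 5, seed = 2), "clipped")
  expect_true(g$csa > 0 && all(g$fractions > 0))
  # jittered parameters build a valid geometry
  ov <- gen_geometry_params(2, 0.1, seed = 3)
  geo <- make_archetype(2, overrides = ov)
  expect_s3_class(geo, "tendon_geometry")
})
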