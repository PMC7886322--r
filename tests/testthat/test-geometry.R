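# Parametric cross-sections and archetype geometries.

test_that("archetypes reproduce the recorded lengths, CSAs and section layout", {
  g1 <- make_archetype(1)
  expect_equal(g1$length, 70)
  expect_length(g1$sections, 8)              # 10 mm spacing over 70 mm
  for (g in list(g1, make_archetype(2), make_archetype(3))) {
    target <- c(`1` = 89.1, `2` = 90.4, `3` = 42.3)[[as.character(g$model_id)]]
    sa <- section_areas(g)
    tot <- tapply(sa$area_mm2, sa$z, sum)
    expect_true(all(abs(tot - target) < 0.5), label = paste("model", g$model_id))
  }
  # model 1 twists most
  expect_gt(make_archetype(1)$twist, make_archetype(2)$twist)
})

test_that("partition areas follow the mean sub-tendon fractions at every level", {
  sa <- section_areas(make_archetype(1))
  sol_frac <- sa$area_mm2[sa$sub_tendon == "SOL"] / tapply(sa$area_mm2, sa$z, sum)
  expect_true(all(abs(sol_frac - 32.8 / 55.5) < 0.02))
  lg_frac <- sa$area_mm2[sa$sub_tendon == "LG"] / tapply(sa$area_mm2, sa$z, sum)
  expect_true(all(abs(lg_frac - 9.3 / 55.5) < 0.02))
})

test_that("partition closure holds within 1 mm^2 on every generated section", {
  for (mid in 1:3) {
    g <- make_archetype(mid)
    for (s in g$sections) {
      areas <- vapply(s$partitions, polygon_area, numeric(1))
      expect_lt(abs(sum(areas) - polygon_area(s$outer_boundary)), 1)
      expect_true(all(areas > 0))
      expect_true(all(vapply(s$partitions, polygon_is_simple, logical(1))))
    }
  }
})

test_that("zero twist produces a prism with identical sections", {
  g <- make_archetype(2, overrides = list(twist = 0))
  p1 <- g$sections[[1]]$partitions
  pN <- g$sections[[length(g$sections)]]$partitions
  for (st in SUB_TENDONS) expect_equal(p1[[st]], pN[[st]], tolerance = 1e-12)
})

test_that("polygon areas follow the shoelace formula, orientation-free", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_area(sq[4:1, ]), 1)      # reversed orientation
  r1 <- cbind(c(0, 0.5, 0.5, 0), c(0, 0, 1, 1))
  expect_equal(polygon_area(r1), 0.5)
})

test_that("invalid archetype requests fail loudly", {
  expect_error(make_archetype(4), "unknown model_id")
  expect_error(make_archetype(1, overrides = list(banana = 1)), "unknown override")
  expect_error(make_archetype(1, overrides = list(csa = -5)), "non-positive")
  expect_error(make_archetype(1, overrides = list(fractions = c(LG = -1, MG = 1, SOL = 1))))
})

test_that("twist metadata increases monotonically from the distal section", {
  g <- make_archetype(1)
  tw <- vapply(g$sections, `[[`, numeric(1), "twist_angle")
  expect_equal(tw[1], 0)
  expect_true(all(diff(tw) > 0))
  expect_equal(tw[length(tw)], 90)
})
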