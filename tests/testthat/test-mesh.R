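# Lofted TET10 meshing: validity, volume, conformity, interface pairing,
# convergence driver.

test_that("prism meshes are valid and volume-exact", {
  g <- make_archetype(2, overrides = list(twist = 0))
  m <- loft_mesh(g, 4)
  q <- subtendon:::tet_metrics(m$nodes, m$elements)
  expect_gt(nrow(m$elements), 0)
  expect_true(all(q$vol6 > 0))                       # positive Jacobians
  expect_equal(m$volume, 90.4 * 40, tolerance = 1e-9)  # zero twist: exact
  # refinement changes the (already exact) prism volume by < 0.5 percent
  m2 <- loft_mesh(g, 2)
  expect_equal(m2$volume, m$volume, tolerance = 0.005)
})

test_that("twisted meshes recover the geometric volume within 1 percent", {
  m <- loft_mesh(make_archetype(3), 2.5)
  expect_equal(m$volume, 42.3 * 40, tolerance = 0.01)
  expect_lte(m$max_edge, 1.5 * 2.5)
})

test_that("interface pairs coincide exactly and cover every interface node once", {
  m <- loft_mesh(make_archetype(1), 4)
  pr <- m$interface_pairs
  expect_gt(length(pr$a), 0)
  gap <- sqrt(rowSums((m$nodes[pr$a, , drop = FALSE] - m$nodes[pr$b, , drop = FALSE])^2))
  expect_lt(max(gap), 1e-6)
  # frames orthonormal
  expect_lt(max(abs(rowSums(pr$normal * pr$t1))), 1e-9)
  expect_lt(max(abs(rowSums(pr$normal * pr$t2))), 1e-9)
  expect_equal(rowSums(pr$normal^2), rep(1, length(pr$a)), tolerance = 1e-9)
  # pairing is symmetric and complete: no node appears on both sides of the
  # same pair, and each (a, b) pair is unique
  expect_false(any(pr$a == pr$b))
  expect_false(any(duplicated(paste(pr$a, pr$b))))
  # tributary areas total twice nothing: they sum to the interface area once
  expect_gt(sum(pr$area), 0)
})

test_that("merged meshes share interface nodes and carry no pairs", {
  g <- make_archetype(3)
  mp <- loft_mesh(g, 4)
  mm <- loft_mesh(g, 4, merge_interfaces = TRUE)
  expect_length(mm$interface_pairs$a, 0)
  expect_lt(nrow(mm$nodes), nrow(mp$nodes))
  expect_equal(mm$volume, mp$volume, tolerance = 1e-9)
})

test_that("element labels partition the mesh by sub-tendon", {
  m <- loft_mesh(make_archetype(2), 4)
  expect_setequal(unique(m$label), SUB_TENDONS)
  sa <- section_areas(make_archetype(2))
  vol_frac <- tapply(subtendon:::tet_metrics(m$nodes, m$elements)$vol6, m$label, sum)
  vol_frac <- vol_frac / sum(vol_frac)
  area_frac <- tapply(sa$area_mm2, sa$sub_tendon, mean) / 90.4
  expect_equal(as.numeric(vol_frac[SUB_TENDONS]),
               as.numeric(area_frac[SUB_TENDONS]), tolerance = 0.02)
})

test_that("mesh convergence driver stops by the relative-change criterion", {
  g <- bar_geometry(10, 10, 40)
  mats <- material_map(SOL = neo_hookean_from_modulus(100, 0.3))
  ld <- load_case("SOL", 10, ramp_steps = 1)
  cv <- converge_mesh(g, mats, ld, criterion = 0.01, refinement_factor = 0.7, h0 = 6)
  expect_true(cv$max_edge_length %in% cv$table$max_edge_length)
  last2 <- utils::tail(cv$table, 2)
  expect_lt(last2$rel_change[2], 0.01)
  # chosen edge length is the coarser of the converged pair
  expect_equal(cv$max_edge_length, last2$max_edge_length[1])
  # converged displacement honours the closed-form bar solution within 2 %
  expect_equal(utils::tail(cv$table$displacement, 1), 10 * 40 / (100 * 100),
               tolerance = 0.02)
  # trivial criterion stops after the first refinement pair
  cv2 <- converge_mesh(g, mats, ld, criterion = 1.0, h0 = 6)
  expect_equal(nrow(cv2$table), 2)
})
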