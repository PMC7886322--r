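# Shared small fixtures. Everything is generated in code; meshes are kept
# deliberately coarse so the whole suite stays within a desk-scale budget.

table1 <- read_specimen_table()

tab1_vals <- function(metric, st) table1[[metric]][table1$sub_tendon == st]

# a small single-material bar problem used across solver tests
bar_problem <- function(E = 100, nu = 0.3, w = 10, t = 10, L = 100, h = 4) {
  g <- bar_geometry(w, t, L)
  list(geometry = g, mesh = loft_mesh(g, h),
       materials = material_map(SOL = neo_hookean_from_modulus(E, nu)),
       E = E, A = w * t, L = L)
}

# a synthetic solution_field with prescribed displacements on a given mesh
fake_solution <- function(mesh, u) {
  structure(list(u = u, mesh = mesh,
                 stress = matrix(0, nrow(mesh$elements), 6),
                 vm = numeric(nrow(mesh$elements))),
            class = "solution_field")
}

# linear force-displacement curve with a terminal drop (closed-form oracle)
linear_failure_curve <- function(slope = 150, csa = 30, gauge = 60,
                                 fail_force = 1500, n = 200) {
  d_fail <- fail_force / slope
  d <- sort(unique(c(seq(0, d_fail * 1.2, length.out = n), d_fail)))
  f <- ifelse(d <= d_fail, slope * d, fail_force * pmax(0.3, 1 - 4 * (d - d_fail)))
  test_curve(seq_along(d), d, f, gauge_length = gauge, csa = csa)
}
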