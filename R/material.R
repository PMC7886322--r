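# Compressible neo-Hookean constitutive model, parameterised by an initial
# (small-strain) Young's modulus:
#   W = C10 (Ibar1 - 3) + (1/D1) (J - 1)^2,
# with Ibar1 = J^{-2/3} tr(C). The coefficients follow from linearisation:
# C10 = E / (4 (1 + nu)) (shear modulus mu0 = 2 C10) and
# D1 = 6 (1 - 2 nu) / E (bulk modulus K0 = 2 / D1).

#' Neo-Hookean parameters from an initial modulus
#'
#' @param E initial Young's modulus, MPa (> 0).
#' @param nu Poisson's ratio in [0, 0.5). Tendon is nearly incompressible;
#'   the packaged default is 0.49.
#' @return object of class `neo_hookean_params` with fields `C10` (MPa),
#'   `D1` (1/MPa), `E`, `nu`.
#' @examples
#' neo_hookean_from_modulus(103.1, 0.49)
#' @export
neo_hookean_from_modulus <- function(E, nu = 0.49) {
  if (!is.numeric(E) || E <= 0) stop("E must be > 0")
  if (nu < 0 || nu >= 0.5) stop("nu must lie in [0, 0.5); the incompressible limit is not representable")
  structure(list(C10 = E / (4 * (1 + nu)), D1 = 6 * (1 - 2 * nu) / E, E = E, nu = nu),
            class = "neo_hookean_params")
}

#' Material assignment for the three sub-tendons
#'
#' Defaults are the moduli used to parameterise the finite-element models
#' (LG 226.7, MG 143.2, SOL 103.1 MPa), which were obtained by curve-fitting
#' uniaxial test data and deliberately differ from the tabulated linear-region
#' Young's moduli of the specimens.
#'
#' @param LG,MG,SOL `neo_hookean_params` for each sub-tendon.
#' @return named list of class `material_map`.
#' @export
material_map <- function(LG = neo_hookean_from_modulus(226.7),
                         MG = neo_hookean_from_modulus(143.2),
                         SOL = neo_hookean_from_modulus(103.1)) {
  out <- list(LG = LG, MG = MG, SOL = SOL)
  ok <- vapply(out, inherits, logical(1), "neo_hookean_params")
  if (!all(ok)) stop("all entries must be neo_hookean_params")
  structure(out, class = "material_map")
}

# Principal nominal (first Piola) stresses of F = diag(l1, l2, l2).
.uniaxial_P <- function(params, l1, l2) {
  C10 <- params$C10; D1 <- params$D1
  J <- l1 * l2^2
  I1 <- l1^2 + 2 * l2^2
  Jm23 <- J^(-2 / 3)
  P1 <- C10 * (-(2 / 3) * Jm23 / J * (J / l1) * I1 + Jm23 * 2 * l1) +
    (2 / D1) * (J - 1) * (J / l1)
  P2 <- C10 * (-(2 / 3) * Jm23 / J * (J / l2) * I1 + Jm23 * 2 * l2) +
    (2 / D1) * (J - 1) * (J / l2)
  list(P1 = P1, P2 = P2)
}

#' Nominal stress of unconfined uniaxial extension
#'
#' Solves the traction-free lateral condition P_lat = 0 for the lateral
#' stretch by a damped Newton iteration with bisection fallback (tolerance
#' 1e-10 on the lateral stress relative to E), then returns the axial nominal
#' (first Piola-Kirchhoff) stress. Vectorised over `stretch`.
#'
#' @param params `neo_hookean_params`.
#' @param stretch axial stretch(es), > 0.
#' @return nominal stress, MPa; the lateral stretch is attached as
#'   attribute `"lateral_stretch"`.
#' @export
uniaxial_nominal_stress <- function(params, stretch) {
  stopifnot(inherits(params, "neo_hookean_params"), all(stretch > 0))
  l1 <- as.numeric(stretch)
  l2 <- l1^(-params$nu)            # small-strain initial guess
  tol <- 1e-10 * params$E
  for (it in 1:100) {
    P <- .uniaxial_P(params, l1, l2)
    if (all(abs(P$P2) <= tol)) break
    h <- pmax(1e-7, 1e-7 * l2)
    dP <- (.uniaxial_P(params, l1, l2 + h)$P2 - .uniaxial_P(params, l1, l2 - h)$P2) / (2 * h)
    step <- P$P2 / dP
    step <- pmin(pmax(step, -0.2), 0.2)  # damping
    l2 <- pmax(l2 - step, 1e-3)
  }
  P <- .uniaxial_P(params, l1, l2)
  if (any(abs(P$P2) > 1e3 * tol))
    stop("lateral-stress root-find failed to converge")
  structure(P$P1, lateral_stretch = l2)
}

#' Fit the initial modulus to a tensile test curve
#'
#' Converts the curve to nominal stress (force / CSA) against stretch
#' (1 + displacement / gauge length), restricts to the ascending pre-failure
#' region with force between `band[1]` and `band[2]` of the failure force,
#' and least-squares fits the uniaxial neo-Hookean response with a free toe
#' strain offset: stress ~ P_nh(stretch - eps0; E). Because the model stress
#' is exactly proportional to E at fixed stretch, the fit is a 1D search
#' over eps0 with E obtained in closed form by regression through the origin.
#'
#' @param curve a `test_curve` (see [test_curve()]).
#' @param nu Poisson's ratio used in the model.
#' @param band force band (fractions of failure force) defining the fit
#'   region.
#' @param monotone_tol maximum tolerated relative force drop inside the fit
#'   region before the curve is declared non-monotone.
#' @return list with `E` (MPa), `eps0` (toe strain offset), `resid_norm`
#'   (root-mean-square stress residual, MPa) and `n_used`.
#' @export
fit_initial_modulus <- function(curve, nu = 0.49, band = c(0.2, 0.95),
                                monotone_tol = 0.1) {
  stopifnot(inherits(curve, "test_curve"))
  f <- curve$force
  fmax_i <- which.max(f)
  fmax <- f[fmax_i]
  if (fmax <= max(1e-9, curve$preload * 1e-3 + 1e-9) || fmax <= 0)
    stop("flat or zero-force curve: nothing to fit")
  idx <- which(seq_along(f) <= fmax_i & f >= band[1] * fmax & f <= band[2] * fmax)
  if (length(idx) < 10) stop("fewer than 10 samples in the fit band")
  if (min(diff(f[idx])) < -monotone_tol * fmax)
    stop("non-monotone force in the fit region beyond the configured noise band")
  stretch <- 1 + curve$displacement[idx] / curve$gauge_length
  stress <- f[idx] / curve$csa
  max_eps0 <- max(0, min(stretch) - 1 - 1e-4)

  sse_for <- function(eps0) {
    s_model1 <- uniaxial_nominal_stress(neo_hookean_from_modulus(1, nu), stretch - eps0)
    E_hat <- sum(s_model1 * stress) / sum(s_model1^2)
    c(sum((E_hat * s_model1 - stress)^2), E_hat)
  }
  if (max_eps0 <= 1e-8) {
    opt_eps0 <- 0
  } else {
    opt_eps0 <- stats::optimize(function(e) sse_for(e)[1], c(0, max_eps0), tol = 1e-9)$minimum
    if (sse_for(0)[1] <= sse_for(opt_eps0)[1]) opt_eps0 <- 0
  }
  res <- sse_for(opt_eps0)
  if (!is.finite(res[2]) || res[2] <= 0) stop("modulus fit diverged")
  list(E = res[2], eps0 = opt_eps0,
       resid_norm = sqrt(res[1] / length(idx)), n_used = length(idx))
}
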