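# Seeded synthetic-data generators. Each generator is a pure function of
# its specification and seed: identical inputs give identical outputs. The
# generators state the world the analyses assume: tensile curves with a toe
# region joined to a neo-Hookean response, stimulation cohorts with a
# soleus-specific age deficit at the design effect size, and jittered
# geometry parameter sets around the three archetypes.

#' Synthetic tensile test curve
#'
#' Nominal stress follows a quadratic toe region joined C1 to the uniaxial
#' neo-Hookean response at initial modulus `E` (implemented as the
#' neo-Hookean curve shifted by a toe strain offset, with the quadratic
#' coefficient chosen for continuity of value and slope at the junction),
#' truncated by failure at `failure_strain` with a force drop of at least
#' 20 percent. Multiplicative Gaussian noise is applied to the force.
#'
#' @param E generating initial modulus, MPa.
#' @param csa cross-sectional area, mm^2.
#' @param gauge_length gauge length, mm (protocol: 60).
#' @param toe_strain toe-region strain extent (default 2 percent).
#' @param failure_strain strain at maximum force (specimen range roughly
#'   8-19 percent; default 15 percent).
#' @param preload preload, N.
#' @param rate pull rate, mm/s (protocol: 0.75).
#' @param noise multiplicative force noise SD (fraction).
#' @param seed RNG seed.
#' @param nu Poisson's ratio of the generating model.
#' @param fs sampling rate, Hz.
#' @return a `test_curve`.
#' @export
gen_test_curve <- function(E, csa, gauge_length = 60, toe_strain = 0.02,
                           failure_strain = 0.15, preload = 10, rate = 0.75,
                           noise = 0, seed = 1L, nu = 0.49, fs = 20) {
  stopifnot(E > 0, csa > 0, gauge_length > 0, toe_strain > 0,
            failure_strain > toe_strain, rate > 0, noise >= 0)
  params <- neo_hookean_from_modulus(E, nu)
  # C1 join: post-toe stress = P_nh(1 + eps - eps0); toe = a * eps^2.
  # Continuity of value and slope at eps_t fixes eps0 (root-find) and a.
  eps_t <- toe_strain
  g <- function(eps0) {
    s <- uniaxial_nominal_stress(params, 1 + eps_t - eps0)
    h <- 1e-6
    sp <- (uniaxial_nominal_stress(params, 1 + eps_t - eps0 + h) -
             uniaxial_nominal_stress(params, 1 + eps_t - eps0 - h)) / (2 * h)
    2 * s / eps_t - sp
  }
  eps0 <- stats::uniroot(g, c(1e-6, eps_t * 0.999), tol = 1e-12)$root
  a_toe <- as.numeric(uniaxial_nominal_stress(params, 1 + eps_t - eps0)) / eps_t^2

  t_fail <- failure_strain * gauge_length / rate
  t_end <- t_fail * 1.15
  tm <- seq(0, t_end, by = 1 / fs)
  dm <- rate * tm
  eps <- dm / gauge_length
  stress <- ifelse(eps <= eps_t, a_toe * eps^2,
                   as.numeric(uniaxial_nominal_stress(params, pmax(1 + eps - eps0, 1))))
  # failure: sharp drop to 40 percent of peak beyond the failure strain
  s_fail <- a_toe * eps_t^2
  s_fail <- stress[max(which(eps <= failure_strain))]
  post <- eps > failure_strain
  stress[post] <- s_fail * pmax(0.4, 1 - 8 * (eps[post] - failure_strain) / failure_strain)
  force <- stress * csa
  if (noise > 0) {
    withr_seed <- seed
    old <- .Random.seed_safe_set(withr_seed)
    force <- force * (1 + noise * stats::rnorm(length(force)))
    on.exit(old(), add = TRUE)
  }
  test_curve(tm, dm, force, gauge_length = gauge_length, csa = csa, preload = preload)
}

# Set the RNG deterministically and return a restorer.
.Random.seed_safe_set <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
}

#' Synthetic stimulation cohort
#'
#' For each participant and stimulated muscle a reference (contracted
#' muscle) trace and a soleus-MTJ trace are generated as smoothed
#' trapezoidal pulse trains (3 cycles of 4 s on / 4 s off after a lead-in),
#' with plateau amplitudes chosen so the normalized displacement is
#' Normal(group mean, sd). Group means are separated by `d * sd` for the
#' soleus trial (the age-related sliding deficit) and equal for the
#' gastrocnemii trials.
#'
#' @param n_young,n_old group sizes (study design: 9 and 7).
#' @param d named effect sizes per stimulated muscle (default soleus 1.9,
#'   gastrocnemii 0).
#' @param mean_norm,sd_norm mean and within-group SD of the normalized
#'   displacement (defaults 0.5 and 0.12, chosen so d = 1.9 stays in the
#'   positive range).
#' @param trace_noise additive trace noise SD, mm.
#' @param on_s,off_s,cycles,lead_in_s cycle timing, s.
#' @param fs sampling rate, Hz (ultrasound video rate).
#' @param ref_amplitude reference-muscle plateau displacement, mm.
#' @param muscles stimulated muscles to generate (all three by default).
#' @param seed RNG seed.
#' @return list of `stim_trial`s.
#' @export
gen_cohort <- function(n_young = 9L, n_old = 7L,
                       d = c(LG = 0, MG = 0, SOL = 1.9),
                       mean_norm = 0.5, sd_norm = 0.12, trace_noise = 0.02,
                       on_s = 4, off_s = 4, cycles = 3L, lead_in_s = 2,
                       fs = 25, ref_amplitude = 2, muscles = SUB_TENDONS,
                       seed = 1L) {
  stopifnot(n_young >= 1, n_old >= 1, sd_norm > 0, all(muscles %in% SUB_TENDONS))
  restore <- .Random.seed_safe_set(seed)
  on.exit(restore(), add = TRUE)
  t_end <- lead_in_s + cycles * (on_s + off_s)
  tm <- seq(0, t_end, by = 1 / fs)
  onsets <- lead_in_s + (seq_len(cycles) - 1) * (on_s + off_s)
  pulse <- function(amp) {
    y <- numeric(length(tm))
    rise <- 0.8
    for (t0 in onsets) {
      up <- pmin(pmax((tm - t0) / rise, 0), 1)
      down <- pmin(pmax((t0 + on_s - tm) / rise + 1, 0), 1)
      y <- y + amp * pmin(up, down)
    }
    y
  }
  groups <- c(rep("young", n_young), rep("old", n_old))
  ids <- sprintf("P%02d", seq_along(groups))
  trials <- list()
  for (i in seq_along(groups)) {
    for (mu in muscles) {
      dd <- if (mu %in% names(d)) d[[mu]] else 0
      gmean <- mean_norm + (if (groups[i] == "young") +0.5 else -0.5) * dd * sd_norm
      ratio <- stats::rnorm(1, gmean, sd_norm)
      ratio <- max(ratio, 0.02)
      ref <- pulse(ref_amplitude) + trace_noise * stats::rnorm(length(tm))
      mtj <- pulse(ref_amplitude * ratio) + trace_noise * stats::rnorm(length(tm))
      trials[[length(trials) + 1L]] <-
        stim_trial(ids[i], groups[i], mu, tm, mtj, ref, onsets, on_s)
    }
  }
  trials
}

#' Jittered geometry parameters around an archetype
#'
#' Multiplicative Gaussian jitter (SD = `jitter` of the default) on total
#' CSA and area fractions, additive jitter on the total twist; non-physical
#' draws are clipped (with a message). Zero jitter returns the archetype
#' defaults exactly.
#'
#' @param model_id archetype 1, 2 or 3.
#' @param jitter fractional jitter level (>= 0).
#' @param seed RNG seed.
#' @return named list usable as `overrides` in [make_archetype()].
#' @export
gen_geometry_params <- function(model_id, jitter = 0, seed = 1L) {
  stopifnot(jitter >= 0)
  def <- .archetype_defaults[[as.character(model_id)]]
  if (is.null(def)) stop("unknown model_id: ", model_id)
  if (jitter == 0)
    return(list(csa = def$csa, length = def$length, twist = def$twist,
                fractions = .default_fractions))
  restore <- .Random.seed_safe_set(seed)
  on.exit(restore(), add = TRUE)
  clip <- function(x, lo, what) {
    if (any(x < lo)) {
      message("gen_geometry_params: clipped non-physical ", what)
      x <- pmax(x, lo)
    }
    x
  }
  csa <- clip(def$csa * (1 + jitter * stats::rnorm(1)), 1, "CSA")
  fr <- clip(.default_fractions * (1 + jitter * stats::rnorm(3)), 0.02, "fractions")
  twist <- clip(def$twist + jitter * def$twist * stats::rnorm(1), 0, "twist")
  list(csa = csa, length = def$length, twist = twist,
       fractions = fr / sum(fr) * sum(.default_fractions))
}
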