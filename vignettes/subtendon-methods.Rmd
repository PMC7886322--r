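---
title: "Modelling sub-tendon sliding in the human Achilles tendon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sub-tendon sliding in the human Achilles tendon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(subtendon)
```

## The problem

The human Achilles tendon is not one rope but three: distinct sub-tendons
arise from the lateral gastrocnemius (LG), medial gastrocnemius (MG) and
soleus (SOL) muscles and remain separable along the free tendon. The
interfaces between them permit longitudinal sliding in young tendon and
stiffen with age. How much the sliding capacity matters — for the
displacement of the soleus musculotendinous junction (MTJ, the landmark
used by essentially all in vivo ultrasound studies of Achilles mechanics)
and for the internal stress distribution — depends on the individual
geometry of the sub-tendons: their cross-sectional areas (CSA), lengths
and twist.

This package implements that entire chain as testable code: parametric
three-sub-tendon geometries, a nonlinear finite-element (FE) solver with a
tunable sliding interface, the displacement and stress outcome measures,
the tensile-test and stimulation-trial analyses, and seeded generators for
every input the pipeline needs.

## Parametric geometry

Only a handful of quantitative geometric facts are available per dissected
tendon: total CSA, free-tendon length, the proximal arrangement (SOL
anterior, MG posterior-medial, LG posterior-lateral) and a qualitative
lateral twist toward the distal insertion. `make_archetype()` encodes
exactly these: an elliptical outer boundary (width-to-thickness ratio 2.5,
a typical mid-portion Achilles shape) is split by two chords so the three
regions carry the mean sub-tendon area fractions (9.3 : 13.4 : 32.8, from
the packaged specimen table), stacked every 10 mm with a linear twist.

The three archetypes are: archetype 1, long and twisted (70 mm,
89.1 mm^2); archetype 2, short and thick (40 mm, 90.4 mm^2); archetype 3,
short and thin (40 mm, 42.3 mm^2). No numeric twist angles were recorded
for the dissected tendons; the defaults are stated assumptions, not
measurements: archetype 1 twists 90 degrees in total (its LG reaches the
anterior surface distally, implying roughly a quarter turn) and archetypes
2–3 twist 40 degrees. Both are plain parameters (`twist` override) and the
trend conclusions below were checked to be insensitive to halving them.

The cross-sections are genuinely parametric, not traced from photographs;
individual shape irregularities, the flattened distal insertion, and the
aponeurosis are deliberately out of scope. A green trend test therefore
establishes that the *mechanism* (geometry-dependent load transfer through
a tunable interface) behaves as described, not that any particular
dissected tendon is reproduced.

## Mesh

`loft_mesh()` triangulates the partitioned section once (Bowyer–Watson
Delaunay with hexagonal interior seeding and Laplacian smoothing; the two
chords are shared point-for-point between regions so the mesh conforms),
extrudes it along z applying the per-level rotation, splits each prism
into three tetrahedra with the minimum-global-index diagonal rule (which
guarantees neighbouring prisms agree on quad-face diagonals), and inserts
shared edge midpoints to form straight-sided 10-node tetrahedra (TET10).

Interface nodes are then duplicated per sub-tendon and matched into pairs
carrying a local orthonormal frame — interface normal `n`, longitudinal
tangent `t1` (the projection of the z axis onto the surface) and in-plane
transverse tangent `t2` — plus a tributary area (each quadratic interface
face contributes one sixth of its area to each of its six nodes).

Units are mm / N / MPa throughout (1 N/mm^2 = 1 MPa). Distal is z = 0; the
models end 10 mm proximal to the calcaneus, where the real fascicles
intertwine, and that face is rigidly fixed.

## Material

Each sub-tendon is compressible neo-Hookean,
$W = C_{10}(\bar I_1 - 3) + \tfrac{1}{D_1}(J-1)^2$, parameterised by its
initial (small-strain) modulus: $C_{10} = E / (4(1+\nu))$,
$D_1 = 6(1-2\nu)/E$. The packaged defaults are the moduli obtained by
curve-fitting uniaxial test data — LG 226.7, MG 143.2, SOL 103.1 MPa —
which deliberately differ from the tabulated linear-region Young's moduli
of the test specimens: the former parameterise the simulation, the latter
summarise the specimens. Poisson's ratio is not reported anywhere;
`nu = 0.49` (near-incompressible soft tissue) is the default and all
modulus-level behaviour is defined at the stated E regardless of nu.

`uniaxial_nominal_stress()` solves the traction-free lateral condition by
a damped Newton iteration (tolerance 1e-10) and is the analytic oracle for
both the solver verification and the modulus fit. Because the stress is
exactly proportional to E at fixed stretch, `fit_initial_modulus()` needs
only a 1-D search over a toe-strain offset with E in closed form — exact
on noiseless generated curves.

## Solver

`solve_static()` is a total-Lagrangian Newton solver: internal forces and
the consistent material-plus-geometric tangent of the TET10 elements are
assembled in compiled code (4-point Gauss rule), the interface adds
node-pair penalties, and the sparse symmetric system is factorised with
CHOLMOD (LDL', because the tangent passes through indefinite states while
the transverse rotation of the twisted stack develops).

The interface is the discrete analogue of a surface-to-surface
translational joint: the normal (n) and transverse (t2) relative
displacements of each pair are penalised bilaterally — separation and
interpenetration are both resisted — while the longitudinal (t1)
behaviour selects the mode: free (frictionless), tied (bonded), or an
elastic-predictor/return-mapping Coulomb law capped at $\mu |F_n|$
(frictional), with the slip reference updated once per converged load
increment (the loading is monotone, so a single stick reference per
increment suffices). Penalty defaults are $k_n = k_t = 10^3$ MPa/mm per
unit tributary area; doubling them moves the outcome scalars by less than
1 % (tested), and a very stiff bonded penalty reproduces a merged-node
mesh within 0.5 % (tested).

Numerical behaviour worth knowing about:

* The 100 N loads are applied as uniform tractions over the loaded
  sub-tendon's proximal face (corner nodes of a quadratic face receive
  zero, midside nodes A/3 — the consistent load vector), ramped linearly.
  `ramp_steps` is a hint: increments are halved adaptively when Newton
  stalls and re-grown after success. A backtracking line search with a
  persistent starting step handles the long finite-rotation path — these
  thin, soft structures (E ~ 100 MPa, millimetre sections) bend and
  untwist visibly before tension stiffening takes over, and the first load
  increments are genuinely the hardest part of the solve.
* Pair frames are *convected*: each pair stores one adjacent interface
  face, and (n, t1, t2) are rebuilt from that face's deformed geometry at
  the start of every load increment (then frozen during the Newton
  iterations of the increment). With fixed reference frames, the finite
  transverse rotation of the twisted stack (up to ~10 degrees here) would
  convert true tangential sliding into parasitic normal penalty force and
  make the frictionless solution depend visibly on the penalty stiffness.
  The facet's own normal is used (not a nodal average): the penalty
  constrains the faceted discrete surfaces, so the facet frame is the
  consistent choice. The residual penalty-stiffness sensitivity decreases
  with mesh refinement: doubling k moves the soleus-face displacement by
  about 1.2 % at a 5 mm mesh and below 1 % from about 3 mm (tested).
* Within a sweep, interfaces are solved stiffest-first (bonded, then
  descending mu, then frictionless), warm-starting each solve from the
  previous one at full load; a failed warm start falls back to a cold
  ramp. For the monotone proportional loading used here the converged
  state is insensitive to this path (bonded/frictionless are
  path-independent; the frictional return mapping from a single full-load
  application coincides with the ramped path for proportional loading).
* Near convergence of a frictional solve the stick/slip active set and the
  slip-force caps are frozen once the relative residual falls below 1e-3,
  which stops active-set chattering; the normal force moves by well under
  1 % afterwards, so the converged state satisfies the Coulomb condition
  to the tested 1 % tolerance.
* Convergence is declared at relative residual 1e-6; global equilibrium
  (reactions + applied loads) closes to better than 1e-4 of the applied
  load (tested).

## Outcome measures

`mean_face_displacement()` is the area-weighted nodal average of the
longitudinal displacement over the proximal soleus face — the quantity an
ultrasound probe at the soleus MTJ tracks. Normalization
(`normalize_sweep()`) divides by the frictionless row within each
(model, load) group. `stress_summaries()` reports the volume-weighted mean
von Mises stress of the whole tendon (a plain element mean is available;
the choice is not documented in the source protocol) and the peak von
Mises stress excluding one element ring next to the rigidly fixed distal
face, where the constraint concentrates stress as a discretisation
artefact (`exclusion_layers = 0` restores the strict definition). Peak
locations are classified by the dominant axis of the nearest exterior face
normal (±y posterior/anterior, ±x lateral/medial; interface-adjacent or
buried peaks are "internal", and near-ties go to "internal").

## Statistics

The in vitro analysis reads per-specimen tensile metrics from failure
curves: failure force at the curve maximum (a ≥ 20 % drop must follow),
ultimate stress and strain from it, and stiffness / Young's modulus as the
maximum straight-line slope of a window slid over the ascending limb
between 20 % and 80 % of the failure force — a deterministic reading of
"the slope of the linear region", which excludes both toe and yield.
Because a neo-Hookean post-toe segment is genuinely curved (its tangent
falls ~4 % below E by 2 % strain), this slope estimator systematically
underestimates the generating modulus of synthetic curves by a few
percent; exact recovery is the job of the model-based
`fit_initial_modulus()`.

Group comparisons are exact: `kruskal_wallis()` uses mid-ranks with tie
correction, and `mann_whitney_exact()` evaluates the permutation
distribution of the rank sum exactly for combined samples up to 20
(dynamic programming without ties, complete enumeration with ties),
doubling the smaller tail. Post hoc comparisons of each gastrocnemius
against the soleus are flagged at p < 0.017 (Bonferroni 0.05/3 as
printed). At n = 5 vs 5 with complete separation the exact p is
2/252 ≈ 0.0079.

The in vivo statistic is the peak soleus-MTJ displacement per stimulation
cycle — maximum over the 4 s on-phase relative to the median of the 0.5 s
pre-onset baseline — aggregated across the ≥ 3 cycles by the median (the
aggregation is not documented in the source protocol; the median is robust
to a single corrupted cycle), then normalised by the contracted muscle's
own peak displacement. `sample_size_two_group_t()` computes the a priori
sample size with the noncentral t distribution; at d = 1.9, alpha = 0.05
and power 0.90 the one-tailed computation returns a total of 12 (the
published design total), while a two-tailed test would need 14 — which is
why the one-tailed reading is adopted, with the tails flag explicit. The
"beta = 0.90" of the design is read as the power, the G*Power convention.

## Synthetic data

`gen_test_curve()` joins a quadratic toe region C1-continuously to the
uniaxial neo-Hookean response at the generating modulus and truncates it
with a sharp post-peak drop; the toe shape is invented but parameterised,
because the analyser must tolerate a toe region to be credible on real
curves. `gen_cohort()` builds smoothed trapezoidal pulse trains (3 cycles
of 4 s on / 4 s off at 25 Hz, the video rate of a typical ultrasound
loop) whose plateau ratios are Normal(group mean, SD), with the young/old
means separated by d x SD for the soleus trial and equal for the
gastrocnemii; defaults n = 9 young, n = 7 old, mean 0.5, SD 0.12 — chosen
once so that d = 1.9 stays comfortably inside the positive range — and
d = (0, 0, 1.9) for (LG, MG, SOL). `gen_geometry_params()` jitters the
archetype parameters for population-variability experiments. All
generators are pure functions of (spec, seed).

## Desk-scale economics

The archetype sweeps in the test suite run at coarse meshes (edge length
5-7 mm, a few hundred to ~1,500 TET10 elements per model) with the stated
10-increment ramp, so the whole friction x load x model grid fits a
single-CPU budget of minutes. The trend conclusions (displacement
monotonicity in mu, bonded-vs-frictionless mean stress ordering) are
already stable at this resolution; peak-stress *locations* are the most
mesh-sensitive output and are reported but not asserted at desk scale.
`converge_mesh()` implements the 1 % refinement criterion when proper
resolution is wanted.

Two documented divergences between this parametric world and the source
observations are left as failing expectations rather than papered over:

* Among the archetypes, the *relative* increase of soleus-face
  displacement under gastrocnemius load (normalized to frictionless) is
  largest for the short archetypes, not the long twisted one. Their
  near-zero frictionless gastrocnemius-to-soleus coupling inflates the
  normalized ratio; the long archetype has by far the largest *absolute*
  coupling, but the elliptical chord-partitioned sections evidently do not
  reproduce the interdigitated real geometry whose frictionless baseline
  coupling set the published ordering.
* The power of the exact two-sided Mann-Whitney test on the synthetic
  stimulation cohort at the design effect size (d = 1.9, n = 9 vs 7) is
  about 0.89 over the fixed seed set, just under the 0.90 design target.
  The design value derives from a one-tailed t-test computation (power
  0.97 at these group sizes); the exact nonparametric two-sided test
  achieves about 0.91 under ideal normal sampling, and the trace-level
  analysis (peak extraction under measurement noise) costs the remaining
  margin.

## Known limitations

* Sections are idealised ellipse partitions; real sub-tendon borders are
  irregular and the distal insertion is not modelled.
* The frictional interface couples conforming node pairs; there is no
  large-sliding contact search, consistent with the small relative
  displacements (< 2 mm) of the loading protocol.
* The peak-stress tangent coupling of the frozen slip cap and the
  area-lumped interface weights introduce errors well below the 1 %
  verification tolerances, but they are approximations.
* Viscoelasticity, anisotropy and failure are out of scope; the material
  is parameterised entirely by an initial modulus.
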