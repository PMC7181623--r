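---
title: "Methods: simulating impact damage to bone around a dental implant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating impact damage to bone around a dental implant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A dental implant has no periodontal ligament: a transient blow — a fall, a
sports impact, a traffic accident — transmits force directly into the
alveolar bone and propagates through the implant–bone composite as stress
waves. When local stress exceeds the bone's dynamic strength, trabeculae
fracture and the osseointegrated interface fails, even when the cortical
surface looks intact. `osseoimpact` models this chain end to end: dynamic
material properties from split Hopkinson pressure bar (SHPB) analysis, an
explicit elastodynamic finite-element simulation of a rigid ball striking an
implant embedded in bone, and a von Mises yield / element-deletion damage
rule, exercised over a load magnitude x direction matrix.

## SHPB stress-wave analysis (`shpb_*`, `specimen_*`)

A specimen sandwiched between two long elastic bars is loaded by a
compressive pulse; strain gauges at the bar midpoints record the incident
(`eps_I`), reflected (`eps_R`) and transmitted (`eps_T`) waves.
One-dimensional stress-wave theory gives the specimen histories

  sigma_s(t)   = E (A_b / A_s) eps_T(t)
  eps_s(t)     = -(2 C0 / l_s) \int_0^t eps_R dt
  eps_dot_s(t) = -(2 C0 / l_s) eps_R(t)

with `E`, `A_b`, `C0 = sqrt(E/rho)` the bar modulus, cross-section and wave
speed, and `l_s`, `A_s` the specimen length and cross-section. We adopt a
compression-positive convention throughout; the reflected wave is then
negative and carries the minus signs above. Records measured with the
opposite polarity can be declared `tension_positive` and are flipped on
entry. Integration is cumulative trapezoidal on the (required) uniform time
grid, so the strain-rate output integrates back to the strain output
exactly.

The forward generator `synthesize_waves()` is the package's oracle: it
emulates the rig for an elastic–perfectly-plastic specimen under the
standard quasi-static specimen-equilibrium assumption. The incident pulse is
a trapezoid of amplitude `v/(2 C0)` (striker velocity `v`) and duration
`2 L_striker / C0` with 10% rise and fall; at each sample the transmitted
strain solves force equilibrium `sigma(eps_s) A_s = E A_b eps_T`, fixed-point
iterated to 1e-10, with the specimen strain advanced trapezoidally. Because
the generator and the analyzer share only the physics (not the code path),
round-tripping a synthetic record through the analysis and
`extract_yield_strength()` is a genuine parameter-recovery test; it recovers
yields across a broad modulus/yield grid to well within 1%.

Yield extraction defaults to the plateau method: the initial modulus is
fitted to the early loading branch (origin-constrained, points below 20% of
peak strain) and the plateau is the set of loading samples whose tangent
modulus falls below 10% of it. The 10% threshold is deliberately loose: for
elastic–perfectly-plastic response the tangent drops to ~0 at yield, so any
threshold well below 1 works; 10% tolerates discretization noise near the
knee. A fully linear curve returns an explicit no-yield result rather than
an error, since a valid test can simply not reach yield. The 0.2%-offset
method is available for hardening materials.

Defaults mirror the rig that measured the bone: steel bars (E = 209 GPa,
rho = 7830 kg/m^3, C0 ~ 5166 m/s, 14.5 mm diameter), striker ~10 m/s, which
puts the specimen strain rate at the order of 1e3 1/s.

## Geometry (`geometry_params()`, `build_mesh()`)

Rather than reconstructing micro-CT volumes, the mesh is parametric: a
structured hexahedral grid over a bone block, each cell split into 6
tetrahedra along a common diagonal (Kuhn subdivision). This is conformal by
construction — every interior face is shared by exactly two tets — so the
implant–bone "tie constraint" (perfect osseointegration) is realized exactly
as shared nodes, and node/element counts are analytic. Elements are labeled
by centroid: inside the implant cylinder (diameter 4 mm, length 8 mm,
entering from the top face) -> `IMPLANT`; within 1.5 mm of the outer block
surface -> `CORTICAL`; else `CANCELLOUS`. The default block is
12 x 12 x 16 mm at 1 mm spacing — 13,824 tets, a desk-scale stand-in for the
anatomic model; the damage findings the package reproduces are ordinal
(monotonicity, worst direction, peak ordering) and are checked at this
scale, with finer grids available through the config.

Cancellous bone defaults to a homogeneous effective continuum, consistent
with continuum-level yield data. `apply_trabecular_porosity()` can knock out
a random fraction of cancellous elements (seeded, reproducible) as a crude
stand-in for unresolved trabecular architecture; it is opt-in and off by
default. What the generator does **not** emulate: real trabecular geometry,
implant threads (a smooth cylinder bonds over its whole surface; threads
concentrate stress locally), anisotropy, or marrow. Passing tests on this
geometry therefore validate the solver and the ordinal damage structure, not
patient-specific stress magnitudes.

The two block faces normal to one transverse axis are clamped
(`select_fixed_nodes()`), mirroring a specimen held on opposite sides;
clamping the loaded (entry) face is rejected.

## Explicit dynamics (`fe_model()`, `fem_run()`)

Small-strain linear kinematics on constant-strain tetrahedra with isotropic
Hooke's law; lumped mass (each element's `rho V` split equally over its 4
nodes); central-difference (leapfrog) time integration. Small strain is
adequate because the failure rule deletes elements before large strains can
accumulate. The stable step is `cfl_factor` (default 0.5) times the minimum
over active elements of altitude / dilatational wave speed; with contact
active, the penalty-oscillator limit `2/omega` is also applied. The energy
ledger records the leapfrog invariant (staggered kinetic product plus strain
and penalty energy) and drifts by well under 1% of peak kinetic energy; it
is the cheapest global integrator diagnostic and is exported with every run.

The impactor is a rigid sphere (default: the 1.5 cm, 15 g drop ball)
coupled to the implant's exposed top patch by frictionless penalty contact —
force `k g` along the sphere normal on each penetrating node, with the
equal-and-opposite resultant on the sphere, so linear momentum is conserved
exactly. The penalty stiffness defaults to 10x the stiffest contact-adjacent
nodal stiffness estimate `E h`: penetrations are then ~1 um (negligible
against the 1 mm grid) while the contact frequency stays at the mesh CFL
scale; a stiffer spring would only shrink the stable step with no accuracy
gain.

The loading protocol forces the ball to be removed immediately after
contact. Implemented literally (removal at the instant of touch) no impulse
would be transmitted; left in place the ball plows the implant through the
block and turns a transient impact into sustained penetration. The rule used
is: removal at the first genuine separation (full gap with the sphere
receding), or at the latest one penalty half-period `pi sqrt(M/k)` (~12 us
at the defaults) after first touch — the natural duration of a single
bounce, identical across load conditions so the direction/magnitude
comparisons are fair. Before first touch, if the mesh is at rest, the
approach phase is skipped analytically and does not consume the simulated
time budget.

## Damage rule (`von_mises()`, `apply_failure()`)

Once per step, after the stress update, every active bone element whose von
Mises stress has **reached** its region's dynamic yield strength (cortical
180 MPa, cancellous 8.9 MPa by default — the SHPB results) is deleted:
stiffness removed, mass retained (standard element-deletion practice, which
avoids spurious momentum loss), stress reported as zero, irreversibly.
"Reached" is implemented as `>=`, so a tie at exactly the yield strength
deletes — matching the rule's wording. The implant is exempt: titanium does
not yield at bone-level stresses and the question under study is bone
damage. Deletion events carry element, region, time and stress; reports
count them by region and separately for the bone–implant interface
(elements within one grid spacing of the implant surface) — a view, not a
third region.

## The load matrix and its windows (`run_condition()`, `run_matrix()`)

Conditions are speed (4.0, 5.1, 6.3 m/s — free-fall speeds of the 0.8 m and
2.0 m drops round to the first and last) crossed with direction (0 deg =
axial, 45, 90 deg = horizontal, measured from the implant long axis; the
lateral component points along +x, toward a clamped face). The sphere is
aimed at the implant-top patch point extremal in the loading direction, at
a 2 mm standoff.

A run ends `post_window_factor` (default 5) contact durations after the
sphere separates **or after the last deletion event, whichever is later**,
capped by `t_end`. The extension matters: damage continues long after
unloading — the impact energy reverberates between the implant, the
cortical shell and the clamped faces, and cancellous elements keep failing
for tens of contact durations. Ending at a fixed small multiple of the
contact duration truncates exactly the delayed, reflection-driven damage
that distinguishes the oblique load case; with the quiescence rule every
condition is measured at its damage plateau. At the defaults, runs span
~0.5 ms of dynamics after first touch.

Two default probes track the stress history: `cortical_neck` (cortical ring
adjacent to the implant entry, half a grid spacing below the surface) and
`cancellous_apex` (1 mm below the implant tip, on the axis). A probe samples
the element nearest its point, identity fixed at the start; if that element
is deleted the curve is flagged truncated and ends at the deletion time.
Under axial loading the neck stress peaks during contact while the apex
stress builds gradually and peaks long after unloading, with most cancellous
deletions occurring after separation — the wave-driven damage sequence that
motivates the model.

`convergence_study()` reruns a fixed condition over non-increasing grid
spacings and monitors the peak probed von Mises stress, declaring
convergence when a level changes by less than 5% against the next finer
level.

## Numerical choices and degenerate inputs

* Voigt order `[11, 22, 33, 12, 23, 31]`, tensor shear components; SI units
  everywhere; 1-based indices at the R surface, 0-based in the compiled
  core.
* Tetrahedra are oriented to positive signed volume at build time; degenerate
  (zero-volume) elements are rejected.
* A non-uniform gauge time grid, a clamped loaded face, a porosity knockout
  that disconnects the implant from all bone, probing outside the mesh, and
  a fully linear stress–strain curve are all rejected or flagged explicitly
  rather than silently handled.
* No structural damping is applied by default; dissipation enters only
  through element deletion (each deleted element's stored energy leaves the
  ledger). Optional stiffness-proportional damping (`damping_beta` in
  `fe_model()`) adds the viscous stress `beta C : eps_dot` to the force
  assembly only — not to the failure criterion — and correspondingly tightens
  the stable time step by the standard `sqrt(1 + xi^2) - xi` factor.
* Determinism: the only random element is the optional porosity knockout,
  which requires a seed and restores the caller's RNG state; identical
  configurations reproduce runs bit for bit.

## Known limitations

The elastic constants of the three regions default to literature-typical
values (cortical E = 15 GPa, cancellous 0.5 GPa as an effective continuum,
CP titanium 110 GPa) and are flagged `assumed` in every report; the yield
strengths are the measured dynamic values. Absolute damage counts scale with
mesh resolution, window length and these moduli — they are comparative
quantities, not predictions. Strain-rate dependence of the moduli,
viscoelasticity, anisotropy, friction, implant thread mechanics and bone
remodeling are out of scope.

The homogeneous-continuum cancellous model also bounds which direction
effects the package can reproduce. Oblique (45 deg) loading is the worst
case at 4.0 and 5.1 m/s, as expected from the combined compression-shear
load path; at 6.3 m/s the axial case edges ahead by a few percent on the
default mesh, because the compressive pulse reflected at the implant tip
crosses the low cancellous yield over a broad column — a mechanism an
effective continuum exaggerates relative to real trabecular bone, whose
rod-and-plate architecture is disproportionately weak in the bending and
shear that oblique loading induces. The 0 vs 45 degree margin at the highest
speed is ~6-9% and sensitive to solver details at this resolution, so it
should be read as "comparable", not as a robust axial maximum.
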