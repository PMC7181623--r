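# osseoimpact

Simulation of transient impact damage to the bone surrounding an
osseointegrated dental implant, for biomechanics researchers and implant
engineers who need a reproducible, scriptable model of what a blow does to
peri-implant bone.

An implant has no periodontal ligament, so an impact — a fall, a sports
injury, an accident — feeds force straight into the alveolar bone and then
travels onward as stress waves through the implant–bone composite. The
package models the full chain:

* **SHPB analysis** — split Hopkinson pressure bar records (incident,
  reflected, transmitted bar strains ε_I, ε_R, ε_T) are converted to
  specimen histories by one-dimensional stress-wave theory,

  σ_s = E (A_b/A_s) ε_T,  ε_s = −(2C₀/l_s) ∫ ε_R dt,  ε̇_s = −(2C₀/l_s) ε_R,

  plus a forward generator of synthetic gauge records for
  elastic–perfectly-plastic specimens that serves as a parameter-recovery
  oracle, and plateau / 0.2%-offset yield extraction.
* **Parametric geometry** — a conformal tetrahedral mesh (structured
  hex-to-tet) of a Ø4 × 8 mm cylindrical implant bonded through a 1.5 mm
  cortical shell into cancellous bone; the tie constraint is realized as
  shared nodes.
* **Explicit elastodynamics** — central-difference integration on
  constant-strain tetrahedra with lumped mass, CFL-limited steps, clamped
  lateral faces, and a rigid 1.5 cm / 15 g sphere coupled by frictionless
  penalty contact and removed immediately after contact.
* **Damage rule** — an element whose von Mises stress reaches its region's
  dynamic yield strength (cortical 180 MPa, cancellous 8.9 MPa, from the
  SHPB tests) is deleted: stiffness removed, mass retained. Damage reports
  count ineffective elements by region and at the bone–implant interface.
* **Pipeline** — the 3 speed × 3 direction load matrix (4.0/5.1/6.3 m/s at
  0°/45°/90° from the implant axis), stress–time probes, a mesh-convergence
  study (5% tolerance on peak probed von Mises), and per-run reports
  (JSON metadata + CSV events/energy/probes).

## Worked example

Recover a dynamic yield strength from synthetic SHPB records, then run one
impact condition:

```r
library(osseoimpact)

bar  <- bar_properties(E = 209e9, rho = 7830)        # steel bars, C0 ~ 5166 m/s
spec <- specimen_geometry(length = 0.008, area = 6e-3 * 3e-3)  # cortical 6x3x8 mm
rec  <- synthesize_waves(epp_material(15e9, 180e6), spec, bar,
                         striker_velocity = 10)
y <- extract_yield_strength(reconstruct_curve(rec, bar, spec))
y$yield / 1e6
#> [1] 180
```

The recovered plateau stress equals the 180 MPa yield given to the
generator, validating the analysis chain at cortical-bone conditions
(strain rate ≈ 1.2 × 10³ 1/s here).

```r
r <- run_condition(load_condition(4.0, 0), default_config())
print(r)
#> impact run: 4.0 m/s at 0 deg
#> damage report (ineffective elements):
#>   total 66 | cortical 0 | cancellous 66 | interface 41
#>   contact 500 us to 516 us, 3800 steps of 47.8 ns
```

At 4 m/s axial loading the cortical shell survives (0 deletions) while 66
cancellous elements fail, 41 of them at the bone–implant interface — and 58
of the 66 *after* the sphere has unloaded, driven by the stress waves
ringing between implant, cortical shell and the clamped faces. The full
matrix (about 3 minutes on one CPU):

```r
run_matrix(c(4.0, 5.1, 6.3), c(0, 45, 90), default_config())
#>  speed_m_s angle_deg total cortical cancellous interface
#>        4.0         0    66        0         66        41
#>        5.1         0  1367      124       1243       865
#>        6.3         0  1788      150       1638       994
#>        4.0        45   936        6        930       679
#>        5.1        45  1419      134       1285       846
#>        6.3        45  1679      168       1511       895
#>        4.0        90   547       11        536       500
#>        5.1        90  1178      144       1034       776
#>        6.3        90  1222      136       1086       781
#> monotone in speed: angle_0=TRUE, angle_45=TRUE, angle_90=TRUE
#> argmax angle: speed_4=45, speed_5.1=45, speed_6.3=0
```

Damage grows with impact speed at every direction. Oblique (45°) loading is
the worst case at 4.0 and 5.1 m/s; at 6.3 m/s axial crushing of the
homogeneous cancellous continuum edges ahead of the oblique case by ~6% on
this mesh (see the vignette's limitations — an effective continuum lacks
the bending-weak trabecular architecture that penalizes oblique loading in
real bone). Counts are comparative quantities at the default desk-scale mesh
(13,824 tets), not absolute predictions.

A thin command-line driver is included at `inst/scripts/impactsim.R`
(subcommands `mesh | shpb | simulate | matrix | converge`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/impactsim.R", package="osseoimpact"))')" \
    matrix --out-dir out --seed 1
```

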