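---
title: "Image-based finite element assessment of osteochondral graft stability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based finite element assessment of osteochondral graft stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ocgraft` is an open, tested implementation of a specimen-specific finite
element methodology for the *immediate* (pre-osseointegration) mechanical
stability of osteochondral grafts: cylindrical bone-plus-cartilage plugs
press-fitted into drilled condylar holes. The pipeline has three arms that
mirror how such models are built and calibrated against bench experiments:

1. **Material property mapping** — micro-CT-style binary bone volumes are
   downsampled to a bone volume fraction (BV/TV) field and converted to
   per-element Young's moduli through a single linear factor, calibrated
   so virtual platen-compression stiffnesses match measured ones.
2. **Friction calibration** — interference-fit graft push-in tests are
   simulated over a grid of Coulomb coefficients, and the pair maximising
   Lin's concordance with measured push-in forces is selected.
3. **Tibiofemoral joint scenarios** — a two-condyle joint under axial
   load, with intact / defect / graft / pin cases per condyle, analysed
   through sensel-grid contact pressure maps as a thin-film pressure
   sensor would record them.

Because the cadaveric scans behind the original methodology are not
shipped, a seeded synthetic phantom generator stands in for them, and the
calibration arms are validated by *parameter recovery*: observations are
generated by the forward model at known parameters (plus optional noise),
and the calibrations must find those parameters again.

## Synthetic phantoms

`generate_trabecular_volume()` thresholds a Gaussian random field smoothed
to a chosen correlation length (default 0.6 mm, a typical trabecular
spacing). Thresholds are per-slice quantiles, so the achieved BV/TV equals
the target to within voxel-count rounding, both globally and per slice
when a depth gradient is requested. The gradient is centred on mid-depth
(the global mean stays at the target) and emulates the density decline
beneath the subchondral plate that makes host-site properties matter for
graft support. Default voxel size is 0.082 mm, mirroring HR-pQCT
acquisitions; generators are pure functions of (parameters, seed).

What the phantom does *not* emulate: anatomic trabecular architecture
(plate/rod morphology, anisotropy, fabric), cortical geometry, scanner
physics (noise spectra, beam hardening, partial volume). Passing
recovery tests therefore demonstrates that the *pipeline* is correct and
self-consistent at realistic density statistics — not that a particular
cadaveric specimen would be predicted accurately.

`generate_condyle_specimen()` pots an elliptical bone cylinder between
PMMA endcaps (platen compression specimens); a radial bias concentrates
bone toward the periphery like a shell without changing the global
fraction. `generate_graft_host_pair()` builds the push-in geometry: a
host block with a 6.35 mm hole drilled normal to the articular surface
and a 6.5 mm graft (0.15 mm diametral oversize), each with independent
microstructure. Cartilage thickness is not reported for the source
specimens; the 1.5 mm default is a typical human femoral value and is
configurable.

## Density mapping

The image chain is deliberately plain: fixed-threshold binarisation
(threshold is a required parameter; synthetic fixtures use 0.5),
block-mean downsampling (0.082 mm binned 2x to 0.164 mm; exact bone
volume conservation when the factor divides the shape), and per-element
modulus `E = max(floor, c x BV/TV)` MPa. Elements sample the BV/TV field
with a 5-point rule (vertices + centroid, nearest voxel); at 1 mm
elements over 0.164 mm voxels this stays within 2% of volume-weighted
averaging, which the tests verify against a dense-sampling oracle. The
floor (0.1 MPa) only prevents empty elements from making the stiffness
matrix singular. Bone Poisson's ratio defaults to 0.3 — a standard
choice for mapped trabecular models; neither it nor the binarisation
threshold is dictated by the methodology itself, so both are exposed.
The mapping is element-size dependent; meshes default to the 1 mm edge
at which the factor is calibrated.

## Meshing

Labelled volumes are resampled by majority vote onto cubes near the
target edge length and each cube splits into six Kuhn tetrahedra, which
makes conformity and positive volumes structural guarantees and keeps
the mesh a deterministic function of its inputs. Cylindrical plugs are
meshed by mapping a square-section block lattice onto the disc
(elliptical map), so the lateral wall lies exactly on the cylinder:
voxel staircases carry a geometric roughness of a third of the element
edge, far larger than the 0.075 mm radial interference that drives the
push-in physics. Articular surfaces of the synthetic joint are snapped
onto their analytic height field for the same reason.

## The finite element engine

Linear TET4 elements throughout (the methodology this follows found
<1% difference to quadratic elements for these outputs). Bone and PMMA
are linear elastic; cartilage is compressible neo-Hookean with
`W = G/2 (Ibar1 - 3) + K/2 (J - 1)^2`, K = 16.67 MPa, G = 1.37 MPa,
which linearises to E ~ 4 MPa, nu ~ 0.45. Kinematic couplings tie platen
or femoral surfaces to 6-DOF reference points (prescribed finite
rotations are exact Rodrigues rotations; free rotation DOFs use
linearised lever arms — adequate for quasi-static platen loading).
Constraints are imposed by elimination, so reactions come out of the
residual exactly.

Contact is node-to-surface penalty with Coulomb friction. Two gap
evaluations coexist:

* **mesh projection** (articular cartilage-on-cartilage): slave nodes
  project onto master triangles each iteration; the contact direction is
  the averaged slave-node normal, which varies smoothly where facet
  normals flicker.
* **analytic master surfaces** (bore wall, hole base, tibial plateau):
  the gap is measured against the exact cylinder/plane carried by the
  master body, with the slave position pulled back by the master
  displacement at a *fixed reference-configuration projection*. Master
  compliance is retained; facet noise is eliminated. This is what makes
  a 0.075 mm interference representable on 1-2 mm elements.

Numerical choices that mattered (all surfaced as defaults, none tuned
per-case): normal penalty 50x the softer neighbour's modulus per element
edge, with a C1 quadratic blend over the first 2 µm of penetration (the
stiffness jump at activation otherwise leaves Newton zigzagging around
nodes sitting at zero penetration); tangential penalty k_n/100 (the
~10 µm elastic pre-slip is irrelevant at 1 mm sliding distances, and a
razor-thin stick zone destabilises the solver); smooth tanh saturation
of the friction cap instead of a hard stick/slip switch; contact band
edges fade over 0.3 mm. The friction tangent is genuinely asymmetric
(the traction cap follows the normal force one way), so frictional
solves factorise with sparse LU; frictionless problems use sparse LDL'
(which handles the mildly indefinite tangents near contact activation
directly, with rank deficiency read off vanishing pivots and a diagonal
regularisation fallback).
Newton runs with increment clamping (half an element edge), backtracking
line search, factor reuse while progress is fast, adaptive increment
cutback (max 6 halvings), and a stagnation acceptance: residuals that
chatter below ~1.5% of the contact force scale (and above the absolute
tolerance of 0.05 N) are accepted — frictional micro stick/slip floors
the residual there while every reported force is converged to well under
a percent. Convergence additionally requires the *net* force residual of every
body (and every coupling reference) to vanish at a tighter bound: an
L2-small residual spread over thousands of dofs can otherwise hide a
whole-body force imbalance. Smooth problems reach 1e-6 relative as
usual. Force-controlled contact approach has no Newton path across an
open gap, so the joint inserts a small displacement-controlled settle
phase before the load ramp, and the synthetic condyles start in touch
with the tibial plateau.

Bodies held only by contact (the graft before its interference engages)
get weak grounding springs (5e-4 N/mm per node) and, during the
shrink-fit phase only, a centroid pin plus a tangential "spin" pin whose
reactions vanish by symmetry; the spin pin alone stays on during push
loading (it does not resist axial sliding).

The interference itself is resolved as a shrink fit: the permitted wall
penetration ramps from the radial interference down to zero over a few
equilibrium solves, leaving radial compressive pre-stress. On
homogeneous bodies the resulting mean wall pressure sits within ~20% of
the plane-strain thick-walled-cylinder (Lame) estimate, and the
friction-only push force within ~25% of mu x pressure x wall area —
both verified in the tests.

## Virtual experiments

*Compression*: encastre lower endcap, coupled upper endcap, 1 mm
prescribed displacement, stiffness as the force-window slope (the
experimental 400-600 N window is the default; synthetic desk-scale
specimens use a window they actually span, e.g. 40-80 N — the window is
a protocol parameter, not physics). The model is linear, so the slope
equals force/displacement.

*Push-in*: after the shrink fit, the 6 mm rigid flat indenter is
equivalent to prescribing the axial motion of the covered graft-top
nodes (the face is frictionless and the top is flat); the push-in force
is the reaction at 1 mm. Grafts seat on the hole base by default — the
experimental insertion endpoint, which also reproduces the below-flush
behaviour of a drill-depth/graft-length mismatch and makes host bone
under the hole carry much of the load (the host-site density-force
correlation emerges for exactly this reason). A flush seat with base
clearance is available and is what the zero-interference/zero-friction
"zero force" contract and the Lame friction oracle use.

*Joint*: two condylar half-ellipsoids (rotated analytically about the
medial-lateral axis for flexion) articulate on a flat tibial cartilage
plate — flat rather than dished, since the femur is guided laterally by
the rig-like coupling and a shallow dish adds nothing at these angles.
Tibial base encastre; 500 N ramped at the femoral reference with
in-plane translations and rotations held (the rig). Defects are open
drilled holes at the loaded contact point; grafts/pins are plugs seated
flush (or recessed) whose interference resolves in a pre-phase. Joint
bone is uniform linear elastic at `conversion factor x mean BV/TV`
(default 60 MPa): the synthetic joint carries no microstructure, and at
these loads the contact response is cartilage-dominated. The rigid
flush pin attracts a larger load share than an osteochondral graft in
this idealised congruent geometry — experimentally pins were
indistinguishable from intact; treat pin-case load shares as an upper
bound of the idealisation, not a prediction.

## Calibration statistics

Lin's concordance uses population (1/n) moments — at n = 12 the (n-1)
convention changes nothing visible, but the choice is fixed. The
conversion factor is fitted by golden-section minimisation of the RMS
percentage stiffness error over [10, 1000] MPa (bracketing literature
values); compression models are prepared once and reused per evaluation.
Friction is an explicit grid search (default 0.1-stepped rectangle
mu_bb in 0.1-0.9, mu_cb in 0.1-0.7; ties break toward the smaller pair,
lexicographically) because the response is near-flat in mu — the
recovered optimum is a cell, not a continuous estimate. With noise-free
forward-model observations both calibrations recover their generating
parameters (factor within 2%; friction at the exact cell with CCC ~ 1);
with 10% observation noise the factor stays within 15% and the RMS
objective rises to the mid-teens of percent, the same order as reported
for cadaveric specimens.

## Pressure-map analysis

FE contact output is rasterised to a sensel lattice (default 1.27 mm
pitch) by triangle supersampling with cloud-in-cell (bilinear)
deposition — adaptive to triangle size, conservative, and exact for
linear pressure fields — so the map integral equals the contact force
sum exactly; nodal pressures
for rasterisation use force over *projected* tributary area, which keeps
conservation exact even where a snapped surface folds slightly over a
staircase. Contact area is the non-zero-sensel count times the sensel
area (partial contact counts the full sensel — the sensor convention),
and the perimeter-sensel count times sensel area bounds the
overestimation from partial edge contact. Defect footprints are the
largest connected region inside the reference patch whose pressure drops
below a configurable fraction (default 50%) of the intact reference,
reported as axis-aligned extents in sensels; defects in soft-sensor maps
read as reduced rather than strictly zero pressure, hence the fractional
cutoff.

## Problem sizes and limitations

The test-suite and acceptance runs use 32³-56-slice phantoms at
0.164 mm, push-in meshes at 1.5-1.8 mm element edges (~3-8k elements)
and the joint at 1.5 mm (~40k elements) — sizes chosen so the full suite
runs in tens of minutes on one CPU while every oracle stays within its
stated tolerance. Known limitations: quasi-static and rate-independent
(no preconditioning, hold periods, or viscoelasticity), no damage or
plasticity (so no permanent subsidence), no menisci or ligaments, no
fabric/anisotropy in bone, penalty (not exact) contact, and a synthetic
joint geometry whose absolute contact-patch positions are
convention-dependent.
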