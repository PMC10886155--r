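---
title: "Modelling orthokeratology lens wear: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling orthokeratology lens wear: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(okfea)
```

Overnight orthokeratology (Ortho-K) reshapes the central cornea with a rigid
reverse-geometry contact lens: the treated cornea develops a central
flattened zone (CFZ) and an annular steepened zone (ASZ), measurable as a
refractive power change (RPC) map. `okfea` implements a desk-scale,
patient-specific modelling chain for this process: topography ingest,
tangential power and RPC mapping, treatment-zone and lens-decentration
detection, eyelid reconstruction from the topography coverage footprint,
hexahedral meshing of cornea / lens / eyelid, constrained ICP lens seating,
a staged implicit finite-element contact simulation, and quantitative
comparison of five FEA stress/strain "barometers" against the RPC map via
2D normalized cross-correlation (NCC) and the structural similarity index
(SSIM). This vignette records the science and, where the design was
genuinely open, why the package does what it does.

## Optics: tangential power and the RPC map

Corneal topographers deliver the anterior surface as elevation on a polar
grid (the package's clinical dialect uses 300 azimuths x 333 radial
stations). Tangential (instantaneous) curvature is the meridional curvature
of each radial profile,

$$R_t(r) = \frac{(1 + z'(r)^2)^{3/2}}{|z''(r)|},$$

evaluated with centered finite differences; profiles are continued through
the apex using the opposite semi-meridian so the map centre is well defined.
Power follows the reduced Gaussian optics formula
$P_t = (n_h - n_{air}) / R_t$ with the keratometric index $n_h = 1.3375$
and $R_t$ in metres; a 7.5 mm sphere maps to 45.0 D. The RPC map is the
elementwise post-wear minus pre-wear power on the intersection of validity
masks.

Power maps are smoothed with a DCT-based penalized least-squares smoother
(a discretized smoothing spline): the smoothed field minimises
$\|W^{1/2}(z - y)\|^2 + s\,\|Lz\|^2$ with $L$ the discrete Laplacian,
solved exactly in the DCT eigenbasis and iterated over the weights when the
map has gaps. The default factor $s = 4.5$ is meaningful only under this
convention, which is why the smoother is implemented rather than
approximated; an outermost-ring down-weight (weight 0.2) suppresses the
edge effect of finite maps. A robust (bisquare-reweighted) mode is
available for maps with outliers.

## Treatment-zone detection and decentration

Per semi-meridian, the zero crossings of the RPC profile are located by
linear interpolation; crossings within an edge-exclusion margin (default
0.5 mm, configurable) of the profile rim are discarded. The CFZ is the
central negative region bounded by the innermost admissible crossings.

For the CFZ centre the package departs from a pure |RPC|-weighted centroid
(kept as `estimator = "centroid"`). Tangential curvature is measured along
map-centred meridians, so a decentred, radially symmetric effect produces a
slightly asymmetric RPC field; the centroid is biased toward the map centre
by roughly 15% of the offset, which fails a 0.1 mm recovery target at
clinically common decentrations near 1 mm. The default estimator instead
fits algebraic circles to the CFZ boundary and to the outer ASZ boundary
and averages the two centres; their opposite-signed biases largely cancel,
and recovery errors stay below ~0.07 mm across the generator's range. The
decentration is the centre offset resolved into X and Y components.

## The synthetic cohort

The generator emulates the clinical measurement conditions so every stage
is testable without clinical data:

* metadata: age 14.1 +/- 4 y, IOP 15 +/- 3 mmHg, CCT 0.554 +/- 0.033 mm,
  right-eye fraction 132/249, all clipped to physiological ranges;
* pre-wear surfaces: conicoids with meridian-dependent apical radius from
  the sampled Sim-K (flat 42.6 +/- 1.3 D, steep 44 +/- 1.3 D) and
  meridian-dependent asphericity (0.66 +/- 0.1 / 0.4 +/- 0.18). The
  printed asphericity values do not state their sign convention; the
  generator treats them as conicoid eccentricity $e$ (so $Q = -e^2$,
  giving physiologically typical prolate corneas) and exposes `"Q"` and
  `"p"` conventions as alternatives;
* the Ortho-K effect is imposed in elevation space: a radially symmetric
  sag perturbation about the (decentred) effect centre whose curvature
  profile is a central flattening lobe, an annular steepening lobe and one
  outer compensation lobe whose amplitude is solved so the apex slope is
  zero; integrating the sag curvature inward from the compact-support rim
  conserves the surface exactly outside
  `annulus_radius + 2 * transition_width`. Amplitudes are calibrated in
  power space, so `central_flattening = -3` D produces approximately -3 D
  of measured RPC at the centre;
* coverage masks are bounded by upper/lower lid parabolas (cohort means
  from the clinical lid fits) with seeded slit-like eyelash gaps dropped
  radially inward from the lid edge;
* effect magnitudes: central flattening -2 +/- 0.6 D, annular steepening
  1.4 +/- 0.4 D, annulus radius 2.6 +/- 0.2 mm, decentration components
  N(0, 0.25) mm. These are the package's chosen study conditions: the
  flattening range brackets the cohort's observed Sim-K change (about
  -1.3 to -1.6 D on average, deeper in individual eyes).

What the generator does **not** emulate: microlattice measurement noise,
tear-film artefacts, diurnal regression of the effect, or epithelial
redistribution biology. Passing tests therefore demonstrate the analysis
chain's correctness and internal consistency, not clinical predictive
accuracy.

A single integer seed drives everything; per-case streams are hashed from
`(seed, index)`, so cases are reproducible individually and in parallel.

## Surface extension and meshing

Measured coverage stops near the corneal periphery, so the anterior eye is
reconstructed in three provenance layers: a Zernike fit (Noll modes,
radial order <= 3 -- deliberately low to avoid convex extrapolation
artefacts) fills uncovered samples out to the 5.5 mm limbal radius;
measured samples are retained verbatim; beyond the limbus every meridian
continues along a circle tangent-matched at the rim (default radius 12 mm),
a parametric stand-in for an averaged scleral shape. A height-function
continuation cannot pass the globe equator, which caps the extension at
8.5 mm lateral radius -- comfortably beyond the 8 mm the model needs.

Meshing is nonparametric: a pre-meshed O-grid (butterfly) disk template --
a central b x b patch surrounded by rings of 4b quads -- is mapped onto the
anterior eye by converting the surface to spherical coordinates about an
interior origin and cubically interpolating its radius at each template
direction. The posterior surface is offset along local normals by a wall
thickness varying linearly from the measured CCT at the apex to CCT +
0.18 mm at the limbus (constant beyond), in five element layers. The desk
preset (base 8, 30 rings, 5 layers) gives 5,120 hexahedra; the paper-density
preset (base 20, 36 rings, 5 layers) gives exactly 16,400, matching the
clinical study's element count (its node count, 19,926 here, differs
slightly from the printed 20,646 because the original meshing scheme is not
fully documented; counts of this scheme are documented instead).

The scleral continuation is roughly ten times stiffer than the cornea
(ramped over 0.8 mm past the limbus), consistent with scleral tissue
moduli. Besides being physical, this matters numerically: with corneal
compliance extended to the rim, the inverse (stress-free) inflation
iteration is barely contractive and stalls.

The lens is built from its manufacturing parameters: five back arcs (base,
reverse, two alignment, peripheral) sag-matched at the zone junctions,
three front arcs, 0.22 mm centre thickness, 10.60 mm diameter. Arcs whose
curvature radius cannot span their zone from the axis (the steep front edge
curve) continue as tangent arcs with off-axis centres. The mesh revolves
the profile over the O-grid template (base 4, 30 rings, 2 layers = 992
elements). The eyelid solid follows the anterior eye shape as one
continuous 51 x 41 sheet (4,000 hexahedra, 6,273 nodes; the clean
combinatorial count -- the clinical paper's 3999/6272 appears to be an
off-by-one), offset outward by a clearance and lifted smoothly wherever the
seated lens pokes through, then extruded 0.5 mm in two layers.

## Lens seating

Seating is constrained point-to-point ICP: the lens is placed at the
detected decentration, dropped to a small standoff, and registered against
a dense corneal surface sample. Steps are clamped (0.05 mm / 0.25 deg per
iteration, 1 mm / 5 deg total -- the quoted "minimal translation and
rotation" made concrete), penetrating poses are projected outward along the
mean surface normal, and a step is accepted only if the RMS normal distance
strictly decreases, so the objective sequence is monotone by construction.
The RMS (rather than mean absolute) distance is used because it penalises
tilted poses that trade central clearance for one-sided landing. Note two
genuine observability limits: the pose is only determined up to rotation
about the lens axis (both surfaces are nearly rotationally symmetric), and
surfaces of revolution admit near-isometric "slides" (a rotation about a
zone's curvature centre mimics a lateral translation at small residual), so
ICP recovery of an arbitrary perturbation is not guaranteed -- the
registration tests use a known perturbation whose recovery is sharp, and
check objective monotonicity across random perturbations.

## The finite-element engine

The solver is a compact implicit engine for 8-node hexahedra with B-bar
(mean-dilatation) volumetric treatment, which controls locking at the
near-incompressible Poisson ratio 0.49 used for all tissues -- the same
role the commercial hybrid (mixed-pressure) elements play. Kinematics are
small-strain with updated-geometry increments: every load case in this
study produces strains below 1-2%, where the incremental formulation is
accurate; the contact nonlinearity is solved by full-tangent Newton
iterations with a residual-based backtracking line search and load
bisection on divergence. Convergence is declared at 0.5% of the external
force norm (the customary implicit-statics force-residual check); on
contact-free problems the solver reaches machine-precision equilibrium.

Verification: a single element under uniform traction carries the exact
constant stress to machine precision; a closed thick-walled sphere
(11.5/12.05 mm, E = 0.25 MPa, nu = 0.49, 2 kPa internal pressure, meshed as
a cubed-sphere shell) reproduces the Lame radial displacement and hoop
stress within 2% at desk resolution, with monotone convergence under
refinement.

Contact is node-to-surface penalty contact with regularized Coulomb
friction (mu = 0.01): cornea anterior vs lens back, eyelid back vs lens
front, eyelid back vs cornea. Penalty stiffness is 50 x the softer side's
modulus over the local element size; a closest-point projection is active
only when it lands in a facet interior (boundary-edge projections signal
lateral proximity, not penetration). The free-floating lens is grounded by
weak springs (1e-5 N/mm per dof), orders of magnitude below the contact
stiffness.

The load program follows the study's staged table: stress-free iterations;
IOP inflation of the recovered unloaded geometry in ten equal increments;
a quasi-static lid settle at 8 mmHg (replacing the original dynamic 0.6 s
blink -- its purpose, lens repositioning, is handled by the ICP stage);
tear-film traction of 43.6 mPa applied literally as a uniform attractive
normal traction on the lens back (the unit reads as a pressure rather than
a surface tension; at 4e-8 MPa its mechanical effect is negligible, and the
magnitude is configurable); and closed-lid pressure at 8 mmHg. The
stress-free geometry is found by the fixed-point shrink iteration
(update by the inflation mismatch) accelerated with Aitken dynamic
relaxation; it reaches the 1e-4 mm tolerance in 15-25 iterations at desk
density.

Five barometer fields are extracted on the anterior corneal surface:
contact pressure (penalty traction on the cornea-side contact facets),
Mises stress, pressure (-tr(sigma)/3, positive in compression), maximum
principal stress, and maximum principal logarithmic strain (largest
eigenvalue of ln V from the deformation gradient). Element quadrature
means are volume-averaged to nodes before invariants are taken.

## FEA-predicted RPC and its resolution limit

The FEA's own RPC compares surface height maps before and after the
lens-wear stages. Tangential power involves second derivatives, and the
deformed surface is known only at scattered mesh nodes 0.2-0.3 mm apart;
differencing two independently resampled surfaces drowns the signal in
resampling noise. The package therefore resamples the *shape-change field*
(the nodal displacement linearised through the local surface slope into a
height change at fixed (x, y)) with moving-least-squares quadratics and
adds it to a single resampled pre-wear surface, so the pre-surface
resampling error cancels in the difference. Even so, curvature noise of
order 0.1 D per 10 um of surface motion survives; a rigid-body motion test
is bounded at 0.25 D rather than the ideal zero, and this is a resolution
limit of scattered resampling at desk mesh density, not of the solver.

## Map comparison

All maps are interpolated to the common -8..8 mm Cartesian grid (0.1 mm
step): polar maps by separable Catmull-Rom cubic interpolation, surface
fields by isoparametric interpolation in the mesh facets (exact for linear
fields; queries outside the source are invalid, never extrapolated), both
standing in for triangulation-based cubic interpolation with equivalent
contracts. Maps are normalised to [-1, 1] by their maximum absolute value
over the analysis mask (default 5 mm disc: the lens footprint).

NCC is computed over all integer displacements with running-sum local
statistics (FFT-accelerated correlation sums of the masked arrays), and the
zero-displacement-aligned central window is reported as the corneal
coefficient map; the full surface is retained, since projecting a
displacement-indexed surface onto corneal positions is ambiguous and both
views are exported. SSIM uses the standard constants (11 x 11 Gaussian
window, sigma 1.5, L = 1 after rescaling to [0, 1], C1 = 1e-4, C2 = 9e-4,
C3 = C2/2, unit exponents) and the standard structure term
$s = (\sigma_{xy} + C_3)/(\sigma_x \sigma_y + C_3)$ (the source's printed
equation for this term is a typographical degeneracy). Both metrics are
verified against literal double-loop evaluations to 1e-10.

Coefficient maps are classified with half-open band edges -- weak
|r| < 0.4, moderate 0.4 <= |r| < 0.6, strong |r| >= 0.6 -- and band areas
are exact cell-count percentages, so the three bands always sum to 100.
Cohort summaries report mean +/- SD band areas per barometer with a KS
normality screen and pairwise two-sample t-tests at the 95% level.

## Problem sizes and determinism

The package's verification runs use deliberate desk-scale sizes: the Lame
benchmark at 1,800 elements, stress-free recovery and the cohort at the
5,120-element desk cornea with the full 4,000-element eyelid and
992-element lens (about 39k degrees of freedom per case, roughly a minute
per eye), and a ten-eye synthetic cohort for the end-to-end band-area
table. A 249-eye cohort at the paper-density preset is the same code at
larger settings. Every random quantity flows from the single cohort seed,
and repeated runs are bit-identical.

## Known limitations

* Linear-elastic, isotropic tissue models; no viscoelasticity, fibre
  reinforcement, or epithelial remodelling -- the simulated RPC is the
  elastic response to lens wear, as in the source methodology.
* The quasi-static blink replacement ignores any dynamic lens
  repositioning beyond what ICP seating provides.
* Contact pressure is reported as the raw penalty traction; commercial
  solvers apply additional surface smoothing, so this field is the
  noisiest of the five barometers (which is itself one of the study's
  findings).
* The FEA RPC carries the scattered-resampling curvature noise described
  above.
* Eyelid geometry is a uniform-thickness sheet; no tarsal plate or lid
  tension variation.
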