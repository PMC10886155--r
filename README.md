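# okfea

Patient-specific finite-element simulation of orthokeratology (Ortho-K)
contact lens wear, from corneal topography to quantitative comparison of
FEA stress/strain fields against the clinically measured refractive power
change.

## What it does

Overnight Ortho-K lenses reshape the cornea: a central flattened zone (CFZ)
and an annular steepened zone (ASZ) appear in the refractive power change
(RPC) map, the post-wear minus pre-wear tangential power

    Pt = (nh - nair) / Rt,      Rt(r) = (1 + z'(r)^2)^(3/2) / |z''(r)|

with the keratometric index nh = 1.3375. `okfea` implements the full
modelling chain around this map:

* **Topography**: a documented plain-text dialect for polar elevation grids
  (300 azimuths x 333 stations), Zernike (order <= 3) reconstruction to the
  5.5 mm limbus with measured samples kept verbatim, and a tangent-matched
  scleral continuation beyond it.
* **Power maps**: tangential curvature/power, DCT-based penalized
  least-squares smoothing (factor 4.5), RPC maps, CFZ/ASZ detection and
  lens decentration from per-meridian zero crossings.
* **Eyelid**: lid boundary parabolas detected from the coverage footprint
  (0.3 mm radius histogram, second-order fits) and a two-layer eyelid solid
  (51 x 41 grid, 0.5 mm thick) draped over the anterior eye.
* **Meshing**: O-grid hexahedral meshes of the anterior eye (CCT-based
  posterior offset, +0.18 mm at the limbus), the reverse-geometry lens
  (base/reverse/alignment/peripheral arcs, 0.22 mm centre thickness), and a
  cubed-sphere shell for solver verification.
* **Seating**: constrained iterative closest point registration of the lens
  back surface onto the cornea at the detected decentration, with
  non-penetration and a monotone objective.
* **FEA**: an implicit B-bar hex8 engine with penalty frictional contact
  (mu = 0.01) executing the staged program — stress-free geometry recovery
  (1e-4 mm tolerance), IOP inflation in ten increments, quasi-static lid
  settle and closure at 8 mmHg, tear traction 43.6 mPa — and extraction of
  five barometers: contact pressure, Mises stress, pressure, maximum
  principal stress, maximum principal logarithmic strain. The corneal
  modulus follows the age law E = 0.0032 age + 0.2 MPa.
* **Comparison**: resampling to the common -8..8 mm grid (0.1 mm step),
  [-1, 1] normalisation, full-surface normalized cross-correlation with
  running-sum statistics, SSIM with standard constants, and
  weak/moderate/strong band areas (edges 0.4 / 0.6) with cohort statistics.
* **Synthetic cohort**: a seeded generator emulating the clinical cohort
  (age 14.1 ± 4 y, IOP 15 ± 3 mmHg, CCT 554 ± 33 µm, Sim-K 42.6/44 ± 1.3 D,
  lid parabola means, eyelash slit artefacts, imposed Ortho-K effects with
  known decentration) so the whole chain is testable without clinical data.

## Worked example

```r
library(okfea)

spec <- cohort_spec(n = 3, seed = 7)         # synthetic study conditions
case <- generate_case(spec, 1)                # pre/post topography + truth

pre  <- power_map_pipeline(case$pre)          # tangential power, smoothed
post <- power_map_pipeline(case$post)
rpc  <- rpc_map(pre, post)
zones <- detect_zones(rpc)
zones
#> <zone_analysis> CFZ centre (-0.120, -0.333) mm; decentration (-0.120, -0.333) mm

report <- run_case(spec, 1)                   # full FEA pipeline (~1-2 min)
print(report$bands, n = 6)
#> # A tibble: 30 x 4
#>   metric band     area_pct component
#>   <chr>  <fct>       <dbl> <chr>
#> 1 ncc    weak       100    contact_pressure
#> 2 ncc    moderate     0    contact_pressure
#> 3 ncc    strong       0    contact_pressure
#> 4 ssim   weak        53.6  contact_pressure
#> 5 ssim   moderate     7.75 contact_pressure
#> 6 ssim   strong      38.6  contact_pressure
```

The `zones` line is the detected lens decentration recovered from the RPC
map (the generating truth for this case is (-0.124, -0.345) mm); the band
table gives, per barometer, the percentage of the corneal analysis disc
whose NCC/SSIM agreement with the clinical-style RPC map is weak, moderate
or strong. `run_cohort(spec)` aggregates these into mean ± SD band areas
per barometer with normality and pairwise t-test screens, and
`plot_band_areas(out$summary)` draws the barometer x band bar chart.

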