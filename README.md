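# ovtr — virtual torsional rigidity and callus morphometry for ovine osteotomy studies

`ovtr` implements the quantitative evaluation chain used in preclinical
sheep tibia osteotomy experiments that compare a treated and an untreated
arm (n = 6 + 6) across two defect models (a 3-mm gap and a 17-mm
autograft-filled critical defect). It is written for researchers who run
or re-analyse such studies and want every stage — imaging, virtual
mechanics, physical mechanics, histology, statistics — as tested,
scriptable R, with a synthetic-data generator that provides analytic
ground truth for end-to-end validation without any animal data.

The chain:

1. **Densitometry calibration** — ordinary least squares on rod-phantom
   means converts scanner Hounsfield units to mineral density,
   ρ = (HU − b)/a in mg HA/cm³.
2. **Callus morphometry** — new mineralised callus is separated from old
   cortical bone (day-0 mask + density threshold + island cleanup);
   endpoints are callus volume (cm³) and mean mineral density.
3. **Virtual torsional rigidity (VTR)** — an image-based finite-element
   model (one trilinear hexahedron per voxel at 0.4 mm working
   resolution) with a dual-zone material law: elements below
   665 mg HA/cm³ get a soft-tissue modulus of 50 MPa, elements at or
   above it follow E = E_ref (ρ/ρ_ref)^γ; Poisson ratio 0.3 throughout.
   A simulated torsion test (distal face fixed, proximal face rotated,
   axial float) yields VTR = (T/θ) · L in Nm²/deg. The solver is a
   matrix-free Jacobi-preconditioned conjugate gradient (relative
   residual ≤ 1e-8) validated against the Saint-Venant closed form
   G·J·π/180 for a hollow cylinder.
4. **Biomechanics** — torque–rotation traces (5°/min ramp, 20 Hz, stop at
   10 Nm or 12°) are regressed between 6 and 10 Nm for torsional
   stiffness (Nm/deg); rigidity = stiffness × gauge length; operated-limb
   rigidity is normalised by the contralateral limb as a percentage.
5. **Histomorphometry** — tissue-class percentages of the non-background
   area, globally and by anatomical sector (cis / endosteal / trans).
6. **Statistics** — pooled-variance Student's t, Levene (mean-centred),
   Kolmogorov–Smirnov normality with estimated parameters (Lilliefors,
   Monte-Carlo p), exact Mann–Whitney U (full enumeration at 6 + 6), and
   Cohen's d = (m₂ − m₁)/s_pooled, assembled into two-arm report tables.

A synthetic micro-CT generator renders osteotomized hollow-diaphysis
tibiae with a parametric fusiform callus whose volume and density are
exact set-points, and samples whole two-arm studies from the published
arm distributions, so every stage is tested against known truth.

## Worked example

```r
library(ovtr)

# one synthetic 17-mm subject through the image pipeline
geom <- scan_geometry(gap_width = 17, voxel_spacing = 0.4)
scan <- make_tibia_scan(geom, callus_spec(12.0, 762, density_noise_sd = 30),
                        calibration = c(1.2, -50), noise_sd = 20, seed = 1)
cal  <- fit_calibration(make_phantom_scan(c(0, 200, 400, 800),
                                          calibration = c(1.2, -50),
                                          noise_sd = 20, spacing = 0.4, seed = 2))
dens <- apply_calibration(scan, cal)
seg  <- segment_callus(dens, scan$truth$old_bone, roi = c(-18.5, 18.5))
compute_morphometry(seg, dens)
#> callus volume 12.00 cm^3, density 761 mg HA/cm^3, Dice 1.000

# biomechanics of a synthetic torsion trace, gauge length 100 mm
trace <- make_torsion_trace(3.2, noise_sd = 0.05, seed = 3)
analyze_trace(trace, gauge_length = 100, contralateral = 1.25)
#> stiffness 3.213 Nm/deg -> rigidity 0.321 Nm^2/deg (26% of contralateral)

# effect-size arithmetic on printed group summaries (mean, SD, n)
cohens_d_summary(0.32, 0.27, 6, 0.90, 0.33, 6)
#> [1] 1.92
```

The recovered volume and density match the generator set-points (12.0 cm³,
762 mg HA/cm³) to well under a percent; the Dice coefficient of 1.000 says
the segmented callus mask coincides with the ground-truth mask. The
stiffness of 3.213 Nm/deg recovers the trace's true slope of 3.2 within
noise, and 0.321 Nm²/deg is the corresponding rigidity at a 100-mm gauge.

## The analysis workflow

The numbered drivers under `analysis/` run the study end to end and write
tables under `results/`:

| script | stage |
|---|---|
| `01_simulate_study.R` | sample both two-arm synthetic studies |
| `02_morphometry.R` | scans → calibration → segmentation → volume/density |
| `03_virtual_torsion.R` | FE benchmark + VTR of operated/intact tibiae |
| `04_biomech.R` | traces → stiffness → rigidity → normalisation |
| `05_group_report.R` | group tables and effect-size arithmetic |

`run_study(run_config(...))` performs the same orchestration as a single
call, either through the full image pipeline or at summary level.

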