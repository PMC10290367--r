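---
title: "Methods: synthetic ground truth, voxel finite elements, and the two-arm evaluation chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic ground truth, voxel finite elements, and the two-arm evaluation chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ovtr` evaluates bone healing in plate-stabilised ovine tibia osteotomies
along five quantitative axes — micro-CT densitometry, callus morphometry,
image-based virtual torsion, physical torsion testing, and
histomorphometry — and compares a treated against an untreated arm with a
small-sample statistical battery. This vignette explains the models and
conventions behind each stage, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
design choices made where the methodology was genuinely open.

## The synthetic scan generator

Real study data of this kind (scanner volumes, torsion-rig traces,
histology slides) are rarely shareable, so the package ships a generator
whose outputs have *analytic* ground truth.

The diaphysis is an idealised hollow cylinder: outer radius 10 mm,
cortical thickness 4 mm, 80 mm field of view, isotropic voxels. The
default voxel spacing is 0.2 mm — deliberately coarser than a clinical
micro-CT scanner's ~60 µm — so that complete pipelines run at desk scale;
spacing is a first-class parameter and all outputs are computed
per-spacing. A transverse gap of 3 or 17 mm interrupts the cortex.

The callus is a parametric fusiform body: an envelope
`F(z) = base(z) + A cos²(πz/Lc)` grows from the endosteal radius inside
the gap (where the cortex was resected) and from the periosteal surface
outside it, plus an endosteal plug of canal radius whose length carries
the endosteal share (`1 − periosteal_fraction`, default 0.3) of the
volume. The amplitude `A` is solved by bisection *on the voxel grid* so
the rendered mask hits the requested volume essentially exactly
(observed error < 0.1% across 0.3–19 cm³ at 0.4 mm spacing); targets too
small to span the gap shrink the plug instead — producing an unbridged
defect, the faithful image of an insufficient callus — and targets too
large for the field of view raise an explicit capacity error. Voxel
densities are the target mean plus Gaussian heterogeneity
(`density_noise_sd`, default 30 mg HA/cm³); HU values follow a linear
map with additive Gaussian scanner noise. Real calluses are irregular,
partial-volume-blurred and beam-hardened; none of that is simulated,
which is precisely why recovery tests against this generator certify the
*accounting* of the pipeline (segmentation, unit conversions, mass
bookkeeping) and not its robustness to real-scanner artefacts.

Torque–rotation traces are bilinear — zero torque over a settling toe
region (default 0.5°), then linear at the prescribed stiffness — sampled
at 20 Hz during a 5°/min ramp and stopped at the first sample reaching
10 Nm or 12°, with additive torque noise. The toe region exists to make
the 6–10 Nm regression window consequential and testable.

Whole studies are sampled per-subject from per-arm normal distributions
of callus volume, callus density, operated-limb rigidity and
contralateral rigidity, with the published group means and SDs of the two
defect models as defaults. Strictly positive quantities are redrawn when
a draw is non-positive (truncated normal by rejection); the redraw count
is recorded. Every generator is a pure function of its arguments and
seed: the RNG state is saved and restored around each call.

## Calibration and morphometry

Calibration is unweighted ordinary least squares of mean rod HU on known
rod density. The phantom's actual rod densities are scanner-site
information and are therefore a required input rather than a default.
Applying a calibration inverts the line voxelwise; negative densities are
retained (clipping would bias the mean of any later region average) and
thresholds are applied downstream.

The published segmentation workflows for separating new callus from old
cortex live in proprietary tooling, so the package defines a transparent
replacement with three ingredients: an externally supplied old-bone mask
(from day-0 geometry; in synthetic studies the generator's truth mask), a
voxelwise mineralisation threshold (default 450 mg HA/cm³ — the
literature prints only the finite-element soft-tissue cutoff of 665, not
the morphometric one, so this default is a declared stand-in and fully
configurable), and removal of connected components below 50 voxels.
Volume is voxel count × spacing³; density is the mean over the mask; an
empty mask reports volume 0 and density `NA` rather than 0.

## Virtual torsion

The finite-element stage follows the image-based virtual mechanical
testing paradigm: down-sample the density image to 0.4 mm (block mean for
integer ratios, which conserves mineral mass exactly; trilinear
interpolation otherwise, audited to 2%), assign each element a modulus
from the dual-zone law, and simulate a torsion test.

Material model: ρ < 665 mg HA/cm³ → 50 MPa (soft tissue); otherwise
E = E_ref (ρ/ρ_ref)^γ with defaults E_ref = 20 GPa, ρ_ref = 1200
mg HA/cm³, γ = 1.5, clamped between the soft modulus and the law's value
at 1500 mg HA/cm³; ν = 0.3 everywhere. The published ovine scaling law's
coefficients are cited but not printed in the sources this design
follows, so the power law here is a declared, configurable stand-in — and
for that reason every structural test of the solver (analytic oracle,
linearity, monotonicity, recovery) is independent of the law's
coefficients.

Elements are voxel-aligned trilinear hexahedra rather than quadratic
tetrahedra from a commercial mesher: the mesh is the image, the element
matrix is one 24×24 stencil scaled by E·h, and the contract is
convergence to the analytic benchmark rather than mesh identity. Only
voxels inside the body mask (bone, callus, enclosed medullary tissue) are
retained — the 50 MPa zone is for soft *tissue*, not for air — and only
the connected component joining both end planes carries load. If no
component joins them the model raises a "discontinuous structure" error,
the virtual analogue of a nonunion, which the pipeline records per
subject instead of aborting the study.

Boundary conditions: the distal end plane is fully fixed; the proximal
plane receives the rigid in-plane displacement of a small rotation about
the section centroid with axial motion left free, mimicking a torsion rig
with axial float under pre-load (a fully rigid coupling is available via
`rigid_axial = TRUE`). Whether the physical rigs drive rotation or
torque, and over what gauge, is not documented; both conventions coincide
for a linear model up to the reported quantity, and the gauge is defined
here as the distance between constrained planes. VTR = (T/θ) ·
gauge, in Nm²/deg.

The solver is a matrix-free Jacobi-preconditioned conjugate gradient
(Rcpp) with relative residual tolerance 1e-8. The initial guess
interpolates the applied rotation linearly along the axis — the exact
Saint-Venant field for circular sections, which do not warp — so the
homogeneous benchmark converges in a few hundred iterations and realistic
two-material models in about a thousand. The oracle is
G·J·π/180 · 10⁻⁶ Nm²/deg with G = E/2(1+ν), J = π(r_o⁴−r_i⁴)/2: at
spacing r_o/20 the voxel model agrees within 0.6%, and halving the
spacing changes the result by ~0.5%. At coarser spacing the error
oscillates with how the circular boundary falls on the voxel lattice
(−2.8% at r_o/10), which is why the convergence contract is stated at
r_o/20.

## Biomechanics

Stiffness is the OLS slope of torque on rotation restricted to
loading-ramp samples with torque in [6, 10] Nm; unloading samples are
discarded by truncating at the torque maximum. A trace that never enters
the window (e.g. stopped at the 12° cap below 6 Nm) raises a
window-unreachable error carrying the trace's maximum torque; an optional
fallback window exists but is off by default, and the pipeline records
such subjects as missing rather than silently re-windowing.

Converting stiffness (Nm/deg) to rigidity (Nm²/deg) necessarily
multiplies by a length that the source methodology never states. The
package makes it an explicit, required configuration value
(`gauge_length`, default 100 mm for synthetic studies) so the unit system
is auditable; contralateral normalisation, 100 × operated/contralateral,
is gauge-independent. The 5 N axial pre-load is metadata only — no
computed quantity uses it.

## Histomorphometry

Sections are hard-labelled integer images with a legend; the area of
interest is every non-background pixel (100%), and class percentages are
pixel counts over that area. Sector fractions (cis cortex, endosteal,
trans cortex) divide callus pixels by analyst-drawn sector masks, which
must be disjoint and jointly cover the callus — mirroring manual
highlighting practice, where sectors are drawn per slide rather than
computed anatomically. An optional ignore label accommodates artefacts.
The synthetic renderer fills the area of interest with exact pixel counts
(largest-remainder rounding), so accounting is testable to machine
precision.

## Statistics

The battery mirrors small-sample preclinical reporting:

* **Student's t** is the classical pooled-variance test (the named test,
  gated by a variance screen), df = n₁+n₂−2; Welch is deliberately not
  the default. Zero pooled variance follows the documented convention
  p = 1 (equal means) / p = 0 (unequal).
* **Levene** uses absolute deviations from the group *mean* (the variant
  matched to normal-theory screening).
* **Kolmogorov–Smirnov normality** uses the sample's own mean and SD,
  which makes the classical KS table invalid; the implementation is
  therefore the Lilliefors variant with a seeded Monte-Carlo null table
  (default 1000 replicates). A constant sample is non-normal by
  convention.
* **Mann–Whitney U** uses midranks and, for n₁+n₂ ≤ 14 (the 6 + 6 study
  regime), an exact two-tailed p from full enumeration of all
  `choose(n, n₁)` labelings of the observed ranks — valid under ties
  because the actual midranks are permuted. Enumerated null
  distributions are memoised per rank multiset, which keeps
  10 000-replicate calibration studies cheap. Larger samples use the
  tie-corrected normal approximation with continuity correction. Note
  the exact 6 + 6 test is discrete: its attainable size at the nominal
  α = 0.05 is 38/924 ≈ 0.041, so simulated rejection rates sit slightly
  below 0.05 by construction.
* **Cohen's d** uses the pooled SD and is computable from raw samples or
  from printed (mean, SD, n) summaries, which agree exactly; the report
  computes d for every parameter and flags those a significance-gated
  report would print.
* **Test selection** follows the reporting rule: t when both arms pass
  the KS screen and Levene at α = 0.05, Mann–Whitney otherwise; the
  per-parameter assignment can be fixed by an override map, as when
  morphometry and VTR are compared parametrically but biomechanics
  nonparametrically. No multiple-testing correction is applied, matching
  per-parameter α = 0.05 reporting.

## Summary-level studies and the VTR surrogate

Replicate-study simulations (power, direction, null calibration) bypass
the image stages: morphometry values come from the sampled ground truth
and operated-limb VTR from a closed-form surrogate — the series
combination of per-slice Saint-Venant rigidities of the same idealised
geometry the voxel generator renders, with shear moduli from the dual-zone
law at the callus mean density. The surrogate is monotone in callus
volume and density by construction and is used for *direction and
ordering*, not for absolute magnitudes: it ignores voxel-level density
heterogeneity (which, at a control-like mean of 674 mg HA/cm³, puts a
large fraction of voxels below the 665 threshold in the full model) and
therefore runs stiffer than the image-based result. In summary mode the
contralateral VTR is the intact-tube closed form and is constant across
subjects; between-subject contralateral variation exists only in the
sampled biomechanical rigidities.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: synthetic scans at
0.2–0.8 mm spacing (the 0.2 mm recovery case is ~1.5 million callus
voxels), FE benchmarks at cylinder spacings r_o/10 to r_o/40 (up to
~260 000 elements, solved in seconds to tens of seconds on one CPU),
10 000 simulated 6 + 6 studies for null calibration, 200 replicate
studies for power/direction, and 500 traces for stiffness recovery —
sizes chosen so the whole suite completes in about a minute while leaving
Monte-Carlo error well inside the asserted bands. Bisection tolerances
(60 halvings) are far below voxel granularity; the FE tolerance of 1e-8
on the relative residual leaves discretisation, not solver error, as the
dominant error term.

## Known limitations

* The callus is analytic and connected (unless volume-starved); no
  fibrous interzone, cartilage islands, or graft remnants — recovery
  results certify accounting, not scanner-realistic robustness.
* The FE stage is linear elastic with isotropic voxelwise moduli: no
  strength, no contact, no geometric nonlinearity, no screw holes.
* The modulus power law is a stand-in; absolute VTR values depend on it,
  while the oracle, linearity, monotonicity and two-arm direction
  results do not.
* Old-bone masks are inputs; registration between post-mortem scan and
  day-0 geometry is out of scope.
* The biomechanical gauge length is a convention, and normalised
  percentages are the gauge-independent quantity to compare across
  sites.
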