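---
title: "Measuring mandibular canal regeneration: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring mandibular canal regeneration: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canalregen)
```

## The measurement problem

After inferior alveolar nerve transposition the mandibular canal is
interrupted between the implant apices. On a one-year CBCT the question is
not "is there bone near the nerve?" but "over what fraction of the
disrupted segment has a *canal* — a continuous, tubular, substantially
enclosing bony wall — re-formed?". `canalregen` turns that question into a
deterministic computation on three inputs: an HU-calibrated volume, the
nerve/canal centerline (an ordered polyline in world mm), and the two apex
landmarks bounding the defect.

The pipeline is: (1) resample square cross-sections perpendicular to the
centerline every `step_mm`; (2) score each section against the density,
enclosure and morphology criteria at both HU thresholds; (3) apply the
continuity criterion across sections; (4) report the accepted canal length
inside the defect as a percentage of the defect length.

## Criteria and their operationalization

**Density (thresholds).** Walls must exceed 800 HU (mature bone) or 400 HU
(early, partially mineralized bone); bone is bounded above at 3071 HU, the
12-bit clamp ceiling. CBCT gray values approximate HU imperfectly, which is
one reason the thresholds are deliberately conservative; `read_volume()`
accepts an optional affine recalibration (`gain`, `offset`) when a site
calibration exists. Samples at the ceiling are treated as metal, not bone:
implants reconstruct at or above the ceiling, and a ray that meets metal
before qualifying bone is excluded from the enclosure denominator
("occluded") rather than counted either way. Interpolated samples radially
adjacent to metal are also excluded from the bone mask — they are
partial-volume blends of metal and soft tissue that can land anywhere in
the bone range. Sections where more than `occlusion_max_frac` (default
10%) of rays are occluded are flagged low-confidence.

**Enclosure.** `ray_count` (default 360) equally spaced rays are cast from
the section centre; a ray is *walled* when, inside the radial annulus
`[band_inner_mm, band_outer_mm]`, it crosses a contiguous supra-threshold
chord of at least `min_wall_mm` (default: one in-plane sample). The
enclosure angle is 360° × walled / unoccluded rays. Coverage is the
*union* of walled rays: the clinical criterion does not say whether 270°
must be one contiguous arc, and we chose total coverage as the primary
reading; the longest contiguous arc is recorded alongside
(`contiguous_deg` attribute, `contiguous_*` verdict columns) so the
alternative reading can be analyzed without recomputation. The annulus
defaults — 0.8 × the nominal canal radius to the radius + 3 mm — tolerate
modest centerline error while excluding distant cortical bone.

**Morphology.** The criterion "tubular or circular configuration" is
qualitative in origin; our operationalization is the radial-uniformity
score `1 − min(1, MAD/median)` of the first-wall-hit radii over walled
rays (0 when fewer than 3 rays are walled). A circular wall at any radius
scores near 1; sheets, spicules and blobs score low. The 0.6 default
acceptance bound is a package choice, exposed in `scoring_params()` and
recorded in every output. The score is computed once per section over the
full bone range (> 400 HU) and gates both thresholds, matching the intent
that morphology is a property of the section, not of the threshold.

**Continuity.** A passing section only counts inside a run of passing
sections. `find_runs()` merges passing blocks separated by at most
`max_gap_sections` failing sections (default 0) and discards runs whose
passing span is below `min_run_mm` (default 0.9 mm, i.e. three sections at
the default 0.3 mm step — "sequential sections", plural, read as at least
three; no number is fixed by the clinical definition). A run's length is
the number of passing stations × step, so tolerated gaps never inflate the
measured canal.

## Lengths, the defect, and clipping

The defect length is the *straight-line* distance between the mesial apex
of the mesial implant and the distal apex of the distal implant. The
regenerated length, in contrast, is accumulated along the centerline
stations between the two apex projections. Each station stands for a
step-wide slab of canal centred on it, and runs crossing a defect boundary
are truncated there, so a fully passing straight segment measures exactly
the defect length. On a curved axis the arc exceeds the chord and the
ratio can exceed 100%; we clip at 100 and set a `clipped` flag rather than
report an impossible percentage. (The original clinical measurement took
both lengths on one standardized sagittal view — a 2D projection; this
package measures in 3D along the axis, a deliberate deviation that the
clipping guard accompanies.)

Station placement at `0, step, 2·step, …` uses central-difference tangents
and a minimal-rotation frame transport; enclosure is rotation-invariant in
the section plane, so the frame only needs continuity. Out-of-volume patch
samples are filled with −1024 HU and counted.

## The phantom generator

`build_phantom()` renders the radiographic situation the criteria are
designed for, with analytically known truth: a trabecular/graft background
(150 HU), a soft-tissue lumen (40 HU, radius 1.5 mm), and an annular wall
(thickness 1 mm) whose angular coverage and HU follow a per-station table;
optional implant cylinders at the clamp ceiling; additive Gaussian noise
(seeded). Voxels belong to a structure when their *centre* is inside the
analytic surface — no anti-aliasing — so the truth fractions computed from
the station table are exact at voxel-centre resolution and invariant to
noise and implants. Wall arcs are single contiguous intervals per station,
matching the single-enclosure criterion.

Defaults mirror a standard CBCT protocol: 0.3 mm isotropic voxels, a
50 × 50 × 64 grid (15 × 15 × 19.2 mm), landmarks 2.1 mm in from the axis
ends (14.7 mm defect). The cohort generator `sample_cohort()` draws true
mature-threshold regeneration fractions from a normal distribution
truncated to [0, 1] — default mean 0.727, sd 0.13, the regime of the
published one-year cohort it emulates, with 22 cases and 30 HU noise —
and builds one phantom per case (330° / 1200 HU walls over the
regenerated span, an under-enclosed 120° wall elsewhere).

What the phantoms do *not* emulate: real mandibular anatomy (cortical
plates, trabecular texture), beam hardening and streak artifacts around
implants, centerline extraction error, and gray-value/HU miscalibration.
Passing the validation suite therefore demonstrates that the estimator is
correct *given its inputs* — a faithful centerline and calibrated
densities — not that those inputs are easy to obtain clinically.

## Numerical choices

* Trilinear interpolation everywhere a world point is sampled; bilinear on
  section grids for ray profiles. Values compare strictly (`> threshold`,
  `< 3071`).
* Enclosure validation uses an independent voxel-space oracle
  (`enclosure_oracle()`): wall voxels of the slab classified into 1°
  polar-angle bins, occupied bins counted. Ray-casting and oracle agree
  within 2° on noiseless phantoms *provided the voxel angular subtense in
  the wall band is well below one bin*; the validation geometry therefore
  uses 0.1 mm voxels with an 8 mm lumen radius (≤ 0.7° per voxel), where
  the 269°/271° arcs straddle the 270° bound exactly. At the clinical
  0.3 mm / 1.5 mm geometry a voxel subtends several degrees and the
  *oracle itself* quantizes; the ray-cast measurement degrades more
  gracefully there.
* Ties in the nearest-centerline-point search resolve toward smaller arc
  length; two apices mapping to the same point are a degenerate defect and
  an error.
* Percentages are compared against 100 with a 10⁻⁶ slack before the clip
  flag is raised, so exact-100 cases are not spuriously marked clipped.
* Degenerate inputs fail loudly with classed conditions
  (`canalregen_geometry_error`, `canalregen_spec_error`, …): centerlines
  outside the volume, station tables that do not tile the axis, implants
  intersecting the lumen, defect intervals with fewer than two stations.

## Validation problem sizes

The test-suite and acceptance phantoms are sized to exercise every code
path at comfortably interactive speeds: single cases use the default
50 × 50 × 64 grid (≈ 0.2 s per case to score), the oracle-equivalence
phantom is 236 × 236 × 55 at 0.1 mm, and the cohort demo runs 22 cases.
The per-case absolute error against analytic truth is well under one
percentage point at 30 HU noise; the dominant error term is station
quantization (± step/2 at each run boundary, ≈ ±1 point on a 14.7 mm
defect at 0.3 mm).

## Known limitations

* The centerline is an input (or phantom ground truth); the package does
  not trace the nerve. Enclosure tolerates centerline error only within
  the wall-search annulus.
* Circularity and `min_run_mm` encode qualitative clinical criteria as
  specific formulas and defaults; sensitivity to these choices should be
  reported alongside results (all parameters are embedded in every
  output).
* Multi-arc enclosure topologies, sub-voxel wall thickness and volumetric
  bone fill are out of scope — the statistic is linear canal restoration,
  deliberately.
* The published one-year cohort means (72.7% ± 13 at > 800 HU,
  78.1% ± 11 at > 400 HU) stem from patient data that is not distributable;
  they parameterize the synthetic demo regime and are not reproduced by
  this package.
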