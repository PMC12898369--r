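# canalregen

Computer-assisted quantification of **mandibular canal regeneration** from
CBCT volumes.

When the inferior alveolar nerve (IAN) is transposed to allow implant
placement in a severely atrophic posterior mandible, the bony mandibular
canal is necessarily destroyed along the surgical segment. One year later,
CBCT often shows the canal re-forming around the nerve. `canalregen`
implements a reproducible pipeline that measures *how much* of the
disrupted segment has regrown a true canal, for clinician-researchers who
want that number computed the same way on every scan rather than read off a
workstation by eye.

## The statistic

A canal cross-section at arc-length station *s* along the nerve centerline
is accepted as regenerated canal only if it meets four strict criteria:

1. **continuity** — it belongs to a run of passing sections spanning at
   least `min_run_mm` (default 0.9 mm = 3 sections at 0.3 mm), so isolated
   hyperdense spots do not count;
2. **wall density** — wall bone above the threshold in use: > 800 HU for
   mature bone, or > 400 HU to include early mineralizing bone (upper bone
   bound 3071 HU; values at the clamp ceiling are treated as metal);
3. **enclosure** — ≥ 270° of circumferential bony coverage, measured by
   casting 360 radial rays from the canal centre and counting rays that
   cross supra-threshold bone inside a wall-search annulus;
4. **morphology** — a tubular/circular configuration, scored as
   1 − robust CV of the first-wall-hit radii over the walled rays
   (≥ 0.6 by default).

With `L_regen(θ)` the summed length of accepted runs at threshold θ inside
the defect segment, and `L_defect` the straight-line distance between the
mesial apex of the mesial implant and the distal apex of the distal
implant:

```
Regeneration(θ) [%] = 100 × L_regen(θ) / L_defect ,   θ ∈ {800 HU, 400 HU}
```

reported at both thresholds (the 400 HU figure is never smaller; the gap
measures maturing bone that has not yet reached full density).

Because no patient imaging ships with the package, a synthetic phantom
generator (`phantom_spec()` / `build_phantom()`) renders CT volumes with a
canal whose wall coverage and density vary along the axis according to a
station table, and returns the analytically exact truth value of the
statistic for validation.

## Worked example

```r
library(canalregen)

# a phantom whose true mature-bone regeneration is exactly 70% of the
# defect: 330-degree 1000 HU walls over 2.1-12.39 mm, an under-enclosed
# 120-degree wall beyond, 30 HU noise
ph <- build_phantom(phantom_spec(
  stations = data.frame(s0 = c(0, 2.1, 12.39, 16.8),
                        s1 = c(2.1, 12.39, 16.8, 18.9),
                        arc_deg = c(0, 330, 120, 0),
                        hu = c(0, 1000, 1000, 0)),
  noise_sd = 30, defect = c(2.1, 16.8), seed = 7))
ph$truth$true_regen_fraction_800
#> [1] 0.7

fit <- canal_regen(ph$volume, ph$truth$centerline, ph$truth$landmarks)
fit
#> Mandibular canal regeneration
#>   defect length: 14.70 mm (50 stations at 0.30 mm)
#>   > 800 HU (mature bone):   10.35 mm regenerated = 70.4%
#>   > 400 HU (early + mature): 10.35 mm regenerated = 70.4%
```

The pipeline recovers the 70% ground truth to 0.4 points; the defect is the
14.7 mm between the apex landmarks, of which 10.35 mm carries an accepted
canal run (`summary(fit)` lists the runs, `plot(fit)` draws the per-station
enclosure trace). On real data you would start from files instead:

```r
v  <- read_volume("scan.nii.gz")        # or .nrrd; HU-calibrated
cl <- read_centerline("centerline.csv") # x,y,z per line, world mm
lm <- read_landmarks("landmarks.csv")   # mesial apex, then distal apex
fit <- canal_regen(v, cl, lm)
```

A cohort is summarized in the clinical reporting style with
`summarize_cohort()` (mean ± SD at each threshold, Shapiro–Wilk p, counts
above 70% / below 50% / below 40%). The same steps are scriptable through
`cmd_phantom()` / `cmd_score()` / `cmd_cohort()` or the installed
command-line wrapper:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "canalregen", package = "canalregen"))')
Rscript $CLI phantom --spec spec.json --out case1/
Rscript $CLI score --volume case1/volume.nii.gz \
    --centerline case1/centerline.csv --landmarks case1/landmarks.csv \
    --out case1-results/
Rscript $CLI cohort --reports results-root/ --out cohort/
```

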