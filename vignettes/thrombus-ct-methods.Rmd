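---
title: "Simulated CT monitoring of oxygenator thrombosis: models and methods"
author: "oxyCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated CT monitoring of oxygenator thrombosis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clot formation inside hollow-fiber membrane oxygenators is a leading
complication of extracorporeal membrane oxygenation (ECMO). Because blood,
the polypropylene fibers and the housing are all optically opaque, thrombus
deposits cannot be observed directly; they are inferred late, from a rising
trans-membrane pressure drop (dpMO) and falling platelet counts. Serial
cone-beam CT of a perfused oxygenator offers a way to *see* deposits as
they form: an erythrocyte-rich (red) clot concentrates hemoglobin and
attenuates X-rays more strongly than flowing whole blood, while a
platelet/fibrin-rich (white) clot attenuates less. Subtracting a baseline
scan, acquired before any deposition, from a later scan therefore shows red
deposits as positive grey change and white deposits (or trapped air) as
negative grey change — without any knowledge of absolute clot attenuation
coefficients.

oxyCT implements this measurement principle as a fully simulated, testable
pipeline: digital phantoms of an annular-bundle oxygenator with growing
thrombi, cone-beam acquisition with realistic detector effects, the
standard pre-processing and FDK reconstruction chain, baseline-subtraction
change detection with red/white classification and volumetry, and the
accompanying blood/pressure monitoring analytics of a low-anticoagulation
in-vitro loop experiment. Because every input is synthetic, every output
can be checked against known ground truth.

## Device and phantom model

The modelled device is a neonatal-scale oxygenator: blood enters through an
open inner core, crosses into an annular bundle of gas-exchange fibers at a
punctual inlet transition, and leaves at the top. Fibers have an outer
diameter of 0.300 mm with a mean inter-fiber gap of 0.260 mm. The phantom
voxelizes this geometry on an isotropic grid (materials: air, housing,
fiber, blood, red thrombus, white thrombus), with the device axis along z
and voxel centres at `origin + (i - 0.5) * voxel`.

Two deliberate simplifications:

* **Square fiber lattice.** The real bundle is a coiled fiber mat; the
  phantom uses a regular square lattice with pitch = diameter + gap
  (0.560 mm). For attenuation statistics — mean bundle density, fiber
  volume fraction `pi (d/2)^2 / pitch^2 = 0.225` — the lattice is
  equivalent, and it is declared in the device descriptor rather than
  hidden.
* **Homogenized-bundle mode.** When the voxel size exceeds the inter-fiber
  gap the lattice is unresolvable; `buildPhantom()` refuses such grids
  unless `homogenizeBundle = TRUE`, in which case bundle voxels carry the
  fiber-fraction-weighted mean of fiber and blood attenuation (label code
  6). The weighted mean is exact to numerical precision by construction.

Absolute attenuation coefficients for ovine blood and polypropylene at the
emulated source energy are not published; only the ordering
red > blood > white > air matters for the subtraction method. The defaults
(air 0, housing 0.05, fiber 0.04, blood 0.06, red 0.075, white 0.045, all
1/mm) respect that ordering at soft-tissue-like magnitudes and are
config-overridable; the `MaterialTable` validity method enforces the
ordering on every replacement.

Thrombi are inserted as axis-aligned ellipsoids (semi-axes in mm) or
fiber-hugging strands (partial annular sheaths), centred in device cylinder
coordinates. Insertion relabels only blood voxels; overlap with fibers or
housing is clipped and the clipped fraction recorded, so every phantom
carries an exact ground-truth table (voxel count, analytic volume,
location) for recovery experiments. `simulateGrowthSeries()` produces the
serial-scan states: scan 1 is always thrombus-free (the baseline role) and
the default schedule places 85% of the final thrombus volume between the
last two scans, emulating a late severe clotting event.

## Acquisition model

The scan geometry mirrors the emulated laboratory protocol: source–object
distance 750 mm, object–detector distance 1445 mm (magnification 2.93), a
1024 × 1024 flat panel with 0.194 mm pitch, 5000 projections over a full
360° rotation at 7 fps — a 714 s (12 min) scan at 0.50°/s. Simulation
studies run at a bench scale (`deskGeometry()`: 256² detector, 400
projections, virtual isocentre pixel 0.15 mm); the full protocol remains
available through the configuration but buys nothing for method validation.

`forwardProject()` computes Beer–Lambert line integrals by Joseph-style
ray tracing: trilinear interpolation of the attenuation grid at a fixed
step of at most half a voxel along each source-to-pixel ray (midpoint
rule, ray/box clipping). Detector counts are
`gain × I0 × exp(-integral) + dark`, with:

* Poisson counting noise at `I0` photons/pixel (default 10⁴);
* a static per-column (and optional per-pixel) gain map shared with the
  flat field;
* optionally, per-column gain *drift* between the reference frames and the
  scan (`gainDriftSigma`). This term matters: gain structure present in
  both the scan and the flat cancels exactly in flat-field correction, so
  it is the uncorrected drift that survives into the sinogram and creates
  ring artifacts, exactly as on real detectors.

Everything is deterministic given the seed. Phase contrast is modelled
only as an optional image-domain surrogate: `edgeEnhance()` adds a
strength-scaled negative Laplacian, reproducing the bright/dark fringe
pairs of near-field propagation imaging. Full Fresnel propagation and
phase retrieval are out of scope — the downstream change-detection logic
does not depend on them.

## Pre-processing and reconstruction

`reconstructScan()` applies, in order: flat-field correction
`T = (raw - dark)/(flat - dark)` clamped to `(1e-6, 1.5]`; optional
dead-pixel inpainting (pixels deviating more than 5 robust sd from their
3 × 3 local median in the flat are replaced by that median everywhere) —
this stands in for the undocumented detector-artefact correction of the
original processing chain; the Beer–Lambert inversion `p = -log T`; and
optional ring suppression. The ring filter is the parameter-light
angle-mean method: per detector row, the angle-averaged column profile is
median-smoothed and the high-frequency residual subtracted from every
angle. Its known failure mode is intrinsic: a feature of the *object* that
is invariant over the rotation (e.g. a cylinder centred exactly on the
axis) is indistinguishable from a detector bias. Tests therefore probe the
filter with off-axis objects, and the reconstruction accuracy checks keep
it switchable.

Reconstruction is standard full-scan FDK: cosine pre-weighting
`SOD/sqrt(SOD² + u² + v²)` in virtual (isocentre) detector coordinates,
ramp filtering along u via zero-padded FFT with the analytic band-limited
Ram-Lak kernel (`1/(4Δ²)` at 0, `-1/(π²k²Δ²)` at odd lags; optional Hann
apodization), and voxel-driven back-projection with the distance weight
`(SOD/(SOD - x·r̂))²`, bilinear detector interpolation and `Δθ/2` angular
scaling. On a uniform cylinder the reconstructed attenuation is accurate
to well under 1%; the mid-plane agrees with an independent 2D fan-beam
oracle to < 1% RMS. Short-scan (Parker) weighting is not implemented; the
protocol rotates a full 360°.

Grey values are attenuation times a global scale chosen so that
free-flowing blood maps to 1000. The clip range applied to subtraction
images, −200 to +150 grey values, is then meaningful relative to blood
contrast: with the default materials, red thrombus sits at +250 (clipped
to +150), white thrombus at −250 (clipped to −200) and air at −1000.

## Change detection

`alignScans()` estimates the integer-voxel translation between serial
scans by phase correlation of gradient-magnitude images, with an edge mask
(99th-percentile gradient threshold, dominated by the housing edges)
applied to the reference only — masking both operands with one mask would
pin the correlation peak at zero. Shifts up to 10 voxels are recovered
exactly on noiseless data and to within ±1 voxel under Poisson noise at
I0 = 10⁴. An ambiguous peak (ratio to the runner-up below 1.2) falls back
to zero shift with a warning; the periodic fiber lattice can legitimately
trigger this guard on already-aligned scans, where zero is the correct
answer. Rotational drift is out of scope: the emulated experiment aligned
on housing edges to ±1 pixel, translation only.

`subtractBaseline()` computes follow-up minus baseline, so that red
(attenuation up) is positive — the physically meaningful orientation for
"higher change = more erythrocytes". The stored volume is clipped to
[−200, +150]; the unclipped difference is retained alongside, because the
clip (harmless for display) destroys exactly the white-vs-air magnitude
distinction that `flagAirAmbiguity()` needs, and biases volumetry of
strong deposits.

`segmentThrombi()` implements detection as cluster-forming plus peak
significance:

* **Detection field.** The unclipped difference pre-smoothed by 2 passes
  of a separable (1,2,1)/4 binomial kernel (≈ 1 voxel Gaussian). This is a
  matched-filter step: deposits of interest span ≥ 50 voxels, while
  voxelwise FBP noise at the default conditions (σ ≈ 55 grey) would push
  a 3σ voxel threshold beyond the clip range. With `presmooth = 0` the
  clipped difference is thresholded directly (the plain subtraction
  semantics, used by the size-rule checks).
* **Thresholds.** ±3 × 1.4826·MAD of the detection field, floored at 5%
  of the clip span so noiseless data do not degenerate to a zero
  threshold. User thresholds must bracket zero and stay inside the clip
  range.
* **Size rule.** Connected components (26-connectivity in 3D; 8-connectivity
  per slice in 2D mode) are kept only if *strictly larger* than 30 voxels.
* **Peak rule.** FBP noise is streak-correlated, not white: suprathreshold
  noise clusters above 30 voxels occur routinely and reach 7–11 robust sd.
  A component must therefore contain a peak of at least 12 robust sd
  (genuine deposits at the default contrasts reach 25–43), which removes
  correlated-noise clusters by an order of magnitude of margin rather than
  by a tuned knife-edge.
* **Artifact classes.** Fiber-adjacent parallel-line alterations are
  rejected by a shape test: components that are strongly line- or
  sheet-like (principal-axis ratios < 0.15) *and* at most about one voxel
  thick are dropped; genuine strand-like deposits keep a multi-voxel
  cross-section. An edge-contrast score (95th percentile of the
  detection-field gradient over the component and its one-voxel shell,
  against the background gradient level) guards against diffuse
  low-contrast clusters; the shell matters because central differences
  vanish on ridges thinner than two voxels.
* **Volumetry.** Reported volumes use half-maximum volumetry on the lightly
  smoothed unclipped difference: voxels connected to the component peak
  above half the component plateau (median of values within 75% of the
  peak). The plateau median, rather than the raw maximum, keeps the
  estimate unbiased under noise; the half-maximum contour makes it robust
  to reconstruction blur. For a flat synthetic blob this reduces exactly
  to the thresholded voxel count.

At the bench-scale study conditions the pipeline recovers one red and one
white inserted deposit as exactly two components of the correct classes,
with volumes within 5% of ground truth noiselessly and within 15% under
Poisson noise at I0 = 10⁴ — the figures `scripts/acceptance.R` recomputes.

White components whose core change is below −500 grey (half the
blood-to-air contrast under the default scaling) are relabeled
`ambiguous_air`: the subtraction method genuinely cannot distinguish white
thrombus from a trapped air bubble by sign, only by magnitude, and only
when the clip is bypassed. `quantifyThrombi()` converts counts to mm³,
reports per-class totals and maps centroids into device cylinder
coordinates with a coarse region assignment (inlet transition / bundle /
outlet).

## Monitoring analytics

The `monitoring` module reproduces the loop analytics. The loop
specification carries the circuit design values: 0.12 m² membrane area and
20 mL device priming volume in a loop of 0.0356 m² blood-contacting area
and 140 mL priming volume at 95 mL/min and 2.5 USP/mL heparin, giving an
exposure ratio of 7.5 cm²/mL and a test-to-foreign surface ratio of 3.37.
Sample acceptance follows the platelet rules: a syringe is discarded below
250,000 PLT/µL or below 70% of the animal baseline (the conservative
either-rule reading; the connective is switchable and logged).
`normalizeToStart()` expresses any parameter as percent of its value at
experiment start.

`detectTermination()` fires at the earliest of: normalized platelets below
10% of start ("absence of platelets"); a dpMO rise of ≥ 100% within a
10-minute sliding window (the operationalization of "rapid increase" —
no numeric criterion is published, so the window and factor are declared
defaults); or the 4-hour in-vitro blood-vitality limit. Red-cell stability
(±5% of start, the analyzer's error band) is evaluated as a validity flag
rather than a trigger: an unstable RBC count changes the attenuation of
the blood itself and invalidates serial CT comparison.

`generateSyntheticExperiment()` produces seeded traces for three
archetypes: a *normal* late-event run (platelet plateau, decline from
~65 min, crash with a concurrent steep sigmoidal dpMO rise so that the
detector, not the generator, places termination in the 90–130 min window);
a *cold-activation* run (platelets start from a cold-depressed baseline,
recover to ~1500–1800% of start by 80 min as the loop rewarms, then fall
below baseline, termination near 100 min); and a *hypercoagulable* run
(immediate platelet crash and pressure rise, termination well inside
30 min). ACT decreases monotonically with occasional device-error flags
(value absent, flag set); aPTT decreases until ~30 min before termination
and then exceeds the 400 s cuvette limit, stored capped at 400 s with the
out-of-range (OOR) flag — the invariant "aPTT ≤ 400, and = 400 iff OOR"
is enforced by the class validity method. Pressure is sampled every
minute, blood at 0 and 15 min then every 30 min, temperature every
15 min, per the loop protocol.

What the generator does *not* emulate: analyzer-specific measurement
error structure beyond simple Gaussian noise, heparin pharmacokinetics,
temperature feedback on coagulation, or any mechanistic coupling between
the CT-visible deposits and the pressure curve. Passing monitoring tests
therefore shows that the *analytics* behave correctly on realistic trace
shapes, not that the generator predicts real experiments.

## Numerical choices and problem sizes

* Ray step = voxel/2 (midpoint rule); ray tracing agrees with a
  dense-sampling brute-force oracle to < 0.5%.
* Ramp filtering pads to the next power of two ≥ 2·n_u to avoid circular
  wrap-around; filtering and back-projection are exactly linear, and two
  runs on the same inputs are bit-identical.
* Transmittance clamp ε = 10⁻⁶ keeps the logarithm finite in opaque
  pixels; the upper slack 1.5 tolerates noise overshoot above the empty
  beam.
* The test suite and the acceptance script run the full pipeline at
  256² × 400 projections reconstructed on 128³ (voxel 0.15 mm), with
  smaller instances (≤ 192² detectors, ≤ 96³ grids) for alignment,
  ring-suppression and oracle comparisons; these sizes were chosen so the
  whole validation remains a desk-scale computation while every claim is
  still exercised at realistic sampling ratios.
* All stochastic stages (gain maps, drift, Poisson draws, monitoring
  noise) are seeded; phantom generation is deterministic.

## Known limitations

* Thrombus placement is geometric, not flow-derived; no hemodynamics.
* Polychromatic spectra, scatter, detector lag and source-spot blur are
  not modelled; attenuation values are nominal, so only contrast
  *orderings* and *ratios* are meaningful.
* The ring filter cannot separate rotation-invariant object structure from
  detector bias (inherent to the angle-mean method).
* Registration is integer-translation only.
* White-thrombus vs air disambiguation relies on the unclipped difference
  and the default grey anchoring; with a different grey scale the
  `airLevel` threshold must be rescaled accordingly.
* The 30-voxel size rule is applied in 3D by default; the per-slice 2D
  mode reproduces the planar reading of the same rule, and both are
  provided because the published description is ambiguous on this point.
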