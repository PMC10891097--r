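---
title: "Models and methods behind sonoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sonoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonoquant)
```

# The problem

Recurrent glioblastoma is largely shielded from systemic chemotherapy by the
blood–brain barrier (BBB). An implantable nine-emitter ultrasound array,
placed in the skull in place of a 58 mm × 58 mm bone flap, can open the BBB
transiently over a large peritumoral volume when activated together with
intravenous microbubbles (low-intensity pulsed ultrasound, 1 MHz, 25 ms
pulses every 2 s for 270 s at 1.03 MPa per emitter, the nine emitters firing
sequentially). `sonoquant` implements the quantitative analysis layer such a
study needs:

1. **geometry** — per-emitter cylindrical regions of interest (ROIs) and
   distance-to-axis maps on voxel grids;
2. **scoring** — automated per-emitter BBB-disruption (BBBD) grading from
   pre/post-gadolinium T1-weighted MRI;
3. **kinetics** — the exponential model of BBB closure after sonication;
4. **dynamics** — in-field tumor growth slopes and radial progression
   coverage, with rank-based cohort comparisons;
5. **design** — the exact single-arm binomial design statistics;
6. **acoustics** — a Rayleigh–Sommerfeld simulator of the per-emitter
   pressure fields and their overlap;
7. **synth** — a synthetic study generator that gives every stage inputs
   with known ground truth.

All tabular results are tibbles; fitted objects support `tidy()`,
`glance()` and `autoplot()`; volumes are plain arrays tied to a
`voxel_grid` affine (NIfTI conventions, world coordinates in mm, RAS+,
0-based voxel indices) and move through `RNifti`.

# Geometry

Each emitter insonifies a **10 mm diameter × 75 mm cylinder** in front of
it; tumor-field analyses dilate this by a **5 mm diffusion margin** to
20 mm × 80 mm. The implant is modeled as a flat 3 × 3 grid with a default
pitch of 58/3 ≈ 19.33 mm, the spacing at which the array exactly fills the
bone flap; the pitch is configurable because the true layout of the device
is not public, and the flexible implant's conformation to skull curvature
is deliberately not modeled (no bending parameters are available).

Rasterization is **voxel-center-in-region**: a voxel belongs to cylinder
*k* when its centre is within `radius + margin` of axis *k* and within
`[0, length + margin]` along it. Where dilated cylinders overlap, the voxel
goes to the nearest axis (ties to the lowest emitter index), so per-emitter
labels partition the union and per-emitter volumes add up. Volumes are
voxel counts × voxel volume.

One numerical caveat is worth stating precisely. Binary voxelization of a
5-mm-radius disc at 1 mm resolution has a lattice-alignment-dependent
error: when a voxel column of centres falls exactly on the axis, the disc
picks up the classic lattice excess (up to ≈ +3–5% for a single cylinder);
averaged over the nine cylinders, or for generically aligned grids (any
clinical affine), the error is below 1–2%, and it vanishes as the voxel
size shrinks (the tests verify a strict error decrease over 2, 1 and
0.5 mm). Analyses that depend on absolute volumes should use 1 mm grids or
finer; grading decisions are robust because planned volumes sit far from
the 0.5 mL decision boundary.

Distance-to-axis maps take, per voxel, the minimum over emitters of the
perpendicular distance to the emitter axis, counting an emitter only while
the voxel's axial coordinate lies within the sonicated length; **tube
shells** (`[r1, r2)` bands of that distance) partition the peritumoral
brain into the "ring-shaped" regions used for radial progression analysis.
The default bins are 2.5 mm wide over 0–20 mm, matching the granularity at
which the clinical analysis reported significance (up to 7.5 mm).

# Scoring

The enhancement map is the voxelwise relative signal change between a
co-registered pre/post T1w pair, after matching the post image's median to
the pre image's over a reference region of normal, non-sonicated brain:
`map = (post' − pre) / max(pre, ε)`, with `ε` set to 1% of the within-brain
median of the pre image. Inputs are assumed co-registered and
bias-corrected upstream (registration is delegated, as in the clinical
pipeline; the synthetic generator produces co-registered volumes by
construction).

The detection threshold τ is the value exceeded by 1% of a non-sonicated
control region — the upper 1% tail. We read the clinical rule
("1st centile of the control ROI") as this upper tail deliberately: the
literal lower 1st percentile of a noise distribution centred at zero would
declare essentially all control tissue "enhanced". The tail fraction is
configurable.

Grading per evaluable emitter, on suprathreshold voxels inside the
cylinder that were not enhancing before sonication (cavity and tumor
labels removed):

| grade | rule (defaults) |
|---|---|
| 0 | enhanced volume ≤ 0.5 mL |
| 1 | > 0.5 mL but ≥ 90% of enhanced voxels in the subarachnoid label |
| 2 | otherwise, enhanced white-matter volume ≤ 0.25 mL |
| 3 | enhanced white-matter volume > 0.25 mL |

The published scale lumps grades 0–1 (subarachnoid-only) versus 2–3 (gray
or gray+white); the 0/1 and 2/3 splits above preserve the published 0.5 mL
floor and the tissue definitions while remaining configurable, since the
exact sub-rules were not published. Emitters whose cylinder is more than
30% cavity/tumor are excluded from grading (threshold configurable, strict
inequality; the published analysis excluded such emitters without stating
a fraction).

Session-level metrics: **success** is grade ≥ 2 on at least two-thirds of
evaluable emitters (boundary inclusive: 6/9 succeeds); **I90** is the 90th
percentile of the enhancement map over the union of evaluable cylinders;
**depth** is the largest axial coordinate (mm from the plate plane)
reached by suprathreshold enhancement. Depth is a maximum statistic and is
therefore noise-fragile by construction: a single suprathreshold noise
voxel deep in a cylinder sets it. The depth-identity checks consequently
use noiseless constructions; on noisy data depth should be read as an
upper envelope.

# Closure kinetics

Enhancement intensity against sonication-to-gadolinium delay *t* follows

$$E(t) = E_0\, e^{-\lambda t}, \qquad t_{1/2} = \ln 2 / \lambda ,$$

fitted by Levenberg–Marquardt least squares, initialized from a log-linear
regression on positive intensities. No asymptotic offset is included by
default: the clinical observation is full closure within hours, and the
published fit form gives no offset; a non-closing best fit (λ ≤ 0) is
flagged with `t_half = Inf` rather than silently reported. Delays are
recorded in minutes, half-times reported in hours, and the fit is
unit-invariant (tested to 1e-7 relative).

Confidence intervals use a **case-resampling bootstrap** (percentile
intervals, seeded, 1000 resamples by default); the published interval's
method was unstated, and case resampling is the assumption-lightest choice
at n ≈ 31. Spearman's ρ between delay and intensity is the accompanying
trend diagnostic (exact permutation null for n ≤ 9 without ties,
asymptotic otherwise).

# Tumor dynamics

Enhancing-tumor volume is split exactly into in-field (inside the union of
margin cylinders) and out-of-field parts; conservation is voxel-exact and
tested. Per-patient growth is the OLS slope of volume against months from
first sonication (months of 30.44 days), in mL/month; patients with fewer
than two time points are flagged and dropped from cohort summaries,
mirroring the clinical exclusion of one patient. Cohorts are compared by a
two-sided Wilcoxon–Mann–Whitney test — exact when the combined sample is
≤ 20 without ties, normal approximation with continuity correction
otherwise.

The **progression mask** is the voxelwise set difference between the last
and first enhancing-tumor masks. Its **radial coverage profile** is the
fraction of each tube shell covered; per-bin cohort differences use the
same rank-sum test with raw p-values by default (the clinical analysis
reported unadjusted p-values across bins); Holm adjustment is available
behind a flag.

# Design statistics

The phase-2 success proportion is tested against an objective performance
criterion (OPC) of 0.30 at one-sided 2.5%: effectiveness is declared when
the lower limit of the exact Clopper–Pearson 95% CI exceeds the OPC. The
critical value from this CI rule is proven (by exhaustive check to
n = 100, in the tests) identical to the tail rule
`P(X ≥ k | p0) ≤ α`. For n = 15, p0 = 0.30, p1 = 0.70 the critical value
is 9 successes and the exact power is 86.89%, consistent with the
protocol's stated 86% (whose rounding convention is unknown; we treat it
as a lower bound). `carboplatin_dose()` implements the Calvert formula,
dose = AUC × (GFR + 25), warning outside the protocol's 4–6 mg/mL·min
range.

# Acoustic field simulation

Per-emitter steady-state pressure magnitudes come from direct
Rayleigh–Sommerfeld summation over the piston surface,

$$p(\mathbf{x}) = p_0 \frac{k}{2\pi}\left|\sum_j
\frac{e^{(ik-\alpha)R_j}}{R_j}\, \Delta S_j\right| ,$$

with ≥ 10 surface elements per wavelength, in a linear, lossy, homogeneous
soft-tissue medium (c = 1540 m/s, 0.5 dB/cm/MHz, ρ = 1040 kg/m³ —
standard values; the device sits epidurally in place of bone, so no skull
layer is modeled, and neither nonlinearity nor microbubble dynamics enter
the thresholded-pressure picture). The solver is validated against the
closed-form on-axis solution
`p/p0 = 2|sin((π/λ)(√(z²+a²) − z))|` to < 0.5%. Because the array is flat
and the medium homogeneous, all nine fields are translates of one another:
the solver tabulates a single axisymmetric (r, z) field per piston
geometry and interpolates it onto the 3-D grid per emitter. Emitters fire
sequentially, so fields are never summed coherently.

Two textbook near-field facts that the tests pin down, because they are
easy to get backwards: a half-wave path difference
(z = a²/λ − λ/4 ≈ 15.85 mm for a 5-mm, 1-MHz piston in brain) is the last
axial *maximum* (p = 2p₀), not a null — the last null needs a full-wave
difference (≈ 7.35 mm); and increasing attenuation is guaranteed to
decrease the field only beyond the immediate near field, since within a
couple of millimetres of the face it reweights interfering contributions
and can locally raise the magnitude.

The **BBBD region** is the volume above 0.2 MPa; **overlap metrics** report
the fraction of the sonicated volume covered by ≥ 2 beams and the acoustic
energy (∝ p² × duty cycle) in the overlap zone relative to the field
maximum. With the flat conformation and 19.3 mm pitch, the above-threshold
beam radius (≈ 7.5 mm) never reaches the 9.65 mm midpoint between adjacent
axes, so the computed overlap fraction is 0% — safely below the ≤ 10%
bound observed clinically. The in-vivo overlap arises from skull-curvature
tilting of the outer emitters, which this model intentionally omits; the
simulator therefore bounds, rather than reproduces, the patient-specific
overlap spread.

# Synthetic data

The generator produces geometric, not anatomical, phantoms: a cylindrical
brain under the implant plane with depth-layered labels — subarachnoid/CSF
rim, gray ribbon, white core — plus an optional spherical cavity wrapped
in enhancing tumor. Two deliberate distortions serve testability: the
subarachnoid rim (12 mm) and gray ribbon (12 mm) are thicker than anatomy
so that subarachnoid-confined and gray-only openings can exceed the 0.5 mL
grading floor within a 10-mm cylinder; and z voxel centres start exactly
on the plate plane so axially truncated injections return their truncation
depth exactly. Default phantoms are 128³ at 1.5 mm (a full-head-scale
field of view); tests use smaller grids where the check does not depend on
extent.

Sessions are injected multiplicatively (`post = pre × (1 + e_eff)` in the
planned tissue classes inside each planned cylinder), with
`e_eff = e0 · 2^{−t/t_{1/2}}` tying the injected amplitude to the closure
model, and multiplicative Gaussian acquisition noise (default 2% — typical
T1w SNR scale; Rician refinement is out of scope at these SNRs). With the
default amplitude e0 = 0.3 and the 1%-tail threshold, injected openings
sit at more than twice τ, and generated sessions round-trip: the grading
pipeline returns exactly the planned grades (tested across grade
patterns).

Closure datasets draw delays uniformly on the observed 10–77 min range
with additive noise of 15% of E0 at n = 31 — the published cohort's
conditions. Growth cohorts draw true slopes from a normal distribution
(symmetric, hence its median is the specified cohort median: 2.31 mL/month
for 14 patients, 0.54 mL/month for 12, matching the two published
cohorts), with 4–6 monthly measurements, 10 mL baseline and 0.2 mL
measurement noise; tumor masks grow voxel-by-voxel around a seed point
near the central axis, excluded from a configurable near-axis control tube
for the cohort under effective local therapy, which makes radial coverage
suppression constructible and volume-consistent (masks match trajectory
volumes to < 5%).

What passing on synthetic data does **not** show: robustness to
registration error, bias fields, motion, contrast-agent brand differences,
or radiologist-level ambiguity in segmentations — all of which the
clinical pipeline handles upstream of the quantities modeled here.

# Problem sizes and numerical choices

Defaults were chosen once to match the study conditions: 31 closure
observations, 200 replicate fits for the half-time summary, 300 replicate
cohorts for slope recovery, 10-session/90-cylinder grading sets at 1.5 mm,
5-session depth sets at 1 mm, and 1-mm acoustic grids to 80 mm depth with
0.25 × 0.5 mm field tables. Quantiles use the linear-interpolation (type
7) convention throughout. Bootstrap and all generators require explicit
seeds; every generator output is a pure function of its spec. Degenerate
inputs fail loudly (empty control regions, zero evaluable emitters,
constant intensities) rather than returning silent numbers.

# Known limitations

* The emitter pitch and the curved conformation of the implant are not
  public; the flat 19.3-mm-pitch array is an explicit assumption
  (configurable) and is the reason simulated beam overlap is a bound, not
  an estimate.
* The 0/1 and 2/3 grade sub-rules and the evaluability fraction are
  package choices within the published 0–3 scale's constraints.
* Whether the published phase-2 CI on emitter-level success accounted for
  within-patient clustering is unstated; `success_proportion_evaluation()`
  treats observations as independent.
* Depth is a maximum statistic; see the scoring section.
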