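---
title: "Serial IVUS-VH plaque analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial IVUS-VH plaque analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Serial intravascular ultrasound with virtual histology (IVUS-VH) images the
same coronary artery at baseline and again about a year later. Each pullback
yields an ordered stack of cross-sectional frames; for every frame the
segmentation provides the lumen and external elastic membrane (EEM)
cross-sectional areas (CSA) and the VH tissue classification splits the
plaque into fibrous (F), fibro-fatty (FF), necrotic core (NC) and dense
calcium (DC) areas, plus the circumferential arc over which NC touches the
lumen. `serialvh` takes these per-frame tables — image segmentation itself
is out of scope — and answers the longitudinal questions: how did plaque
burden, composition, phenotype and risk score change per co-registered 5-mm
vessel segment, and how do the changes differ between patient groups
(diabetic vs non-diabetic)?

## Morphometry

Per frame: plaque CSA = EEM CSA − lumen CSA; plaque burden = plaque / EEM.
Composition fractions are taken relative to *characterized* tissue
(F + FF + NC + DC), not to plaque CSA, because VH leaves media and
unclassified pixels uncounted; with that convention the four fractions sum
to one, matching how relative compositions around 0.55/0.15/0.15/0.09 are
conventionally reported. Per segment we report unweighted frame means
(frames are treated as uniformly spaced, an approximation of ECG gating; a
config flag enables distance-weighted means), the percent atheroma volume

PAV = 100 × Σ(EEM − lumen) / Σ EEM,

the minimal lumen area (MLA, ties broken toward the most distal frame) and
a remodeling index (RI). The RI of a segment is defined here as the EEM CSA
at the MLA frame divided by the mean EEM CSA of the segment's two boundary
frames. Lesion-level remodeling indices normally use proximal and distal
reference sites; in a tiling segment design the segment boundaries are the
nearest available references. The definition lives in one function
(`remodeling_index()`) so alternatives are drop-in.

## Phenotype classification

Six categories in ascending severity: NL (no lesion), PIT (pathologic
intimal thickening), FP (fibrous plaque), FcP (fibro-calcified plaque),
ThCFA (thick-cap fibroatheroma), TCFA (thin-cap fibroatheroma). The
frame-level cascade is:

1. plaque burden < 40% → NL;
2. NC ≥ 10% of characterized tissue *and* NC-lumen contact arc ≥ 30° →
   TCFA candidate;
3. NC ≥ 10% without contact → ThCFA;
4. DC ≥ 10% → FcP;
5. FF ≥ 15% → PIT;
6. otherwise FP.

The burden threshold is the standard lesion definition; the remaining
numeric thresholds follow the established VH-phenotype literature and are
all exposed in `analysis_config()`, because flowchart-style definitions
differ slightly between studies and reproducibility requires tunable,
explicit values. Two surrogates deserve mention. NC *confluence* cannot be
evaluated from a scalar area, so the total NC fraction stands in for it.
The absent fibrous cap of a TCFA is below IVUS resolution, so lumen contact
of the NC is the operational criterion; an `nc_arc_contact_deg = 1` setting
reproduces the strict "any visible contact" reading.

A TCFA additionally needs three consecutive candidate frames. Shorter
candidate runs are demoted to ThCFA — NC-rich, but with the cap criterion
unconfirmed — rather than to FP, a severity-conservative choice. Each 5-mm
segment is labeled with the most advanced confirmed frame phenotype it
contains, and a confirmed run that straddles a segment boundary labels
*both* segments TCFA.

## The Liverpool Active Plaque Score

Per frame,

LAPS = −2.149 + 0.68 × NC/DC + 3.39 × MLA + 5.1 × [RI > 1.05] + 3.7 × [VH-TCFA].

Segment LAPS is the highest frame LAPS in the segment; pullback LAPS is the
mean over segments. Three reading decisions:

* **MLA term.** LAPS is computed for each frame, but MLA is a lesion-level
  quantity; the only frame-local reading uses the frame's own lumen CSA,
  which is the default (`laps_frame_mla = "frame"`). A config switch uses
  the enclosing segment's MLA instead.
* **NC/DC at DC = 0.** The ratio is undefined; DC is floored at
  0.01 mm² and the ratio capped at 10, keeping scores finite and monotone.
* **Sign of the MLA coefficient.** As printed the score *increases* with a
  larger lumen. The coefficients are config values, not code, so users can
  substitute the original published coefficients (including a negative MLA
  weight) without touching the implementation.

## Registration and segmentation

Landmark frame pairs (two fiduciary points at minimum, typically plus a
mid-vessel landmark) define a piecewise-linear, monotone map from baseline
to follow-up axial position, exact at every landmark and clamped outside
the outermost pair. Windows of 5 mm are laid on baseline coordinates
starting at the distal landmark — matching the distal-fiduciary pullback
protocol — and the residual proximal tail shorter than one segment is
dropped. Whether partial tail segments should be analyzed is genuinely
open; dropping them keeps every reported segment a full 5 mm. Each window
maps to a follow-up span that may contain a different number of frames
(registration stretch); per-timepoint means are taken over each span's own
frames. Patients with less than 25 mm of registered overlap are excluded
with a recorded reason, mirroring the usual serial-imaging inclusion
minimum.

## Transitions and TCFA fates

Over the registered segment pairs we report 6×6 baseline→follow-up
transition counts (row-normalized per baseline phenotype) and the TCFA
fates: persistent (TCFA→TCFA), healed (TCFA→other), new (other→TCFA),
never. Published fate percentages rarely state their denominators; the
package emits both conventions and flags as primary: persistent rate =
persistent / baseline-TCFA, new rate = new / baseline-non-TCFA. Percentages
are printed to one decimal with conventional half-up rounding.

## Group statistics

Between-group comparisons use Welch's two-sided t test (group sizes of 17
vs 44 make the unequal-variance form the safer default) or the Mann-Whitney
U test when normality cannot be assumed; the choice is a recorded input
rather than an automatic decision. Categorical contrasts use Fisher's exact
test. Because multiple 5-mm segments cluster within a patient, segment-level
deltas are additionally tested with a linear mixed model,
`delta ~ group + (1 | patient)`, fitted via `lmerTest` with Satterthwaite
degrees of freedom; a singular or inestimable fit falls back to the
fixed-effect model and is flagged, never silent. No multiple-testing
correction is applied by default (a Benjamini-Hochberg column is available
by flag).

## The synthetic cohort generator

No patient-level data accompany the study design this package implements,
so the generator is a first-class module: it emulates the *tabular
statistical structure* the analysis consumes, calibrated to the published
group summaries — 17 DM / 44 non-DM patients; vessel lengths
N(70.5, 15.8) / N(72.9, 18.6) mm clamped at the 30 mm inclusion minimum;
per-segment deltas of plaque area N(0.21, 0.97) / N(−0.47, 1.15) mm² and of
PAV N(0.7, 2.8) / N(−1.4, 2.5) points; per-patient pullback-LAPS change
N(0.13, 1.79) / N(−0.23, 1.66); TCFA fate probabilities 0.203 / 0.126 (new)
and 0.821 / 0.713 (persistent); baseline TCFA segment shares 48.9% / 45.1%.
All defaults live in `inst/extdata/generator-defaults.yaml`.

Generation is top-down so recovery tests have exact ground truth: segment
phenotypes, burden targets and deltas are drawn first, then frames are
synthesized to match. Key mechanics and the reasoning behind them:

* **Both geometric deltas are hit exactly on the noise-free profile.** Given
  a segment's drawn plaque-area delta and PAV delta, follow-up EEM per frame
  is solved analytically (plaque ratio scaling), so the pipeline recovers
  the configured means up to frame noise and windowing effects.
* **Patient random intercepts** carry 15% of each delta's variance
  (marginals unchanged). The share is deliberately modest: a patient-level
  PAV intercept propagates into lumen calibre and hence into pullback LAPS
  at roughly −1.1 LAPS per PAV point, and larger intercept shares push the
  LAPS calibration (below) against its bounds.
* **Pullback-LAPS calibration.** After geometry and fates are realized, the
  patient's pullback-LAPS change is steered to its drawn target by shifting
  NC/DC ratios: uniformly within a segment (so the segment maximum moves by
  exactly the intended amount), two-sided (follow-up with the needed
  change, baseline against it), waterfilled across segments within each
  frame's phenotype-preserving bounds (DC moves, F compensates, NC and FF
  stay fixed). DC fractions are kept deliberately low (NC/DC ≈ 5) to leave
  headroom below the ratio cap of 10; the calibration saturates for a few
  percent of patients with extreme draws, with bounded, roughly symmetric
  residuals. A consequence is that generated DC areas sit below typical
  reported values — a realism trade made for exact score calibration.
* **TCFA runs** are 4-6 frames, placed in the segment interior with a
  ±0.24 mm membership margin so that a follow-up grid stretched by up to
  ±10% still lands at least three frames inside every run, and no run
  touches a window boundary unintentionally.
* **New TCFA in a no-lesion segment** implies lesion formation, so the
  follow-up burden is raised above the 40% threshold; this adds a small
  upward bias (~0.1-0.2 points) to the recovered mean PAV delta, well
  inside the two-standard-error recovery band.
* **Fates and morphometric deltas are drawn independently** given the
  group; their joint distribution is unreported, and conditional
  independence is the neutral assumption.
* **Registration stretch** is piecewise linear through three anchors (both
  ends plus one mid-vessel landmark) with factors in [0.9, 1.1], snapped to
  both frame grids so landmark pairs are exact.

What the generator does *not* emulate: RF backscatter or image content,
realistic 3-D vessel geometry, longitudinal composition drift beyond the
fate edits, inter-segment spatial correlation of composition, or
measurement error in the landmark pairs. Passing recovery tests therefore
demonstrate that the pipeline is an unbiased, correctly plumbed estimator
of the quantities the generator encodes — not that it is robust to the
full messiness of clinical IVUS data.

## Numerical choices and degenerate inputs

* Frame membership in windows is half-open `[lo, hi)` with a 1e-9 mm
  tolerance, so boundary frames belong to exactly one segment.
* MLA ties break to the most distal frame; `which.min` supplies this
  deterministically.
* A frame with no characterized tissue has all composition fractions 0 by
  convention; EEM = 0 is a hard error.
* Composition sums may exceed plaque CSA by at most 5% of plaque CSA
  (configurable) — a fractional rather than absolute tolerance, since the
  uncounted media scales with vessel size.
* Segments need at least 3 frames at each timepoint (RI needs boundaries
  distinct from the MLA frame); with 0.5 mm spacing a 5-mm window holds ~10.
* All randomness flows from a single integer seed; identical inputs and
  configuration give bit-identical outputs.

## Problem sizes in the test suite

The packaged tests run the full default cohort (61 patients, ~840 segment
pairs, ~36 000 frames) once and share it across checks; unit tests use 1-4
patient cohorts and analytic fixtures. The null-calibration check of the
two-sample test uses 1000 replicates at n = 20 per arm. These sizes were
chosen to give stable Monte-Carlo verdicts (2-SE bands) at interactive
runtimes.

## Known limitations

* The phenotype thresholds inside the classification flowchart are
  literature defaults, not values printed by any single study; sensitivity
  to them should be explored via `analysis_config()`.
* The remodeling-index definition is a package choice (segment boundaries
  as references); alternative definitions change the 5.1-point LAPS term
  for borderline segments.
* Pullback LAPS with the as-printed positive MLA coefficient is dominated
  by lumen calibre; between-timepoint LAPS changes are therefore sensitive
  to lumen measurement consistency.
* The generator's calibration guarantees hold under its own assumptions
  (uniform gated spacing, exact landmarks); real pullbacks with speed
  discontinuities violate them.
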