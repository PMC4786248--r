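---
title: "Methods: automated pneumothorax detection and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated pneumothorax detection and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptxcad)
```

## The problem and the signal model

Pneumothorax (PTX) interposes air between the visceral and parietal pleura,
which abolishes pleural sliding at the probe site. Two sonographic readouts
carry that information. In B-mode cine loops the apposed pleura is a
hyperechoic horizontal line just deep to the ribs that shimmers laterally
with respiration; vertical reverberation artifacts (B-lines / comet tails)
arising at the visceral pleura likewise require apposed pleura, so either
sign excludes PTX at that interspace. In M-mode, sub-pleural motion
scrambles the single scan line into granular speckle (seashore sign),
whereas an immobile interface yields rows that are constant across the sweep
(stratosphere/barcode sign).

`ptxcad` operationalizes both readouts on intensity-normalized grayscale
images (every pixel in [0, 1], scaled by the source dtype maximum so
thresholds transfer across 8- and 16-bit exports). Images are indexed
(row, column) = (depth, lateral-or-time), 1-based, row 1 at the skin
surface; column intervals are inclusive. All tunable thresholds sit in two
params objects, `bmode_params()` and `mmode_params()`, so a run is fully
described by (input, params).

## B-mode pipeline

**Rib shadows.** Static anatomy is read off the temporal median frame,
which is robust to sliding: the median over ≥ 3 frames of laterally
shuffling speckle converges on the speckle median, while static structures
pass through unchanged. A shadow is a maximal run of columns (width
≥ `min_shadow_width` = 8 px, about half a neonatal rib width at typical
export resolution) whose mean intensity over the deep half of the image is
below `shadow_factor` = 0.5 of the deep-half global mean — posterior
acoustic shadowing suppresses nearly all echo, so a factor of one half
separates it cleanly from speckle at any overall gain. The rib cap is the
brightest row above the deep half within the run.

**Intercostal space.** The widest gap between consecutive shadows, shaved by
`space_margin` = 4 px per side to stay clear of partial-volume columns; two
discrete ribs are required, and a shrunk gap must still measure
`min_space_width` = 20 px to support the later cross-correlation.

**Pleural line.** Among rows strictly below the deepest rib cap (this depth
constraint is what rejects bright superficial muscle layers), a row
qualifies when at least `min_contiguity` = 60% of space columns exceed
`line_threshold` = 1.5 × the mean intensity of the search region; the
brightest qualifying row wins. The threshold reference is deliberately the
*search-region* mean, not the candidate row's own mean: a uniformly bright
line would never exceed 1.5 × its own row mean, so a row-relative
definition would reject exactly the lines the stage exists to find. For
Rayleigh speckle with scale 0.15 the region mean is ≈ 0.2, so the line
test asks for ≈ 0.3 — about a third of a typical pleural-line intensity and
more than two speckle standard deviations above background.

**Sliding.** For each consecutive frame pair, a strip of `strip_height` = 6
rows starting `strip_offset` = 2 rows below the detected line (restricted to
space columns) is matched at integer lateral shifts up to `max_shift` = 10 px
by normalized cross-correlation; ties prefer the smaller displacement.
The amplitude is half the peak-to-peak excursion of the *cumulated*
displacement trajectory — per-pair increments understate a slow sinusoid,
whereas the trajectory recovers the configured excursion exactly. Sliding is
declared when the amplitude reaches `amp_threshold` = 1.5 px (above the ±1 px
quantization floor of integer matching) *and* the increment sequence changes
sign at least once. The sign-change requirement encodes "to and fro":
probe drift translates tissue monotonically and must not count as sliding.

**Reverberation.** On the median frame, each space column's penetration
score is the fraction of rows from `subpleural_gap` = 4 rows below the line
to the bottom edge that exceed `artifact_threshold` = 0.5 × the line
brightness. For background Rayleigh speckle the per-row exceedance
probability is ≈ 0.7%, so genuine B-lines (score ≈ 1) and background
(score ≈ 0) are far apart; bands need `min_band_width` = 3 consecutive
columns above `penetration_threshold` = 0.5.

**Decision.** `bmode_decision()` is a pure function of three booleans: no
line → indeterminate (dominating); sliding or reverberation → negative;
otherwise positive. Reverberation acting as a *negative* indicator reflects
the clinical reading of pleura-anchored vertical artifacts (B-lines), not
horizontal A-lines, which the pipeline does not model — a deliberate scope
choice, since vertical artifacts are the ones requiring apposed pleura.
Failure modes (no ribs, no space, no line, fewer than 3 frames) all surface
as indeterminate calls with a recorded reason, never as errors.

## M-mode pipeline

The pleural line is the most hyperechoic contiguous row — brightest row
whose contiguity along the sweep reaches 60% at 1.5 × the whole-image mean —
with the top `margin_rows` = 5 rows excluded from candidacy as a near-field
guard (skin-contact reverberation often saturates the first few rows; the
guard excludes those rows from the search rather than aborting, so a genuine
line deeper down is still found).

Texture below the line (starting `gap` = 3 rows down, requiring ≥ 8 rows) is
scored by the per-row temporal coefficient of variation, cv = sd/mean along
the sweep. Barcode rows are constant in time (cv ≈ 0); fully developed
Rayleigh speckle has cv = √(4/π − 1) ≈ 0.52 regardless of gain, so
`cv_threshold` = 0.1 sits several sampling standard deviations from both
populations, and the statistic is invariant under any global intensity
rescaling. Rows with mean < `epsilon` = 0.02 are scored cv = 0: an echo-free
row is static, not granular. A barcode row fraction ≥
`barcode_threshold` = 0.6 is called positive (stratosphere), otherwise
negative (seashore); no line means indeterminate, extending the B-mode rule
to M-mode.

## The phantom generator

The generator stands in for a clinical archive that cannot be redistributed,
so its defaults define the study conditions used throughout the tests:
128 × 192 px frames, 20 frames per clip, rib centers at columns 40 and 152
(16 px wide, caps at row 20, shadow attenuation × 0.15), pleural band at row
60 (brightness 0.95, 2 rows thick), multiplicative Rayleigh speckle with
scale 0.15, sliding amplitude 4 px with a 20-frame period, and a 200-column
M-mode sweep. These are plausible mid-range values for a linear-probe
thoracic view exported at modest resolution; none is derived from a specific
device.

Negatives must carry at least one negative-indicating sign (sliding and/or
B-lines) and positives must carry none — the config constructor enforces
this coupling, so truth labels cannot drift from rendered content. Sliding
is rigid lateral translation of the sub-pleural speckle with a sinusoidal
time course, rendered by windowing a wider static field, so the per-frame
shift table is known exactly and serves as the motion oracle. B-lines are
bright vertical bands drawn *into* that field, hence they move with the
sliding pattern as real comet tails do. `make_cohort()` samples negatives at
a configurable ratio (default 2:1, the study design), jitters nuisance
parameters (rib positions ±6 px, pleural depth ±8 px, speckle scale
±20%), assigns modes at roughly the clinical 80/20 B/M mix, and draws
every exam seed from one seeded stream, so a cohort is a pure function of
(n, ratio, seed).

What the phantoms deliberately do **not** model: sector (curvilinear)
geometry, depth-dependent attenuation and focusing, electronic noise,
cardiac lung-pulse motion, A-line reverberations (generatable in principle
but off by default, since the decision rule does not use them), compression
artifacts, and probe motion. Passing the recovery suites therefore shows the
pipeline implements its stated contracts on clean, fully-specified inputs —
near-perfect phantom accuracy is expected by construction and does not
forecast clinical accuracy, where image quality dominates.

## Evaluation statistics

Adjudication includes an exam only when all raters agree and (optionally)
the *median* ACEP quality score is ≥ 3; the median is the package's choice
of whose score governs the gate, being insensitive to one outlying rater.
Non-unanimous exams are flagged for plenary review, not resolved — resolving
them is a human step outside the package.

Reference-indeterminate exams never enter the 2×2 table.
Prediction-indeterminate exams are governed by an explicit policy flag:
`exclude` (drop them, the default) or `as_error` (count them against the
predictor — conservative, and the policy used by the acceptance script for
phantom recovery). Confidence intervals are exact Clopper–Pearson
throughout, computed by binomial tail inversion; among standard interval
families it is the only one consistent with the printed bounds this package
reproduces in its tests, and its conservative coverage suits small strata.
Printed percentages round half away from zero. Cohen's κ uses the
large-sample standard error √(p_o(1 − p_o) / (n(1 − p_e)²)) with the CI
clipped to [−1, 1]; interpretation bands are > 0.75 excellent, 0.40–0.75
fair to good, below that poor, with band edges compared at square-root
machine tolerance so that a κ of exactly 0.40 lands in its intended band.
Zero-denominator statistics are reported as explicitly undefined (`NA`),
never as 0, and empty strata are reported, not dropped.

## Numerical and degenerate-input choices

- Temporal medians of even-length clips average the two middle order
  statistics (computed by one vectorized sort, not per-pixel calls).
- NCC over near-constant strips (variance < 1e−12) contributes displacement
  0 rather than an arbitrary argmax; ties prefer the smaller shift.
- All-zero images fail line detection cleanly (`found = FALSE`) because the
  intensity threshold degenerates to 0.
- Readers reject rather than clamp out-of-range intensities; every failure
  mode raises a classed condition (`ptxcad_error_*`) so callers can branch
  on it, and the batch classifier converts per-exam failures into
  indeterminate rows with reasons.
- Phantom determinism uses an isolated RNG scope per call (the global
  stream is left untouched), with cohort exam seeds drawn below 2³¹.

## Problem sizes used by the test suite

The recovery suites run 200 balanced B-mode phantoms and 40 M-mode phantoms
at the default geometry (about half a minute), exhaustively check the
decision table, compare the exact CI against a tail-sum bisection oracle for
every (k, n) with n ≤ 50, and verify M-mode calls against an independent
spectral oracle (stratosphere ⟺ > 95% of sub-pleural temporal-frequency
energy at zero frequency). The acceptance script simulates and classifies a
147-exam cohort (49 positives, 2:1 negatives) end to end.

## Known limitations

- One intercostal space per clip; no lung-point search, no probe-motion
  compensation, no quality-score prediction.
- The B-mode/M-mode results are never merged into a single per-patient
  call; each image is classified on its own.
- Integer-pixel motion estimation floors the detectable sliding amplitude
  at about 1 px; sub-pixel refinement was not needed at phantom scales.
- The evaluation module implements pairwise κ only (as diagnostic-accuracy
  studies conventionally report); no multi-reader ROC or Fleiss' κ.
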