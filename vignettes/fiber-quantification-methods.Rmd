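---
title: "Quantifying immunostained fiber density: method, calibration and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying immunostained fiber density: method, calibration and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberdens)
```

# The measurement problem

Catecholaminergic axons (noradrenergic fibers marked by dopamine
beta-hydroxylase, DβH, or the broader tyrosine-hydroxylase-positive
population) form sparse, thin, tortuous arborizations in cortex. After DAB
immunohistochemistry they appear as brown curvilinear elements, roughly
0.2–0.7 µm across, on a bright, lightly tinted background. Depletion
experiments (immunotoxins, 6-OHDA) are read out as the loss of these
fibers, so one needs a number per region of interest (ROI) that tracks the
amount of stained axon. Manual counting is slow and observer-dependent;
`fiberdens` implements an automated estimate: the *relative volume*
occupied by fibers, defined as the proportion of ROI pixels classified as
stained, reported as a percentage.

ROIs follow the study convention of 300 × 300 µm² windows digitized at
1320 × 1320 px (0.227 µm/px), taken per subject × region × hemisphere ×
section at fixed stereotaxic levels. The pipeline does not require that
geometry — any calibrated 3-channel image is accepted — but all default
spatial constants are tuned to that pixel scale.

# Detection algorithm

Each ROI passes through a fixed chain, every constant of which lives in
`quant_params()`:

1. **Channel combination.** The RGB channels are combined with weights
   blue = 1, red = −0.25, green = −0.25. Brown DAB product is strong in
   red and weak in blue, so stained structures come out *darker* than the
   near-neutral background in the combined plane. Channels are addressed
   by name, never by array position, to exclude RGB/BGR confusion.
   Values are carried as signed doubles on the 0–255 scale; nothing in
   the analysis path clips.
2. **Median filter**, disk neighborhood of radius 3 px (29 pixels), the
   rank-filter disk convention of common image software. This removes
   shot-like impulses while preserving fiber edges. Note the flip side:
   structures thinner than about half the disk are attenuated or erased,
   which is why sub-pixel-wide (rendered 1 px) synthetic fibers
   contribute little signal (see *Validation* below).
3. **High-pass.** A Gaussian-smoothed copy (σ = 8 px) is subtracted from
   the median-filtered plane, isolating spatial frequencies finer than
   the smoothing scale. Under the default `stain_dark` polarity the sign
   is flipped so stained elements become positive. "Radius 8" in the
   original macro language is interpreted as σ = 8 px; because the
   historical radius-to-σ mapping of ImageJ-family software is
   ambiguous, the interpretation is configurable and recorded in the
   parameter object.
4. **Large-stain exclusion.** Blots (precipitate, vessels, folds) would
   otherwise be counted as signal. Candidate pixels are those falling
   more than `stain_detect_level` (60) grey levels below the combined
   plane's *median*; candidates are labelled into 8-connected components,
   components of ≥ 2000 px are kept and dilated by 5 px, and the result
   is removed from the detection numerator only — the denominator remains
   the full ROI, preserving the "proportion of detected pixels in the
   ROI" definition literally. Referencing the ROI's own median (for
   sparsely stained tissue, the background) makes the criterion exactly
   invariant to global intensity offsets, which the whole chain then is.
5. **Fixed threshold.** A pixel is detected iff its polarity-corrected
   high-pass value is ≥ 11 (detected *at* 11; the boundary convention is
   fixed and tested). Negative deviations are never detected.
6. **Volume.** `volume_percent` = 100 × (detected pixels / all pixels).

Gaussian and median borders are handled by whole-sample reflection
(mirror about the edge pixel); Gaussian kernels are truncated at 3.5 σ
and renormalized to unit sum. Both filters are validated against
brute-force references (sliding-disk median; dense 2-D convolution by
explicit summation) to 10⁻⁶ on random planes.

## Focus quality control

Out-of-focus sections lose fine-scale contrast before they lose coarse
structure. The chain is therefore run a second time with σ = 20 px — a
pass that admits lower spatial frequencies — and the ratio

> `qc_ratio` = fraction detected at σ = 8 / fraction detected at σ = 20

is used as a focus criterion: sharp images score near 1, defocused images
collapse toward 0, and images with `qc_ratio <` `blur_ratio_cutoff`
(default 0.5) are excluded from aggregation. The cutoff is a repository
default — the source protocol states the criterion but not its numeric
value — and measured separation on synthetic scenes is wide (sharp
0.75–1.0 versus ≤ 0.25 at σ = 4 px defocus), so the conclusion is robust
over a broad range of cutoffs. A ROI with nothing detected at the coarse
pass has an undefined ratio and fails QC with a logged reason.

# Synthetic micrographs with ground truth

No deposited micrographs exist, so validation rests on a generator
(`generate_fiber_scene()`) that emulates the detector-facing statistics
of the data: thin, elongated, tortuous brown structures on a bright
background, occasional large dark blots, sensor noise, and optional
defocus.

Fibers are rendered as persistent random walks: unit-length steps whose
heading accumulates von Mises innovations (dispersion `tortuosity`,
default 0.25 rad), stamped with a disk of the fiber's width (1–3 px,
sampled per fiber). Walks are added — and the last one truncated at pixel
granularity — until the stamped mask reaches `target_density` exactly, so
the ground-truth density is known to one pixel. Stains are stamped first
and fibers drawn on top; the truth mask records exactly the rendered
fiber pixels before noise. Additive Gaussian noise (SD 5 grey levels) and
sparse dark impulses (fraction 5 × 10⁻⁴) follow, then optional Gaussian
defocus, then 8-bit quantization. Everything is a pure function of the
seed.

Default fiber color is light brown (R 200, G 170, B 140) on background
(230, 225, 220), giving a combined-plane contrast of ≈ 59 grey levels.
This models the partial-volume appearance of sub-micron axons sampled at
0.227 µm/px — a fine fiber never fills a pixel, so its recorded color is
a mixture of stain and background, far lighter than the saturated brown
of a dense varicosity. The operating point matters: at this contrast the
fixed threshold detects sharp fibers with a wide margin while σ ≥ 4 px
defocus drops the fine-pass response below threshold, which is the regime
in which a dual-scale focus criterion is informative. With a much darker
color (saturated DAB, contrast ≈ 116) even strongly defocused 3-px fibers
stay above threshold at both scales and no threshold-based focus
criterion can work; the color is configurable for exploring that regime.

What the generator does *not* model: realistic optics (a single Gaussian
stands in for the defocus PSF), stain-intensity variation along fibers,
varicosities, crossing-density correlations, chromatic effects, and
section-to-section registration. Passing tests therefore demonstrate
correctness of the algorithmic chain and its discriminative behavior
under controlled conditions, not performance on any particular real
tissue batch.

## Behavioral generator

`generate_behavior_table()` emulates outcome-devaluation test tables: a
mixed factorial design (between: e.g. group Pre/Post × treatment
CTL/SAP; within: devaluation Ndev/Dev) with Gaussian responses —
baseline + subject random effect + cell effect + residual — matching the
assumptions of the contrast analysis. A devaluation effect (reduction of
responding on the devalued lever) can be confined to designated cells to
produce interaction patterns. Defaults: baseline 10 presses/min, subject
SD 2, residual SD 2.5 — rates and spreads typical of rat lever-press
tests. Negative draws are truncated at zero (≈ 0.1% of values at the
defaults) and counted. `simulate_training_session()` is the point-process
companion for acquisition structure: Poisson pressing thinned by the
random-ratio probability (1, 1/5, 1/10, 1/20), two presentations per
lever, each capped at 10 min or 20 outcomes.

# Planned orthogonal contrasts

All comparisons use planned one-degree-of-freedom contrasts in mixed
(between × within) factorial designs, controlling the **per-contrast**
error rate at α = 0.05 with no familywise correction — a deliberate
choice, standard in this literature but different from omnibus-ANOVA
practice, and worth keeping in mind when reading reports with many lines.

For 2-level factors, `build_contrast_set()` codes each factor −1/+1 and
forms all 2^k − 1 products (main effects and interactions), pairwise
orthogonal under equal-n weighting. `test_contrast()` uses the univariate
contrast-score approach: within-subject weights collapse each subject's
responses to one score; the between-subject weighted combination of cell
means of scores is tested against the pooled within-cell variance of the
scores with df₂ = N − (number of between cells). Pure between contrasts
use subject means as scores. With all within factors at 2 levels, every
within contrast has its own single-df error term, so no sphericity
machinery is required. Unbalanced groups are handled by unweighted cell
means: the hypothesis is about cell means, not about a reweighted
average.

Simple effects (`simple_effects()`) decompose a significant interaction
by testing the remaining factor within each level of a conditioning
factor, against the pooled error term of the full design — hence a
constant df₂ across simple effects. Pooling is the convention matching
the reporting style this engine reproduces; a level-specific error term
would be the conservative alternative and can be obtained by subsetting
the table and rebuilding the design. Degenerate situations are loud:
empty cells and singleton cells are errors, a zero error variance yields
F = ∞ (or 0) with a warning, and subjects with incomplete within-subject
data are rejected (the pipeline drops them listwise, with a warning,
before analysis). Trends across ordered sessions are tested with
`linear_trend_contrast()`, the centred-integer-weight single-df reading
of "response increased across days".

Numerical checks: F equals the squared pooled-variance t for two-group
contrasts (10⁻⁸), between-contrast sums of squares partition the
between-cells SS on balanced data (10⁻⁸), the full mixed analysis matches
`aov()` with an `Error(subject/within)` stratum, F is invariant to
shifting and positive scaling of responses, and the per-contrast type-I
error under the null generator sits inside [0.04, 0.06] at 5000
replicates.

# Validation experiments and problem sizes

The test suite and `scripts/acceptance.R` rerun the following
experiments; sizes were chosen so the whole suite completes in minutes on
one core.

- **Operator oracles.** 100 random planes up to 32 × 32: disk median and
  high-pass versus brute-force references, tolerance 10⁻⁶.
- **Offset invariance.** 20 random 48 × 48 micrographs × 5 random global
  offsets: every measurement field identical.
- **Density recovery.** Default 660 × 660 scenes, target densities
  0.005–0.05 (10 levels × 5 seeds): Spearman ρ between true density and
  detected fraction ≥ 0.95 (measured ≈ 0.99). The detected fraction
  underestimates truth (thin fibers are attenuated by the median filter;
  halo pixels are sub-threshold), which is why the estimator is validated
  as a monotone correlate, not an unbiased density estimate — exactly the
  property needed for between-group comparisons.
- **Blur QC.** 20 sharp/defocused (σ = 4 px) pairs of default scenes:
  ratio ordering in 20/20, and classification at the 0.5 cutoff correct
  for all 40 images.
- **End-to-end depletion pattern.** 50 cohorts of 10 + 10 subjects,
  control densities VO 0.05 / LO 0.04 and depleted 0.01 / 0.01, subject
  density CV 5%, one 160 × 160 ROI per subject × region with fiber
  lengths scaled to the frame (12–50 steps, preserving the
  fiber-to-frame proportion of the default scene) and no stain blots. A
  minimum-area-detectable stain (≥ 2000 px) would occupy ~11% of such a
  reduced frame and its high-pass rim would dominate the fiber signal —
  an artifact of the reduced frame, not of the method, since at the
  default 660 × 660 geometry a stain is 0.65% of the ROI; stain handling
  is validated separately at full scale. The expected pattern —
  significant group effect, group × region interaction, and a VO-vs-LO
  simple effect in controls but not depleted animals — must appear in
  ≥ 90% of runs. Note an irreducible ceiling: the depleted group's
  VO-vs-LO simple effect is a true null tested at α = 0.05, so about 5%
  of runs are expected to flag it by chance even with a perfect
  detector.
- **Devaluation power.** Effect confined to control cells, standardized
  d = 1.2 on the devaluation score, 14 subjects/cell, 500 simulations:
  the treatment × devaluation interaction and the control-only simple
  effect must each exceed 0.8 power (measured ≈ 0.99 and ≈ 1).

# Known limitations

- The radius-to-σ mapping of the original macro is unknown; σ = 8/20 px
  is a declared interpretation.
- The stain-exclusion step is the least specified part of the source
  protocol; the connected-component implementation here (median-relative
  cutoff 60, area ≥ 2000 px, dilation 5 px) is a documented
  reconstruction, with every constant configurable.
- The blur-ratio cutoff 0.5 is a repository default, not a published
  value.
- The detected fraction is a monotone proxy for fiber volume, biased low
  for sub-pixel fibers; absolute percentages are comparable only within
  a fixed parameter set and magnification.
- The contrast engine covers 2-level factorial sets plus single-df trend
  contrasts; multi-level within factors with sphericity corrections and
  likelihood-based mixed models are out of scope.
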