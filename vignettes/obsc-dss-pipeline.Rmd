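---
title: "Dose-response modeling and drug sensitivity scoring for brain slice culture assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-response modeling and drug sensitivity scoring for brain slice culture assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obscdss)
```

## The assay and its signals

Organotypic brain slice cultures (OBSCs) are living slices of brain
tissue that host engrafted micro-tumors. A drug-testing experiment
exposes tumor-bearing slices to an increasing dose ladder of one
therapeutic and, in parallel, exposes tumor-free slices to the same
doses. Three image types carry the data: a pre-treatment tumor image
(one mCherry-fluorescent micro-tumor on a dark background), the day-4
tumor image (a six-well plate, two bioluminescent micro-tumors per
slice, one per hemisphere, overlaid on a grayscale brightfield), and the
day-4 toxicity image (the same plate format with diffuse
propidium-iodide fluorescence marking dead cells in each slice).

`obscdss` turns these into control-normalized percent survival per
micro-tumor and per slice, fits dose-response models to both, and
summarizes on-target kill against off-target toxicity as a Drug
Sensitivity Score (DSS) in [−100, 100].

## Image measurement

**Well assignment.** Well positions are fixed by the plate, so the image
is divided into an `n_rows × n_cols` grid of equal cells (default 2 × 3)
and each slice mask is assigned to the cell containing its centroid. A
centroid exactly on a boundary goes to the lower cell index. Within a
well the slice with the smaller centroid row is "top" and is measured
before the bottom one.

**Bisection.** Tumor measurement needs one mask per slice hemisphere.
`bisect_mask()` computes the minimum-area rotated bounding rectangle of
the mask (rotating calipers over the convex hull) and splits the mask by
the line through the rectangle center *perpendicular to its long axis* —
the anatomical midline. The source description of the split line admits
two readings (along or across the box); we chose across, because slices
are elongated and their two engrafted tumors sit on opposite ends of the
long axis. The halves are half-open: pixels exactly on the line go to
the "left" half, so the hemispheres always partition the parent exactly.
Two tie-breaks make the split deterministic: the long-axis direction is
oriented toward positive x (ties toward positive y), and when the
bounding box is square within 2 % (a circular mask has no meaningful
long axis) the long axis is taken as horizontal, giving a vertical
dividing line.

**Triangle thresholding.** Bioluminescent tumor signals are dim spots
against a large dark background, the regime the triangle (Zack)
threshold was designed for. The sample's histogram (256 bins spanning
its range) is drawn; a chord runs from the histogram peak to the
furthest nonzero tail bin; the threshold bin is the one with maximum
perpendicular distance below the chord, offset one bin toward the signal
tail. Because the perpendicular distance is a fixed positive multiple of
the vertical gap below the chord, the implementation maximizes the gap;
a brute-force enumeration of true perpendicular distances is kept as an
independent oracle in the test suite and must agree bin-for-bin.
Distance ties resolve toward the peak. A constant sample returns its
value with a `degenerate` flag.

**Statistics.** The tumor statistic is the *sum* of signal pixels above
the within-hemisphere threshold — integrated photon flux, proportional
to surviving cells; the toxicity statistic is the *mean* PI fluorescence
under the whole mask. Signal-free hemispheres are not special-cased:
thresholding simply measures the background, which is the desired
behavior for fully killed tumors (and exactly 0 on a noiseless
background). Degenerate inputs (blank or constant regions) return
flagged zero measurements rather than raising, so a whole-plate run
never aborts on one empty hemisphere.

**Segmentation fallback.** Production masks come from an external ML
segmentation service and enter through `ingest_masks()`, which preserves
labels verbatim. `segment_slices_fallback()` is a classical stand-in —
Gaussian smoothing, Otsu threshold, hole filling, size filter, and a
distance-map watershed to split touching slices — whose adequacy is
defined only against the synthetic plates (per-slice IoU ≥ 0.9 in the
suite, ≥ 0.8 for touching pairs).

## Survival normalization

Tumor assays carry a negative control (dose 0): each signal is divided
by the negative-control mean, so that group's mean survival is exactly
100 %. Toxicity assays also carry a positive control (fully killed
slices): the negative mean is subtracted from every fluorescence value,
the result divided by the post-subtraction positive mean, giving percent
killing; survival is 100 minus that. The map is affine, so survival is
invariant to any additive fluorescence offset. Survival is *stored* in
percent (the assay's interchange unit) and *modeled* as a fraction,
matching the parameter boxes below (the dose-0 asymptote is fixed at 1).

An optional per-tumor baseline mode divides each day-4 signal by the
matching day-1 signal before control normalization. It is off by
default: the standard normalization uses day-4 signals only, and the
role of the day-1 image in the survival formula is not written down, so
the package treats it as an auxiliary covariate rather than silently
changing the estimand.

## The model zoo

All curves are survival fractions of dose `x ≥ 0`; `b` is a slope, `c`
the lower asymptote, `d` the dose-0 asymptote, `e` a scale, `f` a
hormesis coefficient:

| family | curve | free parameters (box) | fixed |
|---|---|---|---|
| LL.4 | `c + (d−c)/(1+exp(b(ln x − ln e)))` | b (1, ∞), c (0, 1), e (0.0001, ∞) | d = 1 |
| W1.4 | `c + (d−c)·exp(−exp(b(ln x − ln e)))` | b (1, 50), c (0, 1), e (0.0001, ∞) | d = 1 |
| W2.4 | `c + (d−c)·(1 − exp(−exp(b(ln x − ln e))))` | b (−50, −0.3), c (0, 1), e (0.0001, 10000) | d = 1 |
| EXD.3 | `c + (d−c)·exp(−x/e)` | c (0, ∞), e (0.0001, 10000) | d = 1 |
| CRS.4a/b/c | `c + (d−c+f·exp(−1/x^α))/(1+exp(b(ln x − ln e)))` | b (1, 250), d (0.95, 1.05), e (1e−6, ∞), f (−∞, ∞) | α = 1 / 0.5 / 0.25, c = 0 |
| CRS.5a/b | same | b (1, 250), c (0, 10), d (0.95, 1.05), e (1e−6, ∞), f (−10, ∞) | α = 1 / 0.5 |
| BC.5 | `c + (d−c+f·x)/(1+exp(b(ln x − ln e)))` | b (1, ∞), c (0, ∞), e (0, ∞), f (1e−6, ∞) | d = 1 |
| RBC.5 | BC.5 with `e = e*(b, c, d, f, M)` | b (1, 50), c (0, ∞), f (1e−6, ∞) | d = 1, M from data |

Open bounds are implemented as the closed box `[a + 1e−9, 1e9]` for the
optimizer. Negative `f` in the CRS families deliberately admits
two-stage (biphasic) shapes. Every family evaluates to `d` at dose 0
within 1e−6 and stays finite far beyond the tested range; both are
property-tested.

**RBC.5.** Brain–Cousens controls the hormesis peak only indirectly, so
the reparametrized form replaces the scale `e` by the peak dose `M`.
Setting the BC.5 derivative to zero at `x = M` and solving for `e` gives
a closed form: with `t = f·M / (b(d − c + f·M) − f·M)`,
`e* = M / t^(1/b)`. For `b > 1`, `f > 0`, `d > c` the denominator is
always positive, so the peak exists throughout the optimizer's box; the
reconstruction is verified by a finite-difference stationarity test
(derivative at `M` below 1e−6 across the box) rather than trusted from
algebra. `M` is *fixed*, not merely initialized, at the nonzero dose
with the highest mean survival (ties toward the smaller dose): this is
deterministic and pins the fitted peak to the observed one instead of
letting the optimizer overshoot it.

**Starters.** Fitting quality hinges on start values. Sigmoids start at
`b = ±2`, `c` at the smallest group mean (clamped into its box) and `e`
where the interpolated group means cross halfway between 1 and `c`.
EXD.3 uses a dedicated self-starter: `e0` is the dose where the
interpolated means cross `c0 + (1 − c0)·e^(−1)` — the level an
exponential decay reaches at one time constant — falling back to the
maximum dose when the means never get there. Hormesis families start
`f` from the observed peak excess over 1.

## Categorization, fitting and selection

**Categories.** Experiments are heuristically sorted by their dose-group
means: *Growth* if any mean is at or above 110 % survival; otherwise
*Plateau* if at least three consecutive groups change by less than 15 %
between neighbours, that run is entered by a change above 15 %, and is
either exited by another such change or runs to the end of the ladder;
otherwise *Decreasing*. Decreasing data are offered LL.4, W1.4, W2.4 and
EXD.3; Plateau adds the five CRS variants; Growth further adds BC.5 and
RBC.5. Requiring the *entry* flank matters: a plateau is a flat region
separating (or stalling) killing, and without that requirement the flat
control-adjacent region at the start of every sigmoid ladder would count
as a plateau, offering two-stage CRS shapes to plainly monotone data —
in simulation this measurably degrades curve recovery, because the
flexible shapes can dip inside unsampled dose gaps. The exit flank is
not required at the top of the ladder, where a response may genuinely
stall. All thresholds are configurable (`heuristic_thresholds()`), with
the printed values as defaults.

**Fitting.** Each candidate is fitted to the replicate points (never to
group means) by Levenberg–Marquardt least squares inside the family's
box, with 5 starts: the self-starter plus four seeded 10 %
multiplicative jitters. Fixed parameters never enter the optimizer. A
family with more free parameters than distinct doses minus one is
rejected outright (identifiability guard). Non-finite predictions
(e.g. a parameter region where RBC.5 has no peak) incur a large residual
penalty so the optimizer retreats instead of crashing.

**Fit statistics.** AIC uses the profile Gaussian likelihood with
estimated variance, `AIC = n(ln(2π·RSS/n) + 1) + 2(p + 1)`; the
convention is documented because the selection criterion below branches
on its sign. RSS numerically zero maps to −∞ — a perfect fit wins any
comparison, and is flagged. Lack of fit is the F-test of the parametric
model against the saturated cell-means model,
`F = [(RSS_m − RSS_sat)/(k − p)] / [RSS_sat/(n − k)]`, reported as the
upper-tail p-value; it needs replication and otherwise degrades the
criterion to AIC alone, flagged.

**Selection.** Candidates are ranked by the combined criterion
`CC = AIC/LoF` for positive AIC and `CC = AIC·LoF` for negative AIC
(lower is better; either branch rewards a more negative AIC and a
lack-of-fit nearer 1; at `AIC = 0` both branches give 0, and `LoF = 0`
with positive AIC is +∞). Ties break by fewer free parameters, then
registry order. The ranked fits then pass a plausibility screen on a
1000-point grid over the tested dose range: no prediction above 1.1 ×
the highest observed group mean, none below the lowest mean − 50 %. The
grid is confined to `[0, max dose]` — the screen judges interpolation,
not extrapolation. The best-ranked plausible fit is returned; if none is
plausible the best-ranked fit is returned flagged, with a warning —
the pipeline never silently fails.

## The Drug Sensitivity Score

Eleven windows, each in [−1, 1] (positive = more tumor-selective), are
computed from the fitted pair and the replicate data, then combined as
`DSS = Σ weight_i · window_i`:

* **EDxx (xx = 10, 25, 50, 75, 90).** The tumor's effective dose is the
  smallest dose where the fitted tumor curve predicts xx % killing
  (grid-bracketed bisection). If the slice curve predicts over 100 %
  survival there, the window is 1; otherwise with tumor kill `TK = xx`
  and slice kill `OK`, it is `(TK−OK)/TK` when `OK < TK`, else
  `(TK−OK)/OK`. If the tumor never reaches the level in range the window
  is undefined and contributes 0 points, flagged — the incomplete-kill
  window already penalizes that situation, and a −1 here would count it
  twice.
* **AUC.** Adaptive quadrature of both curves over `[0, max dose]`;
  `(AUC_O − AUC_T)/max(AUC_O, AUC_T)` in sign-symmetric form.
* **TGA.** Maximum predicted tumor survival in range: above 150 % → −1,
  above 125 % → 0, else 1.
* **IK.** Predicted tumor survival at the top dose: above 25 % → −1,
  above 10 % → 0, else 1.
* **MK.** Tumor and slice kill at the top dose, compared like the EDxx
  gap; clamped to [−1, 1] when a kill is negative (growth at the top
  dose).
* **BP.** One-way ANOVA across the three highest tumor dose groups at
  α = 0.05: significant separation (the response is still moving) → 1,
  else −1. The assay description names no test; an omnibus one-way
  ANOVA is the conventional first choice for "are these groups
  different", and α is configurable.
* **Slope.** Absolute curve slopes by central finite difference (step
  `1e−4 × max dose`) at the tumor's ED50, or at the top dose when ED50
  is undefined; both magnitudes below 1e−6 (both responses flat) → 0,
  else the same sign-symmetric gap.

TGA and IK read the *fitted* curve rather than raw group means — the
hormesis families exist precisely to represent the growth peak — with a
configuration switch to observed means. No window extrapolates beyond
the tested dose range.

**Weights.** AUC 35; MK, IK and ED50 10 each; BP and the other EDxx 5
each are the platform's standard values; the TGA and Slope weights are not printed
individually, but the stated score range of ±100 pins their sum to 10,
and no stated rationale ranks one above the other, so the package
assigns 5 each: `35 + 3·10 + 5·5 + 5 + 5 = 100` exactly. Undefined
windows contribute 0 and are listed in the result; the waterfall
decomposition (`dss_waterfall()`, `plot()`) itemizes every
contribution.

## The synthetic-data generator

`generate_plate_image()` emulates the assay's plate images: a 2 × 3 well
grid (480 × 720 px by default), two elliptical slices per well
(semi-axes 55 × 35 px, jittered placement and orientation, rejection
sampling with a 100-retry cap that fails loudly rather than permitting
overlap), brightfield background at level 100 with slices at +80,
optional bright reflection arcs hugging the well walls (to exercise the
fallback segmenter), focal Gaussian tumor spots with exact integrated
intensities placed per hemisphere (spanning the assay's 100-fold dynamic
range), diffuse per-slice death-marker fluorescence, and Gaussian pixel
noise (SD 1 by default). Ground truth is exhaustive: the label image,
per-hemisphere integrated intensities, per-slice means, and the
noiseless channels, so every measurement has a direct summation oracle.
All randomness flows from one integer seed through R's default
Mersenne–Twister generator; identical seeds give bit-identical output.

`simulate_dose_response()` draws replicate survival values as a registry
curve plus Gaussian noise on the fraction scale. Defaults — 4 replicates
per dose, noise SD 0.02 — reflect the assay's design of four
micro-tumors (two slices × two hemispheres) per dose group and the
replicate scatter visible in well-behaved experiments.

What the generator does *not* emulate: tissue texture, uneven
illumination, optical blur between wells, non-Gaussian photon noise, or
segmentation errors in the external masks. Passing tests therefore
demonstrate correctness of the measurement and modeling logic under
controlled conditions, not robustness to real-world image artifacts —
the fallback segmenter in particular is validated only against these
synthetic plates.

## Validation sizes and known limitations

The test suite runs entirely on generated data: plates at 480 × 720 px,
dose-response fits on 4 replicates × 5–6 doses, and a curve-recovery
suite of 20 seeded repetitions per registry family at noise SD 0.02 on
six-dose half-log ladders, checking the selected curve against the
generating one on a fine grid over the tested range.

Two limitations are worth knowing. First, the combined criterion judges
fit to *observed* doses; families that differ mainly inside unsampled
dose gaps — notably the CRS siblings with different fixed `alpha`, whose
shapes diverge only at doses below the first tested concentration — are
observationally equivalent there, and the selected sibling's curve can
deviate from the generating one inside such a gap. This is a property of
any selection procedure under that design, not of the implementation;
denser low-dose ladders resolve it. Second, the plausibility screen
deliberately tolerates excursions down to the lowest observed mean
− 50 %, so a selected two-stage shape may dip inside a wide unsampled
gap between high doses; the candidate ranking table returned with every
selection makes such choices auditable.
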