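---
title: "Methods: motility counting, sperm-function assays and method-comparison statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motility counting, sperm-function assays and method-comparison statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermfx)
```

spermfx is a desk-scale re-implementation of the image-analysis and
statistics pipeline behind automated smartphone semen analyzers. This
vignette is the package's account of the science: the models, the tunables
and why their defaults are what they are, what the synthetic benchmark
scenes do and do not emulate, and where the open design choices were made.

## Motile-sperm counting

### The background-subtraction model

Each pixel's intensity history is modelled as a mixture of `K` Gaussians
(the Stauffer–Grimson formulation). On every frame the best-fitting
component within `match_sigmas` standard deviations of the observation is
moved toward it by the learning rate `alpha` (weight, mean and variance);
when no component matches, the lowest-weight component is replaced by a
fresh one centred at the observation with `initial_variance`. Components
are ranked by weight/SD, and the smallest prefix whose cumulative weight
reaches `bg_weight_fraction` is declared background. A pixel whose
intensity matches no background component is foreground — for a semen
field, part of a motile cell. Immotile cells are static intensity and are
absorbed into the background, which is exactly what the differential HBA
measurement needs: the detector responds only to *moving* sperm.

Two numerical choices matter:

* **Adaptive early learning rate.** For the first frames the effective
  rate is raised to `1/t` (`t` = frames seen), so component weights track
  empirical frequencies while the model is young. Without this, pixels
  vacated by a cell that was present in the very first frame keep a
  stale high-weight component for many frames and produce "ghost"
  detections right after burn-in.
* **Variance floor** (9 intensity², i.e. SD 3). Under low sensor noise the
  matched variance would otherwise collapse until ordinary noise excursions
  are flagged foreground.

Per-frame foreground masks get a single 3×3 morphological opening (kills
single-pixel noise), are labelled with 8-connectivity (diagonal contact
does not split a blob), and components outside the size gate
`[min_area_px, max_area_px]` are discarded.

### Tunables

| parameter | default | units | rationale |
|---|---|---|---|
| `K` | 3 | components | standard for quasi-static microscopy backgrounds |
| `alpha` | 0.05 | — | settles in ~1 s of video at 30 fps; slow enough not to absorb moving cells |
| `match_sigmas` | 2.5 | SDs | classic match gate |
| `bg_weight_fraction` | 0.7 | — | tolerates one transient foreground component per pixel |
| `initial_variance` | 225 | intensity² | SD 15, wide enough to capture early fluctuation |
| `burn_in` | 5 | frames | model settles before counting starts |
| size gate | [4, 200] | px | spans a sperm head at the reference magnification; **must be recalibrated per optical setup** |

### Aggregation

The published device description leaves "total number of motile sperm"
unformalized. Here the aggregate `M` is the **mean per-frame gated
component count after burn-in**. The mean is scale-invariant in the HBA
ratio, robust to a single noisy frame, and needs no inter-frame tracking —
consistent with a pipeline that deliberately forgoes object tracking. No
progressivity criterion is applied: the detector counts motile objects,
and anything that moves enough to escape the background model counts.

## HBA scoring

Mature sperm bind hyaluronic-acid-coated glass and stop moving, so the
percent bound is estimated from motile counts in the coated (`m_ha`) and
uncoated (`m_nc`) regions:

$$\text{PercentBound} = \left(1 - \frac{m_{ha}}{m_{nc}}\right)\times 100,$$

clamped to [0, 100]: counting noise can make `m_ha` exceed `m_nc`, and a
negative percent bound is physically meaningless. `m_nc = 0` is reported
as *uncountable*, never as a score. Classification against the clinical
threshold (default 80) puts the threshold value itself on the negative
side: positive means score < threshold. The two videos are treated as
independent fields; the chip regions are physically distinct, so no
registration is attempted.

## DNA-fragmentation scoring

In the sperm chromatin dispersion (halo) assay, sperm with intact DNA
disperse a chromatin halo; fragmented-DNA sperm show little or none. Under
the analyzer's optics a haloed sperm presents as one large connected
region, so the **head-plus-halo area** is the measured quantity — the halo
is never segmented separately.

Segmentation is adaptive local-mean thresholding: a pixel is foreground
when it is more than `offset` below (dark objects) the mean of its
`window`×`window` neighbourhood, computed with edge replication. The
arithmetic box mean is the simplest statistic that responds to sharp
gradients while cancelling slow illumination drifts; a Gaussian-weighted
mean would satisfy the same contract. Defaults: window 51 px (larger than
any head), offset 5 (≈1.7 noise SDs on the reference scenes), sanity
bounds [15, 2000] px (debris below, fused clumps above; touching heads are
excluded only via the upper bound — no watershed splitting is attempted).

Scoring divides heads at the calibrated area threshold `a_star`: strictly
smaller is fragmented; an area exactly at `a_star` is non-fragmented (a
deterministic tie rule, stated once). The score is
`100 · n_fragmented / n_total`, pooled over all images of a sample before
scoring.

**Calibration.** The device was calibrated on prepared samples of known
fragmentation; the calibration objective was not formalized there, so this
package's choice is explicit: over a grid of candidate thresholds (default
integer areas spanning the 5th–95th percentile of pooled observed areas),
minimize the mean absolute error between computed and known scores, ties
broken toward the smaller threshold. Areas are raw pixels; `pixel_scale`
is metadata only, and transferring a calibrated `a_star` across optics is
deliberately unsupported.

## Viability

`compute_viability()` is pure arithmetic with a clinical guard: viability
is `100 · n_live / (n_live + n_dead)`, and totals below the clinical
minimum (200) are flagged `meets_minimum = FALSE` rather than refused —
the toolkit must still score partial fields. `classify_stained_field()`
is an *extension*, not a reproduction of any published automated pipeline:
the reference viability measurements were manual. It segments heads with
both threshold polarities unioned (live heads are bright, eosin-stained
dead heads dark), opens the mask, and classifies a head dead when its mean
interior intensity falls below `stain_cutoff` (default 0.5) of the local
background (median of non-head pixels in the head's bounding box expanded
by 10 px). The default offset for this segmentation is 20 rather than the
halo module's 5: both stains give strong contrast, and unioning two
polarity masks doubles the noise-speckle density a small offset lets
through.

## Method-comparison statistics

The validation statistics follow the conventions of the clinical
method-comparison literature, with the manual measurement as the reference
standard throughout (x-axis, truth labels).

* **OLS** via `lm()`, CIs from the t distribution on n − 2 df,
  R² = 1 − SS_res/SS_tot.
* **Passing–Bablok**: slope = shifted median of all pairwise slopes
  (slopes of exactly −1 discarded, offset K = #{S < −1} restores
  symmetry under method exchange); CI from the rank bounds
  `M1 = round((N − C)/2)`, `M2 = N − M1 + 1` with
  `C = z·sqrt(n(n−1)(2n+5)/18)`; intercept = median(y − b·x), CI
  evaluated at the slope CI bounds. For an even slope count the median is
  the arithmetic mean of the two middle order statistics.
* **Cusum linearity test**: points scored by their side of the fitted line
  (+√(L/l) above, −√(l/L) below, 0 on the line), accumulated in order of
  the projection onto the line (`x + b·y`, monotone-equivalent to
  `y + x/b` for b > 0); the statistic max|cusum|/√(l+L+1) is referred to
  the Kolmogorov–Smirnov distribution (critical value 1.36 at 0.05).
  p-values are descriptive; nothing in the package makes automated
  decisions from them.
* **Bland–Altman**: differences device − reference; bias = mean,
  SD with the n − 1 denominator (matching MedCalc/Prism practice), limits
  of agreement bias ± 1.96·SD as an exact identity. The pairwise mean on
  the x-axis affects plots only.
* **Diagnostics**: positive means score < threshold for both methods;
  sensitivity/specificity/accuracy carry exact Clopper–Pearson CIs
  (Beta-quantile closed form). An empty margin yields `NA` for that
  metric only.
* **ROC AUC**: predictor oriented as 100 − device score; AUC by the
  rank-sum (Mann–Whitney) statistic with ties worth ½; CI by the DeLong
  placement variance, truncated to [0, 1]. DeLong was chosen over
  Hanley–McNeil as the modern default; published AUC CIs computed with an
  unstated method may differ slightly.

## The synthetic benchmark

Every detector is scored against generator-emitted ground truth. All
generators take one explicit seed, use a private RNG stream, and are
bit-reproducible.

* **Motility scenes** (defaults: 480×360 px, 30 frames at 30 fps — one
  second of video, the reference recording length): anti-aliased discs of
  radius 3 px, contrast +80 over background 60, noise SD 2. Motile cells
  follow a persistent random walk (heading perturbed by wrapped-normal
  steps, speed 6 ± 1.5 px/frame, reflective borders), which resembles
  progressive sperm movement and guarantees sustained displacement for the
  background model; immotile cells are static. The frame size keeps
  transient blob merges rare at 30 motile cells; the scene is placed with
  a 4-radius minimum separation.
* **HBA pairs**: the coated-region video re-renders
  `round(n_motile · (1 − bound_fraction))` of the motile cells as motile
  and the bound remainder as immotile, on a fresh seed.
* **Halo fields** (512×512): dark discs on background 200, contrast 60,
  area populations N(40, 8²) and N(140, 8²) px² (≈12 pooled SDs apart),
  linear illumination ramp of 20 peak-to-peak, noise SD 3, non-overlapping
  placement.
* **Viability fields**: bright (215) and dark (45) heads of area ~80 px²
  on background 128, noise SD 3.
* **Paired tables**: latent true values uniform on `value_range`,
  reference = latent + N(0, σ_ref), device = intercept + slope·latent +
  N(0, σ_dev), both clamped to [0, 100].

What the scenes do **not** emulate: flagellar beat and near-boundary
drift, out-of-focus blur and point-spread, overlapping or clumped cells,
stain-intensity variability, debris, and photobleaching. Passing the
recovery suites therefore demonstrates the algorithms' correctness under
controlled conditions, not clinical-grade accuracy on real semen
preparations — the published clinical accuracy figures depend on real
samples and the device optics and are out of desk-scale reach.

### Benchmark problem sizes

The recovery suites use 20 motility scenes spanning 1–30 motile cells,
three HBA pairs at bound fractions {0.1, 0.5, 0.9} with 20 motile cells
each, four halo fields of 100 cells at fragmentation fractions
{10, 30, 50, 80}% (threshold calibrated on two held-out samples at 20%
and 70%), one 100-head viability field, and 100 paired tables of n = 102
(noise SD 3 on both methods) for the Passing–Bablok coverage study. Oracle
equivalence is checked on 100 random tables each for the Passing–Bablok
(n ≤ 10) and AUC (n ≤ 12, tie-rich) brute-force comparisons.

## Degenerate inputs and tie rules (summary)

* `alpha = 0` freezes the background model entirely.
* `m_nc = 0` → *uncountable*, never a score; empty segmentations →
  no-cells errors, never 0%.
* Head area exactly `a_star` → non-fragmented; HBA score exactly at
  threshold → negative; calibration MAE ties → smaller threshold.
* Pairwise slopes exactly −1 are discarded (Passing–Bablok); x-ties
  contribute no slope.
* Clopper–Pearson bounds are exactly 0 at k = 0 and 1 at k = n.

## Known limitations

* No MP4/AVI decoding: videos are multi-frame TIFF stacks or directories
  of numbered image frames, with the frame rate supplied by the caller.
* No object tracking: kinematic parameters (VCL/VSL), concentration in
  cells/mL and morphology grading are out of scope.
* The viability classifier is monochrome-intensity based; colour (pink vs
  white) discrimination is not attempted.
* Calibrated area thresholds do not transfer across optical setups.
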