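---
title: "Counting molecules in TIRF foci: models and methods in smstoich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting molecules in TIRF foci: models and methods in smstoich}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smstoich)
```

## The measurement problem

Total internal reflection fluorescence (TIRF) microscopy excites only
fluorophores within ~100 nm of the coverslip, so surface-captured protein
complexes appear as diffraction-limited spots ("foci") in a time-lapse
movie.  Two questions drive the analysis this package implements:

1. **How many labelled molecules does each focus contain?**  Each
   fluorophore bleaches irreversibly and independently, so a focus's
   intensity trace decays in discrete steps.  The brightness of a single
   dye, calibrated from photobleaching, converts a focus's initial
   intensity into a molecule count (its *stoichiometry*).
2. **Are molecules of two species bound to each other?**  Two-colour
   imaging answers this spatially: a green and a red focus whose centres
   coincide to well within a PSF width are scored *colocalized*.

A companion workflow quantifies immunofluorescence tissue sections:
nuclei are segmented from the DAPI channel, a square region of interest
is drawn around each cell, and between-channel correlation and summed
background-corrected intensities are reported per cell.

Because raw single-molecule movies are large and instrument-specific, the
package ships a synthetic-data generator with complete ground truth; every
stage of the pipeline is validated by parameter recovery against it.

## Image formation model (the simulator)

A spot at sub-pixel position $(x_0, y_0)$ carrying $n_t$ unbleached
fluorophores during frame $t$ contributes an expected count of

$$\mu_{ij}(t) = \lambda + n_t\,\nu
  \left[\Phi\!\left(\tfrac{i+0.5-x_0}{\sigma}\right)-\Phi\!\left(\tfrac{i-0.5-x_0}{\sigma}\right)\right]
  \left[\Phi\!\left(\tfrac{j+0.5-y_0}{\sigma}\right)-\Phi\!\left(\tfrac{j-0.5-y_0}{\sigma}\right)\right]$$

to pixel $(i, j)$, where $\lambda$ is the background rate
(counts/pixel/frame), $\nu$ the photon yield per fluorophore per frame,
and $\sigma$ the PSF width.  The PSF is a symmetric 2-D Gaussian
*integrated over pixel areas*, not point-sampled, so sub-pixel photometry
and localization tests are exact.  Observed counts are
$\mathrm{Poisson}(\mu) + \mathcal{N}(0, \sigma_r^2)$, clipped at zero and
quantized, as a camera would.  Setting `noise = FALSE` returns the
analytic expectation exactly ("expectation mode"), the basis of the
photon-conservation tests.

Bleaching is irreversible binomial thinning: each fluorophore survives a
frame with probability $1-p$, so $\mathbb{E}[n_t] = N(1-p)^t$ — the
closed-form oracle used by the recovery tests.  Blinking, drift, EMCCD
gain and aberrations are deliberately out of scope; passing tests
therefore demonstrate correctness of the estimators under the stated
model, not robustness to those instrument effects.

Key defaults: 100 nm pixels, 50 ms frames, $\sigma = 1.3$ px,
$p = 0.05$/frame, $\lambda = 20$, $\sigma_r = 2$.  The photon yield per
dye depends on laser power and camera gain and cannot be fixed a priori,
so $\nu$ is a free parameter; the default
$\nu = 4000$ puts a single dye at a per-pixel SNR of roughly 4–5 over the
default background, a usable single-dye imaging regime.  Simulations in
the tests place spots on grids with ≥ 20 px spacing so that photometry
ROIs do not overlap.

## Spot detection and photometry

Candidates are 8-neighbourhood local maxima of a Gaussian-smoothed frame
exceeding the frame median plus `candidate_threshold_sigmas` (default 5)
robust standard deviations; maxima within one PSF width merge, keeping
the brighter (ties resolve to the smaller $(y, x)$).

Centroids are refined by **iterative Gaussian masking**: the
background-subtracted ROI is multiplied by a Gaussian mask
(`mask_sigma_px`, default 1.3 px) centred on the current estimate and the
intensity-weighted centroid of the product becomes the next estimate,
until the shift drops below `convergence_tol_px` (0.02 px) or
`max_iterations` (200).  A uniform ROI is flagged degenerate and the seed
returned unchanged.  On noiseless spots the fixed point agrees with a
full least-squares integrated-Gaussian fit to better than 0.05 px RMS.

Photometry uses a square ROI of half-width 8 px (17×17).  The local
background $b$ is the mean of the ROI's 1-px border ring, the focus
intensity $I = \sum (\text{inner ROI} - b)$, and

$$\mathrm{SNR} = \frac{I / n_{\text{inner}}}{\mathrm{sd}(\text{ring})}.$$

The ROI dimension and SNR formula are reconstruction choices (the
original analysis gives only the acceptance value): this per-pixel
definition makes the strict acceptance rule SNR > 0.4 a permissive
criterion consistent with keeping dim single dyes.  A zero-variance ring
yields the sentinel `Inf` when signal is present and 0 otherwise.
Coordinates are 0-based with pixel centres at integers, $x$ = column.

## Tracking

Accepted foci are linked frame-to-frame within `link_radius_px` (5 px);
each frame pair is resolved by the assignment that maximizes the number
of links and, among those, minimizes total displacement (exact
enumeration per connected component, verified against a brute-force
matching oracle).  No gap closing is allowed: immobilized complexes move
little, and bridging a missed detection would corrupt step traces.
Tracks must last strictly longer than 3 frames.

## Photobleaching analysis and stoichiometry

**Chung–Kennedy filtering.**  For each point and window length
$w \in \{2, 4, 8\}$, the filter forms a *past* predictor (mean of the $w$
points before the sample) and a *future* predictor (mean of the $w$
points after it), truncated at the edges.  Each predictor is weighted by
its local mean squared prediction error over its own side, raised to the
power $-2$, normalised to sum to one; predictors with zero local error
are exact and take all the weight.  This averages within plateaus while
switching weight across a step, so noiseless steps pass through
unchanged.  Window sizes and exponent are conventional choices
(configurable); the implementation is locked to an independent
loop-based evaluation of the same formula to $10^{-9}$.

**Step detection** is recursive binary segmentation: each segment is
split at the location maximizing the two-sample Student $t$ statistic
when it exceeds `step_sensitivity` (5); zero-variance splits with unequal
means always split.  Adjacent segments closer than
`step_merge_factor` (2) pooled within-segment standard deviations merge.
Downward transitions become step events.

**Single-dye calibration.**  The characteristic intensity $I_1$ is the
kernel-density mode (robust to double-step contaminants; mean/median
configurable) of candidate single-dye intensities.  Candidates are the
terminal plateau of every track that ends before the movie does — such a
track ends because its last fluorophore bleached, so its final level is
one dye's brightness — plus final step sizes that land at background.
The plateau route matters in practice: a track rarely records its own
final bleach step, because detection fails the moment the spot vanishes.
$I_1$ is estimated per channel and per run.

**Stoichiometry.**  For tracks starting within the first 10 movie frames
(0-based start < 10), an ordinary least-squares line through the first 4
raw trace points, evaluated at the track's first frame, gives the
photobleach-corrected initial intensity $I_0$; over such short horizons
the linear extrapolation is equivalent to a full exponential fit (for a
10 %/frame decay starting at 200 the intercept is 199.04, a 0.5 % error).
The stoichiometry is $S = I_0 / I_1$.  Raw, unfiltered intensities enter
the regression — filtering serves step visualization, and OLS already
averages noise.  Ineligible tracks are excluded with a recorded reason,
never errored.

## Two-colour colocalization

Each focus is modelled as a unit-height symmetric Gaussian of width
`mask_sigma_px`; the *overlap integral* between a green and a red focus
is the normalized cross-correlation

$$O = \frac{2\sigma_A \sigma_B}{\sigma_A^2+\sigma_B^2}
      \exp\!\left(-\frac{d^2}{2(\sigma_A^2+\sigma_B^2)}\right) \in [0, 1],$$

whose closed form is checked against brute-force 2-D numerical
integration.  The functional form is a documented reconstruction — the
original software defines only the name and the cut-off — chosen because
it is dimensionless, symmetric, monotone in $d$, and makes the threshold
interpretable: for equal widths, $O > 0.75$ is exactly
$d < 2\sigma\sqrt{\ln(4/3)} \approx 1.07\,\sigma$.  Widths are fixed at
the configured mask sigma rather than fitted per spot, for stability on
dim foci.

Candidate pairs within $3\sqrt{\sigma_A^2+\sigma_B^2}$ are assigned
one-to-one greedily by descending $O$; pairs with $O$ strictly above 0.75
are colocalized, and the per-field proportion is colocalized green over
all green foci.  Colocalization is evaluated at each track's first
detected frame (later frames are unreliable under bleaching), and both
channels are restricted to tracks starting within the same first-10-frame
window as stoichiometry: this keeps late re-detections of temporarily
lost spots from inflating the denominator.  Stratified stoichiometry
summaries compare colocalized against non-colocalized foci with a
two-sided two-sample Student $t$ test; the zero-variance degenerate case
is flagged and reported as maximally significant (or $p = 1$ for equal
means) rather than erroring.

## Tissue workflow

The nuclei channel is thresholded by Otsu's method — the split of a
256-bin histogram over the data range that maximizes between-class
variance, implemented directly and verified against exhaustive search;
the threshold is invariant (up to binning) under affine intensity
rescaling.  Interior holes are filled first, then 8-connected components
smaller than 50 px (strictly) are removed — so a filled ring counts with
its hole included.  A 100×100 px box centred on each nucleus centroid
(clipped at borders) defines the cell ROI; "bounding box of 100 pixels"
is read as a fixed 100-px square, configurable via `roi_box_px`.  Per
ROI, the package reports the Pearson correlation over all pixels for
every declared channel pair and each channel's summed
background-corrected intensity, $\sum \max(v - b, 0)$, with $b$ the
per-channel histogram mode (the rule behind "background corrected" being
otherwise unspecified).

The tissue simulator renders non-overlapping discs for nuclei and builds
signal channels with a controllable shared component: channel A carries a
standard-normal field $Z$, channel B carries
$\alpha Z + (1-\alpha) Z'$, so the true correlation is
$\alpha/\sqrt{\alpha^2 + (1-\alpha)^2}$ — the analytic target of the
recovery tests.  Real tissue adds structured autofluorescence,
lipofuscin, and touching nuclei (no watershed splitting is attempted);
the simulations validate the measurement chain, not those complications.

## Numerical and reproducibility choices

* All randomness flows from a single integer seed; identical
  configuration and seed reproduce stacks, tables and files byte for
  byte.
* TIFF output quantizes counts to 16-bit unsigned integers
  (integer-valued stacks round-trip losslessly); CSVs have fixed
  headers; the resolved configuration is serialized as YAML beside every
  result set.
* Problem sizes in the test-suite recovery studies — 100 spots per
  fluorophore-count group over 120 frames, 210-spot colocalization
  fields, 200-replicate correlation studies — were chosen as the
  smallest sizes at which the binomial/CI-based acceptance windows are
  statistically meaningful.
* Colocalization recovery fields are simulated without bleaching
  (`bleach_prob = 0`, 6 frames): colocalization is a spatial measurement
  on first detection, and bleaching during a field would remove dim
  partners from the denominator for reasons unrelated to the pairing
  algorithm under test.

## Known limitations

* Step counting assumes monotone, irreversible bleaching; blinking
  fluorophores would be split into separate tracks (no gap closing).
* The SNR definition, overlap-integral form, ROI sizes, Chung–Kennedy
  windows and background rules are principled reconstructions where the
  original analysis is silent; each is configurable, and the defaults are
  the package's own documented choices.
* Stoichiometries near the single-dye level inherit the KDE-mode
  calibration's bandwidth sensitivity; with fewer than four calibration
  candidates the estimator falls back to their mean.
* The tracker's exact assignment enumerates small ambiguous
  neighbourhoods; fields dense enough to create large connected
  ambiguity components fall back to greedy matching.
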