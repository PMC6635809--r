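---
title: "A recurrent proto-object model of border ownership"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A recurrent proto-object model of border ownership}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protobos)
```

## The problem and the model

Assigning each contour in an image to the object on one of its two sides —
border ownership — is a basic step of figure-ground organization.  Neurons
in primate area V2 signal border ownership within tens of milliseconds of
response onset, for both artificial shapes and natural scenes, and do so for
figures much larger than their classical receptive fields.  `protobos`
implements an image-computable recurrent network that reproduces this
behavior with three cell classes:

* **S cells** — oriented, contrast-polarity-sensitive edge detectors
  (odd-symmetric Gabor filters at 8 orientations, 22.5 degrees apart).  At
  each pixel only the strongest orientation is kept, split into a
  light-polarity map `L` and a dark-polarity map `D` by response sign.
* **B cells** — border ownership cells.  Each S cell drives an opponent
  *pair* of B cells with the same orientation preference but opposite
  side-of-figure preferences (16 directed channels x 2 polarities).  Both
  members of a pair receive the same bottom-up input, so at stimulus onset
  their activities are numerically identical and no side is favored.
* **G cells** — grouping cells with annular receptive fields, one
  light-preferring and one dark-preferring population per pyramid level.
  Feedforward, G activity is the half-wave-rectified sum over directed
  channels of the opponent B difference correlated with an oriented annular
  kernel; a strict winner-take-all then silences the weaker polarity at
  every location.  Feedback, each B cell is multiplicatively gated by a
  logistic of annular-weighted G activity — facilitation by same-polarity G
  on its preferred side, suppression by opposite-polarity G on its
  non-preferred side — so its activity always stays between 0 and twice its
  bottom-up input.

All computations run on a five-level image pyramid (downsampling steps of
2).  The feedback drive at level *k* pools G activity from every level
*j >= k*, each coarser correlation result upsampled bilinearly and weighted
by `2^-(j-k)`, which is what lets a small annular kernel assign ownership of
large figures.  One iteration is one feedforward plus one feedback pass; on
the first iteration the opponent-inhibition term in the feedforward sum is
dropped because opponent B pairs are still exactly tied.  Under a latency
mapping of roughly 10 ms per pass, sign stabilization after 2–3 iterations
corresponds to the 20–30 ms delay at which border ownership signals appear
physiologically.

Readout converts the final finest-level B activity to a *border ownership
signal* (BOS): polarities are summed per directed channel
(`B_theta = B_theta,L + B_theta,D`, contrast-invariant), and channels are
summed as planar vectors, each pointing at its preferred figure side
(`theta + pi/2`).  The resultant's magnitude is contour strength; its
direction is a continuous figure-ground label.  Per image, the BOS is
normalized by its maximum, so signed scene-point values lie in `[-1, 1]`,
negative meaning ownership assigned to the wrong side.

Color images additionally run the same circuitry on red-green (`r - g`) and
blue-yellow (`b - (r+g)/2`) opponent channels; the three decoded fields are
fused as a weighted vector sum (defaults 0.8 / 0.1 / 0.1).  Grayscale input
simply zeroes the color fields.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `n_orientations` | 8 | undirected orientation bins on `[0, pi)`; 16 directed B channels |
| `wavelength` | 8 px | Gabor carrier wavelength at the finest level |
| `n_levels`, `factor` | 5, 2 | pyramid depth and downsampling step (octaves); `factor = sqrt(2)` with 10 levels gives a half-octave pyramid |
| `R0` | 2 px | grouping-cell annulus radius; the effective radius doubles per level |
| `support_radius` | `8 * R0` | grouping kernel truncation radius per level (see below) |
| `n_iterations` | 10 | feedforward/feedback passes; squares stabilize in 2–3 |
| `channel_weights` | 0.8, 0.1, 0.1 | luminance / red-green / blue-yellow fusion |
| `window_radius` | 2 px | disc radius of the scene-point readout |

## The grouping kernel and its truncation

The annular kernel for directed orientation `theta` is, in polar
coordinates around the G cell,

`v(r, phi) = exp[(r - R0) cos(phi - theta + pi/2)] / (2 pi I0(r - R0))`,

a von Mises angular profile whose concentration is the radial distance to
the annulus: isotropic with value `1/(2 pi)` on the annulus `r = R0`,
increasingly concentrated into a lobe pointing at `phi = theta - pi/2`
away from it.  Each kernel is divided by its maximum.  Two numerical
choices:

* The angular term is undefined at the kernel origin; the origin takes the
  angular mean `1/(2 pi)`, which preserves the exact point reflection
  between `v_theta` and `v_theta+pi`.
* Along its lobe the raw profile *grows* slowly with radius (the von Mises
  peak sharpens faster than the normalizer decays), so an untruncated
  kernel is dominated by its rim.  We truncate at `support_radius = 8 * R0`
  per level: each G cell is a local annular receptive field, and
  long-range grouping is carried by the coarser pyramid levels, whose
  kernels cover proportionally larger image areas — exactly the role of the
  `2^-(j-k)` cross-scale feedback.  Empirically this matters: with
  image-wide kernels, distant edges outweigh a figure's own border, the
  wrong-polarity grouping population can win the winner-take-all next to an
  off-center figure, and the saturated logistic then silences both members
  of the affected B pairs, leaving boundary segments with no ownership
  signal at all.  With the local default, centered and off-center squares
  are assigned perfectly and the recurrence settles to a fixed point
  (maximum BOS change ~2e-4 by iteration 10 on the 128 x 128 fixture).

Other conventions: correlations use the no-flip (cross-correlation)
operator with zero padding for all grouping computations; the front-end
Gabor filtering instead reflect-pads the image, which makes the response to
a uniform raster exactly zero up to the border and makes contrast inversion
an exact `L`/`D` swap everywhere.  Winner-orientation ties are detected
with a `1e-9` relative tolerance and resolved toward the lowest orientation
index; without the tolerance, exact geometric ties (e.g., square corners)
are broken by femto-scale FFT noise, which destroys the exact symmetry
properties the package tests (contrast-inversion swap, 90-degree
equivariance).  Exact winner-take-all ties between `G_L` and `G_D` zero
both populations — on a perfectly symmetric centered square the mirror
symmetry line is therefore silent, which is why scene points are sampled on
straight edge segments away from symmetry axes, as in physiological
practice.

## What the synthetic data emulate — and what they do not

`make_square_stimulus()` reproduces the standard physiological probe: a
uniform square (side 16–64 px) on a uniform background, gray levels 0.25
and 0.75 so that contrast inversion is exactly `1 - p`.  The ground truth
is geometric: the boundary mask is the square's perimeter, and the
figure-side angle at each perimeter pixel is the inward normal (diagonal at
corners).  Scene points are subsampled along straight edge segments,
excluding corners.  `simulate_cell_responses()` turns any reference BOS
into per-repeat responses of a simulated cell: `gain x reference` plus
i.i.d. Gaussian noise, seeded and bit-reproducible, matching the variance
decomposition (repeatable signal + trial noise) assumed by the
explainable-variance statistic.

Passing on these fixtures demonstrates the mechanism — correct, fast,
scale-robust, contrast-invariant ownership assignment for isolated convex
figures — but not performance on natural scenes: no clutter, occlusion,
texture, curvature, or multiple mutually occluding objects, and simulated
cells are noisy copies of the model itself (so model-cell similarity is
near 1 by construction, unlike the 0.2–0.7 range one gets against real,
heterogeneous neurons).  Benchmarking against human-annotated boundary and
figure-ground datasets is supported through `pr_sweep()`, `pr_aggregate()`
and `fg_accuracy()` but requires those external images and annotations.

## Comparison statistics

* `consistency()` — fraction of scene points with strictly positive signed
  BOS; zeros count as inconsistent (conservative; the readout returns exact
  zeros at silent pixels).  `consistent_cells()` applies the >80%
  physiological screening threshold.
* `cosine_similarity()` — BOS vectors compared without mean-centering
  (Pearson correlation would remove the sign structure that *is* the
  signal).  Means of similarities go through the Fisher z-transform,
  clamped at `|r| = 1 - 1e-6`.
* `bootstrap_mean_difference()` — two-sided test of the difference of
  Fisher-z means under a pooled null (both groups resampled with
  replacement from the pooled values; group sizes preserved).  The paper's
  protocol does not state the resampling scheme; pooled-null resampling is
  the standard exchangeability construction for a difference of means.
* `tost_equivalence()` — two one-sided Welch t tests against the
  `[-0.25, 0.25]` zone of indifference; Welch because the compared groups
  (cell-cell pairs vs model-cell values) differ in size and variance.
  Reported p is the larger of the two; equivalence requires both below
  alpha.
* `explainable_variance_r2()` — least-squares scale from model to
  trial-averaged cell response, then
  `R2 = (sigma_pred^2 - sigma_noise^2/Ns) / (sigma_resp^2 - sigma_noise^2)`.
  `sigma_noise^2` here is the noise variance *of the trial-averaged
  response* (within-point repeat variance divided by the repeat count):
  with that convention the `1/Ns` correction exactly cancels the noise
  absorbed by the fitted scale, and simulation recovers `R2 = 1` without
  bias when the model is the true signal (mean 0.9999, sd 0.0017 over 500
  runs at Ns = 100, 20 repeats).  Using the raw per-repeat variance
  instead makes the denominator inconsistent (it can go negative whenever
  across-point signal variance is modest) and biases the recovery.  The
  statistic is flagged undefined when response variance does not exceed
  noise variance.

## Problem sizes and runtimes

The test suite runs squares at 64 x 64 (4 levels, 6 iterations, ~2 s each)
and one 128 x 128 fixture at full settings (5 levels, 10 iterations, a few
seconds); the statistical simulations use 1000 bootstrap replications at
499 resamples, and 500 R-squared recovery simulations at 100 scene points x
20 repeats.  These sizes were chosen so the whole suite completes in well
under a minute while every check still runs at the regime the property
describes (the 128 fixture for timing, three figure sizes for scale
robustness).

## Known limitations

* The model is deterministic and rate-based: no spiking, no trial-to-trial
  variability, no synchrony.
* Only luminance and two color-opponent channels; no texture, disparity,
  motion, or junction cues.
* Grouping kernels are convexity-biased annuli: thin elongated or strongly
  concave shapes are not represented well by a single G cell (the
  population across positions and scales partially compensates).
* The greedy one-to-one boundary matcher is an approximation to the
  benchmark assignment solver; translated boundaries can leave a few
  endpoint pixels unmatched that an optimal matcher would pair.
* Amplitudes, not just signs, converge on the tested fixtures; but exact
  winner-take-all ties (perfectly symmetric stimuli) remain silent by
  design, and the logistic gate saturates for strongly grouped figures, so
  graded BOS magnitudes are most informative near figure-ground
  boundaries of intermediate support.
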