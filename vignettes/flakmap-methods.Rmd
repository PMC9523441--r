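---
title: "Methods: predicting post-operative corneal curvature after arcuate keratotomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting post-operative corneal curvature after arcuate keratotomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(flakmap)
```

## The problem

Femtosecond laser arcuate keratotomy (FLAK) places one or two arc-shaped
incisions on an 8.0-mm optical zone of the cornea to reduce pre-existing
regular astigmatism, typically alongside cataract surgery. Surgical planning
is still largely nomogram-driven: the surgeon picks an arc length from the
pre-operative cylinder, the patient's age, and experience. The corneal
response, however, is a full two-dimensional reshaping — different zones of
the cornea deform differently — so a planning tool that predicts the entire
post-operative anterior axial-curvature map, rather than a single cylinder
number, is more informative.

`flakmap` implements that pipeline end to end: tomographer-style raw
curvature maps in, a conditional image-to-image model in the middle, and the
standard ophthalmic evaluation stack (simulated keratometry, Alpins vector
analysis, masked image-quality metrics) out. Because no public paired
pre/post-FLAK dataset exists, the package also ships a synthetic cornea and
surgery simulator with analytically known ground truth, so every stage is
testable without patient data.

## Raw maps and the keratometric conversion

The instrument layout modelled is a square lattice of anterior radius-of-
curvature values (mm) covering a disk of 3.5-mm radius around the corneal
apex. Two presets are provided: `141 x 141` at 0.05-mm spacing (default) and
`71 x 71` at 0.1-mm spacing. Both interpretations of the instrument export
are plausible — the matrix size suggests the former, the commonly quoted
0.1-mm step the latter — so the layout is an explicit field of the map
objects and both presets are first-class.

Radii convert to keratometric power through the standard keratometric index:

$$\mathrm{Dpt} = \frac{(1.3375 - 1)\times 1000}{R} = \frac{337.5}{R},$$

with $R$ in mm. This constant is deliberately not configurable; keeping it
fixed makes the conversion and its inverse bit-faithful, which the round-trip
tests assert at $10^{-9}$.

CSV exports vary by locale, so the reader accepts configurable delimiters and
decimal marks, and treats empty cells and `"0"` as invalid-point sentinels
(both occur in real exports). Invalid cells — everything outside the measured
disk, plus dropped points — live in a validity mask carried through every
operation.

## Simulated keratometry

Zone keratometry summarises a power map in a central zone (1, 3 or 5 mm
diameter here) by the flattest and steepest meridian powers. A meridian is a
full diameter through the apex; its power is the area-weighted mean of
bilinearly interpolated samples along the diameter, at half-lattice-step
radial intervals starting one lattice step out from the apex. Two numerical
choices matter:

* **Apex exclusion and area weights.** Bilinear interpolation very close to
  the apex blurs the angular contrast of a toric surface badly (the four
  neighbouring lattice nodes sit at wildly different polar angles), while
  contributing almost no area. Omitting the innermost half-step and weighting
  samples by radius — i.e. true disk averaging — reduces the cylinder error
  on analytic torics from about 0.05 D to below 0.01 D in the 3-mm zone.
* **Sub-degree axis refinement.** The profile is computed at 1-degree steps
  and the steep axis refined by a three-point quadratic fit around the
  argmax, removing grid quantisation; flat K is then re-measured on the
  exactly orthogonal meridian.

A `"ring"` mode (single ring at the zone diameter, SimK-style) is provided
for comparison, since commercial devices differ in which convention they
report; both agree on globally toric surfaces.

## Alpins vector analysis

Astigmatism vectors (magnitude $M$ in diopters, axis $\theta$ in degrees,
ophthalmic convention, $[0, 180)$) add and subtract only in double-angle
space $(M\cos 2\theta, M\sin 2\theta)$. With the surgical target being zero
astigmatism, the package uses the standard constructions:

* TIA (target-induced astigmatism) = pre-operative astigmatism;
* DV (difference vector) = post-operative astigmatism;
* SIA (surgically induced astigmatism) = double-angle difference
  pre $\ominus$ post, i.e. the change actually achieved;
* CI (correction index) = $|SIA| / |TIA|$, above 1 overcorrection, below 1
  undercorrection, undefined (NA, not infinite) when TIA is zero.

The identity $TIA = SIA + DV$ holds exactly in double-angle space by
construction and is asserted for every computed outcome. Axes are
canonicalised to $[0, 180)$ after every operation; a zero-magnitude vector
reports axis 0 by convention.

Cohort agreement between real and model-synthesised outcomes uses Pearson
correlation of magnitudes, the mean absolute difference of magnitudes (MAE),
and a paired two-sided test. The default test is the Wilcoxon signed-rank —
outcome magnitudes are bounded and skewed, so no normality is claimed — with
a paired t-test behind a flag. Because "MAE of SIA" is ambiguous between
magnitude differences and vector-difference norms, both are reported
(`mae` and `mae_vector`).

## Image-quality metrics

MSE, PSNR and SSIM are computed over masked pixels only (the zone disk
intersected with both maps' validity masks), with the masked count as the
denominator. SSIM defaults to a single global statistic — the standard
formula evaluated once from the masked moments, with $c_1 = (0.01\,MAX)^2$,
$c_2 = (0.03\,MAX)^2$ and population variances — because that is the form the
formula defines without a window; a sliding-window mode exists for
cross-checking against common practice. Metrics are computed on normalised
planes with $MAX = 1$ by default; a rendered-raster mode with $MAX = 255$ is
provided, since published PSNR scales depend on this (usually unstated)
choice.

## The synthetic cornea and surgery simulator

The generator's defaults emulate the adult cataract-surgery population with
pre-existing regular astigmatism: spherical-equivalent keratometry
$44 \pm 1.5$ D, cylinder $1.26 \pm 0.53$ D truncated to $[0.25, 2.7]$ D, a
with-the-rule / against-the-rule / oblique axis mixture (weights
0.5/0.35/0.15, angular spread 12 degrees), ages $60 \pm 13$ years truncated
to $[25, 83]$. The power surface is

$$P(r, \theta) = S + \tfrac{M}{2}\cos 2(\theta - \alpha) + \text{low-order
perturbation} + \text{white noise},$$

converted to radii for storage. The toric term's $(M, \alpha)$ is returned as
ground truth, which makes the generator-analyzer closure testable to
hundredths of a diopter.

The surgical response is a **coupling dipole**: the incised meridian flattens
and the orthogonal meridian steepens equally,

$$P_{post} = P_{pre} - s(r)\,\tfrac{M_{SIA}}{2}\cos 2(\theta - \alpha_{cut}),$$

the minimal model consistent with arcuate-keratotomy physiology that keeps
the true SIA analytically known. The effect magnitude is linear in total arc
degrees (0.016 D/degree at the reference age of 60), scaled by about +1% per
year of age — the classic arcuate-keratotomy rule of thumb — with optional
magnitude noise and axis jitter. These coefficients are calibrated so that
simulated SIA averages about 1 D over the supported 25-65-degree arc range,
the scale reported for this procedure; they are stand-ins for a clinical
response model, not clinical claims. The radial profile $s(r)$ rises
quadratically toward the periphery by default (incisions act at the 8-mm
zone) and can be disabled (`c(center = 1, edge = 1)`) for closure testing.

Two planning policies generate datasets: a nomogram-like rule that titrates
total arc to the pre-operative cylinder (paired above 0.9 D, per-arc length
clipped to 25-65 degrees) — the realistic default, reproducing correction
indices near 1 — and a `"uniform"` policy drawing arc lengths uniformly,
which decorrelates the induced effect from the pre-operative cylinder. The
uniform policy is what the learning tests use: under it, simply copying the
pre-operative map gives a post-operative cylinder correlation of only about
0.5, so a model can only do well by actually reading the incision channel.

What the simulator does **not** emulate: corneal biomechanics (no
finite-element response, no depth or diameter dependence), posterior surface,
epithelial remodelling, measurement dropouts, or irregular astigmatism
beyond a smooth low-order perturbation. Passing tests on synthetic data
therefore demonstrate that the pipeline's machinery is correct and that the
model can learn a deterministic surgical mapping at this scale — not that it
predicts real corneal responses.

## Model input encoding

Three channels, in fixed order: (1) the power map normalised to $[0,1]$ over
a fixed 30-60 D window (stored with every model so predictions invert
exactly back to diopters; invalid points are 0), (2) a constant age plane
normalised over 20-90 years, (3) a binary incision plane. The 8.0-mm
incision circle lies outside the 7.0-mm measured disk, so by default the arc
bands are drawn at the outermost valid annulus of the lattice ("edge"
placement) — drawing at the true radius clipped to the lattice would
rasterise to an empty plane and hide the surgery from the model entirely. The
true-radius "clip" mode remains available for lattices large enough to
contain the zone. Band thickness defaults to 0.15 mm, visible to 4x4
convolution kernels without dominating the plane.

## The conditional GAN

The predictor is a pix2pix-style conditional GAN written natively in this
package (im2col-based convolution and transposed convolution with analytic
gradients in C++, verified against finite differences in the test suite):

* **Generator**: U-Net — stride-2 4x4 convolutions with leaky-ReLU down to a
  bottleneck (default depth 4 at a 64-pixel working resolution, channels
  doubling per stage and capped at 8x the base width), instance
  normalisation after every convolution except the first and last,
  transposed-convolution decoding with skip connections. The output head is
  **residual**: the network predicts a tanh-bounded change added to the
  input curvature channel, clipped to $[0,1]$, rather than repainting the
  whole plane. This is the single most important architectural choice here.
  Surgery is a small change to the input map (a few tenths of a diopter in
  normalised units); with a conventional sigmoid head the network spends its
  entire optimisation budget reconstructing the input through the stride-2
  skip bottleneck, and the reconstruction error it converges to is as large
  as the surgical signal itself — the model then learns only the average
  effect. With the residual head reconstruction is free, all capacity goes
  to the deformation, and held-out performance moves from
  indistinguishable-from-copying to near-oracle within a handful of epochs.
  A plain sigmoid head remains available (`residual = FALSE`).
* **Discriminator**: a small patch classifier over (condition, candidate)
  stacks — two stride-2 stages plus a stride-1 head, emitting a grid of
  per-patch logits, with instance normalisation on the middle stage.
* **Objective**: cross-entropy adversarial loss (the log form of the minimax
  game; a least-squares variant is a config flag) plus $\lambda \cdot L_1$
  with $\lambda = 100$, the canonical pix2pix weighting. An
  `adv_weight = 0` ablation trains the same generator purely supervised.
* **Schedule**: per sample, the discriminator is frozen while the generator
  steps and its output enters a buffer pool (capacity 50, random
  replacement); then the generator is frozen while the discriminator trains
  on the real pair and a pool-drawn fake. With pool capacity 1 this
  degenerates to vanilla alternation on the latest fake, which the tests
  assert. Adam at $2\times10^{-4}$, $\beta_1 = 0.5$, batch size 1.
* **Determinism**: every stochastic choice (weight init, shuffling, pool
  replacement) flows through one seed; repeated runs are bit-identical.
  Early stopping watches the held-out L1 with a configurable patience,
  since "trained to equilibrium" is not otherwise a stopping rule.

Lattice inputs are resampled bilinearly to the power-of-two working
resolution and predictions resampled back, then denormalised through the
recorded window and masked with the pre-operative validity mask.

Checkpoints are plain JSON (weights, shapes, config, window), so a trained
model is a portable text artifact.

## Problem sizes and test design

The test and demonstration runs use deliberately modest sizes chosen to keep
the full suite fast while leaving the conclusions unchanged: the coarse
71 x 71 preset for simulated eyes, 200 noise-free training pairs with 50
held-out eyes, a 64-pixel working resolution and 15 epochs for
learning checks, and three fixed seeds with a 2-of-3 success rule for the
stochastic learning criterion. Oracle comparisons (conversion identities,
double-angle arithmetic, metric formulas) run at $10^{-9}$ to $10^{-12}$;
geometry-limited recoveries (zone keratometry on analytic torics, simulator
closure) at 0.03-0.05 D and 1 degree, which is the interpolation floor of
the default lattice. Published correlations from clinical cohorts are not
reproduction targets: they depend on unavailable patient data, and the
learning checks instead assert the scaled-down analogue (correlation above
0.7 between predicted and true held-out 3-mm cylinder on synthetic eyes).

## Known limitations

* The surgical effect model is a calibrated stand-in; its coefficients are
  not fitted to any clinical cohort.
* Learning results at the 64-pixel working resolution do not establish that
  the same architecture suffices at full instrument resolution.
* The incision encoding collapses depth and optical-zone diameter (fixed at
  90% and 8.0 mm in the modelled procedure); predicting across those
  parameters needs additional channels and data.
* Real Scheimpflug exports contain measurement dropouts and irregular
  astigmatism the simulator does not produce; the CSV reader and masks
  handle them, but no learning claim covers them.
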