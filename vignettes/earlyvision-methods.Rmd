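---
title: "Filter-bank models of early vision with a trained linear readout: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filter-bank models of early vision: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(earlyvision)
```

## The question the pipeline asks

How much of a coarse object-recognition task — telling a face-like pattern
from a non-face object — can be solved by a linear readout of the *earliest*
stages of visual processing? `earlyvision` implements four image-computable
encoders that bracket those stages, feeds them composited grayscale stimuli
under controlled nuisance variation, trains a binary linear classifier on
their outputs, and measures cross-validated percent correct and the
sensitivity index d′. On top of that sit simulated lesions: removing
spatial-frequency channels, or units selected by the sign-consistency of
their learned readout weights, and retraining.

## Encoders

All four encoders share one architecture: four spatial-frequency channels
with carrier wavelengths λ ∈ {256, 128, 64, 32} px (one-octave steps), each
tiling a 340 × 340 px canvas convolutionally with a stride of λ/2 and a
square support of round(1.5 λ) px.

* **V1 simple**: oriented Gabor filters, Gaussian envelope SD σ = 0.4 λ,
  four orientations (0° = vertical, 45°, 90°, 135°) and four carrier phases
  (0°, 90°, 180°, 270°), each followed by half-rectification max(0, ·).
  7,088 units on the default canvas (144, 144, 1,024, 5,776 per channel).
* **V1 complex**: the energy-model construction — the four rectified phase
  responses at one (location, λ, θ) are summed, which equals
  |r₀| + |r₉₀| of the two quadrature responses. 1,772 units.
* **V1 linear RF**: the same bank without the rectification; phases 180°
  and 270° are dropped as exact negations of 0°/90°. 3,544 signed units.
* **LGN**: centre-surround difference-of-Gaussians filters, σ_c = λ/12,
  σ_s = 5 σ_c, surround gain 0.2 on unit-integral Gaussians (the
  integrated-sensitivity convention; an amplitude convention would let the
  surround mass dominate and contradict "on-centre"), on- and off-polarity,
  half-rectified. 886 units (18, 18, 128, 722).

**The λ = 256 boundary case.** That channel's support (384 px) exceeds the
340 px canvas, yet the published per-channel count (144 = 3 × 3 × 16) forces
a 3 × 3 grid. The canvas is therefore zero-padded symmetrically so a 3 × 3
grid at stride 128 exists with its centres centred on the canvas — the only
convention consistent with the counts. One visible consequence: padded
placements respond to uniform canvases, because a zero-DC kernel only
integrates to zero over its *full* support. All other channels are tiled
fully inside the canvas, with the grid centred (margins split evenly);
the counts fix only stride and support, not alignment, and centring treats
all channels consistently.

**Normalisation and gain.** Pixels are mapped to [0, 1]; V1 kernels are
mean-subtracted (zero DC, so uniform backgrounds are invisible to valid
placements) and all kernels are scaled to unit L2 norm. A single global
response gain (default 2, identical for every model kind, so model
comparisons are unaffected) multiplies all linear responses. The gain was
calibrated once against the training procedure's own premise: with SGD at
the fixed learning rate 0.01, held-out accuracy should plateau within
roughly 10 epochs of the full protocol. At unit gain the 7,088-weight
readout is still far from converged after 10 epochs, which contradicts that
premise; gain 2 restores it. No per-condition or per-model tuning is
involved.

**Separable correlation.** Responses are computed by an exact joint
separable decomposition: a 2-D Gabor is analytically rank ≤ 2 (rank 3
after DC correction), a DoG is rank 2, and one channel's kernels share
their row space (one Gaussian envelope, a handful of carrier
frequencies), so a common orthonormal basis U of rank ≈ 6 reconstructs
every kernel as K = U B to machine precision (singular values below
1e-13 of the leading one are dropped). The strided correlation then needs
one small matrix product per row offset and one short dot product per
placement and kernel. The result matches direct patch dot products to
better than 1e-10 relative (asserted in the test suite), while keeping
the whole computation cache-resident — under 2 ms per canvas for all four
model kinds together.

**Truncation of the DoG surround.** With support/σ_s = 3.6 for every
channel, the surround Gaussian loses mass to truncation: the
pre-normalisation kernel sum is 1 − 0.2 (2Φ(1.8) − 1)² ≈ 0.828 rather than
the naive 0.8. The tests assert the truncation-corrected value.

## Synthetic stimulus generator

The real face/non-face/scene image sets behind the original analyses are
not distributable, so the package generates synthetic stand-ins that
emulate their *statistics* rather than their appearance:

* **Faces**: a superellipse outline (exponent 3–4.5) whose largest side is
  exactly 246 px on the 256 px canvas, with bilateral dark eye ellipses, a
  mouth bar, a faint nose ridge and smooth shading. Elongation (largest
  bounding-box side ratio) is drawn from a shifted log-normal.
* **Non-faces**: unions of 2–5 random ellipses (or, with probability 0.25,
  a single oval — curated non-face sets deliberately include oval objects),
  rescaled by an occupancy-preserving max-pool so the bounding box is tight
  at 246 px, with a broad elongation distribution and a smooth random
  texture.
* **Scenes**: horizon split + 1/f-spectrum texture + hard-edged patches,
  histogram-equalised to a uniform luminance CDF, at 340 × 340 px. Blurred
  companions halve contrast about each scene's mean and apply a Gaussian
  blur of SD 3 px.

Each stimulus's foreground luminance is standardised to per-stimulus
targets drawn from class distributions (mean ≈ 103, RMS contrast ≈ 41.5 on
the 0–255 scale for faces). Clipping to [0, 255] shrinks the realised SD,
so the affine standardisation is iterated three times. Non-faces are
generated darker on purpose and the *set-level* luminance match then
applies a ≈ 15% multiplicative lift to the non-face class — reproducing the
curation step applied to the real sets — after which class means of
luminance and contrast agree to < 2%.

**A deliberate impossibility.** The target class means (fraction filled
0.56 with elongation 1.66 and a 246 px largest side) cannot hold jointly
*per image*: a tight 246 × (246/1.66) bounding box simply does not contain
0.56 · 256² pixels. They can and do hold as *means* over a negatively
correlated joint distribution — rounder shapes fill more — which is how the
generator realises them. Statistics are computed over foreground
(alpha > 0) pixels; backgrounds of the stimulus files are transparent, so
whole-canvas statistics would be meaningless.

What passing tests on these stimuli do **not** show: anything about real
photographs. The generator has no hair, no illumination structure, no
object categories, and its within-class variability is far smaller than a
photo set's. Claims made on the packaged benchmark are claims about this
artifact's stimuli, not about the original image sets' numbers.

## Composition and nuisances

Every presentation is composed freshly: an isotropic down-scaling factor
u ~ U[scale_min, 1] and a rotation ρ ~ U[−rot_max, +rot_max] are applied to
pixels and alpha about the 256 px canvas centre; the result is placed on a
340 × 340 background at centre + integer jitter drawn from [−42, +42] px
per axis — a bound that exactly exhausts the (340 − 256)/2 margin, so the
foreground never clips. Compositing is plain alpha blending, and
background pixels are conserved wherever alpha = 0.

Numerical choices: scale-then-rotate is implemented as one composed
inverse-mapped bilinear resampling (a single interpolation pass loses less
high-frequency content than two sequential ones; the mapping itself is
identical), with transparent (zero) fill outside the source support; alpha
is treated as fractional coverage downstream. The `scale_min = 1`,
`rot_max = 0` case returns the stimulus bit-exactly.

Eight background kinds are supported: mid gray (128), uniform gray at the
stimulus's mean foreground luminance, full-resolution 1/f noise (mean 128,
RMS 40 — the pink-noise contrast is unstated upstream and full resolution
was adopted; block-pixelated pink noise is the documented alternative
reading), 4 × 4 px pixelated white/binary/image-sampled noise with
origin-aligned blocks, and high-contrast/blurred scenes. Scene backgrounds
are drawn from a pregenerated pool (mirroring a fixed landscape set,
sampled per presentation); noise backgrounds are synthesised fresh per
presentation.

## Readout and training

The readout is a single linear unit: logit = w·f + b, trained with binary
cross-entropy-with-logits loss by SGD (learning rate 0.01, classical
momentum 0.9, batch 64, shuffled), weights initialised Kaiming-uniform
U(±1/√fan_in) — the common default for linear layers; the √6 variant is the
main alternative — and zero bias. Two protocols:

* **fixed** (face/non-face): 10 epochs, 1,500 resamples per class per
  epoch, drawn with replacement and composed freshly, so the model never
  sees the same input twice.
* **earlystop** (gender): up to 40 epochs, 400 resamples per class per
  epoch, a fixed 80 + 80 validation set, stop after 5 consecutive epochs
  without a strict improvement in validation fraction-correct. The
  validation canvases are composed once at training start: a fixed
  validation set makes "failed to improve" well-defined.

Prediction is positive iff the logit exceeds 0; exact ties go to the
negative class. Evaluation resamples the held-out split (1,500 per class
at full scale), composes each draw freshly, and reports percent correct,
hit rate, false-alarm rate and d′ = Z(hit) − Z(fa) with rates clamped to
[0.005, 0.995] and the result clipped to ±5.15, so a symmetric
99.5%-correct classifier sits exactly at the ceiling and antisymmetry is
preserved.

When several model kinds are trained in one run they share the
presentation stream (the Gabor family shares one set of raw quadrature
responses; the DoG kernel rides along as one extra response column), each
kind keeping an independent readout. This is statistically equivalent to
independent streams and several times cheaper. Per-repeat seeding uses
independent sub-streams (split / init / train / eval) derived from
`base_seed + repeat`, making every run bit-for-bit reproducible.

## The packaged benchmark and its problem sizes

`benchmark_config()` freezes the reduced-scale conditions under which the
package's ordering and lesion claims are made: 200 stimuli per class
(pool seed 42), 5 epochs × 300 resamples per class, 300 evaluation
resamples per class, 10 repeats per condition, a 50-scene background pool.
These sizes were chosen once as the smallest configuration at which the
medians are stable enough to support the qualitative claims below; the
full-scale protocol (10 × 1,500, 100 repeats) is available by passing the
default `train_config()` and `n_repeats = 100` to `run_grid()`.

On this benchmark: phase pooling is nearly performance-neutral
(|median(simple) − median(complex)| ≤ 0.05); oriented filters beat
centre-surround filters decisively (simple − lgn > 0.05); removing the
output nonlinearity hurts (simple > linear); and the V1-simple median
degrades monotonically (tolerance 0.02) as the rotation range grows on a
mid-gray background at 50% scaling. The lesion analyses run under the
reference condition (blurred scene, 50% scaling, ±45° rotation): an
identity lesion reproduces the full model bit-for-bit, and keeping only
units whose readout weight sign is identical across all 10 full-model
repeats performs within 0.02 of the full model's median.

## Degenerate inputs, tie-breaks and limitations

* Empty alpha masks raise a classed degenerate-input error in
  `stim_stats()` and stimulus-dependent backgrounds.
* Zero readout weights count as sign-*inconsistent* in consistency
  lesions (the measure-zero case needs an explicit rule).
* Exact logit ties predict the negative class.
* Non-finite training loss raises a classed training error with the
  current weight magnitude in the message.
* The pipeline is grayscale-only, single-scale-hierarchy (no higher
  spatial frequencies — position jitter makes them uninformative), and the
  gender sub-classes are parametric caricatures (brow, eye size, mouth
  thickness), so fine-discrimination results index the generator's effect
  size, not human gender perception.
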