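---
title: "Pixel-wise stain normalization: models, training and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pixel-wise stain normalization: models, training and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stainnorm)
```

## The problem

Histology and cytology slides scanned on different instruments, or stained in
different batches, show systematic color differences that degrade both human
reading and downstream classifiers. Stain normalization maps a *source* image
into the color style of a *target* domain while preserving tissue structure.
This package implements both families of classical normalizers and a compact
learned alternative:

* **Reinhard matching** — match per-channel mean and standard deviation in a
  decorrelated log-LMS "lab" space to those of one reference image.
* **Stain separation** — express each pixel's optical density (OD) as a
  nonnegative combination of stain vectors, estimated either by SVD geometry
  (Macenko) or by sparse non-negative matrix factorization (Vahadane), then
  rescale concentrations to a reference's stain profile.
* **A pixel-wise network** — a stack of 1×1 convolutions (default 3 layers ×
  32 channels, 1,283 parameters) that maps each RGB value independently,
  trained by *distilling* any teacher normalizer: run the teacher over a set
  of source images, treat its outputs as ground truth, and fit the network
  with L1 loss.

The premise of the learned mapper is that a whole-dataset color relationship
can be compressed into a per-pixel color transform. Because every output
pixel depends only on the matching input pixel, the network commutes with
any spatial partition of the image — tiled application to arbitrarily large
slides is bit-exact and seam-free — and its entire behavior can be baked
into a 256³ lookup table once and applied by indexing alone.

## The synthetic benchmark

Real paired data of this kind comes from scanning the same slides twice and
registering the results. Offline, the package substitutes a simulator with a
known ground truth; everything the tests and the acceptance script assert
runs on it.

`simulate_patch()` renders a stained-tissue-like scene under the
Beer–Lambert law: per-pixel stain concentrations \(c \ge 0\) combine through
a stain basis \(S\) (columns = unit OD absorbance vectors; defaults are the
literature hematoxylin ≈ (0.65, 0.70, 0.29) and eosin ≈ (0.07, 0.99, 0.11)
directions) into \(od = S c\), and transmitted intensity is
\(I = 255 \cdot 10^{-od}\). Nuclei are ellipses with a Gaussian concentration
falloff carrying the hematoxylin-like stain; cytoplasm disks carry a lower
eosin-like concentration — enough spatial structure for SSIM to be a
meaningful score. Gaussian intensity noise (sd 3 levels by default) is added
before 8-bit quantization. Default patches are 64×64, the size used by the
distillation benchmark; unit tests use smaller scenes.

The "second scanner" is a parameterized, exactly invertible pixel-wise map
(`domain_shift()`): per-channel gamma on normalized intensity, a
near-identity 3×3 mixing matrix applied in OD space, and range-preserving
per-channel intensity offsets. Defaults (gamma 0.85/1.15/1.05, off-diagonal
mixing ≈ 0.05, offsets +6/−4/+3) produce a visible, nonlinear shift of a few
intensity levels on tissue. The gamma term is deliberate: a purely linear
shift could be matched exactly by global statistics, which would make the
comparison between learned and classical methods vacuous. Two numerical
choices keep the map stably invertible to within quantization (±1–2 levels):
the OD conversion inside the shift uses a dark floor of 16 levels (without
it, one-level quantization near black moves OD by ~0.3 and leaks across
channels through the mixing matrix), and offsets are applied as a shift plus
compensating gain so the pre-quantization map is a bijection of the 8-bit
cube.

`oracle_teacher()` exposes the exact shift as a callable normalizer. It
plays the role that an externally trained image-to-image model plays on real
data, with the advantage that the student's error against the true mapping
is measurable. What the simulator does **not** model: multi-dye cytology
stains, scanner artifacts (bubbles, defocus, dust), spatial resolution
differences, or registration error. Passing tests therefore demonstrate the
algorithmic properties (function recovery, exactness, invariances), not
performance on real slides.

## Training recipe

`distill()`/`train_stainnet()` follow a deliberately plain recipe: SGD on L1
loss in the network's [−1, 1] working range, batch size 10 images, initial
learning rate 0.01 cosine-annealed to exactly 0
(\(lr(e) = 0.005\,(1+\cos(\pi e/E))\)), and selection of the epoch with the
lowest test loss. Momentum and weight decay exist as knobs but default to
off. The L1 subgradient at 0 is taken as 0. Epoch shuffling is seeded, so a
(config, dataset, seed) triple reproduces training bit for bit. Weights are
He-uniform initialized with zero biases.

Because the network is pixel-wise, mini-batches of whole images are just
large batches of pixels; an optional `pixel_subsample` mode trains on random
pixel subsets per image, which leaves the expected gradient unchanged and
cuts cost proportionally.

The benchmark configuration used by `scripts/acceptance.R` and the
acceptance tests is 200 aligned 64×64 pairs (30% held out) and 100 epochs —
sizes chosen so the full benchmark trains in a few CPU minutes while leaving
the student's held-out mean absolute error against the oracle teacher
comfortably under 3 intensity levels. The 300-epoch default in
`train_config()` is the recipe's published operating point and remains the
package default.

When the teacher is *not* pixel-wise (e.g. Reinhard, whose output depends on
each image's own statistics), no pixel map can fit all pairs at once; the
student converges to an averaged color map and the train loss plateaus above
zero. That approximation is inherent to distilling a content-dependent
mapping into a color transform, and a test asserts the plateau exists rather
than pretending the loss vanishes.

## Evaluation protocol

`evaluate_pairs()` scores a normalizer on the test split of a paired
dataset, mirroring the three-column protocol used in this literature:

* `ssim_target`, `psnr_target` — RGB similarity of output vs. the aligned
  target image (style transfer quality);
* `ssim_source` — SSIM between grayscale output and grayscale source
  (structure preservation). Grayscale uses BT.601 luma (0.299, 0.587,
  0.114). Note what this metric cannot see: any channel mixing that
  preserves luma leaves it unchanged, a blindness a test documents.

SSIM uses a 7×7 uniform (unweighted) window, constants
\(C_1 = (0.01 \cdot 255)^2\), \(C_2 = (0.03 \cdot 255)^2\), sample
(n−1) window variances, and the unweighted mean over channels for RGB
input — the common library defaults; window choice shifts third decimals,
so it is fixed here and stated. PSNR is \(10\log_{10}(255^2/\text{MSE})\);
identical images report the `Inf` sentinel and are excluded from mean ± sd
aggregation with a count (`n_psnr_inf`), since averaging infinities is
undefined. Reported spreads are sample (n−1) standard deviations.

## Numerical choices and degenerate inputs

* **Optical density.** \(od = -\log_{10}((I+\varepsilon)/(i_0+\varepsilon))\)
  with \(i_0 = 255\), \(\varepsilon = 1\) for general conversion: the shared
  offset keeps \(od(255) = 0\) exactly and \(od \ge 0\) everywhere. Stain
  separation uses \(\varepsilon = 10^{-6}\) instead, since a one-level
  offset visibly biases tissue OD directions.
* **lab space.** The Reinhard pipeline uses Ruderman's decorrelated log-LMS
  space (RGB→LMS matrix, log10 with +1 offset, fixed orthogonal transform),
  which is what "Lab" means in that method's lineage; CIE L\*a\*b\* is
  available behind `space = "cielab"`.
* **Quantization.** Float→8-bit is round-half-to-even then clip, applied in
  exactly one helper and used everywhere.
* **Macenko.** Tissue = pixels with any OD channel ≥ β = 0.15; stain vectors
  at the 1st/99th percentiles of the projection angle in the top-2 singular
  plane. Percentiles use the inverted-ECDF (type 1) estimator, making the
  estimate exactly invariant under duplication of the pixel multiset.
  Near-white images (fewer than 100 tissue pixels) and effectively rank-1
  pixel clouds (single stain) raise errors rather than returning garbage.
  Columns are ordered hematoxylin-first by larger blue-OD component, ties by
  red.
* **SNMF.** Objective \(\|OD - CS^\top\|_F^2 + \lambda \sum |C|\), \(C \ge 0\),
  unit-norm nonnegative dictionary columns. The concentration step is exact
  nonnegative-lasso coordinate descent iterated to convergence; the
  dictionary step is projected gradient with backtracking, accepted only if
  the full objective does not increase — so the recorded objective sequence
  is monotone by construction, and exhausting the iteration budget flags
  non-convergence with a warning. For K = 2 the dictionary warm-starts from
  the SVD extreme-angle geometry (blank pixels removed first); with a random
  start, alternating descent can settle in the non-identifiable cone wider
  than the data and land a few degrees off the true stain directions.
* **Concentration fitting.** Per-pixel nonnegative least squares with a
  closed form over active sets for K ≤ 2 — never an unconstrained
  pseudo-inverse, which can produce negative concentrations. Robust maxima
  for rescaling are 99th percentiles.
* **Reinhard degeneracies.** A constant reference (zero lab variance) is
  rejected at fit time; a constant source channel falls back to substituting
  the reference mean.
* **Reinhard's fixed point and quantization.** Moment matching is exact
  before quantization. The tests verify it on uniform random images, where
  the only deviation is quantization and all moments are well-scaled. Two
  caveats, both properties of the method rather than the implementation: on
  stained patches, out-of-gamut clipping after statistics transfer biases
  the recovered moments by several percent; and the chroma channel means of
  near-neutral ensembles sit arbitrarily close to zero, so mean agreement is
  scored relative to the channel standard deviation rather than the mean
  itself.
* **Checkpoints and LUTs.** Checkpoints are one JSON header line plus
  little-endian float64 parameter blocks — float64 so the save/load
  round-trip is lossless. The full 256³ LUT (~200 MB in memory, baked in
  chunks along the blue axis) is bit-exact with the forward pass; the
  strided LUT trades exactness for memory and measures its own worst-case
  deviation on 10,000 random colors at bake time, recording it in the
  object.
* **3×3 ablation.** Kernel size 3 (reflection padding, edge not repeated) is
  supported to probe what the 1×1 constraint buys. `smoothing_stainnet()`
  builds an identity-color network whose 3×3 layers are box filters — hidden
  activations are shifted by +1 so the ReLU stays inactive — giving a
  controlled demonstration that each 3×3 layer extends the perturbation
  radius by one pixel and strictly erodes grayscale fidelity on edge
  patterns. Training and LUT baking are restricted to all-1×1 networks.

## Worked example

```{r example, fig.width = 7, fig.height = 3.5}
shift <- domain_shift()
imgs <- lapply(1:30, function(i)
  simulate_patch(scene_config(size = 32, seed = i))$image)
fit <- distill(oracle_teacher(shift), imgs,
               train_config(epochs = 30, seed = 1), channels = 16)
fit
plot(fit)
```

```{r compare}
ds <- make_paired_dataset(20, scene_config(size = 32), shift,
                          test_fraction = 0.3, seed = 2)
ref <- ds$pairs[[1]]$target
compare_methods(ds, c("reinhard", "stainnet"), reference = ref,
                checkpoint = fit)[, 1:6]
```

A production run would use the full recipe (more pairs, larger patches, 100+
epochs, 32 channels) as in `scripts/acceptance.R`, then `bake_lut()` the
model once and stream a whole slide through `normalize_tiled()`.

## Known limitations

* Two-stain separation is the wrong model for multi-dye cytology stains
  (Pap), which is precisely the regime where a learned pixel map is most
  attractive; the baselines here implement the K = 2 case only.
* The learned mapper is a *color* transform: it cannot correct
  content-dependent effects (local contrast differences, focus), and
  distilling a content-dependent teacher yields its color-average.
* Reference selection for the classical methods is left to the user; there
  is no automatic "representative image" picker.
* Large-image support expects plain arrays, tile readers/writers or tiled
  TIFF-like sources; pyramidal proprietary slide containers are out of
  scope.
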