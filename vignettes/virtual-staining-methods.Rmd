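---
title: "Methods: virtual H&E staining of refractive-index volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual H&E staining of refractive-index volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Histopathology reads tissue through hematoxylin and eosin (H&E): hematoxylin
renders nuclei blue-purple, eosin renders cytoplasm and stroma pink. Chemical
staining is destructive, 2-D, and variable between laboratories.
Holotomography measures a label-free alternative — the 3-D refractive-index
(RI) distribution of the specimen (values roughly 1.33–1.60; the mounting
medium here is 1.495) — but pathologists do not read RI maps. `vistain`
implements the computational bridge: a conditional generative adversarial
network (cGAN) that translates RI images into virtual H&E RGB images,
together with every data-preparation and validation stage the translation
needs: all-in-focus compositing, correlation-driven affine registration,
patch curation, overlap tiling/stitching, and 2-D/3-D morphometrics.

Because real paired microscope data cannot ship with a package, a synthetic
phantom generator stands in for tissue. It is first-class, tested code: every
stage of the pipeline is validated against phantoms whose ground truth is
known by construction.

## Models and procedures

### All-in-focus compositing

A focal stack is reduced to one sharp image by scanning a square vignette
(default 100 px, step 10 px) over the field. In each window the slice
maximizing the *normalized variance* — population variance divided by the
mean, the canonical autofocus metric, which the source description names but
does not define — is selected as the best focal plane; ties break toward the
lowest slice index so the result is deterministic. Window selections are
upsampled to pixels by nearest window centre (the window-to-pixel assembly is
unspecified upstream; nearest-neighbour is the simplest deterministic rule,
and its seam artifacts are invisible at phantom scale). Borders where no full
vignette fits inherit the nearest valid window's index rather than shrinking
the output. Because the metric scales linearly under positive rescaling of
the stack, the argmax — and hence the composite — is scale-invariant.

### Registration by correlation loss

Stained brightfield images are aligned onto the label-free frame by
minimizing `1 - PCC` (the Pearson correlation loss) over planar affine
transforms. The upstream system trains a spatial-transformer network to
predict the transform; the objective, not the predictor, is the substance,
so `estimate_affine()` minimizes the identical loss directly: a 3-level
block-mean pyramid, a coarse translation grid scan at the top level, then
Nelder–Mead refinement of the six affine parameters per level. Nelder–Mead
was chosen over gradient descent because the bilinear-warp objective is only
piecewise smooth; the simplex method is robust to its kinks and the problem
is six-dimensional. Out-of-frame pixels are excluded from the loss through
the validity mask `warp_affine()` returns, so border fill never biases the
correlation. RGB inputs are reduced to luminance (0.299 R + 0.587 G +
0.114 B) before scoring, since the label-free reference is single-channel.
A result that fails to improve on the identity baseline is flagged
(`improved = FALSE`) so callers can fall back.

Two-level curation follows the reference workflow: wide-field pairs are
cropped into patches (1024 px at production scale; configurable), each patch
pair optionally re-registered, and a pair is kept iff its PCC is **at or
above** 0.65 — the exclusion rule is strictly "below threshold", so the
boundary value is kept. Curation is a pure filter: kept and excluded patches
partition the input.

### The staining network

The generator is a U-Net-like encoder–decoder with skip connections,
instance normalization, leaky-ReLU activations and a squeeze-excitation
(channel-attention) block per stage; defaults are 12 initial feature maps,
feature multiplier 2, and "8 layers", which this implementation realizes as
4 encoder stages plus 4 decoder convolutions (3 skip-merge blocks and a 1×1
output head). Downsampling happens `n_stages - 1` times, so inputs must be
divisible by `2^(n_stages-1)`. The discriminator is a five-layer strided
PatchGAN (kernel 4, stride 2), conditioned on the RI input by channel
concatenation, leaky ReLU (slope 0.2) on the first four layers, ReLU then
sigmoid on the fifth.

The objective couples an adversarial term with a correlation reconstruction
term: the generator minimizes `E[log(1 - D(x, G(x)))] + lambda * L_pcc(G(x), y)`
with `L_pcc` computed per RGB channel and averaged. `lambda` is not stated
upstream; the default 100 is the conventional reconstruction weight in
conditional image translation and is exposed in `train_config()`. Training
uses Adam at learning rate 1e-4, 40 epochs at batch size 1 (defaults),
photometric augmentation (blur and Gaussian noise on the input RI channel,
brightness shifts), per-epoch validation PCC loss, and early stopping with
patience 5 (the stopping rule is unspecified upstream; patience on the
validation loss is the standard choice). The best-validation checkpoint is
returned. All randomness — initialization, shuffling, augmentation — derives
from one seed, so training is bit-reproducible.

Three numerical choices deserve explanation because the stated architecture
is degenerate in places:

* **Batch norm at batch size 1.** The first and last discriminator layers
  are declared batch-normalized. With a batch of one, batch statistics
  collapse to per-sample spatial statistics — identical to instance norm —
  which erases absolute intensity, and the correlation loss is itself
  invariant to per-channel affine intensity maps, so nothing would anchor
  the output's global colour level. These layers therefore normalize with
  *tracked running statistics* (momentum 0.1, updated from the real-image
  stream, treated as constants in the backward pass), the standard
  frozen-statistics reading of batch norm when per-batch statistics are
  degenerate. This keeps the discriminator sensitive to global intensity. A
  config switch (`norm = "instance"`) reverts to instance norm everywhere.
* **The final ReLU-then-sigmoid.** As stated, the discriminator's last
  activation bounds scores to [0.5, 1). Worse, once the discriminator
  learns to push fake pre-activations negative, the ReLU clips them to
  exactly 0.5 and the generator's adversarial gradient is identically zero
  — the anomaly is implemented as stated (`final_relu = TRUE` default) but
  flagged, and `final_relu = FALSE` drops the ReLU for experiments that
  need a live adversarial signal.
* **Gauge fixing the correlation loss.** Because `L_pcc` is blind to
  per-channel shift and scale, the output head's bias is initialized at the
  inverse tanh of the per-channel mean of the normalized training targets —
  the image-translation analogue of initializing a classifier bias at the
  class-prior log-odds — so the generator starts at the data's global colour
  balance and the adversarial term only has to correct scale and residual
  shift.

Inputs are normalized from the physical window [1.33, 1.60] to [−1, 1]
(the upstream text never states its input scaling; the physical RI range of
mounted tissue motivates the window); RGB targets map linearly to [−1, 1]
and the tanh output back to [0, 255]. Inference tiles each axial slice into
overlapping patches (50% by default), runs the generator patch-wise,
feather-stitches the results, and can mask non-sample pixels (RI within a
tolerance of the mounting-medium value) to white.

### Tiling and stitching

Anchors sit at multiples of `stride = patch_size * (1 - overlap)`, with one
extra edge-flush anchor when the last aligned patch misses the image border
— edges are never padded with invented pixels. Stitching averages the
patches covering each pixel with separable triangular ("feather") weights
that decay linearly to zero at patch borders (floored at a small epsilon so
lone-coverage pixels stay defined) and are renormalized to sum to one per
pixel. Identical patches therefore reconstruct the input exactly; the
upstream workflow used an external mosaicking plugin, but with exactly known
patch positions no correlation-based placement is needed.

### Quantification

* **Band-limit matching** equalizes the resolution of two images before
  comparison: both are low-pass filtered by a radially symmetric response
  (flat to the cutoff, Gaussian rolloff beyond; a cutoff at Nyquist passes
  the whole representable spectrum, including the diagonal corners), then
  the second image is rescaled linearly to the first's mean and standard
  deviation.
* **SSIM** follows the three-channel definition with C1 = 6.5025 and
  C2 = 58.5225, which presuppose the 0–255 scale: per channel and window,
  luminance/contrast/structure terms from population moments; channels are
  averaged first, then windows. Whether the upstream evaluation used sliding
  windows or one window per patch is unknowable from the text; the default
  is uniform 11×11 sliding windows, and `window_size = NULL` evaluates one
  whole-image window so both readings are available.
* **Jaccard** is intersection over union, defined as 1 when both masks are
  empty.
* **2-D region metrics** compute area, centroid, eccentricity and major axis
  from second central moments (the ellipse-of-equal-moments definitions) and
  perimeter from the marching-squares contour at the 0.5 level — the
  anti-aliased digital perimeter, which cuts staircase corners at 45° and is
  less biased than pixel-edge counting. Border-touching regions are counted;
  the upstream counting convention is unstated, and including them keeps the
  rule simplest and reproducible.
* **Axial profiles** aggregate per-slice nucleus count, mean area and mean
  eccentricity, and lumen area/perimeter/major axis, reporting the
  bottom/top lumen-area ratio for each tracked label present in both end
  slices — the readout of a tapering gland.
* **3-D nucleus metrics**: volume is voxel count times the physical voxel
  volume; surface area is a marching-tetrahedra iso-surface at the 0.5 level
  with anisotropic voxel spacing. No 3-D meshing library exists in the R
  dependency stack, so the 6-tetrahedra cube decomposition is implemented in
  the package's compiled code. The binary indicator is pre-smoothed with a
  3×3×3 box filter before meshing: on voxelized spheres the raw binary
  iso-surface overestimates area by ~10–15% (staircase bias), the smoothed
  one is accurate to a few percent. `smooth = FALSE` restores the raw
  surface.

## The phantom generator

`phantom_spec()` describes a synthetic slide or volume: a wobbly-boundary
cytoplasm region, non-overlapping elliptical nuclei (unique labels), an
optional lumen, compartment refractive indices (background 1.495 — the
mounting-medium value, so "non-sample" masking is meaningful — cytoplasm
1.525, nucleus 1.560, all within the display window), a smooth intra-tissue
RI texture (sd 0.003), and additive Gaussian sensor noise (sd 0.004, the
order of a holotomography noise floor). The paired RGB image is a smooth
piecewise-linear forward colour model applied to the *noise-free* RI map:
background → white, cytoplasm → eosin pink, nucleus → hematoxylin purple,
with anchor colours more than 80 RGB units apart so recovering the map from
paired data is well posed. Volumes extrude the cytoplasm, place ellipsoidal
nuclei at distinct axial offsets, and carve a lumen tube whose radius
follows `r(z) = r0 * sqrt(1 - taper * z/(Z-1))`, so the cross-sectional area
shrinks linearly to `1 - taper` of its top value — the designed 40% reduction
emulates a contracting colonic crypt. Defocus stacks blur a sharp texture
with a kernel growing as `blur_rate * |z - z*(y,x)|` around a known focus
surface; misaligned pairs return the exact ground-truth transform for
recovery scoring. Every generator is a pure function of its spec and seed.

What the phantoms do *not* emulate: optical diffraction and the microscope's
transfer function, multiple scattering, stain chemistry variability,
out-of-focus haze between slices, and the texture statistics of real
chromatin. Passing tests on phantoms therefore demonstrate that the
algorithms are implemented correctly and that the training machinery can
recover a known RI→colour mapping — not that the trained network reproduces
chemical H&E on patient tissue.

## Problem sizes and reference experiments

The package's experiments are desk-scale by design; the pipeline is
size-agnostic and production sizes (1024-px patches, 100-px vignettes) are
plain configuration:

* Mapping recovery: 200 paired 64² phantom slides, a reduced generator
  (2 stages, 8 initial features), discriminator base width 8 without the
  final ReLU and with the non-saturating generator loss, 15 epochs, seeds
  1–3. Held-out mean SSIM against the forward-model ground truth exceeds
  0.80 in all seeds (typically ~0.9); the λ = 0 ablation scores strictly
  lower, confirming the correlation term carries the reconstruction.
* Registration recovery: 20 seeded misalignments (rotation ≤ 5°, shifts
  ≤ 20 px, scale 0.95–1.05) of 256² smooth textures; median endpoint error
  below 1 px.
* Morphometrics: a digitized 50×30 ellipse (eccentricity 0.8, area πab), a
  voxelized radius-10 ball (volume within 5%, surface within 10% of closed
  forms), and a 9-slice tapering-lumen volume (bottom/top area ratio
  0.60 ± 0.03).

`scripts/acceptance.R` re-runs all of these from scratch and writes the
numbers as JSON.

## Storage and I/O choices

Multi-page TIFF carries volumes and label masks; PNG is accepted for 2-D
RGB. The available TIFF writer only stores data normalized to [0, 1], so RI
volumes are encoded as 16-bit samples over a fixed physical window
[1.30, 1.65] — a quantization step of ~5×10⁻⁶ RI, far below sensor noise —
and a JSON sidecar (`<path>.json`) carries the metadata (pixel size, z-step,
value kind, window), making reads self-describing and write–read–write
bit-stable. Axes are always `(z, y, x[, channel])` with 0-based pixel
centres and half-open patch windows.

## Known limitations

* The adversarial terms are evaluated at the pre-update discriminator
  (simultaneous updates), which shares the fake-pass activations between
  both players' gradients; the alternating-update variant would cost one
  extra forward pass per iteration and was not observed to differ on
  phantoms.
* `estimate_affine()` assumes the coarse translation scan brackets the true
  shift (±40 px at full resolution by default); larger offsets need an
  `init` transform.
* The discriminator's stated final ReLU is kept as the default despite its
  dead-gradient pathology; experiments that rely on adversarial anchoring
  must drop it.
* Surface areas of very small regions (a few voxels across) are dominated by
  smoothing; use `smooth = FALSE` and interpret with care.
* SSIM windows are uniform (unweighted) rather than Gaussian-weighted; the
  constants presuppose 8-bit scale, so inputs must be 0–255.
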