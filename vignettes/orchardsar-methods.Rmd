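---
title: "Methods: near-field SAR imaging and apple detection at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: near-field SAR imaging and apple detection at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orchardsar)
```

## What the package models

`orchardsar` implements an end-to-end pipeline for detecting apples in
near-field millimeter-wave SAR imagery of orchard scenes. Apples are weak
quasi-point reflectors embedded in strong branch scatter, diffuse foliage
clutter and multiplicative speckle, which makes them a hard target for
ordinary detectors. The package has three layers:

1. a **physical forward model and image formation** chain (echo simulation
   and wavenumber-domain 3D reconstruction),
2. a **synthetic orchard generator** producing labelled SAR-like images
   with controlled statistics, and
3. a **trainable detector** built from dynamic spatial pyramid pooling
   (DSPP), a recursive feature fusion network (RFN), context-aware feature
   enhancement (CAFE) and an anchor-based head with focal loss.

Everything runs on one CPU at desk scale; no GPU, download or external
data is needed.

## Imaging model

A monostatic element at aperture position $(x', y', -R_0)$ illuminates a
scene of point scatterers. With wavenumber $k = 2\pi f / c$ and slant
range $R = \sqrt{(x'-x)^2 + (y'-y)^2 + (R_0+z)^2}$, the baseband echo of a
scene with reflectivity $\sigma(x,y,z)$ is the coherent sum

$$ s(x', y', k) = \sum_n \sigma_n \, e^{-2jkR_n(x',y')} . $$

The continuous scattering integral is discretized as a sum over ideal
point scatterers; no antenna pattern is modelled (the element beamwidth
only bounds the usable scene extent in the generator). The default sweep
is 32--37 GHz with 64 uniform frequency samples, and the default aperture
uses the prototype pitches of 4 mm (horizontal) by 5 mm (vertical).

Reconstruction is the classical range-migration algorithm:

1. unitary 2D FFT over the aperture: $s(k_x, k_y, k)$;
2. matched-filter multiplication by $\exp(+j k_z R_0)$ with
   $k_z = \sqrt{4k^2 - k_x^2 - k_y^2}$, zeroing evanescent samples
   ($4k^2 < k_x^2 + k_y^2$), which carry no propagating energy;
3. Stolt interpolation onto a uniform $k_z$ grid spanning
   $[2k_{\min}, 2k_{\max}]$ -- implemented as 1D linear interpolation in
   $k$ per $(k_x, k_y)$ column, since the required
   $k = \sqrt{k_z^2 + k_x^2 + k_y^2}/2$ lies on the uniform sweep axis
   (a natural cubic spline option is available);
4. unitary 3D inverse FFT, with explicit phase referencing so that voxel
   coordinates are absolute scene coordinates.

### Conventions and numerical choices

* **Phase signs.** The forward kernel is $e^{-2jkR}$ and every
  reconstruction kernel uses the conjugate sign; the pair is pinned down
  by the requirement that a simulated point target focuses at its true
  position, which the test suite checks over randomized positions.
* **$k_z$ scaling.** The two-way propagation factor is carried in the
  dispersion relation ($k_z = 2k$ at broadside), so the $z$ axis needs no
  additional scaling; this too is fixed by round-trip recovery rather
  than by convention.
* **Unitary FFTs** everywhere, so Parseval checks hold to $10^{-9}$
  relative and catch normalization regressions exactly.
* **Zero padding** of the aperture by 2x (default) before the 2D FFT
  reduces wrap-around; the image is cropped back to the physical aperture
  footprint.
* **Range window.** The reconstructed $z$ axis is cropped to a window
  about the scene centre (default $\pm 10$ cm), appropriate for the
  shallow scenes the generator produces.
* A brute-force **back-projection** imager
  ($\hat\sigma(v) = \sum s \, e^{+2jkR(v)}$, no approximations) serves as
  an independent oracle: on small grids the wavenumber image must agree
  with it in peak location and correlate above 0.9 in magnitude.

The range resolution for the 5 GHz sweep is $c/2B \approx 3$ cm; the
cross-range resolution at $R_0 = 0.5$ m with a 26 cm aperture is about
1 cm. One-voxel localization tests are run on grids matched to these
scales (64 x 64 aperture, 64 frequencies); an aperture much smaller than
this (e.g. 16 x 16) has a point-spread function several voxels wide, and
peak localization within one voxel is no longer guaranteed.

## Synthetic orchard scenes

The generator emulates the statistical structure of orchard SAR imagery:

* **apples**: 2--5 per image, each a compact cluster of 1--5 scatterers
  inside a sphere of radius 2.5--4.5 cm, with relative amplitudes in
  0.25--0.5 -- deliberately *below* the branch band (the constructor
  rejects recipes that violate this, preserving the weak-scatterer
  regime);
* **branches**: 2--4 colinear chains of strong scatterers
  (amplitude 0.9--1.6, one point per cm);
* **leaves**: a Poisson field of weak scatterers (600 m$^{-2}$) with
  Rayleigh amplitudes (scale 0.08);
* **occlusion**: 30% of apples get a locally densified leaf pocket;
* **speckle**: multiplicative multi-look intensity speckle,
  Gamma(looks, looks) with unit mean, 4 looks by default.

Rendering has two modes. *Physics* mode runs every scene through the full
echo-simulation + reconstruction + range-projection chain and is used for
small fixture sets. *Fast* mode stamps the measured point-spread function
(obtained once by imaging a unit point target through the physics chain)
at each scatterer and applies speckle; it preserves the amplitude
ordering, blob shapes and clutter statistics at a rendering cost of a few
milliseconds per image, enabling training-scale datasets. Ground-truth
boxes are the projected apple-cluster extents padded by one PSF
half-width. Images are 128 x 128 pixels at 4 mm pitch by default.

What fast mode does *not* emulate: coherent interference between
neighbouring scatterers (its stamping is incoherent), aperture-edge
vignetting, multipath, or the real prototype's beam pattern. Passing
tests on this data therefore demonstrates that the architecture can learn
weak compact targets under clutter and speckle of realistic statistics --
not that it reaches any particular accuracy on real orchard imagery.

## Detector architecture

The detector is written against the package's own reverse-mode automatic
differentiation core (`ag_*` operators); every operator accepts plain
arrays (inference, oracle tests) or graph tensors (training), so the
module code exists once. Feature maps are `H x W x C` arrays.

* **Backbone**: five stride-2 conv blocks (two 3 x 3 convolutions each,
  widths 8/16/24/32/40), giving four scales C2..C5 at strides 4/8/16/32
  -- a deliberately small analogue of the usual four-scale residual
  backbone, sized for CPU training.
* **DSPP** (on C5): pyramid levels partition the map into $R_l \times
  R_l$ near-equal cells (floor/ceil spans, deterministic); cells are
  pooled, scored by a learnable linear map, softmax-normalized into a
  spatial attention grid per level, and the levels are softmax-weighted
  by learnable logits. The literal output is the attention-weighted
  aggregate vector; since detection needs a map, the module also emits an
  `enhanced_map`: the input modulated by the upsampled level-weighted
  attention (rescaled to unit mean) and passed through an
  identity-initialized channel mixing, so training starts from a
  pass-through. Default grids are (1, 2, 4, 6); the desk-scale detector
  uses (1, 2, 4) because its C5 map is only 4 x 4.
* **RFN**: all four scales are resized (bilinear) to the C3 resolution,
  projected to a common width by learnable 1 x 1 transforms, summed
  (single-pass fusion), then refined by a convolutional GRU whose input
  is the fused map: update/reset gates and a tanh candidate. The
  recursion depth is T = 3 by default in the standalone module and T = 2
  inside the desk-scale detector (the second pass already exercises the
  recurrent path; further passes cost linearly). The fusion width is 128
  in the standalone default and 32 in the detector.
* **CAFE**: non-local self-attention at the fused resolution with channel
  reduction $C_r = C/2$, row-stochastic affinity, and a zero-initialized
  output projection so the block starts as the exact identity -- the
  standard stability trick for residual attention blocks.
* **Head**: RetinaNet-style, 9 anchors per position (sizes 16/22/28 px,
  aspect ratios 0.75/1/1.33 -- matched to the 15--30 px apple boxes the
  generator produces), two shared 3 x 3 conv layers, focal classification
  loss ($\alpha = 0.25$, $\gamma = 2$, prior-bias initialization at 1%
  foreground) and smooth-L1 box regression ($\beta = 1/9$). Anchors with
  IoU $\ge 0.5$ against a ground-truth box are positive, $< 0.4$
  negative, in between ignored; each ground-truth box additionally claims
  its best anchor. Inference applies a 0.05 score floor and greedy NMS at
  IoU 0.5.

### Training

Adam (peak learning rate $3 \times 10^{-3}$, 30-step linear warm-up,
cosine decay; momentum SGD and a step schedule are available as
alternatives), batches of 8, gradient averaging within the batch, and
on-the-fly augmentation (random horizontal flip, integer translation up
to $\pm 8$ px with consistent box shifts, additive Gaussian noise up to
0.02). Training aborts with a diagnostic if the loss turns non-finite.
All randomness (initialization, shuffling, augmentation) derives from a
single seed, and repeated runs are bit-identical.

The evaluation protocol is AP at IoU 0.5 with all-point interpolation;
Recall and F1 are reported at the score cut-off that maximizes F1, since
a single operating point must be chosen and the F1-optimal one is the
natural summary of the precision--recall trade-off. Both the matching
and the AP integration are cross-checked against independent brute-force
enumerations in the test suite.

### Ablation protocol and problem sizes

The directional ablation trains the full model and a base model (DSPP,
RFN and CAFE disabled; the base model keeps the backbone, a single-pass
resize-project-sum fusion and the same head) on 200 synthetic 128 x 128
images for 10 epochs each with a fixed seed, then compares AP on 60
held-out images. The check is *directional* -- the full model must reach
AP $\ge$ 50% and must not trail the base model -- because absolute
numbers at this scale (a few thousand optimizer steps, a 60-image test
set) carry sampling noise of several AP points. Unit tests run on smaller
grids (64 px images, 16--32 element apertures) chosen so the whole
default suite finishes in minutes on one CPU; the acceptance-style
checks use the full 64 x 64 x 64 imaging grid and the 260-image detector
protocol above.

## Known limitations

* The fast renderer's incoherent PSF stamping understates interference
  effects between close scatterers; physics mode covers them but is too
  slow for training-scale data.
* The affinity matrix in CAFE is dense ($N^2$ in the number of
  positions); the optional spatial subsampling flag trades context
  resolution for cost on larger maps.
* The detector is single-class by design; the evaluation assumes one
  "apple" category.
* Back-projection is exact but $O(N_{aperture} N_{freq} N_{voxel})$ and
  only practical as a small-grid oracle.
* Reflectivity bands for apples versus foliage are free parameters of the
  generator; no field-measured radar cross sections stand behind the
  defaults, which is why they are surfaced in `orchard_params()`.
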