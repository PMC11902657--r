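# orchardsar

Apple detection in near-field millimeter-wave SAR imagery, end to end and
at desk scale: a physical echo simulator and wavenumber-domain 3D
reconstruction, a statistical orchard-scene generator, and a trainable
convolutional detector — all in R, on one CPU.

## The problem

Optical fruit detection fails in poor light and weather; millimeter-wave
SAR images through both, but apples appear in it as *weak* quasi-point
reflectors buried in strong branch scatter, foliage clutter and speckle.
The package implements both halves of the problem:

**Image formation.** A monostatic planar aperture at `z = -R0` sweeps
32–37 GHz. The echo of a point-scatterer scene is
`s(x',y',k) = Σ σ_n exp(-2jk R_n)` with
`R = sqrt((x'-x)² + (y'-y)² + (R0+z)²)` and `k = 2πf/c`. The scene is
reconstructed by the range-migration algorithm: 2D aperture FFT, matched
filtering with `exp(+j·sqrt(4k² - kx² - ky²)·R0)`, Stolt interpolation of
the spectrum onto a uniform `kz` grid using the dispersion relation
`kx² + ky² + kz² = 4k²`, and a 3D inverse FFT. A brute-force
back-projection imager serves as an independent cross-check.

**Detection.** A compact detector combining dynamic spatial pyramid
pooling (learnable level and cell attention over pooled pyramid cells),
a recursive feature fusion network (ConvGRU-refined multi-scale fusion),
context-aware feature enhancement (non-local self-attention with a
zero-initialized residual projection), and a RetinaNet-style anchor head
trained with focal loss (α = 0.25, γ = 2) and smooth-L1 regression,
evaluated as AP/Recall/F1 at IoU 0.5. Training runs on the package's own
reverse-mode autodiff core — no deep-learning framework required.

## Worked example

Simulate a point target, reconstruct it, and check the focus:

```r
library(orchardsar)

cfg  <- radar_config(n_freq = 32, R0 = 0.5)     # 32-37 GHz sweep
grid <- aperture_grid(nx = 32, ny = 32)         # 4 x 5 mm sampling
echo <- simulate_echo(sar_scene(0.02, -0.03, 0.04), grid, cfg)
vol  <- reconstruct(echo, pad = 2)
peak_voxel(vol)$coords
#>           x           y           z
#>  0.01800000 -0.03250000  0.04356359
```

The target at (2.0, −3.0, 4.0) cm focuses at (1.8, −3.25, 4.4) cm —
within one voxel (4 × 5 × 29 mm) of the truth.

Generate a labelled synthetic orchard dataset, train the detector, and
evaluate it:

```r
op      <- orchard_params(n_images = 260, seed = 11)
samples <- render_orchard_dataset(op, mode = "fast")
train   <- samples[1:200]
test    <- samples[201:260]

model <- fit_detector(train, detector_config(), epochs = 10,
                      lr = 3e-3, warmup = 30, seed = 7)
evaluate_model(model, test)
#> <metrics_report> AP@0.5 63.4%  Recall 55.0%  F1 63.7%  (TP 115 / FP 37 / FN 94)
```

AP is average precision over the ranked detections at IoU ≥ 0.5; Recall
and F1 are reported at the F1-maximizing score cut-off, with the
corresponding true/false positive and false negative counts. On 60
held-out images of weak apples under clutter, speckle and 30% occlusion,
the full model clears 50% AP and outperforms its ablated base (backbone +
plain fusion + head), mirroring the architecture's design intent.

A thin command-line interface wraps the same functions:

```sh
inst/cli/orchardsar gendata  --config ds.yaml   --seed 1
inst/cli/orchardsar train    --config train.yaml --seed 1
inst/cli/orchardsar eval     --config eval.yaml  --seed 1
inst/cli/orchardsar simulate --config sim.yaml   --seed 1
```

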