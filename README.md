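# cavitygraph

Graph-affinity refinement of weakly supervised 3D lung-cavity
segmentations.

## The problem

Lung cavities — gas-filled, thin-walled spaces in lung tissue and a
radiographic hallmark of tuberculosis — are expensive to annotate voxel by
voxel in CT. Weakly supervised segmentation trains from image-level labels
(cavity count and size class) instead, but the class activation maps (CAMs)
a classifier produces localise only the most discriminative core of each
lesion: thresholding them under- or over-segments, and propagation methods
built on low-level pixel similarity fail at wall discontinuities.

`cavitygraph` is an R implementation of a structure-aware refinement chain
for such weak localisations, aimed at methodologists working on weakly
supervised 3D medical segmentation:

1. **Region graph** — 3D SLIC superpixels; nodes carry
   `h⁽⁰⁾ = [f_Enc ⊕ f_app ⊕ f_coord ⊕ a_init]`; edges join face-adjacent
   regions plus k = 10 appearance-space nearest neighbours.
2. **GA-Net** — L = 4 graph-attention layers
   (`α_ij = softmax_j(aᵀ[Wh_i ⊕ Wh_j])`, `h' = ELU(Σ α W h)`) with a
   logistic edge readout `a_opt = σ(Uᵀ[h_u ⊕ h_v])`, trained against soft
   CAM-overlap targets `w = 2⟨p̂₁, p̂₂⟩ / (‖p̂₁‖₁ + ‖p̂₂‖₁ + ε)` with
   `L_struct` (soft-label cross-entropy) + `λ·L_smooth` (Tikhonov anchor to
   the initial cosine affinities). Analytic gradients, AdamW.
3. **Pseudo-labels** — dual thresholds `(φ_l, φ_h) = (0.32, 0.46)` split
   CAM responses into background / foreground / IGNORE; windowed voxel
   cosine affinities are supervised by the focal affinity loss
   `Σ_{K⁺} log(1+e^{−W})/N⁺ + Σ_{K⁻} log(1+e^{W})/N⁻`.
4. **Random-walk refinement** — `T = D⁻¹Wᵉᵗᵃ` (row-stochastic), applied
   region-wise in overlapping 3D blocks and merged with distance weights.
5. **Segmentation training** — smoothed cross-entropy (ε = 0.15) on refined
   pseudo-labels, partial cross-entropy on contour-derived scribbles, and
   EMA prediction ensembling (δ = 0.2, γ = 8); total loss
   `L_cls + λ₁L_struct + λ₂L_smooth + λ₃L_aff + λ₄L_pce + λ₅L_seg` with
   λ = (0.6, 0.5, 0.5, 0.7, 0.5).
6. **Evaluation** — DSC / IoU / 95th-percentile Hausdorff (mm), exact
   paired Wilcoxon signed-rank tests (Pratt zeros), macro classification
   reports, patient-level folds.

A phantom module generates cavity-like volumes (dark ellipsoidal lumen,
bright wall shell, wall gaps), ground-truth masks, image-level classes and
corrupted CAMs, so the whole chain runs without clinical data. Minimal
NIfTI-1 I/O is built in.

## Worked example

```r
library(cavitygraph)

# a phantom with two cavities and an under-segmented CAM
cfg <- phantom_config(shape = c(32, 32, 24), n_cavities = 2,
                      cavity_radius_range = c(3, 5), seed = 1)
ph  <- generate_phantom(cfg)
cam <- corrupt_cam(ph$mask, cam_corruption(keep_fraction = 0.5,
                                           blur_sigma = 1,
                                           leak_sigma = 0.05, seed = 1), 2)

# refine by a region-wise random walk over mask-derived voxel affinities
fe  <- array(2 * (ph$mask > 0) - 1, c(dim(ph$mask), 1))
aff <- voxel_affinity(fe, window_radius = c(2, 2, 2))
ref <- refine_cam(cam, aff, list(eta = 1, block_size = c(16, 16, 16),
                                 overlap_fraction = 0.5))

before <- overlap_metrics(cam[, , , 1] >= 0.46, ph$mask > 0)
after  <- overlap_metrics(ref[, , , 1] >= 0.46, ph$mask > 0)
round(rbind(before, after), 3)
#>        dsc   iou
#> before 0.568 0.397
#> after  0.906 0.828
```

The raw CAM covers only the lesion core (Dice 0.57 against the true mask at
the foreground threshold 0.46); after one random-walk application the
activation has spread through the high-affinity interior and Dice rises to
0.91.

The full pipeline (classifier → graph → GA-Net → seeding → refinement →
scribbles → segmenter with EMA → metrics) runs from a manifest:

```r
m   <- make_fixture_suite(5, "fixtures", seed = 1, shape = c(40, 40, 28))
res <- run_pipeline(m, pipeline_config(n_segments = 50, ganet_dim = 16,
                                       window_radius = c(2, 2, 2),
                                       block_size = c(16, 16, 16), seed = 1),
                    out_dir = "run")
res$metrics       # per-case dsc / iou / hd95
res$decomposition # weighted total-loss components
```

A thin command-line wrapper with `phantom`, `run-all` and `evaluate`
subcommands lives at `inst/cli/cavitygraph.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end pipeline from scratch: it generates a
5-case phantom manifest at the given seed, runs preprocessing, classifier
and CAM extraction, graph construction, affinity training, dual-threshold
seeding, region-wise random-walk refinement, scribble extraction and
EMA-stabilised segmentation training, reports the run's summary metrics on
the console, and writes the JSON report to `--out`.
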