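---
title: "Refining weak lung-cavity segmentations with graph affinities: models and design choices"
author: "cavitygraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining weak lung-cavity segmentations with graph affinities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Lung cavities — gas-filled spaces in lung tissue, a radiographic hallmark of
tuberculosis — are hard to annotate voxel by voxel: they are irregular,
thin-walled, often broken by wall discontinuities or internal septations.
Weakly supervised semantic segmentation (WSSS) sidesteps dense annotation by
training from image-level labels (how many cavities, how large), but the
class activation maps (CAMs) such training produces localise only the most
discriminative core of a lesion: the raw pseudo-labels under- or
over-segment. `cavitygraph` implements a refinement chain that spreads
confident activation along anatomically consistent paths while leaving
unrelated tissue untouched.

## The model

**Region graph.** A 3D SLIC over-segmentation partitions the volume into
superpixels. Nodes carry features
\(h^{(0)} = [f_{\mathrm{Enc}} \oplus f_{\mathrm{app}} \oplus
f_{\mathrm{coord}} \oplus a_{\mathrm{init}}]\): the region-mean encoder
feature, intensity statistics (mean, sd, 10th/90th percentile), the
centroid normalised by the grid shape, and a node-level summary of initial
edge affinities. Edges join face-adjacent regions plus, for each node, its
k nearest neighbours (k = 10 by default) in appearance space — the
long-range edges that let spatially separated but semantically similar
regions (the two rims of a broken cavity wall) communicate.

**Edge inference (GA-Net).** L = 4 attention layers update node features,

\[\alpha_{ij} = \operatorname{softmax}_{j \in \mathcal N(i)}
  \big(a^\top [W h_i \oplus W h_j]\big), \qquad
  h_i' = \sigma\Big(\sum_{j} \alpha_{ij} W h_j\Big),\]

with \(\sigma = \mathrm{ELU}\); the edge posterior is a logistic readout
\(a^{\mathrm{opt}} = \sigma(U^\top[h_u \oplus h_v])\) evaluated in both node
orders. Supervision is the soft Dice overlap of the two regions' mean CAM
class vectors,
\(w = 2\langle \hat p^{(1)}, \hat p^{(2)}\rangle /
(\|\hat p^{(1)}\|_1 + \|\hat p^{(2)}\|_1 + \varepsilon)\),
through a soft-label cross-entropy \(\mathcal L_{\mathrm{struct}}\) (equal
to KL(Bern(w) || Bern(a)) plus the target entropy), plus a Tikhonov anchor
\(\mathcal L_{\mathrm{smooth}} = \sum \omega\,\tfrac12 (a^{\mathrm{opt}} -
a_{\mathrm{init}})^2\) on the initial cosine affinities.

**Pseudo-labels and voxel affinities.** Dual thresholds
\((\varphi_l, \varphi_h) = (0.32, 0.46)\) split CAM responses into reliable
background (max activation \(\le \varphi_l\)), reliable foreground (\(\ge
\varphi_h\), argmax class) and an ignored uncertainty band. Voxel-pair
affinities in a local window (radius (7,7,7) at full scale) are normalised
cosines \((\cos + 1)/2\) of per-voxel feature vectors; pairs of reliably
labelled voxels supervise them through the focal affinity loss
\(\frac1{N^+}\sum_{\mathcal K^+}\log(1+e^{-W}) +
\frac1{N^-}\sum_{\mathcal K^-}\log(1+e^{W})\) on logit affinities.

**Random-walk refinement.** A row-stochastic transition matrix
\(T = D^{-1} W^{\eta}\) (element-wise power; \(\eta\) sharpens the walk)
multiplies the vectorised CAM. Propagation runs in overlapping 3D blocks;
block outputs are merged with weights that taper linearly with distance to
the block centre. Because every row of T is a convex combination, refined
activations obey a per-block maximum principle. An optional preceding stage
diffuses region-mean activations over the trained region graph.

**Segmentation training.** The refined pseudo-labels supervise a segmenter
through a label-smoothing cross-entropy (\(\epsilon = 0.15\)); scribbles
extracted from pseudo-label contours add boundary supervision through a
partial cross-entropy evaluated only on scribbled voxels; per-case
prediction fields are stabilised by EMA ensembling
\(y_n = \delta f + (1-\delta) y_{n-1}\) with \(\delta = 0.2\), refreshed
every \(\gamma = 8\) iterations. The total objective is
\(\mathcal L = \mathcal L_{\mathrm{cls}} + \lambda_1 \mathcal
L_{\mathrm{struct}} + \lambda_2 \mathcal L_{\mathrm{smooth}} + \lambda_3
\mathcal L_{\mathrm{aff}} + \lambda_4 \mathcal L_{\mathrm{pce}} + \lambda_5
\mathcal L_{\mathrm{seg}}\) with weights (0.6, 0.5, 0.5, 0.7, 0.5).

## Parameters that matter

| knob | default | meaning |
|---|---|---|
| `phi_l`, `phi_h` | 0.32, 0.46 | CAM reliability thresholds (unitless activation) |
| `window_radius` | (7,7,7) | voxel-affinity window, voxels (tests use (2,2,2)) |
| `eta` | 1 | walk sharpness; larger = lower-entropy transitions |
| `block_size`, `overlap_fraction` | 32³, 0.5 | region-wise propagation tiling |
| `k` | 10 | kNN long-range edges per node |
| `ganet_layers`, `ganet_dim` | 4, 256 | attention depth and width (tests use d = 16) |
| `delta`, `gamma` | 0.2, 8 | EMA smoothing factor and refresh interval |
| `epsilon` | 0.15 | label smoothing |
| `lambda` | (0.6, 0.5, 0.5, 0.7, 0.5) | loss weights |
| HU window | [−1200, 600] | lung-density clip before [0,1] normalisation |
| spacing | 1 mm isotropic | resampling target; the 25 mm class cut is applied in mm |

## Design choices where the design was open

- **Soft targets.** The hard set-overlap definition of the target affinity
  is vacuous for disjoint superpixels (distinct regions never share
  voxels); the soft Dice form on region-mean CAM vectors is used as
  normative.
- **Symmetric edge readout.** The concatenation readout is order-sensitive.
  We evaluate both orders and average the *posteriors*, not the logits: a
  logit average reduces to a linear function of \(h_u + h_v\), and for two
  symmetric structures the between-structure logit is then exactly the
  mean of the two within-structure logits — ranking within against between
  becomes impossible in principle. Averaging after the sigmoid keeps the
  order-difference component \((U_1 - U_2)^\top (h_u - h_v)\) available.
- **Optimisation scale.** Full-scale training uses AdamW at lr 1e-4 with
  warm-up and cosine decay over many epochs. At desk scale (hundreds of
  full-batch steps on one small graph) that schedule moves parameters by
  ~1e-2 in total and learns nothing; the package default is plain AdamW at
  lr 1e-2 (weight decay 0.05, \(\beta = (0.9, 0.95)\)).
- **\(\omega\) weights.** The smoothness confidence weight is undefined in
  the source method beyond "feature similarity or edge strength"; the
  default is \(\omega = a_{\mathrm{init}}\).
- **Encoder at desk scale.** The deep image encoder is replaced by a fixed
  multi-scale filter bank (raw intensity, Gaussian blurs at 1/2/4 voxels,
  two gradient magnitudes, a local standard deviation); only linear heads
  are trained on top. This keeps every learning contract testable on a CPU
  in seconds. Consequence: classification accuracy reflects global
  intensity statistics, not learned morphology.
- **Merging weights.** \(w_r = \max(0, 1 - \|x - c_r\|_2 / r_{\mathrm{block}})\)
  with \(r_{\mathrm{block}}\) the half block diagonal, so every in-block
  voxel keeps strictly positive weight and single-cover voxels are exact.
- **Numerical guards.** Posteriors are clamped at 1e-7 before logs (logged);
  zero-norm feature vectors receive the uninformative affinity 0.5 (logged);
  a zero affinity row aborts transition-matrix construction with the row
  named; propagated values escaping [0,1] by more than 1e-6 abort the
  refinement (they indicate a non-stochastic transition matrix).
- **Wilcoxon.** Zero differences are handled by the Pratt method (ranked,
  then dropped from the rank sums); p-values are exact by convolution over
  signed midranks up to n = 25 non-zero differences and use a tie-corrected
  normal approximation above. The significance level used in reports is
  0.05.
- **hd95 surfaces** are face-boundary voxels; distances are between voxel
  centres with anisotropic spacing respected; both directions are pooled
  before the 95th percentile. Empty masks are an error, not a sentinel.
- **Ablation switches** (`disable_struct`, `disable_aff`, `disable_smooth`,
  `disable_pce`) zero exactly their own term's weight in the logged
  total-loss decomposition; `disable_struct` trains the edge network on the
  smoothness prior alone. Because the switches alter training, the *values*
  of other components may drift; only the decomposition structure is
  guaranteed.

## The phantom world

The generator emulates the geometry the method targets, not lung anatomy:
ellipsoidal cavities (semi-axes jittered ±30%) with a dark lumen, a bright
wall shell of configurable thickness, and a random angular sector of the
wall removed to mimic wall discontinuities, on a smoothed-noise background
with additive Gaussian intensity noise (sd 0.05). The ground-truth mask is
the full lumen. Image-level classes follow the count x size rubric used for
cavity burden (class 1: none; 2/3: 1–3 cavities below/above 25 mm; 4/5:
more than 3 cavities below/above 25 mm), with diameter measured as the
largest bounding-box extent in mm at the manifest's voxel spacing (1 mm
isotropic by default).

CAM corruption emulates weak-localisation failure: only the
`keep_fraction` most interior lesion voxels (ranked by distance to the
lesion boundary) stay activated, the indicator is blurred, and smoothed
non-negative leak noise is added. With `keep_fraction = 1`, no blur and no
leak the CAM is exactly the mask indicator — the identity contract several
tests rely on.

What a green test does **not** establish: the phantoms have no airway or
vessel structure, no anatomical texture, and no partial-volume effects, so
passing the refinement-gain check demonstrates the mechanism (activation
spreads along high-affinity paths and stops at low-affinity boundaries),
not clinical accuracy. The headline numbers of full-scale clinical studies
are out of reach of this desk-scale artifact by design.

The planted-partition check uses the standard assortative
stochastic-block-model world: 60 nodes in two communities, edge probability
0.25 within and 0.05 between (the classic 5:1 assortative setting), node
features at ±0.5 hypercube community means with sd 0.5 Gaussian noise,
soft targets 0.9 within / 0.1 between.

## Known limitations

- The desk-scale encoder is untrained; CAMs from the classification head
  are weighted sums of generic filter responses. The refinement chain is
  exercised end-to-end with the phantom's corrupted CAMs instead.
- One random-walk application per refinement (the single-step walk); no
  converged diffusion, no CRF post-processing.
- Single-graph training only; no mini-batching across volumes.
- SLIC and the distance transforms are pure R; they are comfortable at test
  scale (up to ~64³) but not tuned for full clinical volumes.
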