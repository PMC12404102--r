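---
title: "Classifying cells from refractive-index point clouds: models, defaults and limitations"
author: "RIPointNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cells from refractive-index point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the data model, the two sampling stages, the network, the training
protocol, the synthetic phantom that stands in for microscope data, and
every numerical choice a maintainer might want to question. Nothing here
reports an empirical number that the test suite or the acceptance script
does not itself compute.

## The problem and the data model

Holographic tomography reconstructs a cell's 3D refractive-index (RI)
distribution: a voxel grid V = {vᵢ = (xᵢ, yᵢ, zᵢ, nᵢ)}, i = 1…N, where nᵢ
is dimensionless RI (≈1.33 for the aqueous medium, up to ≈1.40 for lipid
droplets). Voxel counts per segmented cell run from 5×10⁵ to 4×10⁶ on a
320 × 320 × 210 crop, which makes direct 3D convolutional classification
expensive. The package works instead on an RI point cloud
P = {pⱼ = (xⱼ, yⱼ, zⱼ, nⱼ)}, j = 1…M with M ≪ N: `VoxelVolume` holds V
(with micrometre voxel spacing and 0-based index-times-spacing
coordinates), `RIPointCloud` holds P, and the RI channel always carries
raw physical RI even after coordinates are normalized.

## Segmented equilibrium sampling

A cell's RI histogram is extremely skewed: cytoplasm near 1.335–1.345
outweighs the highest-RI intervals by three to four orders of magnitude,
so uniform random downsampling starves exactly the organelles (nucleoli,
lipid droplets) that carry diagnostic information.
`segmentedEquilibriumSample()` instead:

1. normalizes the RI range — per-cell min–max by default, or the fixed
   physical range [1.33, 1.40] (`riNormalization = "fixed-range"`);
2. partitions it into L equal-width intervals (default L = 6);
3. draws ⌊M/L⌋ points per interval uniformly *without replacement*, with
   the remainder M mod L assigned to the lowest-index intervals;
4. takes everything an underpopulated interval has and draws the deficit
   uniformly from the pooled not-yet-sampled points of the other
   intervals.

The output has exactly M points (default 10,000), all distinct members of
the input. Design points worth stating explicitly, because the procedure
is described only loosely in the literature the package follows:

* **Which normalization?** Whether the interval grid should be per-cell
  or absolute is genuinely open; per-cell is the default as the most
  literal reading of "normalizes the RI range", and the fixed-range mode
  exists for cross-sample comparability when absolute RI matters.
* **Remainder handling.** Quotas of ⌊M/L⌋ with the remainder to the first
  M mod L intervals: deterministic and order-independent.
* **Supplementation.** Uniform over the pooled unsampled points, not
  proportional to interval size; with a heavily skewed source the pool is
  dominated by the low-RI intervals anyway.
* **No replacement, ever.** Requesting M larger than the cloud is an
  error, not silent replacement; the method is a downsampler.

`intervalHistogram()` reports per-interval counts; on segmented output
from a plentiful source the max–min spread is forced to ≤ 1.

## The hybrid selector

Networks want fixed-size inputs. `ripcsSelect()` builds the K-point
training set S = S_FPS ∪ S_RI (default K = 1024 = 800 + 224):

* **Farthest point sampling** (`farthestPointSample()`): greedy max–min
  selection on coordinates only, giving uniform spatial coverage. Ties
  take the lowest index; the deterministic start is the point farthest
  from the centroid with lexicographic (x, y, z) tie-break; the random
  start makes the selection stochastic.
* **RI-interval-enhanced sampling** (`riiesSample()`): a uniform draw
  from the closed nucleolar band [1.345, 1.355]; if the band holds fewer
  than 224 points, all of them are taken and replicated in shuffled
  cyclic order (multiplicities differ by at most 1) until the multiset
  has exactly 224 entries. Nucleolar size, number and RI are the
  features most associated with declining cell viability, which is why
  this band — and not a data-adaptive one — is enhanced.

The union is realized as multiset concatenation: a point picked by both
samplers appears twice, so |S| = K is guaranteed, which the fixed-input
network requires. Whether the original method deduplicated overlapping
picks is unknown; concatenation is this package's documented choice.
During training the selector runs with a random FPS start and fresh draws
every epoch — resampling *is* the augmentation, exposing the model to
many subsets of each cell. Evaluation always uses the deterministic
variant (deterministic start, fixed per-sample seeds), optionally
averaging class probabilities over several fixed-seed draws
(`evaluateModel(nDraws = …)`), which is still bit-reproducible.

## The network

`RPNetConfig()` describes the reference architecture: three set
abstraction levels followed by a classifier head.

| level | centers | radius | cap | pointwise widths |
|------:|--------:|-------:|----:|------------------|
| 1 | 512 | 0.15 | 32 | 64, 64, 128 |
| 2 | 256 | 0.30 | 64 | 128, 128, 256 |
| 3 | group all | — | — | 256, 512, 1024 |

Each level samples centers by deterministic FPS, groups neighbors by ball
query (radius in unit-sphere coordinates; up to `nSample` points nearest
first, padded by repeating the nearest index; a center is always its own
neighbor; nearest-first capping — rather than first-found — makes each
group a function of the point coordinates alone, which exact permutation
invariance requires), converts coordinates to center-relative
local coordinates, runs the shared pointwise MLP
(affine → batch normalization → ReLU per layer) and max-pools per region.
Level 1 consumes the raw channels (local xyz, plus standardized RI for
4-channel input → width 4); deeper levels consume the previous pooled
width plus 3 local coordinates (131 and 259) — the only reading of the
architecture that reproduces the published parameter count. The head is
1024 → 512 → 256 → 3 with batch normalization and ReLU after layers 1–2,
dropout 0.3/0.4, and a log-softmax output.

Counting every trainable scalar — cin·cout weights + cout biases per
affine layer, plus 2·cout normalization scalars wherever batch
normalization follows (all pointwise layers, head layers 1–2) — gives
1,466,243 parameters, printed as 1.47 M. `countParameters()` computes
this closed form and the tests require it to equal enumeration of a
built model. `countFlops()` counts one multiply–accumulate as one FLOP:
each pointwise layer over G grouped points contributes G·cin·cout MACs
with G = 512·32, 256·64 and 1·256 per level, the head adds
1024·512 + 512·256 + 256·3, for 1,470,956,288 MACs ≈ 1.47 G at a 1024 × 4
input. The convention is declared rather than inferred because published
FLOP figures rarely state their counter; elementwise work (bias,
normalization, rectifier, pooling) is excluded from the headline figure
and available via `countFlops(detail = TRUE)`.

Numerical choices inside the implementation:

* Batch normalization uses ε = 10⁻⁵, biased variance, and running
  statistics with momentum 0.1 (used in eval mode, the conventional
  choice over per-batch freezing).
* The affine bias of every normalization-followed layer cancels exactly
  in Z − mean(Z), so its gradient is identically zero; the implementation
  therefore skips the addition (identical semantics, one fewer pass) but
  keeps the bias as a counted, stored parameter.
* Weights use He initialization; weight decay applies to weight matrices
  only.
* Deterministic FPS centers plus symmetric max pooling make the eval-mode
  forward a pure function of the input point multiset: permutation
  invariance is exact up to floating-point association and is tested at
  10⁻⁵.
* Backpropagation is written by hand (the grouped structure rules out
  off-the-shelf autodiff here) and is verified against central finite
  differences for every parameter tensor in the test suite.
* The RI channel enters the network standardized. The default mapping
  (n − 1.33)/0.07 places the physical RI range on the coordinate scale.
  The desk-scale experiment harness instead uses (n − 1.35)/0.01
  saturated at ±1: centered on the nucleolar band and scaled to
  organelle-level RI differences, because at reduced problem sizes the
  class-defining band differences (~0.002 RI) are ~3% of the
  0.07-scaled channel and a 50-epoch run does not resolve them, while
  unsaturated band-scaling lets droplet outliers (≈ +3) dominate the
  first layer's statistics. Both mappings are exposed as arguments.

## Training protocol

`trainRPNet()` implements: AdamW (β = 0.9/0.999, ε = 10⁻⁸) with initial
learning rate 0.001 and decoupled weight decay 0.0001; cosine annealing
lr·(1 + cos(πe/E))/2 recorded per epoch (so the last epoch's rate is 0);
batch size 16; label-smoothed cross-entropy with α = 0.1 (uniform
predictions score exactly ln 3); 200 epochs at full scale. Each epoch
draws a fresh stochastic point set per cloud and applies three
augmentations independently with probability 0.5: uniform rotation about
z, clipped Gaussian coordinate jitter (σ = 0.01, clip ±0.05, unit-sphere
units), and Gaussian RI noise. The augmentation magnitudes are not
published; jitter follows common point-cloud practice. The RI-noise
default is σ = 0.002, but the desk-scale harness passes σ = 0.0005: on
phantoms whose classes differ *only* in nucleolar mean RI (gap 0.002),
noise of the same magnitude as the class gap erases the only signal, and
a practitioner would keep augmentation noise well below the effect of
interest. `stratifiedSplit()` allocates ⌊0.8·n_c⌋ per class to training
(so counts (123, 179, 154) give exactly 364/92); `kfoldIndices()`
provides stratified folds for configuration tuning, with final metrics
always from the single fixed split. `evaluateModel()` reports accuracy,
macro recall/precision/F1 from the confusion matrix (rows = truth) and
per-class one-vs-rest AUC via pROC, excluding (with a warning) classes
absent from the test set.

## The synthetic phantom

`generatePhantom()` emulates the statistical structure the pipeline
assumes, not cell biology:

* an ellipsoidal cell (nominal semi-axes 8.7 × 7.7 × 5.5 µm, ±10% per
  sample) in a fixed 25.6 × 25.6 × 16.8 µm field, so the foreground
  voxel count scales with grid resolution — the default 160 × 160 × 105
  desk grid holds an eighth of the 320 × 320 × 210 acquisition grid's
  voxels and yields foreground counts inside the scaled per-cell budget;
* orientation is an in-plane spin plus a small random tilt (σ ≈ 5°), the
  way a flattened adherent cell actually lies — a uniform 3D rotation
  cannot fit the long axis into the axial field;
* cytoplasm RI uniform in [1.335, 1.345], a nucleoplasm region slightly
  below the cytoplasm midpoint, class-dependent nucleolus spheres inside
  the nucleus with RI in [1.345, 1.355], and sparse ~0.3 µm lipid
  droplet spheres in [1.355, 1.380];
* additive Gaussian noise, default σ = 0.001 RI — a typical tomographic
  RI precision, and small enough that the lowest histogram interval
  remains the cytoplasm mass rather than a noise tail, preserving the
  ≥ 10³ low-over-high interval dominance the generator must emulate;
* three classes encode a viability analogue through nucleolar count,
  radius and mean RI (defaults 2/3/4 nucleoli, 1.2/1.0/0.85 µm, mean RI
  1.352/1.350/1.348). The literature ties nucleolar size, number and RI
  to viability but does not give directions, so these are documented
  synthetic conventions, freely configurable — no biological claim.
  `riOnlyClassParams()` makes the classes geometrically identical so
  *only* nucleolar mean RI differs; the ablation harness uses it to
  probe RI-channel use.

What the phantom deliberately does not model: diffraction, the
missing-cone artifact, reconstruction noise correlations, realistic
organelle morphology (everything is a sphere or ellipsoid), RI texture
within compartments, or touching/dividing cells. Consequently, passing
tests demonstrate that the *pipeline machinery* behaves as specified and
that the network can exploit RI structure when it is the only signal —
they say nothing about accuracy on real tomograms, and the published
real-data accuracies are not reproducible without the original dataset.

## The ablation harness and desk-scale sizes

`ablationArms()` enumerates the eight-arm matrix (3D/4D input × random/
segmented cloud sampling × FPS/RIIES/hybrid selection);
`runAblation()` runs any subset end to end. The experiments and the
heavier tests use desk-scale sizes chosen as the package's own working
point: 48 × 48 × 32 phantom grids, 60 volumes per class, 2048-point
segmented clouds, K = 256 selections (200 FPS + 56 RIIES, preserving the
800:224 ratio), the `smallRPNetConfig()` profile (64/16/group-all
centers, widths 32–256, head 256→128→64→3 with dropout 0.1/0.1 — the
small network trained for 50 epochs needs lighter regularization than
the full profile's 0.3/0.4), 50 epochs, and probability averaging over
5 deterministic selector draws at evaluation. On these conditions the
RI-aware hybrid arm separates the RI-only classes while the
coordinate-only FPS arm stays at chance; the expectation is directional
(4D > 3D, hybrid > FPS-only), not a reproduction of published
magnitudes. `ripcsRobustness()` re-evaluates a fitted model under
repeated stochastic selector draws and reports mean ± sd accuracy.

## Known limitations

* Training is CPU-bound R + BLAS; the full 1024-point, 200-epoch
  protocol is supported but slow — the desk profile exists precisely so
  that the full loop remains testable.
* The quota sampler's supplementation rule and the multiset union are
  one documented reading of loosely specified procedures; both are
  property-tested against brute-force reimplementations of the stated
  rule, not against the original code.
* AUC for a class absent from a test split is undefined and excluded
  from the mean.
* The PLY reader supports exactly the package's own binary little-endian
  layout (x, y, z, refractive_index [, provenance]), not arbitrary PLY.
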