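---
title: "Rough-fuzzy discretization and deep-supervised segmentation of OCT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rough-fuzzy discretization and deep-supervised segmentation of OCT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfdseg)
```

## The problem

Optical coherence tomography (OCT) produces volumetric B-scan stacks of the
retina in which fluid lesions -- retinal edema area (REA), subretinal fluid
(SRF) and pigment epithelial detachment (PED) -- must be delineated for
diagnosis and monitoring. Two properties of OCT make voxel-wise segmentation
hard: multiplicative speckle noise, and a grey-level resolution (256 levels
per 8-bit slice) far finer than the handful of tissue categories of
interest. Most of those grey levels are redundant: they encode noise, not
anatomy.

`rfdseg` addresses this with a *supervised feature discretization
pre-module*: before a volume enters the segmentation network, its brightness
axis is re-partitioned into a small number of intervals chosen so that the
intervals distinguish tissue categories as well as the raw grey levels do.
Discretization is the denoising step -- the package deliberately applies no
smoothing or intensity normalization beforehand.

## The discretization model

An image with its gold-standard mask is an *information decision table*:
each pixel carries one condition attribute (brightness) and one decision
attribute (its category among M classes). Three ingredients turn this into a
searchable objective.

**Fuzzification.** Fuzzy c-means clustering (fuzzifier fixed at m = 2)
assigns each pixel a membership `u_ij` to each category, so category j is a
fuzzy set `A_j` over the pixels. Membership is a function of brightness
alone, so the iteration runs over the unique brightness values weighted by
their counts -- identical arithmetic to the per-pixel iteration (the test
suite checks equality to 1e-10 against a naive per-pixel implementation) at
a fraction of the cost.

**Rough approximation.** A set of selected breakpoints cuts the brightness
axis into half-open intervals `(s_k, s_{k+1}]`; pixels in the same interval
(and, for per-slice tables, the same slice) are indistinguishable -- an
equivalence relation R. The lower/upper approximation of `A_j` at pixel x is
the inf/sup of `A_j` over x's equivalence class, and the per-class precision
is the ratio of their sigma-count cardinalities (sums of membership). The
*average approximate precision* is

    eta_bar = (1/M) * sum_j card(lower_j) / card(upper_j)

which is 1 exactly when every interval is pure (inf = sup) and degrades as
intervals mix brightness values with different memberships. Selecting every
candidate breakpoint always gives eta_bar = 1; removing cuts can only merge
intervals, so eta_bar is monotone under scheme refinement (a property test
covers 100 random scheme pairs).

**Breakpoint search.** Candidate breakpoints are the sorted unique observed
brightness values (so a full-range 8-bit slice has exactly 256 candidates,
and a 128-slice stack has 128 x 256 = 32768 under per-slice accounting). A
binary chromosome selects a subset; its fitness is

    Fitness = alpha * (N_CB - N_DS) / N_CB + beta * eta_bar

with `alpha + beta = 1`: parsimony (few cuts) traded against approximation
precision. A seeded genetic algorithm (tournament selection, single-point
crossover, per-bit mutation, elitism) searches the 2^n schemes; the empty
and all-selected chromosomes are injected into the initial population so the
result is never worse than either limit. On instances small enough to
enumerate, the GA finds the exact optimum in virtually every seeded run
(tested against a 2^n exhaustive oracle).

The selected scheme is applied to images by replacing each voxel with its
interval's mean observed brightness, rescaled to [0, 1] -- this keeps
intensity semantics for the convolutions while deleting within-interval
noise. Interval-index and midpoint encodings are also available.

## The segmentation network

The network is a compact 3D encoder-decoder operating on patches:

* residual double-convolution blocks (two 3x3x3 convolutions, batch
  normalization, ReLU, identity/1x1x1 shortcut);
* encoder channels double per stage from 16, clamped at 128; 2x2x2
  max-pool downsampling and nearest-neighbour upsampling;
* skip features pass through a *dual attention block* -- a channel
  squeeze-gate (global average pool, two dense layers, sigmoid) times a
  spatial sigmoid gate -- before fusion with decoder features;
* an *attention refinement block* applies parallel 3x3x3 and 5x5x5
  convolutions (hybrid kernels) whose outputs are concatenated into 16
  feature maps ahead of the two-convolution classifier head;
* optional *deep supervision*: a 1x1x1 classifier at every decoder stage,
  upsampled to full resolution. The main output is the separate attention
  refinement classifier, so even a depth-2 model has one supervision head;
  this keeps the supervision loss meaningful at every depth.

The training loss is

    L_total = kappa * L_DSC + gamma * L_CE + lambda * L_max

with defaults kappa = 1, gamma = 1, lambda = 0.5: a soft Dice loss and an
unweighted cross-entropy on the main head, plus a class-weighted
cross-entropy averaged over the deep-supervision heads. Dice terms aggregate
`g_i p_i` and `g_i + p_i` spatially per class (so empty classes contribute
`eps/eps` and are not penalized); cross-entropy terms average over voxels.
Class weights default to inverse class frequency in the batch, normalized
to mean 1 over present classes -- absent classes get weight 0, which is
immaterial because their gold indicator is identically zero.

All layers and their gradients are implemented in R: convolutions are
im2col gathers followed by one BLAS matrix product, and a small
reverse-mode tape replays analytic backward rules. The full composite-loss
gradient is verified against central finite differences through every block
type (relative error below 1e-6 in the build's checks; the suite asserts
1e-4).

### Optimization

Mini-batch SGD with momentum 0.9, L2 weight decay 1e-4, a global
gradient-norm threshold, and a step schedule multiplying the learning rate
by 0.1 at configurable iterations. The reference profile
(`train_config()`: lr 1e-3, clip 0.005, drops at 1000/2500) reflects
full-scale training on clinical volumes over thousands of iterations. For
desk-scale capacity checks that profile is far too conservative: a norm cap
of 0.005 bounds total parameter movement by `lr x clip x iterations`, which
after 300 iterations is about 1.5e-5 -- no model can fit anything under it.
`toy_train_config()` (lr 0.05, no clipping, no drops) is the package's
chosen profile for single-phantom overfitting, and is what the end-to-end
tests use.

## The phantom generator

No public OCT dataset with SRF/PED/REA gold standards is bundled, so the
package generates seeded synthetic volumes that emulate the data regime the
method targets: a retina band whose thickness matches the REA target
fraction (default 0.61), bounded by smooth sinusoidal surfaces with
configurable waviness; one SRF ellipsoid strictly inside the band (default
0.7% of voxels); one PED half-ellipsoid bump hanging from the lower
boundary (default 0.03%); stylized, well-separated class intensities
(background 30, REA 110, SRF 190, PED 240); and multiplicative gamma
speckle with a `looks` parameter (default 16, mean 1, variance 1/looks --
the canonical multiplicative noise model for coherent imaging).
`speckle_looks = Inf` disables noise. Targets below one voxel for the
requested shape are emitted empty with a warning rather than an error.

What the phantom does *not* emulate: real retinal layer texture, vessel
shadows, motion artifacts, anisotropic voxel spacing, or the ambiguity of
manual annotations. Passing tests on phantoms therefore demonstrate the
correctness and internal consistency of the pipeline -- exact discretization
of separable intensities, capacity to overfit, metric arithmetic -- not
clinical segmentation accuracy.

## Numerical choices and edge cases

* **FCM**: termination when the largest membership change falls below
  `epsilon = 1e-5`, capped at 300 iterations (neither value is prescribed by
  the method's description; these are conventional). Center initialization
  uses the (j+0.5)/M brightness quantiles -- deterministic and seed-free --
  with a fallback to evenly spaced unique values under heavy ties; a seeded
  random init is retained for robustness experiments. A brightness value
  coinciding with a center receives membership 1 split over coincident
  centers (the standard FCM limit convention). Tied updated centers are
  perturbed by 1e-9 to preserve distinctness.
* **Rough-fuzzy**: precision of an empty upper approximation is defined as 1
  (vacuously exact, avoids 0/0). Intervals are `(lo, hi]` -- a breakpoint
  separates `v <= s` from `v > s`; any consistent convention works, this one
  is fixed for reproducibility. In per-slice mode equivalence classes never
  cross slices and the volume eta_bar is the pixel-weighted mean of
  per-slice values. The data-inconsistency statistic is the fraction of
  pixels whose equivalence class contains more than one gold label (the
  quantity is reported in the field without a formal definition; the
  fraction makes 0 mean "perfectly consistent" and is monotone under
  refinement).
* **GA**: hyperparameters are not prescribed by the method; defaults are
  population 50, 100 generations, crossover 0.8, mutation 1/n per bit,
  tournament size 2, elitism 1, and alpha = beta = 0.5. All are recorded in
  the scheme JSON. Fitness values are cached by chromosome since eta_bar
  dominates the cost.
* **Metrics**: the Dice coefficient is implemented as `2|P.T| / (|P|+|T|)`
  (the union-denominator variant printed in some descriptions equals 2 for
  identical masks, contradicting DSC's [0, 1] range). HD95 ships in two
  modes: `paper` -- the literal `0.95 * max(d_XY, d_YX)` scaled maximum --
  and `percentile` -- the conventional 95th percentile of pooled directed
  surface distances; both are tested and `paper` is the default. Surfaces
  are foreground voxels with a background 4/6-neighbour or touching the
  image border. Distances are voxel units unless a spacing vector is given.
  Nearest-neighbour queries use blocked exact BLAS distance computation,
  verified against a double-loop oracle.
* **Network**: batch statistics are used for normalization at both training
  and inference (batch size is small and patches are large, so this is
  effectively instance normalization and keeps prediction deterministic).
  Sliding-window inference averages probabilities over 50% overlaps, which
  preserves per-voxel normalization; argmax ties break toward the lower
  class index.

## Problem sizes used by the checks

The bundled tests and the acceptance script run entirely on synthetic data
at desk scale, chosen as the smallest sizes that exercise every code path:
breakpoint accounting on a 128 x 16 x 16 stack; FCM/rough-fuzzy oracle
equivalence on tables of up to 500 and 200 pixels; GA-vs-enumeration on up
to 12 candidates; exact discretization of a noiseless 16 x 64 x 64 phantom;
and a depth-2 network overfitting one speckled 16^3 phantom to macro
training DSC >= 0.9 within 300 iterations. The full-scale configuration
(depth 4, 64^3 patches, 16 -> 128 channels) is constructed and
shape-checked but not trained in the checks.

## Known limitations

* Training is CPU-bound R; it is suitable for methodological work and small
  volumes, not for full clinical 1024 x 512 x 128 stacks.
* 2D network operation is not provided; small 3D patches stand in for
  desk-scale experiments.
* The rough-fuzzy model uses the single brightness attribute; no
  multi-attribute equivalence relations or variable-precision rough sets.
* No DICOM or vendor raw formats; NIfTI, TIFF and PNG only.
* The GA is single-objective with fixed operator rates.
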