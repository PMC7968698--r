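---
title: "Classifying dividing-yeast trap images: models, synthetic data, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying dividing-yeast trap images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-throughput yeast-aging chips hold single mother cells in microfluidic
traps (a pocket with a ~6 µm inlet at the top and a ~3 µm outlet at the
bottom) while daughters are washed out by the medium flow. Scoring
replicative lifespan from such movies requires classifying, frame by frame
and trap by trap, what each 60×60-pixel trap sub-image contains. The
package works in two label spaces:

* **5 computed categories** — `nC` (empty), `mC` (mother only), `mduC`
  (mother + daughter above), `mddC` (mother + daughter below), `exC`
  (more than two cells). Separating the two daughter orientations gives
  the classifiers more consistent spatial patterns to learn.
* **4 biological categories** — `mduC` and `mddC` describe the same
  biology (a mother with one daughter), so for interpretation they merge
  into `mdC`. Merging is exact bookkeeping: probabilities add, confusion
  matrix rows/columns add, and 4-space accuracy can only be ≥ 5-space
  accuracy, with equality exactly when no `mddC`↔`mduC` confusions exist.

Three classifiers are compared on this task: a 2-layer baseline CNN
(`build_cnn2()`), a 13-layer SimpleNet-style CNN (`build_cnn13()`), and a
capsule network with dynamic routing (`build_capsnet()`), plus all four
validation-accuracy-weighted ensembles of the three.

## The capsule core

A capsule's output is a vector whose length encodes the probability that
its feature is present. Lengths are bounded by the squash map

$$v = \frac{\lVert s\rVert^2}{1+\lVert s\rVert^2}\,\frac{s}{\lVert s\rVert},$$

which preserves direction and maps lengths into [0, 1). Each input capsule
$i$ predicts each parent $j$ through a learned affine map
$\hat u_{j|i} = W_{ij} u_i$; routing-by-agreement then computes coupling
coefficients $c_{ij}$ (softmax over parents of logits $b_{ij}$, initialized
at zero), parent inputs $s_j = \sum_i c_{ij}\hat u_{j|i}$, outputs
$v_j = \mathrm{squash}(s_j)$, and reinforces logits by the agreement
$\hat u_{j|i}\cdot v_j$. With one iteration the couplings are exactly
uniform; the package's `dynamic_routing()` is tested against a plain-loop
oracle at 1e-10.

On a 60×60 input the network is: 9×9 convolution (stride 1, valid) to
52×52 maps; 9×9 stride-2 primary-capsule convolution to a 22×22 grid
reshaped to 22×22×32 capsules of dimension 8; dynamic routing to five
16-dimensional class capsules; and a dense decoder that reconstructs the
input from the correct class capsule (reconstruction error enters the
loss with weight 5e-4 per pixel-sum). Class probabilities are the capsule
lengths normalized to sum to one — keeping the "length is probability"
reading rather than a softmax over lengths.

## Design choices the sources leave open

* **Losses.** The CNNs use categorical cross-entropy. The capsule network
  uses margin loss ($m^+ = 0.9$, $m^- = 0.1$, $\lambda = 0.5$) plus the
  down-weighted reconstruction term, following the baseline capsule
  formulation it descends from.
* **Routing backward pass.** Gradients flow through the final parent
  inputs with the coupling coefficients treated as constants
  (stop-gradient). With one routing iteration this is exact (verified by
  finite differences); with more iterations it is the standard practical
  approximation. Forward routing is exact in all cases.
* **Optimizer.** Adam; learning rate, batch size, epochs, noise and
  augmentation flags form the six-axis search grid (108 combinations by
  default). Routing iterations only exist for the capsule network, so the
  grid axis collapses for the CNNs.
* **Batch-norm statistics.** At smoke scale a model sees only a few dozen
  optimizer steps, so momentum-tracked running statistics lag the weights
  badly — catastrophically so through 13 stacked normalized layers. After
  each epoch the package therefore recomputes the running statistics with
  a forward pass over (up to 192) training images under the current
  weights ("precise BN") before validating.
* **Model selection.** The returned model is the epoch with the highest
  validation accuracy; the test split is touched exactly once, for the
  final report.
* **CNN-13 grouping.** The 13 convolutions are grouped 2/3/3/3/2 with 2×2
  max-pooling between groups (60→30→15→7→3), batch normalization and 25%
  dropout on every layer, reference widths 64–256 scaled by `width_scale`
  for CPU runs. CNN-2 keeps its reference widths (16, 32) everywhere —
  it is cheap enough.
* **Feature-wise normalization** (center + std, fitted on the training
  split only) feeds the CNNs. The capsule network trains on raw [0, 1]
  images because its decoder reconstructs the input through a sigmoid.
* **Augmentation defaults** are mild (rotation ±15°, shifts ±10%,
  brightness 0.8–1.2, both flips, Gaussian noise 0.02) since the source
  material lists the transform kinds but not magnitudes. Note that a
  vertical flip converts a daughter-above scene into a daughter-below
  scene while keeping its 5-space label — harmless after merging, but it
  adds 5-space label noise; this is inherent to flipping with orientation
  labels. For that reason `run_comparison()` augments with
  orientation-preserving transforms only (no vertical flip) and keeps the
  magnitudes inside the generator's own nuisance envelope (rotation ±8°,
  shifts ±5%, brightness 0.9–1.1): at smoke scale, stronger transforms
  than the data's actual variation measurably hurt the small baseline CNN
  and invert the augmentation comparison. The default multiplier of 32
  approximates the published ~3,000 → ~100,000 expansion; CPU-scale runs
  use 2–3.

## What the synthetic generator emulates — and what it does not

Each scene renders the trap outline (wider inlet up, narrower outlet
down, 6 px/µm so the trap fills the central ~2/3 of the tile), cells as
anti-aliased ellipses with dark rims and lighter interiors (bright-field
appearance), then nuisance structure: Gaussian blur, background level
and illumination ramps, oblique multiplicative shadows, additive noise,
and occasionally near-transparent cells. Pre-noise ground-truth masks are
retained so tests can verify, with an independent connected-component
pass, that every image contains exactly the cell configuration its label
promises (0, 1, 2, or ≥3 cells; daughter centroid strictly above/below
the mother for `mduC`/`mddC`).

Two presets state the experimental conditions:

* **easy mode** (default) is the nearly separable regime: light blur
  (0.3–0.7 px), noise sd 0.015, 10% shadows, no transparent cells,
  daughter tangent just outside the mother. Its purpose is to verify that
  every architecture can learn the task to ≥90% at smoke scale; during
  development the first-draft values turned out to leave ~10%
  irreducible class overlap even for converged models, so they were
  recalibrated once to match this stated purpose and then frozen.
* **hard mode** is the mid-difficulty regime used for model comparisons:
  blur 0.6–1.3 px, noise sd 0.04, 45% shadows, 10% transparent cells,
  daughter squeezed against the mother. It was likewise calibrated once —
  the first draft (blur to 2 px on 4–6 px daughters) pushed all models to
  chance, which defeats the point of comparing them.

The generator does **not** emulate time-lapse dynamics, photobleaching,
focus drift across a movie, or the spatial correlation of real camera
noise; a green test on synthetic data establishes that the pipeline's
machinery is correct and that the qualitative model orderings can be
reproduced, not that the published real-data accuracies transfer.

## Numerical notes

* `squash()` guards the division by the norm with an epsilon of 1e-12;
  the zero vector maps to zero exactly.
* Argmax ties break by canonical category order (`nC, mC, mduC, mddC,
  exC`), so predictions are deterministic.
* Metrics with zero denominators (a category never predicted, say)
  report 0 and set an `undefined` flag instead of erroring; per-category
  accuracy is the one-vs-rest form (including true negatives), overall
  accuracy is trace over total.
* Stratified splitting rounds cumulative fractions, so each per-category
  split count is within one image of the exact proportion.
* All randomness is drawn under explicit seeds through an isolated RNG
  scope; identical seeds give bit-identical datasets, augmentations and
  training runs.

## Known limitations

* The neural-network engine is R over BLAS with two small compiled
  kernels (patch extraction and its scatter-add inverse): correct (every
  layer is finite-difference tested) but slow compared to a GPU framework, so
  default experiment configurations are smoke-scale (reduced widths, few
  epochs, ~100 images per category). The full-scale settings are the
  same code with larger numbers.
* Capsule-network training cost grows with the primary-capsule count;
  the reference 32-type configuration is available but impractical on
  one CPU, so training configs default to fewer types while construction
  and shape checks use the reference.
* Images are read and written as PGM (plain or raw), not PNG/TIFF — the
  target environment has no R binding for compressed image formats, and
  PGM round-trips 8-bit grayscale losslessly.
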