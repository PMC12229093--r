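---
title: "Aligning histology with spatial gene expression and predicting expression from images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning histology with spatial gene expression and predicting expression from images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histex)
```

## The problem

Spatially resolved transcriptomics (SRT) measures a UMI count vector at
each capture spot of a tissue section together with the H&E histology
under that spot. The two modalities describe the same biology, which
raises two questions this package addresses:

1. **Alignment** — can a spot's image patch and its expression profile be
   embedded into a shared space where true pairs are more similar than
   unpaired combinations, so that one modality retrieves the other?
2. **Generation** — once such a space exists, can the expression of a
   high-expression gene panel be predicted from histology alone, including
   for whole-slide images (WSIs) with no measured expression at all?

## The model

### Stage 1: momentum-distilled contrastive alignment

Each spot contributes a 40×40-pixel patch $h_i$ (resized to the image
encoder's input resolution) and a normalized expression vector $x_i$ over
the highly variable gene (HVG) panel. A ViT-style encoder $H(\cdot)$ maps
patches to $v_i \in \mathbb{R}^{512}$; the gene encoder $G(\cdot)$ maps
expression to $e_i \in \mathbb{R}^{512}$ through the chain: per-gene
tokens (a learned gene-identity embedding plus a learned embedding of the
binned expression value), a transformer backbone, a 2D convolution with
kernel $(7,5)$ and padding $(0,2)$ over the token × embedding map, global
average pooling **across the embedding/channel axis** (one pooled value
per post-convolution gene token), and a three-layer fully connected head
with ReLU and dropout.

A momentum ("teacher") copy of both encoders, parameters $\theta_m$, is
advanced each step by the exponential moving average
$\theta_m \leftarrow \beta\theta_m + (1-\beta)\theta$ with $\beta = 0.995$.
Cosine-similarity softmax distributions at temperature $\tau = 0.07$ are
computed in both directions (image→gene and gene→image); the training
targets mix the teacher's distribution $p_M$ with the one-hot pairing
matrix $A$:

$$y = \alpha\, p_M + (1 - \alpha)\, A, \qquad \alpha = 0.4,$$

and the contrastive loss is the symmetrized cross-entropy between the
primary model's distributions and these pseudo-targets. The mixing keeps
training robust to noisy pairs: a spot whose expression resembles several
patches is not forced onto a single hard label.

A second, finer-grained objective (IGM, image–gene matching) fuses the
two token streams — self-attention over gene tokens, then cross-attention
with the histology tokens as Key and Value, then a residual feed-forward
block, all post-normalized — and classifies fused pairs as matched or
mismatched. Negatives are the *hardest* in-batch candidates: for each
expression profile, the non-paired image with the highest momentum-space
cosine similarity. The default mines one hardest image per expression
profile (S positives + S negatives, matching the matching-head batch
contract); symmetric two-sided mining is available via
`fusion_config(symmetric_negatives = TRUE)`.

### Stage 2: expression decoding

The stage-1 image encoder is frozen. Its embeddings are projected by two
linear layers (ReLU between) to a wider feature, reshaped into a short
token sequence (8 tokens by default; a transformer over a single vector
would be degenerate), passed through stacked multi-head self-attention
blocks with residual connections and layer normalization, and mapped
linearly to the target panel — the 300 genes with the highest mean
normalized expression over the training spots (50 in the desk-scale
configuration). Training minimizes the mean squared error against
log-normalized expression; the raw Frobenius-norm variant of the
objective is available as `mse_loss(variant = "l2")`.

### WSI zero-shot inference

A whole-slide image is tiled on a non-overlapping 512×512 grid. Each tile
gets a tissue fraction $T_t$ (HSV saturation threshold; background in an
H&E scan is desaturated) and a nuclei fraction $N_t$ (hematoxylin
concentration from Ruifrok–Johnston color deconvolution). Tiles with
$T_t < 0.6$ are excluded ($T_t = 0.6$ is retained — the boundary follows
the strict inequality); survivors are ranked by $N_t \tanh(T_t)$ and the
top 20 are embedded, decoded, and averaged elementwise into the slide's
predicted expression profile.

## Parameters that matter

| parameter | default | units / range | role |
|---|---|---|---|
| `beta` | 0.995 | [0,1] | EMA speed of the momentum teacher |
| `alpha` | 0.4 | [0,1] | pseudo-target mixing weight |
| `tau` | 0.07 | >0 | similarity softmax temperature |
| `lambda_igm` | 1 | ≥0 | IGM loss weight relative to contrastive |
| HVG panel | 2000 | genes | encoder input (dispersion-ranked) |
| target panel | 300 | genes | decoder output (mean-ranked) |
| patch crop | 40 | px | center crop per spot, zero-padded at borders |
| dropout | 0.5 | [0,1) | gene-encoder head (0.1 in the tiny preset) |
| `warmup_steps` | 50 | steps | linear learning-rate warmup |

Two optimization choices deserve explanation because the full-scale
defaults do not transfer to a desk-scale run:

* **Warmup.** Training both encoders from random initialization at
  $\tau = 0.07$ makes the initial softmax confidently wrong (the loss
  starts *above* the uniform value $\ln S$), and the steepest descent
  direction is to equalize all cosines. Without warmup the run converges
  to that sample-independent saddle and never recovers; a linear warmup
  of the learning rate over the first ~1/3 of training avoids it. This
  failure mode is specific to from-scratch training — encoders
  initialized from pretrained weights start with well-spread similarity
  distributions.
* **Dropout.** A 0.5 dropout directly on the embedding is a
  regularization suited to tens of thousands of spots and many epochs. A
  300-step run is under-fit, not over-fit, and heavy embedding dropout
  prevents the alignment from forming at all at this scale; the tiny
  preset uses 0.1.

## Design decisions in ambiguous territory

* **Log normalization.** "Natural logarithmic transformation" of CPM is
  implemented as $\ln(1 + \mathrm{CPM})$: zeros stay zero and all values
  remain non-negative, the standard single-cell convention.
* **HVG statistic.** Dispersion = variance/mean of normalized values,
  ties broken by gene name, computed on the pooled training spots
  (per-slice selection is possible by calling `select_hvg` per slice).
* **GAP axis.** The gene-encoder pooling averages across the embedding
  channels, leaving one value per gene token. The alternative (pooling
  across tokens) reduces the expression input to a bin histogram —
  empirically unlearnable for retrieval — and contradicts the description
  of the pooling as a mean over channels.
* **Patch size.** Crops are 40×40 and then resized to the encoder's
  input resolution; both numbers are configurable.
* **Candidate pools.** "Identifying the pair among k adjacent spots" is
  read as a pool of the true partner plus the k nearest spots by
  Euclidean distance (chance = 1/(k+1)). Cosine ties count as incorrect.
* **Similarity.** `sim(·,·)` is cosine on L2-normalized embeddings
  throughout; raw embeddings feed the fusion module.
* **Eq-level sums vs means.** The IGM loss is reported as the per-pair
  mean (batch-size invariant) with the raw sum attached as an attribute;
  the MSE objective is the mean over entries.
* **Hard-negative source.** "Previous training round" similarities are
  taken from the current batch's momentum embeddings (detached), the
  closest stateless reading.
* **`ln p` guard.** Probabilities are floored at $10^{-12}$ inside every
  cross-entropy; losses are never NaN.
* **IGM gradients** flow into both encoders (no stop-gradient) by
  default.
* **Alpha schedule.** $\alpha$ is constant; a warm-up schedule can be
  emulated by chaining `train_alignment` calls with different configs.

## The synthetic benchmark

`generate_slice()` plants a shared latent $z_i \sim N(0, I_4)$ per spot.
The patch is a deterministic render of $z_i$ (per-quadrant brightness,
blob amplitude and hue) plus Gaussian pixel noise (sd 8 on the 0–255
scale); counts are Poisson with rates
$\mathrm{depth}\cdot\mathrm{softmax}(Wz_i)$, depth 10000 — a realistic
per-spot UMI total — with a fixed loading matrix $W$ shared across slices
(`loading_seed`), and **no gene-specific intercept**: all genes share the
same expected depth, so a decoder that merely learns per-gene means gains
nothing, which is what makes the shuffled-target control informative.
Coordinates lie on a regular grid.

What the generator does *not* emulate: histological texture, stain
variation, spatial autocorrelation of expression (latents are i.i.d.
across the grid, so "adjacent" candidate pools are as hard as random
ones), batch effects, and gene–gene correlation beyond the rank-4 latent
structure. Passing the recovery tests therefore demonstrates that the
architecture and losses can extract and align a planted cross-modal
signal at desk scale — not that the pipeline reaches any particular
accuracy on real tissue.

Problem sizes used by the tests and the acceptance script: 256 training
spots, 64 held-out spots, 200 genes with a 64-gene HVG panel and a
50-gene target panel, encoders of depth 2 and width 64, 300 alignment
steps (batch 16) and 200 decoder steps (batch 64). These sizes are the
package's desk-scale study conditions; the full-scale defaults
(`default_run_config(tiny = FALSE)`) restore the full-scale panels and
encoder sizes.

## Numerical notes

* All randomness flows through a single integer seed via
  `derive_seed(seed, label)`; identical runs are bitwise identical,
  including the training trajectory.
* Ties are deterministic everywhere: gene panels break by name, nearest
  neighbors and hardest negatives by smallest index, tile ranking by
  raster order.
* Degenerate inputs: all-zero spots are an error in normalization
  (undefined CPM); constant vectors give `NA` Pearson with a warning and
  are excluded from means; zero qualifying WSI tiles return all
  survivors with a warning.
* The autodiff engine underlying the encoders is a plain reverse-mode
  tape over matrices; every primitive is finite-difference tested, and
  attention is additionally checked against a naive three-loop oracle.

## Known limitations

* Pure R training is practical at the tiny scale (a full test run takes
  minutes on one CPU) but the full-scale configuration is provided for
  completeness, not speed.
* The tissue/nuclei estimators are classical thresholding methods,
  calibrated on the Beer–Lambert synthetic fixture; real slides with
  atypical staining may need the pluggable thresholds adjusted.
* Pretrained ViT/scBERT initialization is an optional hook (random
  initialization is the default); no download is required or attempted.
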