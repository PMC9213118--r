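---
title: "Methods: a multiscale fusion and attention network for lesion segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multiscale fusion and attention network for lesion segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msfanet)
```

## The segmentation problem

Dermoscopy images show a pigmented lesion against surrounding skin, and the
task is a pixel-wise binary decision: lesion or not. Three situations make
this hard in practice: very small, high-contrast targets that are easy to
miss entirely; large, prominent targets whose low-contrast rim is hard to
delineate; and targets with strongly irregular boundaries. The network in
this package addresses these with multiscale context (parallel dilated
convolutions), attention (scSE gates) and an input-resolution bridge that
lets the decoder re-calibrate its features against near-raw image evidence.

## Architecture

All blocks preserve the spatial grid: there is no pooling or upsampling
anywhere in the network. This is a deliberate structural choice — the
decoder's pixel-wise calibration product and the channel concatenations are
only shape-consistent if every path runs at the input resolution — and it
keeps the model small (about 1.25 M parameters at the default width).

**Multiscale fusion encoder (MSF).** Five parallel branches see the input at
different receptive-field scales, set by dilation rates
$(r_1,\dots,r_5) = (1, 3, 6, 12, 18)$. The rate-1 branch uses a $1\times 1$
kernel (pixel-wise sampling that preserves global per-pixel information);
the others use $3\times 3$ kernels with taps spaced $r_i$ pixels apart and
"same" padding equal to $r_i$. Each branch follows its dilated convolution
with an ordinary $3\times 3$ convolution that filters the spatial
information, then batch normalization and ReLU, producing $G = 128$ channels
by default. Branch outputs are concatenated on channels into a
$5G$-channel map.

**scSE attention.** Concurrent spatial and channel squeeze-excitation: the
channel branch global-average-pools the map, passes it through a bottleneck
of reduction ratio 2, and gates each channel with a sigmoid; the spatial
branch projects the map to one channel with a $1\times 1$ convolution and
gates each pixel; the two gated maps are added. Placement is configurable:
on each branch before concatenation (I), on the fused map (II), both
(default), or neither. Both placements appear in the architecture's
description; the ablation driver (`cmd_ablate()`) exists precisely to
compare them.

**Asymmetric skip-connection bridge (ASCS).** A bridge from the raw input to
the decoder: three parallel convolution + batch-norm + ReLU paths with
$3\times 3$, $1\times 3$ and $3\times 1$ kernels, all at $G = 3$ channels.
The asymmetric pair costs $2\cdot 3 C^2$ weights against $9 C^2$ for a
square kernel — exactly one third fewer. The three path outputs are fused
element-wise. The published formula for this fusion is typographically
corrupted; the only operator named in the surrounding text is the Hadamard
product, so the default rule is
$\hat Y = (Y^{1\times3} \odot Y^{3\times3}) \odot (Y^{3\times1} \odot
Y^{3\times3})$ (`fusion_rule = "literal_product"`), with
$(Y^{1\times3} + Y^{3\times3}) \odot (Y^{3\times1} + Y^{3\times3})$
available as `"sum_product"`. The ambiguity is preserved as a switch rather
than silently resolved. Dropout (rate 0.1 by default) follows the fusion
during training.

**Calibrating decoder.** The $5G$-channel encoder output $\tilde Y$ is
compressed to 3 channels by a $1\times1$ convolution + batch norm + ReLU
($\tilde Y'$), calibrated by a pixel-wise product with the bridge output
($\tilde Y'' = \tilde Y' \odot \hat Y$), and the three 3-channel maps
$\hat Y, \tilde Y', \tilde Y''$ are concatenated into a 9-channel map from
which a final $1\times1$ convolution + batch norm + sigmoid produces the
single-channel probability map. Two published statements are corrected here
on shape grounds: the calibration multiplies the *bridge* map (3 channels),
not the uncompressed encoder map (640 channels, which cannot enter a
Hadamard product with a 3-channel map), and the concatenation of three
3-channel maps has 9 channels, not 3.

**Deep supervision.** The training loss attaches auxiliary heads (a
$1\times1$ convolution + sigmoid each) to $\hat Y$, $\tilde Y'$ and
$\tilde Y''$, because a 3-channel feature map cannot be compared to the
1-channel label directly. The objective is

$$L = \mathrm{BCE}(Y_{pred}) + \mu\,\mathrm{BCE}(h(\hat Y)) +
\nu\,\mathrm{BCE}(h(\tilde Y')) + \xi\,\mathrm{BCE}(h(\tilde Y'')),
\qquad \mu + \nu + \xi = 1 .$$

Only the simplex constraint on $(\mu,\nu,\xi)$ is prescribed; the default is
the uniform $1/3$ each, configurable through `loss_weights()`. The published
loss formula is truncated mid-expression; the completion above (main term
plus three weighted auxiliary terms) is the documented assumption.

## Training

**Optimizer and schedule.** Adam (standard moments, $\beta_1 = 0.9$,
$\beta_2 = 0.999$) under a two-stage learning-rate annealing rule: the rate
(default $\eta = 10^{-4}$) is frozen for the first half of training
($\tau = s/2$ with $s = 150$ planned epochs by default); afterwards, any
epoch that fails to improve on the previous epoch's training loss halves the
rate, floored at $10^{-6}$. The interior of the published schedule exists
only as an unavailable figure; this plateau-halving rule implements its
stated intent (adapting to the loss change of adjacent iterations) and is
the pluggable default. "Iteration" is read as epoch, consistent with
$s = 150$. Model selection uses the best validation Dice (the alternative,
validation loss, is not stated either way).

**Implementation.** No deep-learning framework is involved: convolutions
are im2col + GEMM kernels (compiled, chunked over output columns so the
patch matrix stays small at $224\times224$ with wide channels), and a
minimal reverse-mode tape differentiates the composite loss end to end.
Correctness is enforced two ways in the test suite: every kernel geometry
is checked against an explicit sliding-window loop oracle, and the full
composite-loss gradient is checked against central finite differences.
Batch norm uses biased batch variance in training, running statistics
(momentum 0.1, $\varepsilon = 10^{-5}$) at inference; inference passes are
therefore bit-deterministic. Weights use Kaiming fan-in initialization with
a pinned seed; biases and batch-norm shifts start at zero.

## Evaluation

Pixel confusion counts give $\mathrm{IoU} = TP/(TP+FP+FN)$ and
$\mathrm{Dice} = 2TP/(FP+2TP+FN)$; the identity
$\mathrm{Dice} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$ holds for every count
triple and is asserted property-style in the tests. Dataset metrics are
micro-averaged (counts pooled over all images) by default, with a macro
average (mean of per-image metrics) behind a flag; which average the
published tables use is not stated. The empty-versus-empty case ($0/0$) is
defined as 1 by convention. Probability maps are binarized at 0.5 (the
threshold is not stated; it is exposed as a parameter).

## Synthetic data: what it emulates and what it does not

The generator emulates the three morphologies above as darker elliptical
blobs on skin-toned backgrounds: a seeded low-frequency angular modulation
$\rho(\theta) = 1 + \sum_{k=2}^{6} (a_k \cos k\theta + b_k \sin k\theta)$
perturbs the ellipse radius (clamped at 0.25 so the region stays
star-shaped, hence connected), with category-specific area bands — small
(0.5–5 % of the image), prominent (15–45 %), irregular-edge (5–25 % with
amplitude 0.35 instead of 0.08). Axes are solved from the target area and
rescaled until the measured mask fraction lands inside the band. Optional
thin dark Bézier arcs imitate hair. The mask is the exact binary indicator
of the lesion region even where the image blends softly at the boundary.

These images share with real dermoscopy the properties the architecture is
built around — scale diversity, boundary irregularity, a darker lesion on a
lighter background, occlusion artifacts — but not the hard parts of the
real task: low lesion/skin contrast, color variegation inside lesions,
ruler marks and gel bubbles, camera vignetting. A model that segments these
fixtures well has demonstrated that the blocks, loss, schedule and
optimization work as specified; it has demonstrated nothing about clinical
performance, and the published benchmark numbers are expressly not
reproduced here (they require the external archive and GPU-scale training).

## Problem sizes and numerical choices

The scaled-down learning check trains a width-8 model (the architecture is
width-agnostic; 8 channels per branch suffice for the synthetic contrast
cue) on 200 training / 50 validation images at $64\times64$ for 15 epochs
of Adam at $10^{-3}$, batch 8 — a configuration chosen once for a small
fast run, stated here as the package's own scaling choice. Cross-entropy
probabilities are clamped at $10^{-7}$; the scSE bottleneck floor is one
channel; dropout is inverted (inference needs no rescaling); the area
solver aborts with an explicit error if a requested band cannot be placed
in the frame. Coordinates are row-major with origin top-left throughout;
masks resize with nearest-neighbor interpolation so they stay binary.

## Known limitations

* Full-resolution processing makes the default 224-pixel, 128-channel
  forward pass expensive on a CPU (tens of seconds); the design trades
  compute for shape consistency and parameter economy.
* The published parameter/FLOP table is internally inconsistent, so exact
  counts are reported (`cmd_summary()`) but not asserted against it.
* The annealing schedule's interior and the fusion rule are documented
  reconstructions behind switches, as described above.
* K-fold cross-validation is simplified to one fixed split by default.
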