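# msfanet

Pixel-wise segmentation of skin lesions in dermoscopy images with a
lightweight multiscale fusion and attention network — for researchers who
need a small, fully inspectable encoder–decoder segmentation model and a
reproducible training/evaluation harness in R.

The network is built from resolution-preserving blocks (no pooling, no
upsampling):

* **MSF encoder** — five parallel branches at dilation rates
  (r₁,…,r₅) = (1, 3, 6, 12, 18): a 1×1 kernel for the rate-1 branch, 3×3
  kernels with taps spaced rᵢ pixels otherwise, each followed by a 3×3
  filtering convolution + batch norm + ReLU (G = 128 channels per branch by
  default), concatenated on channels.
* **scSE attention** — concurrent channel gating (global average pool →
  bottleneck → sigmoid) and spatial gating (1×1 convolution → sigmoid),
  combined by addition; applied per branch and/or after fusion.
* **ASCS bridge** — 3×3, 1×3 and 3×1 convolution paths (G = 3) from the raw
  input, fused by Hadamard products; the asymmetric pair carries exactly
  one third fewer weights than a square 3×3 kernel.
* **Calibrating decoder** — compress the encoder map to 3 channels (1×1
  convolution), calibrate it by a pixel-wise product with the bridge,
  concatenate bridge/compressed/calibrated (9 channels), and predict one
  sigmoid channel: Ŷ_pred = σ(bn(conv₁ₓ₁(Λ(Ŷ, Ỹ′, Ỹ″)))).

Training minimizes a deep-supervision objective
`BCE(Y_pred) + μ·BCE(h(Ŷ)) + ν·BCE(h(Ỹ′)) + ξ·BCE(h(Ỹ″))` with
μ + ν + ξ = 1, using Adam under a two-stage schedule: the learning rate
(default 10⁻⁴) is constant for the first half of the planned epochs, then
halves whenever an epoch fails to improve the previous training loss,
floored at 10⁻⁶. Evaluation reports pixel-level IoU = TP/(TP+FP+FN) and
Dice = 2TP/(FP+2TP+FN).

All numerical machinery — im2col/GEMM convolutions (compiled), batch norm,
scSE, reverse-mode differentiation, Adam — lives in the package; tests
verify the convolutions against a sliding-window loop oracle and the full
loss gradient against finite differences. A seeded synthetic dermoscopy
generator (small / prominent / irregular-edge lesion morphologies, exact
binary masks, optional hair artifacts) makes every pipeline stage testable
without external data. See the methods vignette
(`vignettes/msfanet-methods.Rmd`) for the model account and design
decisions.

## Worked example

Train a narrow model (8 channels per branch) on 60 synthetic 64×64 images
and evaluate it:

```r
library(msfanet)

dir <- file.path(tempdir(), "demo")
split <- generate_dataset(60, dir, image_size = c(64, 64), seed = 7,
                          fractions = c(0.7, 0.3, 0))
ds <- load_split(split, size = c(64, 64))

model <- msfa_model(model_config(branch_channels = 8, seed = 1))
fit <- train_model(model, ds$train, ds$val, epochs = 30, batch_size = 8,
                   lr = 1e-3, seed = 1)
print(fit)
#> <msfa_fit> 30 epochs; best val Dice 0.9465 at epoch 27; final lr 6.25e-05

tail(fit$history[, c("epoch", "lr", "val_loss", "val_dice", "val_iou")], 3)
#>    epoch       lr  val_loss  val_dice   val_iou
#> 28    28 2.50e-04 0.9691726 0.9455858 0.8967878
#> 29    29 1.25e-04 0.9822627 0.9382691 0.8837164
#> 30    30 6.25e-05 0.9795289 0.9390114 0.8850344

evaluate_model(fit$best, ds$val)
#> <seg_metrics> Dice 0.9465  IoU 0.8984  (tp 13623 fp 1462 fn 79 tn 58564)
```

The history shows the two-stage schedule at work: the rate holds at 10⁻³
for the first 15 epochs, then halves on each loss plateau. The final line
pools pixel confusion counts over the validation set (micro average): of
13 702 true lesion pixels, 13 623 are recovered (Dice 0.9465, IoU 0.8984 —
the two always satisfy Dice = 2·IoU/(1+IoU)). `predict_mask()` returns the
probability map and binarized mask for a single image.

A shell front end wraps the same functions
(`inst/cli/msfa.R train|eval|predict|ablate|summary|synth`); runs are
configured by a YAML file and every run writes its resolved configuration,
history CSV and a self-describing checkpoint next to its outputs.

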