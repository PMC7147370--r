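---
title: "Stochastic activation-layer replacement and sum-rule ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic activation-layer replacement and sum-rule ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochact)
```

## The idea

A convolutional network is usually built with one activation function —
almost always ReLU — repeated at every nonlinearity. This package implements
a different design: keep the architecture and weights, but treat the
*activation layers* as replaceable slots. Replacing them uniformly with a
learnable function (MeLU, SReLU, APLU, ...) gives a family of stand-alone
model variants; replacing each slot independently with a random draw from a
pool gives *stochastically perturbed* variants that differ from one another
even when trained identically. Because the resulting models disagree in
useful ways, fusing several of them by the sum rule — adding their
post-softmax score vectors and taking the argmax — yields ensembles that
tend to outperform any single member.

The package provides the three ingredients end to end: the activation
catalogue with exact gradients, the model surgery, and the fusion and
evaluation machinery, plus synthetic fixtures and a tiny CNN so the whole
pipeline runs on one CPU in minutes.

## The activation catalogue

All ten functions act elementwise on a pre-activation $x$. Three are static:

* **ReLU** $f(x) = \max(x, 0)$;
* **Leaky ReLU** $f(x) = a x$ for $x<0$, $x$ otherwise (default
  $a = 0.01$; $0.1$ also circulates in the literature, so the slope is a
  spec knob);
* **ELU** $f(x) = a(e^x - 1)$ for $x<0$, $x$ otherwise ($a = 1$).

Seven carry learnable parameters, all initialized so the function *equals
ReLU exactly* at the start of training:

* **PReLU** — Leaky ReLU whose slope $a_c$ is learned per input channel;
  initialized at 0.
* **SReLU** — piecewise linear with four per-layer knots
  $(a_l, t_l, a_r, t_r)$: the line $t_l + a_l(x-t_l)$ below $t_l$, the
  identity between the thresholds, and $t_r + a_r(x-t_r)$ above $t_r$.
  Initialized at $(0, 0, 1, \mathrm{maxInput})$, which is ReLU.
* **APLU** — $\mathrm{ReLU}(x) + \sum_{c=1}^{N} a_c \max(0, -x + b_c)$ with
  $N = 3$ hinges per channel; slopes $a_c$ start at 0 and positions $b_c$
  are drawn once, uniformly on $[0, \mathrm{maxInput}]$. Training adds an
  L2 penalty $0.001 \sum a_c^2$ to the loss.
* **MeLU / wMeLU** — PReLU plus a learned combination of *Mexican-hat*
  triangular bumps
  $\phi_{\alpha,\lambda}(x) = \max(\lambda M - |x - \alpha M|,\, 0)$
  with $M = \mathrm{maxInput}$:
  $f(x) = \mathrm{PReLU}_{c_0}(x) + \sum_j c_j\,\phi_{\alpha_j,\lambda_j}(x)$.
  The centers and widths are fixed ($k=4$: $\alpha = (2,1,3)$,
  $\lambda = (2,1,1)$; $k=8$ adds four half-width bumps), chosen so the
  first bump peaks at $2M$ and vanishes at $0$ and $4M$, and successive
  bumps recursively bisect those supports. All $c_j$ start at 0.
* **GaLU / sGaLU** — same construction over a bump/dip pair
  $\phi^g_{\alpha,\lambda}(x) = \max(\lambda M - |x-\alpha M|, 0) +
  \min(|x - \alpha M - 2\lambda M| - \lambda M,\, 0)$, with $k=4$
  ($\alpha=(1, 0.5, 2.5)$, $\lambda=(1, 0.5, 0.5)$) and $k=2$
  ($\alpha=1$, $\lambda=1$).

`maxInput` is a normalization factor (1 for inputs in $[0,1]$, 255 for
$[0,255]$) that scales every center and width, making the families
positively homogeneous: $f(sx; sM) = s\,f(x; M)$.

```{r catalogue}
sp <- activation_spec("MeLU")
x <- c(-1, 0, 1, 2, 3)
act_melu(x, activation_state(sp), sp)   # equals ReLU at initialization
mexican_hat(c(0, 2, 4), a = 2, lam = 2, max_input = 1)
```

### Gradient conventions

Analytic gradients with respect to the input and every learnable parameter
are implemented for all ten functions and verified against central finite
differences (`gradient_check()`, step $10^{-6}$, relative tolerance
$10^{-4}$, at points kept $10\times$ the step away from breakpoints). Two
conventions deserve a note:

* At a breakpoint the right-hand branch is used, matching ReLU's
  $f'(0) = 1$ convention.
* Two published derivative branches do not survive differentiation of
  their own defining expressions, and a finite-difference check exposes
  both immediately. For SReLU, $\partial y / \partial t_l$ on $x < t_l$ is
  $1 - a_l$ (differentiating $t_l + a_l(x - t_l)$), not $-a_l$; the right
  knot mirrors it as $1 - a_r$. For APLU, the hinge consistent with the
  slope gradient $\partial y/\partial a_c = -x + b_c$ (active on
  $x < b_c$) is $a_c\max(0, -x+b_c)$, whose position derivative is
  $\partial y / \partial b_c = +a_c$ on $x < b_c$, not $-a_c$. The package
  implements the true derivatives throughout; with the printed variants the
  gradient checks fail by exactly the predicted margins.
* APLU's hinge itself is sometimes written with $\min(0, -x+b_c)$; that
  form contradicts the accompanying gradients, so the max form (also the
  original APLU definition) is implemented.

## Model surgery

`list_activation_slots()` enumerates the activation layers of a
`model_graph`; `replace_all()` installs one chosen function in every slot;
`stochastic_replacement()` draws each slot's function independently and
uniformly from a pool — by default the nine non-ReLU members of the
catalogue at a single `maxInput`. Replacement constructs a fresh
initialized state for each slot (channel counts inferred from the producing
layer) and never touches any other layer's weights — the suite asserts
bit-identical serialization of every non-activation layer.

Randomness is deliberately rigid: a master seed spawns one child seed per
slot, each slot's draw and state initialization consume only its child
stream, and the pool is canonically ordered before drawing. The assignment
is therefore a pure function of `(model, pool, seed)`, stable under pool
reordering, and fully recorded in a manifest (slot index, function name,
`maxInput`, child seed).

Because every learnable function initializes to ReLU, a stochastically
replaced model whose pool excludes Leaky ReLU and ELU computes *exactly*
the same function as the all-ReLU base until training starts — surgery
changes the trainable function class, not the starting point.

## Ensembles and fusion

`create_ensemble()` generates $N$ stochastic replacements with distinct
child seeds and fine-tunes each with a user-supplied trainer.
`fuse_sum()` adds post-softmax score matrices and takes the per-sample
argmax; `fuse_masks()` adds per-pixel score arrays and takes the per-pixel
argmax, which on hard one-hot member masks is exactly a majority vote (the
suite checks it against a brute-force vote oracle). Argmax ties resolve to
the lowest class index, deterministically. Named recipes (`FusRan3/10/20`,
`FusAct3/10`, `FusAR20`) are thin compositions: `FusAct10` fuses the ten
uniform-replacement stand-alone models, `FusRan20` stacks two `FusRan10`
pools at `maxInput` 1 and 255, `FusAR20` concatenates `FusAct10` and
`FusRan10`.

The sum rule operates on post-softmax scores, not logits — summed scores
are comparable across members and scaling all inputs by a common positive
constant cannot change a decision.

## Training contract

`train_config()` reproduces the published fine-tuning settings as defaults:
batch size 32, learning rate $10^{-4}$ (classification) / $10^{-3}$
(segmentation), 30 / 50 epochs, augmentation on (first 30 epochs for
segmentation), inverse-frequency class weighting for segmentation, input
224×224. Choices the published table leaves open are made explicit and
configurable:

* **Optimizer** — SGD with momentum 0.9, the conventional choice for such
  fine-tuning setups.
* **Loss** — cross-entropy (pixel-wise and class-weighted for
  segmentation), the conventional pairing with softmax outputs.
* **Gradient clipping** — the global gradient norm of each minibatch is
  clipped to 5 before the update. Per-channel activation parameters
  accumulate gradients over every pixel of a feature map, so their raw
  norms can dwarf weight gradients by orders of magnitude; without
  clipping no single learning rate serves all nine pool members.
* **Augmentation geometry** — horizontal and vertical reflection each with
  probability 1/2, then independent axis rescales drawn uniformly from
  $[1,2]$, bilinear interpolation, center crop back to the original shape.
  Masks receive the identical draws with nearest-neighbor interpolation so
  labels stay integral and aligned. Images travel to the model at 224×224
  by bilinear resize; predicted masks travel back to the original size by
  nearest neighbor.

APLU's L2 penalty joins the loss only during training; forward evaluation
is penalty-free.

## Synthetic fixtures and the tiny CNN

The generators stand in for real classification and skin-segmentation
datasets; they emulate the *shape* of the two tasks, not the intensity
statistics of any real dataset — passing tests demonstrate the machinery,
not clinical performance.

* `gen_classification()` — per-class sinusoidal gratings (class-specific
  frequency and orientation, random phase per image) plus Gaussian noise,
  clipped to $[0,1]$. At zero noise a frequency-domain nearest-centroid
  rule is perfect, so classes are separable by construction; `noise_sd`
  controls difficulty.
* `gen_segmentation()` — random filled ellipses with a warm, skin-like
  color cluster on a cooler background cluster; the ground-truth mask
  equals the painted pixels exactly.
* `tiny_cnn()` — a conv/activation/pool stack (He initialization, 3×3
  kernels, 8 filters) ending in a dense softmax head, or a mirrored
  pool/upsample variant with a per-pixel softmax for segmentation, with
  exactly `n_act_layers` replaceable activation slots. It is the
  desk-scale stand-in for a full-scale backbone; hooks exist to express a
  real backbone in the same layer vocabulary via `model_graph()`.

All generation and training is a pure function of its seed: the RNG is
scoped, single-threaded and restored after use.

## The desk benchmark

`desk_bench()` runs the toy-scale analogue of the headline comparison:
3 classes × 60 images at 32×32×3, a 2:1 stratified train/test split, a
single all-ReLU `tiny_cnn` versus a 5-member stochastic ensemble of the
same base, everyone trained identically (6 epochs, SGD momentum 0.9,
learning rate 0.05, batch 32, no augmentation in the loop — a
random-initialized 8-filter network neither needs nor benefits from the
full fine-tuning recipe). One run takes well under a minute; the
acceptance suite averages 10 seeds and asserts the directional claim that
the ensemble's mean test accuracy is at least the single model's.

Two sizing choices matter and were fixed once, by design:

* **Difficulty.** At the generator's mild default noise (0.15) every model
  tests at 100% and the comparison is a vacuous tie; at 0.45 members
  collapse to chance and the benchmark measures optimizer stability
  instead of ensemble diversity. The benchmark default is `noise_sd =
  0.35`, where the single baseline sits visibly below ceiling while the
  task remains learnable.
* **Scale.** Problem sizes (60 × 32×32 images, 5 members, 6 epochs, and a
  smaller 16×16 × 3-member sweep inside the property tests) were chosen so
  the entire suite runs in minutes on one CPU.

## Evaluation statistics

* `accuracy()` — the fraction of true predictions.
* `pixel_f1()` — $2tp / (2tp + fn + fp)$ with counts aggregated over *all
  pixels of all images* of a dataset, not averaged per image, so the score
  is independent of how pixels are distributed across images. The
  degenerate empty-truth/empty-prediction case is defined as 1.
* `wilcoxon_signed_rank()` — the paired two-sided signed-rank test used to
  compare methods across datasets. Zero differences are dropped and ties
  mid-ranked. For up to 12 nonzero pairs the p-value is *exact*: the full
  distribution of the positive-rank sum over all $2^m$ sign assignments is
  built by convolution over the observed (doubled) mid-ranks, so ties are
  handled exactly — something the standard exact tables cannot do. Larger
  samples fall back to the tie-corrected normal approximation with
  continuity correction. The suite checks the exact branch against an
  independent brute-force enumeration and, on tie-free data, against
  `stats::wilcox.test(exact = TRUE)`.
* `eval_report()` — per-dataset metric table, averages, ranks by average,
  and the pairwise Wilcoxon p-value matrix.

## Numerical notes and limitations

* All computation is in R doubles; the gradient and init-equivalence
  checks are specified in 64-bit arithmetic and pass exactly (the
  ReLU-equality at initialization holds to max-abs-difference 0, not
  merely within tolerance, because every term added to ReLU is exactly
  zero at the initial parameters and the SReLU upper branch
  $t_r + 1\cdot(x - t_r)$ is exact in IEEE arithmetic for these
  magnitudes).
* Interpolation (augmentation rescale, 224×224 resize, mask travel) is
  delegated to EBImage; bilinear for intensities, nearest for labels.
* The tiny CNN is CPU-sized: no residual connections, batch norm, or
  atrous convolutions. Full-scale backbones are out of scope; the surgery
  operates on any model expressed in the `model_graph` layer vocabulary.
* Stochastic-replacement draws are uniform i.i.d. per slot with
  replacement; no weighting of the pool is implemented.
* `FusAct3`'s member list (wMeLU, MeLU, PReLU) follows the published
  lightweight recipe; `select_best()` provides the generic
  pick-the-top-$n$ alternative.
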