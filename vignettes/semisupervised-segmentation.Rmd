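---
title: "Semi-supervised segmentation with Mean-Teacher training and stability-scored pseudo-labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised segmentation with Mean-Teacher training and stability-scored pseudo-labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stabseg)
```

## The problem

Dense pixel-level annotation of volumetric medical images is expensive, so a
common compromise is *sparse slice-wise annotation*: an expert densely labels
a few slices per volume and leaves the rest unannotated. Because adjacent CT
sections are highly correlated, the unlabeled neighbours of a labeled slice
carry nearly the same information as the labeled slice itself — an ideal
setting for semi-supervised learning. The motivating application is
segmentation of interstitial lung disease (ILD) patterns — honeycombing,
ground-glass opacity, reticular and linear opacities, consolidation — whose
CT appearances are textures with overlapping intensity ranges, restricted to
the lung region.

`stabseg` implements a complete semi-supervised training procedure for this
regime, combining two complementary ways of exploiting unlabeled slices:

1. **Consistency regularization (Mean-Teacher).** A *teacher* network, whose
   weights are an exponential moving average (EMA) of the *student*'s,
   predicts each batch member under independent input-noise perturbations
   (plus dropout on the student). The student is penalized for disagreeing
   with the teacher, on labeled and unlabeled members alike.
2. **Selective self-training.** After each training round, the teacher
   pseudo-labels the remaining unlabeled slices. Pseudo-labels are ranked by
   a *checkpoint-stability score* and only the most stable fraction is
   admitted into the labeled set before the next training round. This
   follows the selective re-training idea of the ST++ line of
   work: reliability is judged by how early in training a prediction
   stabilized, not by confidence alone.

## Model and losses

Let $p_t(x)$ be the softmax probability that pixel $x$ belongs to class $t$
($t = 0, \dots, T-1$) and $y_t(x)$ the one-hot reference. Pixels outside the
region of interest carry the reserved ignore value (255) and are excluded
from every sum below.

**Supervised loss.** A compound of soft-dice and focal terms,
$$L_{sup} = (1 - \rho)\, L_{Dice} + \rho\, L_{FL}, \qquad \rho = 0.75,$$
with the soft-dice loss
$$L_{Dice} = 1 - \frac{1}{|C|} \sum_{t \in C}
  \frac{2 \sum_x p_t y_t}{\sum_x p_t^2 + \sum_x y_t^2 + \varepsilon},
  \qquad \varepsilon = 10^{-6},$$
where $C$ is the set of classes present in the reference (classes absent
from the truth are skipped so no term degenerates to $0/0$), and the focal
loss
$$L_{FL} = \frac{1}{N} \sum_x \sum_t \beta_t (1 - h_t)^\gamma (-\log h_t),
  \qquad h_t = \begin{cases} p_t & y_t = 1 \\ 1 - p_t & y_t = 0,\end{cases}$$
with $\gamma = 2$. Probabilities are clamped to $[10^{-7}, 1 - 10^{-7}]$
before the logarithm, and the analytic gradient is zero where the clamp is
active, so the implemented loss is exactly differentiable everywhere (the
test suite verifies all gradients against central finite differences). The
class weights $\beta_t$ default to normalized inverse class frequencies
computed from the *human-labeled* slices of the current labeled set
(pseudo-labels are excluded to avoid drift), rescaled to mean 1; uniform and
explicit modes are available. The per-pixel focal sum runs over all $T$
one-vs-rest terms by default; a `true_class`-only mode is provided behind a
switch since either reading of the per-class sum is defensible.

**Consistency loss.** The mean squared difference between teacher and
student probability maps,
$L_{con} = \mathrm{mean}_x \, \| f(x; \theta^*) - f(x; \theta) \|^2$,
computed over ROI pixels of every batch member. The total objective is
$L_{total} = L_{sup} + \lambda L_{con}$ with a Gaussian ramp
$\lambda(s) = \lambda_{max} \exp\!\big(-5 (1 - \min(s/L, 1))^2\big)$ that
restarts at each round, so each round first concentrates on the (newly
expanded) labeled data. The ramp length $L$ defaults to 30% of a round's
steps.

**EMA teacher.** After every student step $z$,
$\theta^*_z = \alpha \theta^*_{z-1} + (1 - \alpha) \theta_z$. Two smoothing
phases are used: a faster one while the student is still poor, a slower one
afterwards. The canonical coefficients are $\alpha = 0.99$ (ramp-up) and
$0.999$ (main), which correspond to averaging windows of roughly $1/(1 -
\alpha) = 100$ and $1000$ steps — appropriate when a round lasts tens of
thousands of steps. A desk-scale round here lasts only a few hundred to a
couple of thousand steps, so `run_config()` scales the horizons to
$\alpha = 0.95/0.99$ (windows of 20/100 steps, the same fraction of a
round); with the canonical values the teacher would still be dominated by
its random initialization when the round ends. `ema_config()` itself
defaults to the canonical 0.99/0.999. The teacher never receives gradients,
is evaluated with dropout off (input noise only) during training forwards,
and with all perturbations off when producing pseudo-labels or reported
segmentations. All reported dice values use the teacher.

## Stability-scored selection

During each round, $Q = 4$ teacher snapshots are saved at 25/50/75/100% of
the round's steps. For an unlabeled slice $u_i$, let $Y^p_{ij}$ be the
argmax mask predicted by checkpoint $j$. The stability score is
$$s_i = \sum_{j=1}^{Q-1} \mathrm{meanIoU}(Y^p_{ij},\, Y^p_{iQ}) \in [0, Q-1],$$
where meanIoU averages per-class IoU over the classes appearing in either
mask. $s_i = Q - 1$ iff every checkpoint agreed with the final prediction.
Scores are sorted in descending order (ties broken by ascending image id so
selection is a pure function of its inputs) and the top 25% of the
*remaining* pool is admitted each round, carrying the final checkpoint's
mask as its label. With a pool of 120 this admits 30, 22 and 17 slices over
three rounds. Admission conserves the total record count, never overwrites
a human label, and tags each record with its provenance and admitting
round.

## The training procedure

Rounds after the first continue from the previous round's student and
teacher by default (`round_init = "warm"`), with the consistency ramp and
EMA phases restarting so each round first re-anchors on the enlarged
labeled set. Re-initializing every round from scratch (`"scratch"`) is the
purist's selective re-training variant — it lets the expanded labeled set
shape early features — but at desk scale it demands a per-round step
budget that grows with the labeled set: with the fixed budget used here,
from-scratch later rounds underfit and validation dice degrades rather
than improves, so warm continuation is the default. Batches contain
exactly 1 labeled and 3 unlabeled slices; an epoch visits
every labeled slice at least once, and the unlabeled side cycles through
reshuffled permutations. Each member is augmented once per step (shared
geometric view), and the student and teacher then receive *independent*
additive input noise — the consistency term needs aligned geometry for its
pixel-wise MSE to be meaningful, so only the photometric perturbation
differs between the two forwards. When the consistency weight is zero the
loop skips unlabeled members entirely; this makes the semi-supervised
pipeline with $\lambda \equiv 0$ bit-identical to the plain supervised
baseline under shared seeds, which the test suite asserts.

The optimizer is RMSprop (momentum-free adaptive, learning rate $10^{-3}$,
decay 0.9). Round $r$ runs entirely under seed `seed + r`, making every
quantity in the package bit-reproducible.

## The backbone

Two architectures are provided. The default `tiny` variant is a three-layer
3×3 convolutional stack (width 16, receptive field 7×7, ≈4.9k parameters)
with dropout (rate 0.5) on its final feature map — deliberately small so a
full CPU study finishes in minutes. The `multires` variant is a miniature
parallel multi-resolution network: a full-resolution stream is maintained
throughout, lower-resolution streams run in parallel, and exchange blocks
repeatedly fuse all streams by resize-and-sum. These are the two defining
properties of high-resolution segmentation backbones; the full-scale
architecture is out of scope here and the miniature is not a replica.
Convolutions are computed as nine shifted BLAS matrix products over a
zero-padded plane (compiled), with hand-derived backpropagation; batches
are stacked into single matrix operations. Forward determinism,
initialization determinism, and gradient exactness against central finite
differences are all under test.

## The synthetic benchmark

The clinical data the method targets is private, so the package ships a
seeded generator that reproduces the *structure* of the problem rather than
its anatomy:

- Each volume is a stack of 64×64 slices with a two-ellipse, lung-like ROI;
  everything outside is ignore-labeled.
- Class regions are the argmax of per-class Gaussian-smoothed random
  fields, evolved from slice to slice by small random elastic warps with a
  stationary innovation term — adjacent slices are strongly correlated,
  distant ones decorrelate, mimicking consecutive CT sections.
- Each class combines a base intensity with a characteristic texture
  (speckle dots, honeycomb-like cell walls, oriented striations, blob
  clusters, or none) plus Gaussian pixel noise. Base intensities overlap
  (0.30/0.44/0.58/0.50 for the default four classes) so classes are only
  separable by combining intensity with local texture. The structured
  texture is mean-centred within each class region, so the region mean is
  an unbiased estimate of the base intensity — a testable identity of the
  generator.
- Sparse annotation: 4 evenly spaced labeled slices per 28-slice volume;
  the 3 neighbours on each side of every labeled slice form the unlabeled
  pool (6 per labeled slice, hence a fixed 6:1 unlabeled:labeled ratio).
  The default benchmark uses 9 volumes split 5/2/2 by volume (never by
  slice), giving 20 labeled + 120 unlabeled training slices and 8 slices
  each for validation and test.

What passing on this benchmark does *not* show: anatomical realism, scanner
or slice-thickness effects, inter-rater label noise, 3-D lesion continuity
beyond the elastic-warp correlation, or performance at clinical resolution
(512×512, 8 classes — an 8-class texture mode exists but is not the
default). The benchmark's role is to exercise every mechanism of the method
end-to-end under conditions where unlabeled data demonstrably carries
usable information.

## Numerical and design choices

- **Dice form.** The soft-dice loss above is the standard formulation from
  the dice-loss literature; a literal sum of $-(p_t - y_t)^2/(p_t^2 +
  y_t^2)$ is negative and unbounded below and is not used.
- **Probability clamping** at $10^{-7}$ with a locally flat gradient keeps
  the focal term finite without biasing well-calibrated pixels.
- **Checkpoint placement** at 25/50/75/100% of a round spreads the
  stability probe across training; the final snapshot doubles as the
  pseudo-label source.
- **Ties and degenerate inputs.** Selection ties break by ascending image
  id; per-class dice over an image skips classes absent from both masks;
  an empty unlabeled pool degrades the round to supervised-only training
  with a warning; `epochs_per_round = 0` returns an untrained model with an
  explicit error flag.
- **Even labeled-slice spacing** in the generator is an arbitrary stand-in:
  how experts choose which slices to annotate is not modelled.
- **Problem sizes.** The shipped study runs 3 rounds with a fixed budget
  of 400 optimization steps per round (20 epochs of the initial 20-slice
  labeled set; later rounds run the whole-epoch count closest to the same
  budget); a supervised-only arm trains for one such round on the labeled
  slices alone with the identical network, loss and augmentation. These
  sizes were chosen so the complete two-arm, three-seed study runs on a
  single desktop CPU core in minutes at 64×64 resolution.

## Known limitations

- The miniature backbones cap achievable dice well below what a full-scale
  network reaches on clinical data; results here support *relative*
  comparisons (semi-supervised vs supervised-only, trends across rounds and
  unlabeled fractions), not absolute performance claims.
- The stability score requires the checkpoint predictions to fit in memory
  one slice at a time; scoring cost grows linearly with $Q$ and the pool.
- Pseudo-label errors admitted in early rounds are never revoked; the
  selection fraction is the only curriculum knob (no per-pixel filtering).
  Because stability is judged at the image level, a pseudo-mask that
  *stably omits* a hard class can score highly, and re-training then
  reinforces the omission — the classic confirmation bias of
  self-training. At this benchmark size (20 labeled slices) the
  semi-supervised gain consequently varies across random benchmarks, and
  occasional seeds show no benefit; reported study quantities are
  therefore means over replicate seeds.
- The generator draws each volume's texture parameters independently;
  domain shift between volumes is mild compared to real scanners.
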