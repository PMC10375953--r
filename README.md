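# stabseg

Semi-supervised multi-class segmentation of sparsely annotated image
volumes, built for the *sparse slice-wise annotation* regime of volumetric
medical imaging: an expert densely labels a few slices per CT-style volume
and the many unlabeled neighbour slices — highly correlated with the
labeled ones — are exploited by the training procedure instead of being
discarded. The motivating application is segmentation of interstitial lung
disease (ILD) texture patterns inside a lung mask.

The method combines two uses of the unlabeled slices:

- **Mean-Teacher consistency training.** A teacher network with weights
  θ\* = α θ\*′ + (1 − α) θ (an exponential moving average of the student θ)
  predicts every batch member under independent input perturbations; the
  student pays an MSE consistency penalty
  L<sub>con</sub> = ‖f(x; θ\*) − f(x; θ)‖² on labeled and unlabeled members
  alike, weighted by a ramp λ that grows from ≈0 to 1 within each round.
  The supervised term on labeled members is a dice + focal compound,
  L<sub>sup</sub> = (1 − ρ) L<sub>Dice</sub> + ρ L<sub>FL</sub> with
  ρ = 0.75, γ = 2, and inverse-frequency class weights β<sub>t</sub>.
- **Selective self-training with stability scoring.** After each round, the
  teacher pseudo-labels the remaining unlabeled slices with Q = 4 saved
  checkpoints; each slice gets a stability score
  s<sub>i</sub> = Σ<sub>j&lt;Q</sub> meanIoU(Y<sub>ij</sub>, Y<sub>iQ</sub>) ∈ [0, Q−1],
  and the top-25% most stable pseudo-labels are admitted into the labeled
  set for the next round. Stability over training, not confidence, is the
  reliability proxy.

Everything runs on a plain CPU: the segmentation backbones are deliberately
miniature (a 3-layer convolutional stack by default; a parallel
multi-resolution variant is included), with convolutions and
backpropagation implemented in-package on BLAS. The clinical data such
methods target is private, so the package ships a seeded synthetic texture
benchmark that reproduces the structure of the problem — organ-like ROIs,
overlapping-intensity texture classes, correlated adjacent slices, sparse
evenly spaced annotations — and every result below is computed on it.

## Worked example

```r
library(stabseg)

data <- default_benchmark(seed = 1)   # 9 volumes, split 5/2/2 by volume
data
#> dataset_state: 20 labeled (0 pseudo), 120 unlabeled, 8 val, 8 test

cfg <- run_config(seed = 1, steps_per_round = 400)   # 3 rounds, top-25% admission
fit <- stabseg(data, cfg)
fit
#> stabseg fit (semi-supervised): 3 round(s), tiny backbone, 4 classes
#> validation avg dice by round: 0.576 -> 0.628 -> 0.634

summary(fit)
#> Per-round summary:
#>  round n_labeled n_unlabeled n_admitted val_dice mean_sup_loss
#>      1        20         120         30   0.5759        0.5580
#>      2        50          90         22   0.6280        0.3598
#>      3        72          68         17   0.6339        0.3212

evaluate_split(fit$model, data$test, 4)
#> Per-class dice (mean ± sd over images):
#>   class 0: 0.9370 ± 0.0289 (n = 8)
#>   class 1: 0.7727 ± 0.0270 (n = 8)
#>   class 2: 0.6385 ± 0.1407 (n = 8)
#>   class 3: 0.2295 ± 0.1266 (n = 8)
#>   Avg: 0.6444
```

Reading the output: each round admits the most stable quarter of the
remaining unlabeled pool (30, 22, 17 slices), the labeled set grows
20 → 50 → 72, and validation dice improves round over round. The same
configuration with `method = "supervised"` trains the identical network on
the 20 labeled slices alone:

```r
base <- stabseg(data, cfg, method = "supervised")
evaluate_split(base$model, data$test, 4)$average
#> [1] 0.5576
```

so on this seed the unlabeled slices are worth **+8.7 dice points**
(0.6444 vs 0.5576). Per-class numbers show where the gain comes from: the
easy homogeneous class is near ceiling either way, while the textured
classes (speckle, honeycomb-like) benefit most; the striation class is
hardest for the small receptive field. `plot(fit)` shows the loss trace
and the per-round validation dice; `predict(fit, records)` returns label
masks or probability maps for new slices.

A command-line interface wraps the same functions
(`system.file("cli", "stabseg", package = "stabseg")`):

```sh
stabseg generate --out bench/ --seed 7
stabseg train    --data bench/ --out run/ --seed 7
stabseg evaluate --data bench/ --fit run/fit.rds --out run/test.csv
stabseg score    --data bench/ --fit run/fit.rds --out run/scores.json
```

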