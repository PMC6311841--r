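# sonodae

Bias-field correction and stacked-denoising-autoencoder classification for
breast ultrasound lesion ROIs.

## What problem this solves

Sonograms of breast lesions suffer from two nuisances that obscure the
diagnostic cue radiologists use most — the lesion margin: multiplicative
speckle, and a smooth spatial drift of brightness (intensity
inhomogeneity, the "bias field"). `sonodae` is for researchers studying
whether removing the bias field improves automatic benign/malignant
classification on small lesion-centered regions of interest (ROIs). It
provides, as plain R functions over numeric matrices:

- **Bias-field correction.** The observed image is modeled additively as
  `O_i = mu_psi(i) + P(x_i, y_i) + n_i`: a foreground (lesion) or
  background mean, plus a bivariate polynomial surface `P` of degree `N`
  (default 2, no constant term) over coordinates normalized to
  `[-1, 1]^2`, plus noise. A fuzzy cell-based bipartition supplies the
  foreground/background labels; region means and polynomial coefficients
  are then estimated in one joint linear least-squares solve minimizing
  `eps^2 = (1/N_pix) * sum_i (O_i - mu_psi(i) - P_i)^2`, alternating with
  re-bipartition of the corrected estimate. Corrected image:
  `clip(O - P_hat, 0, 1)`.
- **SDAE classifier, from the equations.** Tied-weight denoising
  autoencoder layers (`Z = S(W x_corrupted + b)`,
  `x' = S(W^T z + b')`), greedy layer-wise pretraining on squared
  reconstruction error, decoder removal, a sigmoid logistic-regression
  head, and full-batch gradient-descent fine-tuning (`w <- w - alpha *
  dE/dw`). All gradients are analytic and finite-difference-verified.
- **Evaluation.** Confusion counts (malignant positive) and the
  precision / recall / specificity / accuracy / F-measure suite.
- **Synthetic phantoms.** A seeded generator of 28×28 ultrasound-like
  lesion ROIs — hypoechoic lesion, speckle, known injected polynomial
  bias field, benign (smooth) vs malignant (lobulated margin + missing
  boundary arc) — so the whole pipeline is testable offline with known
  ground truth.
- **Two-arm experiments.** `run_experiment()` trains identical
  classifiers (same split, same seeded initial weights) on original and
  corrected copies of the same dataset and reports both arms side by side.

## Worked example

Correct a phantom with a known injected bias field, then check the
recovery:

```r
library(sonodae)

bias <- polynomial_surface(c(0.02, 0.01, 0.06, -0.03, 0.05), degree = 2)
spec <- phantom_spec(class_label = "malignant", speckle_sigma = 0.05,
                     bias = bias, seed = 42)
ph  <- render_phantom(spec)
res <- correct_image(ph$image, degree = 2)

cor(as.vector(res$bias), as.vector(ph$bias_field))
#> [1] 0.9984742
res
#> <correction_result 28x28: eps2=9.013e-04, 2 outer iters, converged=TRUE>
```

The estimated surface correlates at 0.998 with the injected field, and the
fit converged in 2 alternation rounds. A small end-to-end two-arm
experiment (reduced sizes so it runs in seconds; the full-size defaults
take a couple of minutes):

```r
cfg <- experiment_config(n_benign = 20, n_malignant = 20,
                         test_fraction = 0.3, data_seed = 3,
                         train = sdae_config(hidden_sizes = c(32, 8),
                                             epochs_pretrain = 40,
                                             epochs_finetune = 400,
                                             seed = 3))
run_experiment(cfg)
#> Two-arm original-vs-corrected experiment
#>   train n=28, test n=12 (6 malignant)
#>   original  TP=0 TN=6 FP=0 FN=6 | acc 0.50 prec 0.00 rec 0.00 spec 1.00 F 0.00
#>   corrected TP=0 TN=6 FP=0 FN=6 | acc 0.50 prec 0.00 rec 0.00 spec 1.00 F 0.00
```

(At these deliberately tiny training sizes neither arm learns the class
boundary — the report shows the format. The full-size experiment in the
acceptance script, 170 ROIs and 256/64 hidden units, prints original-arm
test accuracy 0.67 and corrected-arm 0.93 at seed 1; across seeds the
corrected arm is consistently ahead except when the original arm is
already at ceiling on an easy draw.)

Confusion metrics from counts:

```r
metric_suite(confusion_counts(TP = 18, TN = 15, FP = 5, FN = 2))
#>   precision      recall specificity    accuracy   f_measure
#>   0.7826087   0.9000000   0.7500000   0.8250000   0.8372093
round_half_up(metric_suite(confusion_counts(18, 15, 5, 2)))
#>   precision      recall specificity    accuracy   f_measure
#>        0.78        0.90        0.75        0.83        0.84
```

## Method vignette

`vignettes/methods.Rmd` documents the model assumptions, the bipartition's
spatial constraint, the full-batch training-rate choices, what the phantom
generator does and does not emulate, and known limitations.
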