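# thcnet

Parameterized entropy losses for multitask cancer-recurrence prediction.

## What it does

When a neural network is trained to classify, the loss is almost always the
Shannon cross-entropy. Shannon is, however, only the α = 1 member of the
Tsallis–Havrda–Charvat (THC) family of entropies,

    H_alpha(p) = (1 - sum_i p_i^alpha) / (alpha - 1),      alpha > 0,

with associated cross-entropy
`H_alpha(q:p) = (1 - sum_i q_i^(alpha-1) p_i) / (alpha - 1)` and, for a
batch of N patients with binary labels p_n and predicted probabilities q_n,
the prediction loss

    L_pred_alpha = (1 - (1/N) sum_n [q_n^(alpha-1) p_n + (1-q_n)^(alpha-1) (1-p_n)]) / (alpha - 1).

`thcnet` implements this family exactly (with analytic gradients), embeds it
in a multitask 3-D encoder–decoder that jointly reconstructs an input CT-like
volume and predicts recurrence from the bottleneck features fused with
clinical covariates, and provides the five-fold cross-validation α-sweep
protocol that asks: *for which α does the THC loss beat Shannon, and is the
difference statistically significant?* A row of the sweep is flagged when its
five-fold mean accuracy exceeds the Shannon baseline **and** the paired
t-test p-value is below 0.05.

Because the patient data behind this methodology are private, the package
ships a synthetic cohort generator that plants a controllable label signal
in lesion geometry/contrast and in two blood-work covariates, so the entire
pipeline is testable end to end.

Audience: methods researchers studying loss functions for small-sample
medical prediction, and anyone needing a self-contained, dependency-light R
implementation of THC losses with verified gradients.

## Worked example

```r
library(thcnet)

# THC loss mathematics
shannon_entropy(c(0.9, 0.1))          # 0.325083
thc_entropy(c(0.5, 0.5), alpha = 2)   # 0.5
binary_thc_loss(labels = c(1, 0), predictions = c(0.8, 0.2), alpha = 2) # 0.2

# synthetic cohort with a strongly planted signal
cohort <- generate_cohort(cohort_config(
  n_patients = 60, volume_shape = c(16, 16, 8),
  prevalence = 0.5, signal_strength = 8, seed = 1
))

# small alpha sweep with shared folds
cfg <- network_config(volume_shape = c(16, 16, 8), epochs = 4, seed = 1)
split <- kfold_split(length(cohort), 5, seed = 1)
report <- alpha_sweep(cohort, cfg, alphas = c(0.5, 1, 2), split)
report
#> alpha fold1 fold2 fold3 fold4 fold5 average sd    p_value  sig
#> 0.5   0.50  0.75  0.83  0.83  0.58  0.70    0.15  0.237
#> 1     0.67  0.58  0.50  0.58  0.75  0.62    0.10  N/A
#> 2     0.83  0.42  0.83  0.83  0.83  0.75    0.19  0.0976
```

Both THC rows average above the Shannon baseline here, but at this toy scale
(60 patients, 12-patient folds) neither clears the significance rule — the
fold variance is too large, which is exactly the behaviour the protocol is
designed to expose. The five folds are identical across rows, so the Shannon
comparison is paired; `p_value` is a paired t-test on per-fold accuracy
differences, one-sided in the observed direction, and `*` would mark rows
whose mean beats Shannon at p < 0.05.

The package also ships the published five-fold accuracy tables of an α sweep
on a head–neck (n = 434) and a lung (n = 146) recurrence cohort as reference
data:

```r
tab <- reference_sweep_table("headneck")
summarize_folds(as.numeric(tab[tab$alpha == 1.5, paste0("fold", 1:5)]))
#> $average 0.802   $sd 0.0694   (printed: 0.80 / 0.07)
```

## Command line

```sh
Rscript inst/cli/thcnet.R generate --config experiment.yaml
Rscript inst/cli/thcnet.R sweep    --config experiment.yaml
Rscript inst/cli/thcnet.R report   out/sweep_report.json
```

The YAML config selects either synthetic generator parameters or a directory
of per-patient NIfTI volumes plus a clinical CSV (the layout `write_cohort()`
emits), the network settings, and the α grid.

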