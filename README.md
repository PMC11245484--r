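# ppgfatigue

Fatigue detection from single-channel photoplethysmography (PPG), end to
end: a seeded simulator of two-condition PPG cohorts, discrete-wavelet
shrinkage denoising, window segmentation with derived heart-rate and
breathing channels, compact 1D ResNet/Xception-style convolutional
extractors coupled to a bidirectional LSTM, and subject-wise
cross-validated evaluation with per-subject majority voting.

**Who it is for.** Researchers prototyping wearable-PPG fatigue or
drowsiness classifiers who need a fully reproducible, dependency-light
reference pipeline: every stage — from waveform synthesis to the
backpropagation of the hybrid network — is implemented in this package (R
plus RcppArmadillo kernels) and tested against independent oracles.

## The method

Windows of a PPG recording are classified as *fatigue* vs *non-fatigue*;
a subject's recording is labelled by the majority vote of its windows.
Labels come from the Karolinska Sleepiness Scale (KSS ≥ 4 ⇒ fatigue).

* **Denoising** is wavelet shrinkage: a k-level DWT splits the signal into
  detail bands cD₁..cD_k and an approximation cA_k; details are
  thresholded (hard: zero-or-keep; soft: `sgn(c)(|c| − γ)` past γ) with
  γ = σ√(2 ln n) (universal), hybrid SURE, or the minimax rule, where
  σ = median(|cD₁|)/0.6745; the signal is rebuilt by the inverse DWT.
* **Classification** feeds 1056-sample windows through a 1D residual (or
  depthwise-separable) extractor with total stride 8 — the reference
  36-layer ResNet emits a 15 × 132 feature map, the 37-layer Xception a
  64 × 132 one — then a BiLSTM, mean-pooling, and a scaled softmax
  σ(z)ᵢ = e^{βzᵢ}/Σⱼe^{βzⱼ}. Training minimises cross-entropy by SGD with
  momentum, ΔW(t+1) = −(lr·wd/r)W − (lr/batch)∂C/∂W + mΔW(t), with
  gradient-norm clipping.
* **Evaluation** is subject-disjoint cross-validation (k-fold over
  subjects or leave-one-subject-out), pooling window predictions for
  accuracy/precision/recall/F1, rank-based AUC, MAE/MSE/RMSE, and a gate
  requiring all of AUC, F1, precision and accuracy > 0.825.

No real recordings ship with the package; a seeded simulator generates
two-class cohorts whose conditions differ in beat-interval variability and
dicrotic-wave amplitude, contaminated by baseline wander, powerline
interference and white noise, with KSS/PVT metadata calibrated to the
bundled 12-participant assessment table. See the methods vignette
(`vignettes/ppg-fatigue-methods.Rmd`) for the full account.

## Worked example

Simulate a small cohort, segment it, and run subject-wise 3-fold
cross-validation with the desk-scale hybrid model (≈ 50 s on one CPU):

```r
library(ppgfatigue)

cohort  <- simulate_cohort(6, synth_config(duration_s = 102, seed = 42))
windows <- segment_cohort(cohort)
plan    <- make_folds(unique(windows$subject_id), "kfold_by_subject",
                      k = 3, seed = 42)
report  <- run_cv(windows, model_config(epochs = 40, seed = 42), plan)
report
#> <cv_report> 3 folds, 144 test windows
#> pooled: accuracy 1, precision 1, recall 1, F1 1, AUC 1
#> subject votes correct: 12/12
tidy(report)
#> # A tibble: 3 × 8
#>    fold n_train n_test accuracy precision recall    f1 final_loss
#>   <int>   <int>  <int>    <dbl>     <dbl>  <dbl> <dbl>      <dbl>
#> 1     1      96     48        1         1      1     1   0.00154
#> 2     2      96     48        1         1      1     1   0.000969
#> 3     3      96     48        1         1      1     1   0.00110
gate(report)
#> [1] TRUE
```

Every window of the held-out subjects is classified correctly and all
twelve recording-level majority votes are right: the model recovers the
simulated class structure (attenuated dicrotic wave, reduced heart-rate
variability) through a fully subject-disjoint protocol. `autoplot(report)`
draws the pooled ROC curve; `glance(report)` adds MAE/MSE/RMSE and the
vote accuracy.

Denoising a 5 dB-SNR recording (soft thresholding, universal rule, db4,
4 levels) against the simulator's known clean signal:

```r
rec   <- cohort$record[[2]]
clean <- rec$clean
pw    <- function(v) mean((v - mean(v))^2)
set.seed(7)
noisy <- clean + rnorm(length(clean), 0, sqrt(pw(clean) / 10^0.5))
den   <- denoise_signal(noisy, "db4", 4, "universal", "soft")
10 * log10(pw(clean) / mean((noisy - clean)^2))  # input SNR
#> [1] 4.96
10 * log10(pw(clean) / mean((den - clean)^2))    # after shrinkage
#> [1] 10.82
```

The cohort summary statistics of the bundled KSS/PVT reference table:

```r
cohort_stats(read.csv(system.file("extdata", "cohort_kss_pvt.csv",
                                  package = "ppgfatigue")))
#> # A tibble: 2 × 6
#>   condition       n kss_mean kss_sd pvt_mean pvt_sd
#>   <chr>       <int>    <dbl>  <dbl>    <dbl>  <dbl>
#> 1 fatigue        12     7.42  0.640     469.   90.7
#> 2 non_fatigue    12     2.83  0.373     356.   28.7
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/ppgfatigue.R` (subcommands `simulate`, `denoise`, `train`,
`evaluate`, `sweep`, `run`).

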