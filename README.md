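# ieegactive

Unsupervised, fully automated classification of task-active intracranial
EEG (iEEG) electrodes.

## The problem

In iEEG studies of cognition, tens to hundreds of electrodes are implanted
per patient, but only a minority record activity modulated by the task —
typically a broadband high-gamma (65–115 Hz) power increase during
stimulus presentation accompanied by a theta-band power decrease.
Identifying these *active* electrodes by expert review is slow and
subjective. `ieegactive` automates it in three steps:

1. **Normalize.** Event-locked 3000 ms epochs (700 ms / 1600 ms / 700 ms
   around word onset, 500 Hz, adjacent bipolar montage) are converted to
   spectrograms: six Bartlett–Hanning band-pass filters, 500 ms windows
   slid by 50 ms, 2-Hz bins, log power z-scored per frequency bin within
   each epoch (`S(t,f)` is the trial average of
   `(S_w(t,f) − μ_w(f)) / σ_w(f)`), then averaged over a band's bins into
   the *mean band power change* `S̄_FB(t)`.
2. **Summarise.** Three interpretable metrics per electrode (11 features):
   *induced power* `IP_FB = Σ_t |S̄_FB(t)|` in six bands; *smoothness
   score*, the lag-1 autocorrelation `Corr(S̄(t), S̄(t−1))` of the two
   theta bands; and *gamma consistency*, the sorted absolute pairwise
   correlations among the low-gamma and split high-gamma power courses.
3. **Cluster.** A two-component Gaussian mixture over electrodes pooled
   from all subjects; the **smaller-weight component is the active
   cluster** (typically 10–30 % of electrodes respond). The posterior of
   that component is the activity score; repeated seeded fits quantify
   robustness.

Evaluation machinery (sensitivity/specificity, rank-based AUC,
leave-one-subject-out cross-validation, anatomical region summaries), a
standard-deviation thresholding baseline, PCA of the metric space, and a
synthetic-signal generator with known ground truth are included, so the
whole pipeline is testable end to end without patient data.

## Worked example

```r
library(ieegactive)

cfg <- synth_config(n_subjects = 2, n_electrodes = 30, n_trials = 20,
                    frac_active = 0.2, seed = 7)
res <- run_pipeline(cfg, n_runs = 20)

res$fit
#> <gmm_result> 1 features, weights 0.233/0.767, active = component 1 (23.3% labelled active)
res$evaluation$confusion[c("sensitivity", "specificity")]
#> $sensitivity: 100      $specificity: 100
res$evaluation$auc
#> [1] 1
res$baseline[c("sensitivity", "specificity")]   # sd > 0.05 thresholding step
#> $sensitivity: 100      $specificity: 84.78261
head(res$labels, 4)
#>   subject_id electrode_id    label     posterior
#> 1        S01           E1 inactive 1.197846e-170
#> 2        S01           E2 inactive 2.452215e-169
#> 3        S01           E3   active  1.000000e+00
#> 4        S01           E4 inactive 2.623248e-156
```

Reading this output: the mixture found an active component holding 23.3 %
of the 60 electrodes (the construction truth drew 20 % actives per
electrode); clustering induced high-gamma power recovered every
constructed label (sensitivity and specificity 100 %, AUC 1.0), while the
thresholding baseline kept all actives but mislabelled ~15 % of inactive
electrodes as active — the same qualitative gap that motivates the
mixture over a fixed cutoff. Posteriors are saturated because the
synthetic effect sizes put the two clusters far apart; real recordings
produce boundary electrodes with intermediate posteriors, which is where
the 100-run repeat protocol (`res$repeat_protocol$agreement`, here 1.0)
becomes informative.

For raw recordings instead of simulations, see `read_signals()`,
`read_layouts()`, `read_events()`, `build_bipolar_montage()`,
`subtract_bipolar()`, `resample_to_500()` and `extract_epochs()`; from an
`epoch_set` onward the path is identical (`analyze_epochs()`,
`fit_gmm()`, …). A thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

## Package layout

- `R/bands.R`, `R/filters.R`, `R/spectrogram.R` — frequency bands, notch /
  FIR filter bank / resampling, z-scored spectrograms and band power.
- `R/montage.R` — contact layouts, bipolar montage, epoching, text I/O.
- `R/metrics.R` — induced power, smoothness score, gamma consistency.
- `R/gmm.R` — seeded EM mixture, smaller-component rule, repeat protocol,
  PCA, thresholding baseline, model serialisation.
- `R/evaluation.R` — confusion metrics, rank AUC, LOSO CV, region summary.
- `R/synthetic.R` — signal- and feature-level generators with truth.
- `R/pipeline.R` — orchestration and artifact writing.
- `vignettes/active-electrode-classification.Rmd` — methods, parameter
  choices and limitations.
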