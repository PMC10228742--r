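# pacpredict

Interictal-vs-preictal classification of long multichannel scalp EEG from
phase–amplitude coupling (PAC) and band spectral features, with a
configurable seizure prediction horizon (SPH).

**Who it is for.** Researchers working on EEG-based seizure prediction who
need a tested, reproducible reference pipeline: state labelling around
annotated seizure onsets, sliding-window feature extraction, seizure-aware
cross-validated classification, and an SPH sweep — plus a synthetic-EEG
generator with controllable coupling so every stage can be exercised
offline, without clinical data.

## The statistic at the core

For a low band with Hilbert phase Φₓ and a high band with envelope a_y,
the phase axis (−180°, 180°] is split into N = 18 bins of 20°. The mean
envelope per bin, normalised to a distribution P, gives the
**modulation index**

    H(P) = −Σⱼ P(j) log P(j)
    MI   = (log N − H(P)) / log N        ∈ [0, 1]

— the Kullback–Leibler distance of P from uniform, scaled by its maximum.
MI ≈ 0 means the high-frequency amplitude ignores low-frequency phase;
MI = 1 means total concentration in one phase bin. MI is computed for all
lower-triangle band pairs of delta/theta/alpha/beta/gamma (the
comodulogram); Welch peak and median frequency per band provide the
frequency-domain comparison. Features feed a random-forest classifier
under seizure-grouped 10-fold cross-validation; accuracy, precision,
recall and F1 are reported per channel and fold, and the whole pipeline
can be re-run at SPH ∈ {5, 10, 15} min with a Kruskal–Wallis comparison of
per-recording accuracies.

## Worked example

Generate a two-hour synthetic recording with one seizure at 6600 s, label
states with a 5-min SPH and 30-min preictal, extract balanced 30-s
windows, and compute the beta–gamma modulation index per window:

```r
library(pacpredict)
cfg <- synthetic_config(fs = 256, duration = 7200, seizure_onsets = 6600, seed = 42)
rec <- generate_recording(cfg)
rec
#> <recording: 1 channel(s), fs = 256 Hz, 7200.0 s, 1 seizure(s)>

sc <- segmentation_config()   # SPH 5 min, preictal 30 min, 30 s / 15 s windows
iv <- label_states(7200, merge_lead_seizures(rec$annotations, sc$cluster_gap_min), sc)
iv
#>   start_s end_s      label seizure_id
#> 1       0  4500 interictal         NA
#> 2    4500  6300   preictal          1
#> 3    6300  6600        sph          1
#> 4    6600  6660      ictal          1
#> 5    6660  7200   unusable         NA

wins <- balance_windows(extract_windows(iv, sc, labels = c("interictal", "preictal")),
                        seed = 1)
table(wins$label)
#> interictal   preictal
#>        119        119

ft <- build_feature_table(rec, wins,
        feature_config(bands = canonical_bands(fs = 256), feature_set = "pac",
                       pairs = list(c("beta", "gamma"))))
aggregate(mi_beta_gamma ~ label, ft, mean)
#>        label mi_beta_gamma
#> 1 interictal  3.557921e-05
#> 2   preictal  2.807381e-03
```

The preictal windows carry ~80× more beta–gamma coupling than baseline —
the generator put it there (preictal χ = 0.8 vs interictal χ = 0.05), and
the feature recovers it. Classifying a four-recording mini-cohort with
grouped folds:

```r
report <- train_eval(tab, rf_config(n_estimators = 100L, min_samples_split = 2L,
                                    max_depth = Inf, k = 4L, seed = 7L))
report
#> <eval_report>
#>   overall: accuracy=1.0000  precision=1.0000  recall=1.0000  f1=1.0000
#>   4 fold-evaluations over 1 channel(s), seed 7

kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))[c("H", "p_value")]
#> $H
#> [1] 7.2
#> $p_value
#> [1] 0.02732372
```

Perfect separation is expected here: the synthetic states differ by
construction and the windows are balanced; see the methods vignette
(`vignettes/pac-seizure-methods.Rmd`) for what a green run does and does
not establish. Real EDF recordings enter through `read_edf()` /
`read_annotations()` (CSV sidecars or summary-text dialect) and multi-file
subjects through `read_manifest()`. A command-line front end covering
`synth / inspect / segment / features / classify / sweep / run` is exposed
via `pac_cli()` (launcher script in `inst/cli/`).

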