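---
title: "Phase-amplitude coupling features for seizure prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-amplitude coupling features for seizure prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Epileptic seizures are preceded, in many patients, by measurable changes in
the scalp EEG. A practical seizure-prediction system must decide, from a
sliding window of EEG, whether the brain is in its between-seizure baseline
(*interictal*) or in the window preceding a seizure (*preictal*). Two time
parameters frame the task: the **seizure prediction horizon (SPH)** — the
buffer between the end of the preictal period and the seizure onset, the
time available for intervention — and the preictal length itself. This
package implements that pipeline end to end: state labelling around
annotated seizure onsets, sliding-window feature extraction, random-forest
classification with seizure-aware cross-validation, and a sweep over SPH
settings, together with a synthetic-EEG generator so the whole chain is
testable without access to clinical databases.

## The coupling statistic

The discriminative feature is **phase–amplitude coupling (PAC)**: the
dependence of a high-frequency band's amplitude on a low-frequency band's
phase. Both series come from zero-phase band-pass filtering followed by the
Hilbert analytic signal: the phase $\Phi_x(t)$ of the low band and the
envelope $a_y(t)$ of the high band. The phase axis $(-180^\circ, 180^\circ]$
is split into $N = 18$ bins of $20^\circ$; the mean envelope per bin,
normalised to a probability vector $P$, gives the **modulation index**

$$
H(P) = -\sum_{j=1}^{N} P(j)\,\log P(j), \qquad
\mathrm{MI} = \frac{\log N - H(P)}{\log N},
$$

the Kullback–Leibler distance of $P$ from the uniform distribution, scaled
to $[0, 1]$. MI is 0 when the envelope ignores phase and 1 when all
amplitude concentrates in one bin. It is invariant to the logarithm base
(asserted in the tests) and to positive rescaling of the envelope. Empty
phase bins contribute nothing via the $0 \log 0 = 0$ convention; with 30-s
windows at 256 Hz and 18 bins they are vanishingly rare. Bin $j$ covers
$[-180 + 20(j-1), -180 + 20j)$ degrees, with exactly $+180^\circ$ assigned
to bin 18.

Canonical bands are delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30 and
gamma 30–80 Hz. MI is computed for every *lower-triangle* pair (phase band
strictly below the amplitude band) — the comodulogram. For comparison, two
frequency-domain features per band are computed from a Welch spectrum:
**peak frequency** (PSD argmax within the band) and **median frequency**
(smallest frequency at which cumulative band power reaches half the band
total).

## Pipeline and its fixed parameters

| parameter | default | unit | why |
|---|---|---|---|
| window / step | 30 / 15 | s | standard sliding-window grid for this task |
| preictal length | 30 | min | conventional choice for scalp-EEG prediction |
| SPH | 5 (swept 5/10/15) | min | intervention buffer; the sweep is the point |
| phase bins | 18 × 20° | — | standard MI binning |
| Butterworth order | 5 | — | applied forward–backward (zero phase) |
| notch | 50 or 60, Q = 30 | Hz | mains interference sits inside gamma |
| Welch | 2-s Hann, 50% overlap | — | 0.5 Hz resolution, resolves delta |
| mapping range | (−1, 1) | — | max–min normalization of features |
| folds | k = 10, grouped by seizure | — | see below |

Numerical choices worth stating:

* **Zero-phase filtering.** The band-pass is realised as second-order
  sections and applied forward–backward. This doubles the effective order
  but leaves the Hilbert phase unbiased — a causal filter would shift phase
  estimates and corrupt MI. The filter was validated against an independent
  scientific-computing implementation to ~1e-12 during development.
* **Filter once, window later.** Filtering and the analytic transform run
  on the full continuous record; windows are slices of the phase/envelope
  series. Filtering each 30-s window separately would put edge transients
  inside every window. A 1-s guard at each record edge is excluded.
* **Gamma at low sampling rates.** Band upper edges are capped at
  0.45·fs; at 256 Hz the 80 Hz gamma edge stands. Bands that collapse
  entirely (e.g. gamma at 64 Hz) are dropped with a message.
* **High-pass-filtered sources.** Recordings acquired with hardware
  high-pass filtering exclude the delta band
  (`canonical_bands(exclude_delta = TRUE)`), leaving four bands and six
  pairs.

## State labelling

For each retained seizure at onset $t_0$: ictal is the annotated span, SPH
is $[t_0 - \mathrm{SPH}, t_0)$, preictal is the 30 min before that. All
coordinates are seconds from record start, 0-based, half-open. Decisions
the source material leaves open, fixed here:

* **Cluster merging.** A seizure starting within `cluster_gap_min`
  (default preictal + SPH = 35 min) of the previous offset is merged into
  its lead seizure: a follow-on seizure inside the lead's prediction zone
  cannot have a clean preictal of its own.
* **Postictal guard.** Interictal windows must be at least 30 min after
  any seizure offset; the guard is labelled unusable. Without it,
  immediately-postictal EEG would contaminate the baseline class.
* **Insufficient lead-in.** Seizures whose preictal + SPH would run off
  the record start or into the previous seizure are dropped from
  classification (logged); their ictal span stays labelled.
* **Class balance.** Per seizure with $n$ preictal windows, $n$ interictal
  windows are sampled (seeded) and tagged with that seizure's id. The
  interictal pool of a long record is otherwise hours deep and the
  imbalance would inflate apparent accuracy.

## Classification

Features are max–min normalised to (−1, 1) with parameters fitted on
training rows only. Cross-validation is **grouped by seizure**: a seizure's
preictal windows and its paired interictal sample always share a fold.
Adjacent 30-s windows overlap by 15 s; splitting by window would leak
near-duplicate rows across the train/test boundary and overstate accuracy —
this grouped design is deliberately conservative. With fewer seizures than
k, k falls back to leave-one-seizure-out with a warning.

The classifier is a bagged CART ensemble (Gini splits, majority vote,
`mtry = floor(sqrt(p))`), implemented in compiled code inside the package
so that results are reproducible bit for bit from a seed. The grid search
over tree count {50, 100, 200}, minimum split {2, 5, 10} and depth
{5, 10, unbounded} runs as an inner grouped 3-fold loop on each training
fold. Metrics — accuracy, precision, recall, F1 with preictal positive —
are computed per (channel, fold), averaged over folds within channel, then
over channels, matching a single-channel analysis design. The SPH sweep
repeats the pipeline at SPH 5/10/15 min and compares per-recording mean
accuracies with a tie-corrected Kruskal–Wallis test (all-identical groups
are defined as H = 0, p = 1; groups smaller than 5 flag the chi-square
approximation as rough).

## The synthetic generator: what it emulates and what it does not

The generator produces a long multichannel record with pink (1/f) or white
background noise, annotated seizure onsets, and state-dependent PAC built
by amplitude modulation:

$$
s(t) = A_{lo}\sin(2\pi f_p t)
 + A_{hi}\Big[1 - \chi + \chi\,\tfrac{1 + \sin(2\pi f_p t)}{2}\Big]
   \sin(2\pi f_a t) + \varepsilon(t).
$$

$\chi = 0$ gives a flat envelope (MI ≈ 0); MI rises monotonically with
$\chi$ (a tested invariant). Preictal coupling can be gated by a seeded
square wave (`burst_duty`, default period 10 s) to mimic rhythmically
bursting preictal coupling; ictal spans add a large 4 Hz discharge plus a
broadband burst — they only need to be annotated, never classified.

Defaults are free parameters, chosen once: interictal $\chi = 0.05$
(coupling in baseline EEG is weak but rarely zero), preictal $\chi = 0.8$
with 50% burst duty, pink noise with SD 2 against a 10-unit low carrier.
The *recording-level* default couples beta phase (20 Hz) to gamma amplitude
(60 Hz) so that the beta–gamma MI — the pair this analysis design singles
out — is the separating feature; the single-signal generator used in the
comodulogram-recovery tests defaults to theta→gamma (6/60 Hz). The
generator does **not** emulate ocular/muscle artifacts, volume conduction,
inter-channel correlation structure, or patient heterogeneity. A green
end-to-end test therefore establishes that the pipeline recovers a known
coupling difference between states — not that any particular clinical
accuracy is reproduced.

## Known limitations

* The artifact-removal stage is an explicit pass-through hook: independent
  component selection on clinical data is a manual judgement that cannot
  be automated faithfully here, and synthetic data needs none.
* The EDF layer covers integer sampling rates and 1-s records — enough for
  the 256/512 Hz clinical dialects and the generator — and carries seizure
  annotations in a CSV sidecar rather than EDF+ annotation streams.
* One mechanistic acceptance property (the accuracy drop when coupling is
  confined to the final 10 min before onset and the SPH grows from 5 to
  15 min) has a geometric ceiling: at SPH 5 the horizon itself absorbs
  half of the coupled time, so only ~20 of 119 preictal windows carry
  signal and the attainable accuracy gap is about 0.08. The direction of
  the effect is robust and tested; the package reports the measured gap
  honestly rather than tuning the generator to inflate it.
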