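---
title: "Dominant-frequency EEG features of cognitive fluctuations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominant-frequency EEG features of cognitive fluctuations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cognitive fluctuations (CF) — spontaneous, transient changes in attention
and alertness — are a core clinical feature of Lewy body dementia, yet
they are hard to rate objectively. Quantitative resting-state EEG offers
a candidate biomarker: in Lewy body disease the dominant cortical rhythm
shifts from the posterior alpha range (8–12 Hz) into a characteristic
"pre-alpha" range (6.0–7.5 Hz) and theta, and the prevalence of
alpha-dominant epochs collapses. `fluctex` implements the full analysis
stack for this question: spectral feature extraction from eyes-closed
EDF recordings, nonparametric group comparison with FDR control,
covariate-adjusted logistic models, and penalized multivariate
classification — plus a synthetic EEG generator so that every stage is
testable end-to-end without clinical data.

## The feature family

A recording is band-pass filtered to the 3–14 Hz analysis window and cut
into contiguous 2-second epochs (a 3-minute recording gives 90 of them).
Each epoch and channel gets a rectangular-window periodogram with 0.5 Hz
bins — the resolution implied by the epoch length — scaled so total
spectral power equals the epoch's mean-square amplitude.

* **DF (dominant frequency):** the bin with maximum power in 3–14 Hz,
  per epoch. Exact ties resolve to the lower frequency, a deterministic
  choice that is conservative for a slowing biomarker.
* **DFV:** the sample standard deviation (n − 1) of the per-epoch DF
  series of a channel.
* **DFP:** the percentage of epochs whose DF falls in each band of the
  five-band scheme — delta (≤ 4.0), theta (4.5–5.5), pre-alpha
  (6.0–7.5), alpha (8.0–12.0), beta (> 12.0 Hz). Summing to 100% across
  bands is enforced by construction.
* **IAF:** the per-epoch power peak restricted to 8.0–12.0 Hz, averaged
  over epochs. When no alpha rhythm exists the argmax sits at the lower
  edge of the window, so severely slowed subjects pin near 8.0 Hz — the
  floor behaviour visible in clinical cohorts.

The printed band intervals leave gaps (4.0–4.5, 5.5–6.0, 7.5–8.0 Hz)
that no 0.5 Hz bin can occupy. For totality the implementation stores
the half-open extension delta [0, 4.25), theta [4.25, 5.75), pre-alpha
[5.75, 7.75), alpha [7.75, 12.25), beta [12.25, ∞), which agrees with
the printed intervals at every on-grid frequency; off-grid inputs (other
epoch lengths) therefore classify without error.

Channel-level features are averaged, unweighted, over four derivations:
anterior (Fp1, Fp2, Fz, F3, F4, F7, F8), temporal (T3, T4, T5, T6),
posterior (Pz, P3, P4, O1, O2) and global. Global uses *all* available
analysis channels including the central row (Cz, C3, C4): only the three
regional groupings are defined anatomically, and leaving channels out of
the global mean would discard signal for no reason. Missing channels do
not abort extraction; the derivation is averaged over available members
and a completeness flag (`n_channels` / `n_defined`) records the gap.
The candidate set for modeling is 7 features (DF, DFV, IAF, DFP in
alpha, pre-alpha, theta, delta) × 4 derivations = 28; DFP beta is
retained internally but mirrors the other prevalences and is not a
candidate.

```{r extract-example}
library(fluctex)
rec <- readEDF("subject01.edf")
feat <- extractFeatures(rec)         # filter, epoch, periodogram, aggregate
feat$regional
```

### Numerical choices

* **Filter:** zero-phase (forward–backward) 4th-order Butterworth,
  corners 3 and 14 Hz. Only the corners are clinically prescribed;
  zero-phase filtering avoids phase distortion at epoch boundaries, and
  demeaning plus odd-reflection padding suppresses the edge transients
  of the forward–backward pass. The continuous record is filtered before
  segmentation so epochs carry no per-epoch transients.
* **Epoching:** contiguous, non-overlapping, trailing partial epochs
  discarded; when a recording holds more than the protocol's 90 epochs
  the first 90 are kept (logged).
* **Artifact handling:** an optional amplitude screen (default
  ±100 µV) stands in for visual review. It is off by default because the
  synthetic recordings the pipeline is exercised on are clean by
  construction.
* **Degenerate inputs:** fewer than 2 kept epochs is an error (DFV needs
  a spread); an empty analysis window is an error; an all-rejected
  screening pass is an error that reports per-channel peaks.

## Statistics layer

Group contrasts use the Mann-Whitney U test with effect size
r = Z/√N, signed positive when the reference (non-fluctuating-like)
group tends larger, so slowing features that are higher without CF carry
positive r. For tie-free samples with N ≤ 12 the p-value is exact (null
U distribution); otherwise the normal approximation with tie and
continuity corrections is used. All 28 candidate tests form one
Benjamini-Hochberg family: the analysis makes one joint claim about the
feature table, so a joint family is the coherent choice.
Kruskal-Wallis and χ² (no Yates correction) wrappers cover ≥3-group
layouts and categorical demographics.

Per-feature logistic models adjust for age, sex and MoCA; odds ratios
are per raw unit (Hz, or percentage point), with Wald 95% intervals and
BH adjustment over the set of features tested. Complete separation is
flagged, and the coefficient is refit under a small ridge penalty with
the Wald interval withheld rather than fabricated.

The multivariate layer first prunes correlated candidates (greedy: while
any absolute Spearman correlation exceeds 0.9, drop the member of the
worst pair with the higher mean absolute correlation; ties drop the
later column). The 0.9 default removes the near-duplicate inter-region
copies — observed inter-region correlations sit around 0.94–0.98 — while
keeping cross-feature structure. The elastic net (mixing parameter 0.5)
runs on standardized features with the penalty weight chosen by
stratified 10-fold cross-validation maximizing out-of-fold AUC; the
out-of-fold linear predictors are pooled before computing the CV AUC, so
small cohorts do not need per-fold AUCs. Both the apparent and the
cross-validated AUC are reported and labeled — a single headline AUC
hides which one it is. A forward-AIC logistic selection provides the
parsimony check. AUC is the trapezoidal ROC integral over score-tie
groups, which equals pairwise concordance with ties counted ½ exactly;
the test suite asserts that equality at 1e-12 against a brute-force
oracle. No selected-feature count is hard-coded anywhere.

## The synthetic generator

`synthRecording()` builds each channel as correlated pink noise (shared
plus private 1/f components, β = 1, background RMS 15 µV) with a band
oscillator on top. Every 2-second stretch draws a band from the
subject's occupancy probabilities and carries a sinusoid at that band's
subject frequency with < 0.25 Hz jitter and random phase. Epoch-locked
switching makes the spec'd occupancies map one-to-one onto DFP, giving a
clean recovery target; real EEG switches asynchronously, and
`asyncSwitch = TRUE` provides exponentially timed switching for
robustness tests. Oscillator amplitude is set per channel so its power
relative to the channel's 3–14 Hz background power matches the
subject's SNR.

Three mechanisms give the regional features realistic covariance
instead of rank-identical copies:

* a scalp topography (alpha posterior-dominant, slow rhythms mildly
  anterior-dominant) multiplying the oscillator amplitude per zone;
* channel-local band switching: with probability 0.12 per stretch a
  channel redraws its own band, so regional dominant rhythms are highly
  but not perfectly correlated — matching the 0.94–0.98 inter-region
  correlations reported for real recordings;
* frontal alpha penetration: per subject, each alpha stretch reaches the
  anterior leads only with probability ~N(0.75, 0.2) (clipped to
  [0.25, 1]); blocked stretches desynchronize frontally into
  low-voltage fast activity, the classic picture of alpha blocking.
  This gives anterior DFP-alpha genuinely independent between-subject
  information — it is the product of alpha occupancy and penetration —
  which is why it emerges as the least redundant alpha representative
  under correlation pruning, as observed clinically.

The `"clinical"` cohort preset encodes the group contrast under study:
the non-fluctuating-like group is alpha-dominant (mean occupancy 0.55 in
alpha, alpha frequency ~N(9.5, 0.6) Hz) and the fluctuating-like group
shifts to pre-alpha/theta (alpha 0.10, pre-alpha 0.45, theta 0.17; slow
frequency ~N(6.2, 0.5) Hz), with the remaining occupancy split between
delta and beta in proportions informed by clinical prevalence tables.
Per-subject occupancies are Dirichlet draws (concentration 5), matching
the wide interquartile ranges real cohorts show; per-subject SNR is
~N(10, 3) dB clipped to [4, 20], a realistic eyes-closed
rhythm-to-background ratio. Ages overlap (both groups ~N(73, 6)) while
MoCA is group-shifted (means 20 vs 24.5) — so global cognition is a
genuine confounder that the adjusted models must handle — and the male
fraction is 0.79 vs 0.54. Covariate targets are generator inputs, never
asserted as outputs. Per-subject seeds derive deterministically from the
master seed: the only systematic group differences are those in the
preset, and passing one parameter set for both groups yields an honest
null generator (validated by the type-I property below).

```{r cohort-example}
co <- synthCohort(nCase = 29, nControl = 24, seed = 1)
fs <- extractCohortFeatures(co)
cmp <- compareGroups(fs, reference = "nonCF")
en  <- fitElasticNet(fs, pruneCorrelated(fs), seed = 1, case = "CF")
```

### What the generator does not emulate

Artifacts (ocular, muscle, electrode pops), drowsiness and state
changes, non-sinusoidal rhythm morphology, volume-conduction geometry
beyond a shared-noise term, within-subject temporal statistics of
fluctuation (bout lengths are a modeling choice — occupancy
probabilities with epoch-locked or exponential switching), and any
biophysical thalamocortical mechanism. Passing tests therefore show the
*pipeline* is correct and the *statistics* behave as designed; they do
not certify performance on clinical recordings.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to keep a full run on
one CPU comfortable: the parameter-recovery property uses 20 seeds per
oscillator frequency at 128 Hz single-channel recordings; the type-I
property uses 200 null cohorts of 8 + 8 subjects, 4 channels (one per
derivation), 60 s at 128 Hz — 5,600 feature tests; the end-to-end
qualitative check runs the full 29 + 24 cohort at 256 Hz, 180 s, 19
channels. The same computations, re-seeded, are what
`scripts/acceptance.R` reports.

## Known limitations

* The EDF reader covers the plain EDF/EDF+ continuous layout used by
  clinical exports (int16 records, per-signal calibration); BDF and
  BrainVision are out of scope, as is montage algebra beyond label
  canonicalization. The recording reference is not modeled; extraction
  is reference-agnostic.
* IAF has no consensus definition; the per-epoch alpha-window argmax
  used here floors at 8.0 Hz for slowed subjects. Centre-of-gravity
  definitions would behave differently.
* The 28 → k pruning count is data-dependent and deliberately not
  asserted on synthetic data.
* DFV on a 0.5 Hz grid is quantized; with strongly slowed, narrow-band
  subjects a floor effect limits measurable variability.
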