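# fluctex

Quantitative resting-state EEG features of cognitive fluctuations in
Lewy body disease.

Cognitive fluctuations (CF) — spontaneous, transient changes in
attention and alertness — are a core feature of Lewy body dementia and
notoriously hard to rate objectively. A well-replicated EEG correlate
exists: the dominant cortical rhythm shifts from posterior alpha
(8–12 Hz) into the "pre-alpha" (6.0–7.5 Hz) and theta ranges, and the
fraction of alpha-dominant epochs collapses. `fluctex` is for
researchers who want to compute and evaluate those features: it reads
eyes-closed EDF recordings (10–20 montage), extracts the
dominant-frequency family, runs the comparison and classification
statistics of a two-group case-control design, and ships a synthetic
EEG generator so the entire pipeline is testable without clinical data.

## The features

Per channel, from 2-second epochs of the 3–14 Hz band-passed signal
(0.5 Hz spectral bins):

| Feature | Definition |
|---|---|
| DF | frequency bin with maximum periodogram power in 3–14 Hz, per epoch; subject value is the epoch mean |
| DFV | sample SD of the per-epoch DF series |
| DFP(b) | % of epochs whose DF falls in band *b*: delta ≤ 4.0, theta 4.5–5.5, pre-alpha 6.0–7.5, alpha 8.0–12.0, beta > 12.0 Hz (Σ = 100%) |
| IAF | per-epoch power peak within 8.0–12.0 Hz, averaged |

Channel values are averaged over anterior, temporal, posterior and
global derivations, yielding 7 × 4 = 28 candidate features per subject.

The statistics layer mirrors a clinical case-control analysis:
median (IQR) summaries, Mann-Whitney U with effect size r = Z/√N,
Benjamini-Hochberg FDR over the 28 tests, logistic models per feature
adjusted for age, sex and MoCA (OR, 95% CI), Spearman-correlation
pruning, an elastic-net logistic classifier (L1+L2, mixing 0.5, CV AUC
from pooled out-of-fold predictions), forward-AIC selection, and
trapezoidal ROC/AUC.

## Worked example

Simulate a small two-group cohort, extract features, compare groups and
fit the classifiers:

```r
library(fluctex)

co  <- synthCohort(nCase = 6, nControl = 6, seed = 42,
                   duration = 60, fs = 128)
fs  <- extractCohortFeatures(co)
cmp <- compareGroups(fs, reference = "nonCF")
round(cmp[c("global_df", "global_dfp_alpha",
            "global_dfp_pre_alpha", "global_iaf"),
          c("case_median", "ref_median", "p", "q", "r")], 4)
#>                      case_median ref_median      p      q       r
#> global_df                 6.5083     8.8421 0.0022 0.0121  0.8321
#> global_dfp_alpha         10.6140    65.0877 0.0022 0.0121  0.8321
#> global_dfp_pre_alpha     38.6842     3.1579 0.0152 0.0424 -0.6934
#> global_iaf                9.3250     9.6123 0.1320 0.1946  0.4623
```

The fluctuating-like (CF) group is slower: its median global DF is
6.5 Hz against 8.8 Hz, only ~11% of its epochs are alpha-dominant
against ~65%, and the prevalence mass moved into pre-alpha. Positive r
means the reference (non-CF) group tends larger; `q` is the
FDR-adjusted p over all 28 feature tests.

```r
fa <- forwardAIC(fs, pruneCorrelated(fs), case = "CF")
fa
#> fluctex classifier (forward_aic)
#>   selected: anterior_df
#>   apparent AUC: 1.000

dfRange(fs)
#>   group   min_df    max_df
#> 1    CF 5.569298  7.923684
#> 2 nonCF 8.615789 10.383333
```

At this toy size the groups separate perfectly; at the default cohort
size (29 vs 24, 180 s at 256 Hz) the elastic net's cross-validated AUC
lands in the realistic 0.9–1.0 range with `anterior_dfp_alpha` among
the selected features.

A command-line wrapper for shell use lives at `inst/cli/fluctex.R`
(sub-commands `simulate`, `extract`, `compare`, `model`), e.g.

```sh
Rscript inst/cli/fluctex.R simulate --n-cf 29 --n-noncf 24 --seed 1 --out cohort/
Rscript inst/cli/fluctex.R extract --edf cohort/ --meta cohort/meta.csv --out features.csv
Rscript inst/cli/fluctex.R compare --features features.csv --out table1.csv
```

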