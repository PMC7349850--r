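# eegconnectome

Weighted brain-network analysis of high-density resting-state EEG across
the Alzheimer's disease continuum.

## The problem

Subjective cognitive decline (SCD) — self-reported memory worsening with
normal neuropsychological performance — is a candidate preclinical stage of
Alzheimer's disease (AD), but standard tests cannot separate SCD from
healthy ageing.  Resting-state functional connectivity can: the parietal
hub regions of the default-mode network disconnect progressively along the
continuum healthy controls (HC) → SCD → mild cognitive impairment (MCI) →
AD.  `eegconnectome` implements the full analysis for 256-channel geodesic
sensor-net EEG:

* **preprocessing** — 5th-order Butterworth band-pass 0.3–75 Hz
  (zero-phase), non-overlapping 500-sample windows, rejection of windows
  with amplitudes over 100 µV, inverse-distance bad-channel interpolation,
  average re-referencing;
* **connectivity** — per-window absolute Pearson correlation |r| between
  every electrode pair, averaged over retained windows into a weighted
  undirected network per subject, at whole-head ("global", 256 electrodes)
  and parietal ("local", 27 electrodes) scope;
* **graph metrics** — strength $S_i = \sum_j w_{ij}$, Onnela weighted
  clustering $C_i^w = \frac{1}{k_i(k_i-1)}\sum_{j\ne h}(w_{ij}w_{ih}w_{jh})^{1/3}$,
  and betweenness centrality
  $BC_i = \frac{1}{(N-1)(N-2)}\sum_{s\ne i\ne t}\sigma_{st}(i)/\sigma_{st}$
  on 1/w edge lengths (Brandes accumulation), with graph values as node
  averages;
* **inference** — one-way ANOVA across the four groups, pairwise pooled
  t tests gated on ANOVA significance, Bonferroni level α/6 ≈ 0.008;
* **discrimination** — ROC curves (one-vs-rest and one-vs-one),
  Mann–Whitney AUC, Youden-optimal thresholds, 65% sensitivity/specificity
  acceptability floor;
* a **synthetic cohort generator** (latent AR(1) factor model with an
  analytically known correlation structure) that emulates the four-group
  study — group sizes 22/20/30/20, parietal coupling weakening
  HC → SCD → MCI → AD, a weaker whole-head source, 1/f-like channel noise,
  >100 µV artifacts and bad channels — so the entire pipeline is testable
  without any clinical data.  See the methods vignette
  (`vignettes/eeg-connectome-methods.Rmd`) for the model and every design
  decision.

Intended users: EEG methods researchers who want a tested, reproducible
reference implementation of correlation-network group analysis, and anyone
who needs a synthetic multichannel cohort with known connectivity ground
truth.

## Worked example

```r
library(eegconnectome)

cfg <- list(out_dir = "demo-run", seed = 42,
            simulation = list(group_sizes = list(HC = 6, SCD = 6,
                                                 MCI = 6, AD = 6),
                              n_channels = 64, duration_s = 20))
res <- run_pipeline(cfg)

loc <- subset(res$summaries, scope == "local")
round(t(sapply(split(loc[, c("cc", "strength", "bc")], loc$group),
               colMeans)), 3)[c("HC", "SCD", "MCI", "AD"), ]
#>        cc strength    bc
#> HC  0.538   14.045 0.001
#> SCD 0.414   10.819 0.000
#> MCI 0.377    9.869 0.000
#> AD  0.320    8.406 0.001
```

The parietal clustering coefficient and strength fall monotonically along
the continuum, as the generator's weakening parietal coupling dictates
(the absolute level is lower than on the full 256-channel montage because
average re-referencing on this small 64-channel demo removes a larger
share of the shared parietal signal).  The group effect is formally
confirmed and followed up pairwise:

```r
cc <- res$comparisons[["cc.local"]]
sprintf("F(%d, %d) = %.2f, p = %.3g", cc$df_between, cc$df_within,
        cc$F, cc$p_anova)
#> "F(3, 20) = 31.61, p = 8.72e-08"
cc$pairwise[1:3, c("group_a", "group_b", "t", "df", "significant_bonferroni")]
#>   group_a group_b        t df significant_bonferroni
#> 1      HC     SCD  5.72661 10                   TRUE
#> 2      HC     MCI 10.75791 10                   TRUE
#> 3      HC      AD  9.57487 10                   TRUE
```

ROC discrimination of HC from all patient groups by the local clustering
coefficient, with the Youden-optimal operating point:

```r
subset(res$roc, contrast == "HC vs rest" & scope == "local" & metric == "cc")
#> AUC 1.00 at threshold 0.492 (sens 1.00, spec 1.00), higher-is-positive
```

(On this tiny noise-free demo the separation is perfect; the scope-contrast
study in `scripts/acceptance.R` measures realistic AUCs on larger cohorts.)
The synthetic neuropsychological battery correlates with local betweenness
centrality with the designed signs, e.g. sleep-problem scores positively
(r = 0.70 here) and MMSE negatively (r = −0.28).

All tables (`summaries.tsv`, `anova.tsv`, `pairwise.tsv`, `roc.tsv`,
`neuropsych.tsv`, `correlations.tsv`), the simulated cohort and a
provenance log are written under `out_dir`; re-running with the same
config reproduces them byte for byte.  A thin command-line front end is
installed at `inst/scripts/run_pipeline.R`.

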