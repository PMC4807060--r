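# xfuzzen

Cross-fuzzy entropy (C-FuzzyEn) and cross-sample entropy (C-SampleEn) for
pairs of time series, with a complete gait-symmetry analysis pipeline built
on top: surrogate-signal generators, Monte-Carlo characterisation
experiments, stride-interval preprocessing and feature extraction,
Mann–Whitney tolerance screening, and leave-one-out RBF-SVM classification.

## The problem and the statistics

A healthy gait is bilaterally symmetric: left and right stride-interval
series share most of their pattern structure.  Neurodegenerative disorders
such as Parkinson's disease (PD) disturb that synchrony.  Cross entropies
quantify the pattern *asynchrony* of two concurrent series $u, v$ of
length $N$ by comparing embedded templates
$x_m(i) = (u(i), \dots, u(i+m-1))$ against $y_m(j)$ under the Chebyshev
distance $d = \max_k |u(i+k) - v(j+k)|$:

* **C-SampleEn**$(m, r, N) = -\ln\left(B^{m+1}/B^{m}\right)$, where $B^m$
  is the fraction of the $(N-m)^2$ template pairs with $d < r$.  With no
  self-matches it can be *undefined* (no matches), which happens readily
  for short series and small tolerance.
* **C-FuzzyEn**$(m, n, r, N)$ replaces the hard threshold with the fuzzy
  membership $e^{-d^{n}/r}$ and subtracts each template's own mean
  (baseline) first.  It is defined for every input, varies continuously in
  $r$, and is markedly more stable at short data lengths — the property
  that makes it attractive for clinical gait series of a few hundred
  strides.

A symmetric gait should give low cross entropy between the left and right
stride series; PD-like gait gives higher values.  The classical scalar
alternative is the absolute symmetry index
$\mathrm{ASI} = 100\,(T_R - T_L)/\tfrac12(T_R + T_L)$ on a per-limb
feature $T$ (here the mean stride interval).

See `vignettes/cross-fuzzy-entropy-methods.Rmd` for the full methods
account and design rationale.

## Worked example

```r
library(xfuzzen)

# one synthetic left/right stride pair, tightly coupled (control-like)
pair <- synthetic_gait_pair(coupling = 0.95, noise_sd = 0.025, seed = 7)
cross_fuzzy_entropy(pair$u, pair$v, m = 1, r = 0.004)
#> <cfuzzyen> m=1 r=0.004 N=200
#>   value = 0.012418  (phi_m = 1, phi_m+1 = 0.987659)

# a 15 PD-like + 16 control-like cohort, per-subject symmetry features
cohort   <- synthetic_gait_cohort(seed = 1)
features <- gait_feature_table(cohort)
features[c(1, 2, 16, 17), c("subject_id", "group", "cfuzzyen", "asi")]
#> # A tibble: 4 × 4
#>   subject_id group cfuzzyen      asi
#> 1 pd01       PD      0.0271  1.06
#> 2 pd02       PD      0.0291 -0.866
#> 3 co01       CO      0.0178 -0.00398
#> 4 co02       CO      0.0111 -0.00205

# tolerance screening by Mann-Whitney U between the groups
sel <- select_r(cohort)
c(sel$best_r, sel$best_p)
#> best r: 1e-04   p: 2.1e-06

# leave-one-out RBF-SVM on the entropy feature
loo_svm(features$cfuzzyen, features$group)
#> <classification_report> positive = PD
#>   TP 15  FN 0  TN 16  FP 0
#>   sensitivity 100.00%  specificity 100.00%  accuracy 100.00%
#>   ROC area 1.000
```

The PD-like group's higher C-FuzzyEn (more asymmetric gait), the small
screening p-value, and the clean separation of this synthetic cohort are
the qualitative pattern the pipeline is built to detect; absolute numbers
on real hallway-walking cohorts depend on the recording protocol.

A thin command-line wrapper with `entropy`, `simulate`, `experiment`,
`gait` and `classify` subcommands lives at `inst/cli/xfuzzen.R`.

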