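# liabilityAUC

Genetic interpretation of the area under the ROC curve (AUC) for genomic
risk profiles, under the liability-threshold model.

## The problem

Genomic profiles combine many risk alleles into a score predicting an
individual's genetic risk of a complex disease. Judged as a diagnostic
classifier, such a score is summarised by the AUC — the probability that a
random case outranks a random control. But a genetic predictor cannot reach
an AUC of 1: disease status also depends on environment, so the AUC of even
a *perfect* genetic predictor has a ceiling fixed by the disease's
epidemiology — its lifetime prevalence *K* and heritability of liability
*h²<sub>L</sub>* (equivalently its sibling recurrence risk ratio
*λ<sub>S</sub>*). The same measured AUC can therefore represent anything
from a small fraction to nearly all of the known genetic variance,
depending on the disease.

This package is for statistical geneticists and genetic epidemiologists who
want to benchmark risk profiles on the scale that matters for gene
discovery: the proportion of genetic variance explained.

## What it computes

Under the liability-threshold model (liability *P = A + E ~ N*(0,1),
disease when *P > T = Φ⁻¹(1−K)*, with *i = z/K* and *v = −iK/(1−K)* the
mean liabilities of cases and controls):

* **h²<sub>L</sub> from (K, λ<sub>S</sub>)** — the Reich threshold
  estimator, `h2_liability_from_sib()`, and its reverse
  `lambda_s_from_h2()`.
* **AUC from variance explained** — a profile explaining *h²<sub>x</sub>*
  of liability variance gives
  AUC = Φ((μ<sub>d</sub>−μ<sub>d′</sub>)/√(σ²<sub>d</sub>+σ²<sub>d′</sub>))
  with μ<sub>d</sub> = i·h²<sub>x</sub>, μ<sub>d′</sub> = v·h²<sub>x</sub>,
  σ²<sub>d</sub> = h²<sub>x</sub>(1−h²<sub>x</sub>·i(i−T)),
  σ²<sub>d′</sub> = h²<sub>x</sub>(1−h²<sub>x</sub>·v(v−T)):
  `auc_from_h2x()`.
* **Variance explained from AUC** — the closed-form inversion with
  *Q = Φ⁻¹(AUC)*: h²<sub>x</sub> = 2Q²/((i−v)² + Q²(i(i−T)+v(v−T))),
  `h2x_from_auc()`; then `proportion_genetic()` (= h²<sub>x</sub>/h²<sub>L</sub>)
  and `sib_risk_explained()` (= (λ<sub>S[x]</sub>−1)/(λ<sub>S</sub>−1)).
* **Empirical rank AUC** — AUC = (r̄ − (n<sub>d</sub>+1)/2)/n<sub>d′</sub>
  from the mean case rank, with midrank ties, plus ROC curves and Somers'
  D: `ranked_cohort()`, `auc_from_ranks()`, `roc_points()`, `somers_d()`.
* **A nuclear-family simulator** validating the analytic formulas:
  `simulate_families()`, `summarize_families()`, `cohort_from_simulation()`.
* **A batch report engine** over disease parameter tables:
  `read_disease_table()`, `render_report()`, with a 19-disease reference
  table packaged (`example_disease_table()`).

## Worked example: age-related macular degeneration

Prevalence after age 80 of 11.8% and a genetic sibling recurrence risk of
2.2 imply a heritability of liability of 0.68. A single-SNP predictor
(CFH rs1061170) with a measured AUC of 0.69:

```r
library(liabilityAUC)
amd <- disease_model("Age-related macular degeneration", K = 0.118,
                     lambda_s = 2.2)
evaluate_profile(amd, auc_target = 0.69)
#> Profile evaluation: Age-related macular degeneration (K = 0.118, lambda_S = 2.2, h2_L = 0.683)
#>       scenario   h2x   auc prop_genetic accuracy lambda_s_x prop_sib
#>     fraction=1 0.683 0.922        1.000    1.000       2.20    1.000
#>   fraction=0.5 0.342 0.809        0.500    0.707       1.54    0.448
#>  fraction=0.25 0.171 0.720        0.250    0.500       1.25    0.212
#>       auc=0.69 0.126 0.690        0.185    0.430       1.19    0.155
```

Reading the rows: a profile explaining **all** the genetic variance would
reach AUC 0.92 (the ceiling for this disease); half, 0.81; a quarter, 0.72.
The observed AUC of 0.69 corresponds to 0.126 of liability variance — 18.5%
of the known genetic variance (prediction accuracy ρ = 0.43) and 15.5% of
the sibling recurrence risk.

## Command line

A thin launcher ships in `exec/`:

```sh
$ Rscript exec/liability-auc varexp --K 0.118 --auc 0.69 --lambda-s 2.2
h2x	0.1265
h2_liability	0.6830
prop_genetic	0.1852
lambda_s_x	1.1854
prop_sib	0.1545
```

Subcommands: `aucmax` (K + λ<sub>S</sub> or h² → attainable AUCs), `varexp`
(K + AUC → variance explained), `table` (disease table → batch report, TSV
or aligned text), `roc` (two-column status/score TSV → rank AUC, Somers' D,
optional ROC curve TSV), `simulate` (seeded family simulation → JSON
summary, optional cohort TSV). Exit codes: 0 success, 2 validation error,
3 model-domain error. File formats: disease tables as TSV/CSV with `name`,
`prevalence` (optionally percent, `--percent`) and `lambda_s` and/or `h2`
columns; score files as two tab-separated columns (status 0/1, score),
header optional.

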