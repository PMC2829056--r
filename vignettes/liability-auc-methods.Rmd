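---
title: "The liability-threshold calculus behind genomic-profile AUC"
author: "liabilityAUC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The liability-threshold calculus behind genomic-profile AUC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liabilityAUC)
```

## The problem

A genomic profile aggregates many risk alleles into a single score that
predicts an individual's *genetic* risk of a complex disease. When such a
score is evaluated as a diagnostic classifier, the usual summary is the area
under the ROC curve (AUC) — the probability that a randomly chosen case
outranks a randomly chosen control. But disease status is not determined by
genotype: even a profile capturing *all* of the genetic variance faces a
ceiling on its AUC that is fixed by two epidemiological parameters, the
lifetime prevalence $K$ and the heritability of liability $h^2_L$
(equivalently, the sibling recurrence risk ratio $\lambda_S$). This package
implements the closed-form calculus connecting these quantities, in both
directions, together with an empirical rank-based AUC, a simulation check,
and a batch report engine.

## The liability-threshold model

Disease is modelled through an unobserved liability $P = A + E \sim N(0,1)$,
with additive genetic values $A \sim N(0, h^2_L)$ and independent
environmental deviations $E \sim N(0, 1 - h^2_L)$. An individual is affected
when $P$ exceeds the threshold $T = \Phi^{-1}(1-K)$. The truncation yields
the selection-theory scalars (`threshold_quantities()`): the density
$z = \phi(T)$, the mean liability of cases $i = z/K$ and of controls
$v = -iK/(1-K)$, which satisfy $K i + (1-K) v = 0$.

The main assumption is a unimodal, approximately normal liability — many
variants of individually small effect and no single dominant genetic or
environmental factor. On the liability scale the genetic effects are
additive, so narrow- and broad-sense heritability coincide; all familial
resemblance is assumed genetic (no shared-environment component), so a
$\lambda_S$ contaminated by common environment overstates the attainable
AUC.

## Conversions

**Prevalence + sibling recurrence → heritability of liability.** With
$T_1 = \Phi^{-1}(1 - \lambda_S K)$ the threshold among siblings of cases,
the Reich threshold estimator gives the proband–sibling liability
regression
$$b = \frac{T - T_1\sqrt{1 - (T^2 - T_1^2)\left(1 - T/i\right)}}
           {i + T_1^2\,(i - T)},$$
and $h^2_L = b / a_S$ with the sibling relationship coefficient
$a_S = 1/2$ (`h2_liability_from_sib()`). The placement of the $1/2$ is
pinned by the standard worked value $(K, \lambda_S) = (0.05, 2) \mapsto
h^2_L = 0.371$ and by the regeneration of the packaged 19-disease table,
both asserted in the test suite. The reverse direction
(`lambda_s_from_h2()`) uses the sibling threshold
$$T_1(h^2) = \frac{T - i\,h^2/2}{\sqrt{1 - (h^2/2)^2\, i(i - T)}}, \qquad
\lambda_S = \frac{1 - \Phi(T_1)}{K}.$$
The two are near-exact inverses (relative error below $10^{-3}$ across the
admissible region), not algebraic ones; both are standard approximations of
the bivariate-normal family model.

**Variance explained → AUC.** A profile explaining $h^2_x$ of the liability
variance has, among cases and controls, means $\mu_d = i h^2_x$,
$\mu_{d'} = v h^2_x$ and variances $\sigma^2_d = h^2_x(1 - h^2_x\, i(i-T))$,
$\sigma^2_{d'} = h^2_x(1 - h^2_x\, v(v-T))$ — truncation selection shrinks
the variance on both sides of the threshold. Treating both groups as normal,
$$\mathrm{AUC} = \Phi\!\left(\frac{\mu_d - \mu_{d'}}
  {\sqrt{\sigma^2_d + \sigma^2_{d'}}}\right)$$
(`auc_from_h2x()`); at $h^2_x = h^2_L$ this is the maximum attainable AUC.

**AUC → variance explained.** The display inverts in closed form: with
$Q = \Phi^{-1}(\mathrm{AUC})$,
$$h^2_x = \frac{2Q^2}{(i-v)^2 + Q^2\left[i(i-T) + v(v-T)\right]}$$
(`h2x_from_auc()`). The algebraic inversion is verified in the tests against
a bisection of the forward formula to $10^{-6}$ over a 200-point grid.
Dividing by $h^2_L$ gives the proportion of the known genetic variance
explained (`proportion_genetic()`), whose square root is the accuracy
$\rho$, the correlation between predicted and true genetic risk. The
sibling-scale analogue (`sib_risk_explained()`) converts $h^2_x$ to the
recurrence risk $\lambda_{S[x]}$ the profile alone would generate and
reports $(\lambda_{S[x]} - 1)/(\lambda_S - 1)$.

AUC targets below 0.5 are rejected rather than reflected: a profile
anti-correlated with risk indicates mis-specified score orientation, which
the empirical ROC reader handles explicitly with its `invert` flag instead.

## Worked example

```{r amd}
amd <- disease_model("Age-related macular degeneration", K = 0.118,
                     lambda_s = 2.2)
evaluate_profile(amd, auc_target = 0.69)
```

The fraction rows give the AUC when the profile explains all, half or a
quarter of the genetic variance (0.92, 0.81, 0.72); the inversion row shows
that a single-SNP predictor with an observed AUC of 0.69 explains about
0.13 of liability variance — 18% of the genetic variance and 15% of the
sibling recurrence risk for this disease.

## Empirical rank AUC

For a scored case-control cohort, `auc_from_ranks()` uses the mean
ascending rank $\bar r$ of the $n_d$ cases among $n_{d'}$ controls:
$$\mathrm{AUC} = \frac{\bar r - (n_d + 1)/2}{n_{d'}},$$
identical to the Mann–Whitney $U$ statistic divided by $n_d n_{d'}$, and to
Somers' $D$ through $\mathrm{AUC} = (1+D)/2$. Ties are resolved to
midranks, which preserves the pairwise definition (a tied pair counts one
half); the tests verify exact agreement with brute-force pair counting on a
thousand random cohorts, and invariance of the estimate under duplication
of the control set. `roc_points()` emits the cumulative (FPR, TPR) sweep,
stepping diagonally across blocks of tied scores, so its trapezoid area
equals the rank AUC exactly.

## The family simulator

`simulate_families()` draws nuclear families directly on the liability
scale: parents $A \sim N(0, h^2)$, children
$A = \tfrac12 A_{dad} + \tfrac12 A_{mum} + A_{mend}$ with
$A_{mend} \sim N(0, h^2/2)$, independent $E$, affection as $P > T$, and the
observed-scale genetic value $G_{01} = 1 - \Phi\!\big((T - A)/\sqrt{1 -
h^2}\big)$, i.e. the conditional disease probability given $A$ (a step
function in the degenerate case $h^2 = 1$). Defaults are 100,000 families
of two children — two children are the minimum that supports a sibling
recurrence estimate, and one sib pair per family avoids within-family
dependence corrections (the second child is always the relative, the first
always the proband). `summarize_families()` estimates $\hat K$,
$\hat\lambda_S$, the empirical maximum AUC (ranking first children on their
true $A$), and $\hat h^2_{01} = \mathrm{var}(G_{01}) / \mathrm{var}(P_{01})$
using population (divide-by-$n$) variances so that
$\mathrm{var}(P_{01}) = \hat K (1 - \hat K)$ holds identically; a
regression of $P_{01}$ on $G_{01}$ estimates the same quantity in
expectation, and the variance ratio was preferred for that identity.
`cohort_from_simulation()` turns a run into a scored cohort whose profile
captures a chosen fraction $f$ of the genetic variance, by scoring
$fA + \varepsilon$ with $\varepsilon \sim N(0, f(1-f)h^2)$, giving a score
with variance and liability-covariance both $f h^2$.

The simulator emulates exactly what the analytic formulas assume — normal
additive liability, random mating, no shared environment, no ascertainment
— so agreement between the two validates the algebra, not the biological
model. Features of real data it deliberately lacks: locus-level genotypes
and linkage disequilibrium, non-additive variance, shared sibling
environment, age structure and censoring, and case-control ascertainment
bias.

## Numerical choices and accuracy

* All normal quantile/density/CDF evaluations use R's erf-based
  implementations (absolute error well below $10^{-10}$); no
  approximations or tables.
* `classifier_rates()` integrates the joint liability density by adaptive
  quadrature (absolute tolerance $10^{-8}$); its swept ROC curve integrates
  to the exact pair-ranking probability to $3 \times 10^{-4}$.
* The forward AUC display is a *normal approximation* to the truncated
  liability distributions. Against exact quadrature its bias is below 0.001
  for $h^2 \le 0.5$ at any prevalence, but grows with heritability for
  common diseases: about $+0.009$ at $(K, h^2) = (0.1, 0.8)$ and $+0.0105$
  at $(0.3, 0.8)$ (the approximation *undershoots* the true ranking
  probability). The simulation tests therefore validate the empirical AUC
  against exact quadrature everywhere and against the analytic formula at
  moderate heritability; at $h^2 = 0.8$ with $K = 0.3$ the analytic value
  is systematically just over 0.01 below the simulated one.
* Reported tables round half away from zero to 2 decimals. Two cells of the
  packaged 19-disease reference regeneration differ from the original print
  by more than rounding of the final value alone (the published values
  chained rounded intermediates): the proportion of genetic variance at
  AUC 0.75 for the first row (printed 0.31, recomputed 0.32) and for
  unipolar disorder (printed 0.52, recomputed 0.54). All forward columns
  (heritability, AUC at full/half/quarter variance) agree unrounded to
  better than 0.009 across all 19 rows.
* Degenerate inputs are rejected with typed conditions: model-domain errors
  (prevalence outside $(0,1)$, $\lambda_S K > 1$, unattainable AUC,
  parameter pairs implying $h^2_L > 1$) versus validation errors (malformed
  files, missing columns), mapped by the CLI to exit codes 3 and 2.
* Test problem sizes: the simulation grid runs 100,000 families per cell
  (12 cells) — prevalences of 0.001 then yield roughly 100 affected
  probands, so Monte-Carlo bands for the rare-disease cells are set from
  binomial/Hanley–McNeil standard errors rather than a fixed constant.

## Limitations

The calculus treats $K$ and $\lambda_S$ as known population parameters;
both are in practice estimated with sampling error and sensitive to
disease definition and age structure, and the implied $h^2_L$ inherits that
uncertainty (no confidence intervals are provided — the intended use is
benchmarking, not inference). All familial covariance is attributed to
additive genetics; any common-environment contribution inflates
$\lambda_S$ and thus the apparent ceiling. Profiles containing
non-inherited genetic information (de novo variants) can legitimately
exceed the sibling-based ceiling. The normal approximation degrades for
$h^2 > 0.8$, and prevalences above 0.5 are outside the intended
parameterisation (accepted with a warning).
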