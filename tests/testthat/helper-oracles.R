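# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks.

# brute-force pairwise concordance: fraction of case-control pairs with
# case scored above control, ties counting one half
pairwise_auc <- function(status, score) {
  cases <- score[status == 1]
  ctrls <- score[status == 0]
  tot <- 0
  for (x in cases) tot <- tot + sum(x > ctrls) + 0.5 * sum(x == ctrls)
  tot / (length(cases) * length(ctrls))
}

# invert auc_from_h2x by bisection (oracle for the closed-form inversion)
bisect_h2x <- function(K, auc, tol = 1e-12) {
  lo <- 0; hi <- 1
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    if (auc_from_h2x(K, mid) < auc) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# trapezoid area under a piecewise-linear curve given as (x, y) points
trapezoid_area <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# exact AUC of ranking cases vs controls on true genetic liability A,
# by adaptive quadrature on the truncated-liability densities
auc_exact_quadrature <- function(K, h2) {
  T <- qnorm(1 - K)
  se <- sqrt(1 - h2)
  sa <- sqrt(h2)
  f_case <- function(a) dnorm(a, 0, sa) * (1 - pnorm((T - a) / se)) / K
  cdf_ctrl <- function(a)
    vapply(a, function(u)
      integrate(function(b) dnorm(b, 0, sa) * pnorm((T - b) / se) / (1 - K),
                -Inf, u, rel.tol = 1e-10)$value, numeric(1))
  integrate(function(a) f_case(a) * cdf_ctrl(a), -Inf, Inf,
            rel.tol = 1e-8)$value
}

# published AUC statistics for the 19 packaged disease rows, in fixture
# order: heritability of liability, AUC at full/half/quarter genetic
# variance, and the proportions of genetic variance and sibling risk
# explained at an observed AUC of 0.75 (all printed to 2 decimals)
published_cells <- data.frame(
  h2_liability = c(0.68, 0.39, 0.72, 0.44, 0.60, 0.44, 0.37, 0.76, 0.64,
                   0.16, 0.63, 0.69, 0.60, 0.76, 0.63, 0.70, 0.86, 0.76,
                   0.64),
  auc_max  = c(0.92, 0.84, 0.95, 0.89, 0.94, 0.90, 0.88, 0.98, 0.96, 0.79,
               0.97, 0.97, 0.97, 0.98, 0.98, 0.98, 1.00, 1.00, 1.00),
  auc_half = c(0.81, 0.74, 0.84, 0.79, 0.84, 0.80, 0.79, 0.89, 0.87, 0.71,
               0.88, 0.89, 0.90, 0.90, 0.90, 0.90, 0.93, 0.95, 0.95),
  auc_quar = c(0.72, 0.67, 0.75, 0.71, 0.75, 0.72, 0.71, 0.80, 0.77, 0.65,
               0.78, 0.80, 0.80, 0.81, 0.80, 0.80, 0.84, 0.86, 0.86),
  prop_genetic = c(0.31, 0.52, 0.25, 0.36, 0.25, 0.33, 0.37, 0.17, 0.20,
                   0.74, 0.19, 0.17, 0.17, 0.15, 0.15, 0.16, 0.12, 0.10,
                   0.10),
  prop_sib = c(0.27, 0.49, 0.18, 0.29, 0.18, 0.25, 0.29, 0.09, 0.12, 0.70,
               0.10, 0.08, 0.07, 0.07, 0.06, 0.07, 0.04, 0.02, 0.02))

# a 19-individual cohort shaped like the worked ROC example: 9 cases,
# 10 controls, case rank-sum 119 (mean rank 13.22, AUC 0.8222)
example_cohort <- function() {
  case_ranks <- c(19, 18, 17, 16, 15, 13, 11, 6, 4)
  status <- integer(19)
  status[case_ranks] <- 1L
  ranked_cohort(status, score = seq_len(19) / 10)
}

round2 <- function(x) sign(x) * floor(abs(x) * 100 + 0.5 + 1e-12) / 100
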