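test_that("group moments carry the selection-theory identities", {
  gm <- group_moments(0.118, 0.683)
  expect_equal(0.118 * gm$mu_d + (1 - 0.118) * gm$mu_dprime, 0,
               tolerance = 1e-10)
  # selection shrinks the within-group variances below h2x
  expect_lt(gm$var_d, 0.683)
  expect_lt(gm$var_dprime, 0.683)
  expect_equal(pnorm((gm$mu_d - gm$mu_dprime) /
                       sqrt(gm$var_d + gm$var_dprime)),
               0.92, tolerance = 0.005)
  # degenerate profile: no variance explained, all moments zero
  gm0 <- group_moments(0.2, 0)
  expect_equal(c(gm0$mu_d, gm0$mu_dprime, gm0$var_d, gm0$var_dprime),
               rep(0, 4))
})

test_that("AUC formula reproduces published cells across diseases", {
  # >= 6 published cells fix the reconstructed mu/sigma^2 forms
  h2_amd <- h2_liability_from_sib(0.118, 2.2)
  expect_equal(auc_from_h2x(0.118, h2_amd), 0.92, tolerance = 0.005)
  expect_equal(auc_from_h2x(0.118, h2_amd / 2), 0.81, tolerance = 0.005)
  expect_equal(auc_from_h2x(0.118, h2_amd / 4), 0.72, tolerance = 0.005)
  h2_t1d <- h2_liability_from_sib(0.0054, 13.7)
  expect_equal(auc_from_h2x(0.0054, h2_t1d / 2), 0.93, tolerance = 0.005)
  h2_bla <- h2_liability_from_sib(0.01, 1.7)
  expect_lt(abs(auc_from_h2x(0.01, h2_bla) - 0.79), 0.005)
  h2_cro <- h2_liability_from_sib(0.001, 26)
  expect_lt(abs(auc_from_h2x(0.001, h2_cro / 4) - 0.86), 0.005)
  expect_equal(auc_from_h2x(0.3, 0), 0.5)
})

test_that("AUC is monotone in variance explained and in rarity", {
  for (K in c(0.001, 0.05, 0.3)) {
    auc <- auc_from_h2x(K, seq(0, 0.95, by = 0.05))
    expect_true(all(diff(auc) > 0))
  }
  for (h2x in c(0.1, 0.4, 0.8)) {
    Ks <- c(0.001, 0.003, 0.01, 0.03, 0.1, 0.3, 0.5)
    aucs <- vapply(Ks, function(K) auc_from_h2x(K, h2x), numeric(1))
    expect_true(all(diff(aucs) < 0))
  }
})

test_that("closed-form inversion agrees with the bisection oracle", {
  for (K in c(0.001, 0.01, 0.1, 0.3)) {
    for (auc in c(0.55, 0.7, 0.85, 0.95)) {
      h2x <- h2x_from_auc(K, auc)
      expect_equal(h2x, bisect_h2x(K, auc), tolerance = 1e-6)
    }
  }
  expect_equal(h2x_from_auc(0.2, 0.5), 0)
})

test_that("forward and inverse AUC formulas round-trip to 1e-6", {
  Ks <- exp(seq(log(0.0003), log(0.5), length.out = 20))
  h2s <- seq(0.01, 0.95, length.out = 10)
  for (K in Ks) for (h in h2s) {
    auc <- auc_from_h2x(K, h)
    if (auc >= 1 - 1e-12) next  # beyond double precision of the normal CDF
    expect_equal(h2x_from_auc(K, auc), h, tolerance = 1e-6)
  }
})

test_that("inversion rejects out-of-range and unattainable AUC values", {
  expect_error(h2x_from_auc(0.1, 0.4), class = "liability_domain_error")
  expect_error(h2x_from_auc(0.1, 1), class = "liability_domain_error")
  # a common disease cannot yield an AUC of 0.999 from genetics alone
  expect_error(h2x_from_auc(0.3, 0.999), "unattainable")
})

test_that("proportions of genetic variance match published values", {
  expect_lt(abs(proportion_genetic(h2x_from_auc(0.01, 0.75),
                                   h2_liability_from_sib(0.01, 1.7)) - 0.74),
            0.005)
  expect_lt(abs(proportion_genetic(h2x_from_auc(0.001, 0.75),
                                   h2_liability_from_sib(0.001, 26)) - 0.10),
            0.005)
  expect_equal(proportion_genetic(0.3, 0.3), 1)
  expect_warning(proportion_genetic(0.5, 0.3), "more variance")
  expect_error(proportion_genetic(0.2, 0), class = "liability_domain_error")
})

test_that("sibling risk explained matches published values", {
  bla <- sib_risk_explained(0.01, h2x_from_auc(0.01, 0.75), 1.7)
  expect_lt(abs(bla$prop_sib - 0.70), 0.005)
  amd <- sib_risk_explained(0.118, h2x_from_auc(0.118, 0.69), 2.2)
  expect_lt(abs(amd$prop_sib - 0.15), 0.005)
  expect_true(amd$lambda_s_x > 1.17 && amd$lambda_s_x < 1.19)
  zero <- sib_risk_explained(0.1, 0, 2)
  expect_equal(zero$lambda_s_x, 1)
  expect_equal(zero$prop_sib, 0)
  expect_error(sib_risk_explained(0.1, 0.2, 1),
               class = "liability_domain_error")
  # lambda_S[x] alone remains defined without an observed lambda_S
  expect_true(is.na(sib_risk_explained(0.1, 0.2)$prop_sib))
})

test_that("full heritability recovers the observed sibling recurrence", {
  for (K in c(0.005, 0.05, 0.2)) for (lam in c(1.5, 2.5, 4)) {
    if (lam * K > 1) next
    h2L <- tryCatch(h2_liability_from_sib(K, lam), error = function(e) NA)
    if (is.na(h2L)) next  # combination outside the admissible region
    expect_equal(sib_risk_explained(K, h2L, lam)$lambda_s_x, lam,
                 tolerance = 1e-3)
  }
})

test_that("liability-cutoff classifier rates match the published contrast", {
  r_common <- classifier_rates(0.5, 0.8, 1)
  expect_equal(round2(r_common$tpr), 0.26)
  expect_equal(round2(r_common$fpr), 0.00)
  r_rare <- classifier_rates(0.01, 0.8, 1)
  expect_equal(round2(r_rare$tpr), 0.99)
  expect_equal(round2(r_rare$fpr), 0.12)
  # a cutoff below all liabilities classifies everyone positive
  r_all <- classifier_rates(0.1, 0.5, -Inf)
  expect_equal(r_all$tpr, 1, tolerance = 1e-7)
  expect_equal(r_all$fpr, 1, tolerance = 1e-7)
  expect_error(classifier_rates(0.1, 1, 0), class = "liability_domain_error")
})

test_that("sweeping the cutoff integrates to the ranking AUC", {
  # the swept (FPR, TPR) curve integrates to the exact probability of
  # correctly ranking a case-control pair on genetic liability; the
  # analytic formula matches it to 1e-3 at moderate heritability (its
  # normal-approximation bias only exceeds that around h2 = 0.6 and above)
  for (K in c(0.05, 0.3)) for (h2 in c(0.3, 0.6)) {
    cuts <- c(-Inf, seq(-6, 6, by = 0.01), Inf)
    rates <- vapply(cuts, function(cc) {
      r <- classifier_rates(K, h2, cc)
      c(r$fpr, r$tpr)
    }, numeric(2))
    ord <- order(rates[1, ])
    area <- trapezoid_area(rates[1, ord], rates[2, ord])
    expect_lt(abs(area - auc_exact_quadrature(K, h2)), 3e-4)
    if (h2 <= 0.3) expect_lt(abs(area - auc_from_h2x(K, h2)), 1e-3)
  }
})

test_that("evaluate_profile assembles the full per-disease evaluation", {
  amd <- disease_model("AMD", 0.118, lambda_s = 2.2)
  ev <- evaluate_profile(amd, auc_target = 0.69)
  expect_equal(nrow(ev), 4)
  expect_equal(round2(ev$auc[ev$fraction == 1]), 0.92)
  expect_equal(round2(ev$auc[ev$fraction == 0.5]), 0.81)
  expect_equal(round2(ev$auc[ev$fraction == 0.25]), 0.72)
  inv <- ev[ev$scenario == "auc=0.69", ]
  expect_lt(abs(inv$h2x - 0.126), 1e-3)
  expect_lt(abs(inv$prop_sib - 0.15), 0.005)
  expect_equal(ev$auc, pnorm(ev$Q))
  expect_equal(ev$accuracy, sqrt(ev$prop_genetic))
  # zero fraction collapses to a useless classifier
  ev0 <- evaluate_profile(amd, fractions = 0)
  expect_equal(ev0$auc, 0.5)
  expect_equal(ev0$prop_sib, 0)
})
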