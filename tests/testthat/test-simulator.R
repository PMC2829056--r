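test_that("simulation is reproducible and respects the additive model", {
  cfg <- family_sim_config(0.5, 0.1, n_families = 30000, seed = 11)
  sim <- simulate_families(cfg)
  sim2 <- simulate_families(cfg)
  expect_identical(sim$A, sim2$A)
  expect_identical(sim$affected, sim2$affected)
  expect_equal(nrow(sim), 30000 * 4)

  res <- summarize_families(sim)
  # genetic variance and sibling covariance of A follow the additive model
  expect_lt(abs(res$var_A_hat - 0.5), 0.01)
  n <- cfg$n_families
  se_cov <- sqrt((0.5^2 + 0.25^2) / n)
  expect_lt(abs(res$sib_corr_A_hat - 0.25), 3 * se_cov)
  # prevalence recovery within 3 binomial SE
  se_K <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(res$K_hat - 0.1), 3 * se_K)
})

test_that("a non-heritable disease yields null genetics in simulation", {
  sim <- simulate_families(family_sim_config(0, 0.1, n_families = 20000,
                                             seed = 12))
  kids <- sim[sim$member == "child1", ]
  expect_true(all(kids$A == 0))
  res <- summarize_families(sim)
  expect_lt(abs(res$K_hat - 0.1), 3 * sqrt(0.1 * 0.9 / 20000))
  expect_equal(res$auc_max_hat, 0.5)
  expect_equal(res$h2_01_hat, 0)
  expect_equal(res$lambda_S_hat, 1, tolerance = 0.1)
})

test_that("fully heritable disease degenerates to a liability step function", {
  sim <- simulate_families(family_sim_config(1, 0.2, n_families = 5000,
                                             seed = 13))
  expect_equal(sim$P, sim$A)
  expect_true(all(sim$G01 %in% c(0, 1)))
  expect_equal(sim$G01, as.numeric(sim$affected))
})

test_that("sibling recurrence estimate matches the liability-scale forward formula", {
  sim <- simulate_families(family_sim_config(0.5, 0.1, n_families = 100000,
                                             seed = 14))
  res <- summarize_families(sim)
  lam_expected <- lambda_s_from_h2(0.1, 0.5)
  n_prob <- sum(sim$affected[sim$member == "child1"])
  se <- sqrt(lam_expected * 0.1 * (1 - lam_expected * 0.1) / n_prob) / 0.1
  expect_lt(abs(res$lambda_S_hat - lam_expected), 3 * se)
})

test_that("observed-scale heritability estimator uses population variances", {
  sim <- simulate_families(family_sim_config(0.68, 0.118,
                                             n_families = 50000, seed = 15))
  kids <- sim[sim$member == "child1", ]
  res <- summarize_families(sim)
  p <- mean(kids$affected)
  # var(P01) = K(1-K) identically under the divide-by-n variance
  expect_equal(mean(kids$affected^2) - p^2, p * (1 - p))
  expect_true(res$h2_01_hat <= 1)
  expect_equal(res$h2_01_hat,
               (mean(kids$G01^2) - mean(kids$G01)^2) / (p * (1 - p)))
})

test_that("empirical maximum AUC tracks the exact ranking probability", {
  # exact P(A_case > A_control) by quadrature as the oracle; the analytic
  # formula is a normal approximation whose bias is checked separately
  cells <- list(c(0.01, 0.5), c(0.1, 0.8), c(0.3, 0.2))
  for (cell in cells) {
    K <- cell[1]; h2 <- cell[2]
    sim <- simulate_families(family_sim_config(h2, K, n_families = 100000,
                                               seed = 16))
    res <- summarize_families(sim)
    exact <- auc_exact_quadrature(K, h2)
    n_d <- sum(sim$affected[sim$member == "child1"])
    se <- sqrt(exact * (1 - exact)) * sqrt(1 / n_d + 1 / (100000 - n_d)) * 1.6
    expect_lt(abs(res$auc_max_hat - exact), 3 * se)
  }
})

test_that("analytic AUC approximation stays within its documented accuracy", {
  # tight agreement at moderate heritability; at h2 = 0.8 the normal
  # approximation is known to undershoot by up to ~0.011 for common disease
  for (K in c(0.01, 0.1, 0.3)) {
    expect_equal(auc_exact_quadrature(K, 0.5), auc_from_h2x(K, 0.5),
                 tolerance = 0.001)
    expect_lt(abs(auc_exact_quadrature(K, 0.8) - auc_from_h2x(K, 0.8)),
              0.015)
  }
})

test_that("simulated cohorts reproduce the partial-profile AUC", {
  sim <- simulate_families(family_sim_config(0.683, 0.118,
                                             n_families = 100000, seed = 17))
  res <- summarize_families(sim)
  # full profile scores on A itself, reproducing auc_max_hat
  set.seed(18)
  full <- cohort_from_simulation(sim, 1)
  expect_equal(auc_from_ranks(full), res$auc_max_hat)
  # half the genetic variance: the published AUC_half for this disease
  half <- cohort_from_simulation(sim, 0.5)
  expect_equal(auc_from_ranks(half), 0.81, tolerance = 0.01)
  expect_equal(auc_from_ranks(half), auc_from_h2x(0.118, 0.683 / 2),
               tolerance = 0.01)
  # no genetic information: chance-level discrimination
  none <- cohort_from_simulation(sim, 0)
  expect_equal(auc_from_ranks(none), 0.5, tolerance = 0.01)
})

test_that("summaries fail informatively when no proband is affected", {
  sim <- simulate_families(family_sim_config(0.5, 0.001, n_families = 50,
                                             seed = 20))
  expect_identical(sum(sim$affected[sim$member == "child1"]), 0L)
  expect_error(summarize_families(sim), "n_families")
})

test_that("simulator config validation catches bad parameters", {
  expect_error(family_sim_config(1.2, 0.1), class = "liability_domain_error")
  expect_error(family_sim_config(0.5, 0), class = "liability_domain_error")
  expect_error(family_sim_config(0.5, 0.1, n_families = 0),
               class = "liability_validation_error")
  expect_error(family_sim_config(0.5, 0.1, n_children = 0),
               class = "liability_validation_error")
})
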