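#' Configuration for the nuclear-family liability simulation
#'
#' @param h2 Heritability of liability in \[0, 1\].
#' @param K Disease prevalence in (0, 1).
#' @param n_families Number of nuclear families (default 100,000).
#' @param n_children Children per family (default 2; two are needed to
#'   estimate sibling recurrence).
#' @param seed Optional integer seed; when given the simulation is fully
#'   reproducible.
#' @return An object of class `"family_sim_config"`.
#' @export
family_sim_config <- function(h2, K, n_families = 100000L, n_children = 2L,
                              seed = NULL) {
  check_proportion(h2, "h2")
  check_prevalence(K)
  if (!is.numeric(n_families) || n_families < 1)
    validation_error("n_families must be >= 1")
  if (!is.numeric(n_children) || n_children < 1)
    validation_error("n_children must be >= 1")
  if (!is.null(seed) && (!is.numeric(seed) || anyNA(seed)))
    validation_error("seed must be an integer")
  structure(list(h2 = h2, K = K, n_families = as.integer(n_families),
                 n_children = as.integer(n_children),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "family_sim_config")
}

#' Simulate nuclear families under the liability-threshold model
#'
#' Parents draw genetic liability \eqn{A \sim N(0, h^2)}; each child inherits
#' \eqn{A = \tfrac12 A_{dad} + \tfrac12 A_{mum} + A_{mend}} with the
#' Mendelian-segregation term \eqn{A_{mend} \sim N(0, h^2/2)}. Environmental
#' deviations \eqn{E \sim N(0, 1-h^2)} are independent, total liability is
#' \eqn{P = A + E}, and an individual is affected when
#' \eqn{P > T = \Phi^{-1}(1-K)}. The genetic value on the observed scale is
#' the conditional disease probability
#' \eqn{G_{01} = 1 - \Phi((T-A)/\sqrt{1-h^2})} (a step function
#' \eqn{A > T} in the degenerate case \eqn{h^2 = 1}).
#'
#' @param config A [family_sim_config()], or `h2` to build one from the
#'   remaining arguments.
#' @inheritParams family_sim_config
#' @return A data frame of class `"family_sim"` with columns `family`,
#'   `member` (`"father"`, `"mother"`, `"child1"`, ...), `child` (index, NA
#'   for parents), `A`, `P`, `affected`, `G01`; the configuration is kept in
#'   `attr(, "config")`.
#' @examples
#' sim <- simulate_families(family_sim_config(0.5, 0.1, n_families = 2000,
#'                                            seed = 1))
#' summarize_families(sim)
#' @export
simulate_families <- function(config, K = NULL, n_families = 100000L,
                              n_children = 2L, seed = NULL) {
  if (!inherits(config, "family_sim_config"))
    config <- family_sim_config(config, K, n_families, n_children, seed)
  if (!is.null(config$seed)) set.seed(config$seed)
  h2 <- config$h2
  n <- config$n_families
  nc <- config$n_children
  T <- stats::qnorm(1 - config$K)
  sd_a <- sqrt(h2)
  sd_mend <- sqrt(h2 / 2)
  sd_e <- sqrt(1 - h2)

  A_dad <- stats::rnorm(n, 0, sd_a)
  A_mum <- stats::rnorm(n, 0, sd_a)
  A_kids <- lapply(seq_len(nc), function(j)
    0.5 * A_dad + 0.5 * A_mum + stats::rnorm(n, 0, sd_mend))

  members <- c("father", "mother", paste0("child", seq_len(nc)))
  A <- c(A_dad, A_mum, unlist(A_kids, use.names = FALSE))
  E <- stats::rnorm(length(A), 0, sd_e)
  P <- A + E
  G01 <- if (h2 < 1) 1 - stats::pnorm((T - A) / sd_e) else as.numeric(A > T)

  out <- data.frame(
    family = rep.int(seq_len(n), times = 2L + nc),
    member = rep(members, each = n),
    child = rep(c(NA_integer_, NA_integer_, seq_len(nc)), each = n),
    A = A, P = P, affected = as.integer(P > T), G01 = G01,
    stringsAsFactors = FALSE)
  attr(out, "config") <- config
  class(out) <- c("family_sim", "data.frame")
  out
}

# population (divide-by-n) variance, so that var(P01) = K(1-K) identically
pop_var <- function(x) mean(x^2) - mean(x)^2

#' Summarise a family simulation into genetic-epidemiology estimates
#'
#' Estimates, from the simulated families: the prevalence \eqn{\hat K}
#' (affected fraction of first children), the sibling recurrence risk ratio
#' \eqn{\hat\lambda_S} (prevalence among second children whose sib is
#' affected, divided by \eqn{\hat K}), the observed-scale heritability
#' \eqn{\hat h^2_{01} = \mathrm{var}(G_{01})/\mathrm{var}(P_{01})} over first
#' children (population variances, so \eqn{\mathrm{var}(P_{01}) =
#' \hat K(1-\hat K)} identically), and the empirical maximum AUC from the
#' mean rank of affected first children when ranked on their true genetic
#' liability `A`.
#'
#' @param sim A `"family_sim"` data frame from [simulate_families()].
#' @return An object of class `"family_sim_result"`: list with `K_hat`,
#'   `lambda_S_hat`, `h2_01_hat`, `auc_max_hat`, `var_A_hat` (sample variance
#'   of first children's `A`), `sib_corr_A_hat` (covariance of sib pairs'
#'   `A`; the sibling correlation of unit-variance liability, expected
#'   \eqn{h^2/2}), and the configuration used.
#' @export
summarize_families <- function(sim) {
  if (!inherits(sim, "family_sim"))
    validation_error("sim must come from simulate_families()")
  cfg <- attr(sim, "config")
  c1 <- sim[sim$member == "child1", ]
  K_hat <- mean(c1$affected)
  if (K_hat == 0)
    domain_error(paste("no affected probands among first children;",
                       "increase n_families for K = %g"), cfg$K)
  lambda_S_hat <- NA_real_
  sib_corr <- NA_real_
  if (cfg$n_children >= 2L) {
    c2 <- sim[sim$member == "child2", ]
    proband <- c1$affected == 1L
    lambda_S_hat <- mean(c2$affected[proband]) / K_hat
    # covariance of sibling genetic liabilities; as total liability has
    # unit variance this equals the sibling liability correlation, h2/2
    sib_corr <- stats::cov(c1$A, c2$A)
  }
  h2_01_hat <- if (cfg$h2 > 0) pop_var(c1$G01) / pop_var(c1$affected) else 0
  auc_max_hat <- if (cfg$h2 > 0)
    auc_from_ranks(ranked_cohort(c1$affected, c1$A))
  else 0.5
  structure(list(K_hat = K_hat, lambda_S_hat = lambda_S_hat,
                 h2_01_hat = h2_01_hat, auc_max_hat = auc_max_hat,
                 var_A_hat = stats::var(c1$A), sib_corr_A_hat = sib_corr,
                 config = cfg),
            class = "family_sim_result")
}

#' @export
summary.family_sim <- function(object, ...) summarize_families(object)

#' @export
print.family_sim_result <- function(x, digits = 4, ...) {
  cfg <- x$config
  cat(sprintf("Family simulation summary (h2 = %g, K = %g, %d families)\n",
              cfg$h2, cfg$K, cfg$n_families))
  cat(sprintf("  K_hat          : %s\n", format(x$K_hat, digits = digits)))
  cat(sprintf("  lambda_S_hat   : %s\n", format(x$lambda_S_hat, digits = digits)))
  cat(sprintf("  h2_01_hat      : %s\n", format(x$h2_01_hat, digits = digits)))
  cat(sprintf("  auc_max_hat    : %s\n", format(x$auc_max_hat, digits = digits)))
  cat(sprintf("  var(A)         : %s\n", format(x$var_A_hat, digits = digits)))
  cat(sprintf("  sib corr(A)    : %s\n", format(x$sib_corr_A_hat, digits = digits)))
  invisible(x)
}

#' Build a scored case-control cohort from a family simulation
#'
#' Constructs a genomic-profile score for each first child that captures a
#' given fraction of the genetic variance: `score = f*A + noise` with
#' independent noise of variance \eqn{f(1-f)h^2}, so the score has variance
#' \eqn{f h^2} and covariance \eqn{f h^2} with total liability -- i.e. it is
#' a liability-scale predictor with \eqn{h^2_x = f h^2}. Its empirical AUC
#' converges to `auc_from_h2x(K, f * h2)`.
#'
#' @param sim A `"family_sim"` data frame from [simulate_families()].
#' @param profile_fraction Fraction `f` of the genetic variance captured by
#'   the profile, in \[0, 1\]. `f = 1` scores on the true genetic liability.
#' @return A [ranked_cohort()] of the first children.
#' @export
cohort_from_simulation <- function(sim, profile_fraction) {
  if (!inherits(sim, "family_sim"))
    validation_error("sim must come from simulate_families()")
  check_proportion(profile_fraction, "profile_fraction")
  cfg <- attr(sim, "config")
  c1 <- sim[sim$member == "child1", ]
  f <- profile_fraction
  noise_sd <- sqrt(f * (1 - f) * cfg$h2)
  score <- f * c1$A + stats::rnorm(nrow(c1), 0, noise_sd)
  ranked_cohort(c1$affected, score)
}
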