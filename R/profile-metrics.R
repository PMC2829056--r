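#' Liability-scale moments of cases and controls for a genomic profile
#'
#' A genomic profile that explains a fraction \eqn{h^2_x} of the liability
#' variance has, by standard selection theory, the following moments among
#' diseased (\eqn{d}) and non-diseased (\eqn{d'}) individuals:
#' \deqn{\mu_d = i h^2_x, \quad \mu_{d'} = v h^2_x,}
#' \deqn{\sigma^2_d = h^2_x\,(1 - h^2_x\, i(i-T)), \quad
#'       \sigma^2_{d'} = h^2_x\,(1 - h^2_x\, v(v-T)),}
#' where \eqn{T}, \eqn{i}, \eqn{v} come from [threshold_quantities()].
#' Selection into the affected tail shrinks the variance by the factor
#' \eqn{i(i-T)}; truncation of the unaffected remainder shrinks it by
#' \eqn{v(v-T)}.
#'
#' @param K Disease prevalence in (0, 1).
#' @param h2x Variance explained by the profile on the liability scale, in
#'   \[0, 1\]. Vectorised.
#' @return An object of class `"group_moments"`: list with `mu_d`,
#'   `mu_dprime`, `var_d`, `var_dprime` (plus `K`, `h2x`).
#' @examples
#' gm <- group_moments(0.118, 0.683)
#' pnorm((gm$mu_d - gm$mu_dprime) / sqrt(gm$var_d + gm$var_dprime))  # 0.92
#' @export
group_moments <- function(K, h2x) {
  check_prevalence(K)
  check_proportion(h2x, "h2x")
  tq <- threshold_quantities(K)
  mu_d <- tq$i * h2x
  mu_dprime <- tq$v * h2x
  var_d <- h2x * (1 - h2x * tq$i * (tq$i - tq$T))
  var_dprime <- h2x * (1 - h2x * tq$v * (tq$v - tq$T))
  bad <- h2x > 0 & (var_d <= 0 | var_dprime <= 0)
  if (any(bad))
    domain_error(
      "non-positive group variance at K = %s, h2x = %s (outside the model's admissible region)",
      format(K, digits = 6), fmt_vals(h2x[bad]))
  structure(list(K = K, h2x = h2x, mu_d = mu_d, mu_dprime = mu_dprime,
                 var_d = var_d, var_dprime = var_dprime),
            class = "group_moments")
}

#' AUC of a genomic profile from the variance it explains
#'
#' The probability that a random case-control pair is correctly ordered by
#' the profile equals the probability that the difference of their
#' liability-scale profile values is positive. Approximating the two group
#' distributions as normal with the [group_moments()] moments gives
#' \deqn{AUC = \Phi\!\left(\frac{\mu_d - \mu_{d'}}
#'   {\sqrt{\sigma^2_d + \sigma^2_{d'}}}\right).}
#' With `h2x` equal to the full heritability of liability this is the
#' maximum AUC a genetic predictor can reach for the disease.
#'
#' @inheritParams group_moments
#' @return AUC in \[0.5, 1\); exactly 0.5 at `h2x = 0`. Vectorised over
#'   `h2x`.
#' @examples
#' auc_from_h2x(0.118, h2_liability_from_sib(0.118, 2.2))  # 0.92 (AUC_max)
#' auc_from_h2x(0.118, 0.3415)                             # 0.81 (AUC_half)
#' @seealso [h2x_from_auc()] for the inversion.
#' @export
auc_from_h2x <- function(K, h2x) {
  gm <- group_moments(K, h2x)
  auc <- ifelse(gm$h2x == 0, 0.5,
                stats::pnorm((gm$mu_d - gm$mu_dprime) /
                               sqrt(gm$var_d + gm$var_dprime)))
  unname(auc)
}

#' Variance explained on the liability scale from an observed AUC
#'
#' Inverts [auc_from_h2x()] in closed form. With \eqn{Q = \Phi^{-1}(AUC)}
#' and \eqn{T, i, v} from [threshold_quantities()],
#' \deqn{h^2_x = \frac{2 Q^2}{(i-v)^2 + Q^2\,[\,i(i-T) + v(v-T)\,]}.}
#' This is the variance a profile must explain on the liability scale to
#' reach the given AUC at the given prevalence; dividing by the heritability
#' of liability ([proportion_genetic()]) gives the proportion of the known
#' genetic variance explained.
#'
#' @param K Disease prevalence in (0, 1).
#' @param auc Observed AUC, in \[0.5, 1). Profiles anti-correlated with risk
#'   (AUC < 0.5) are rejected rather than reflected.
#' @return Variance explained on the liability scale, in \[0, 1\].
#'   Vectorised over `auc`.
#' @examples
#' h2x_from_auc(0.118, 0.69)  # ~0.126: the CFH rs1061170 predictor for AMD
#' h2x_from_auc(0.01, 0.75)   # ~0.118
#' @export
h2x_from_auc <- function(K, auc) {
  check_prevalence(K)
  if (!is.numeric(auc) || anyNA(auc) || any(!is.finite(auc)))
    domain_error("auc must be a finite probability in [0.5, 1)")
  if (any(auc < 0.5))
    domain_error("auc < 0.5 (profile anti-correlated with risk): %s",
                 fmt_vals(auc[auc < 0.5]))
  if (any(auc >= 1))
    domain_error("auc must be < 1; offending value(s): %s",
                 fmt_vals(auc[auc >= 1]))
  tq <- threshold_quantities(K)
  Q <- stats::qnorm(auc)
  C <- tq$i * (tq$i - tq$T) + tq$v * (tq$v - tq$T)
  h2x <- 2 * Q^2 / ((tq$i - tq$v)^2 + Q^2 * C)
  if (any(h2x > 1))
    domain_error("AUC unattainable at this prevalence (K = %s): AUC = %s",
                 format(K, digits = 6), fmt_vals(auc[h2x > 1]))
  h2x
}

#' Proportion of the known genetic variance explained by a profile
#'
#' The ratio of the liability-scale variance explained by the profile to the
#' heritability of liability of the disease. Its square root is the accuracy
#' \eqn{\rho}, the correlation between predicted and true genetic risk.
#'
#' @param h2x Variance explained by the profile on the liability scale.
#' @param h2_liability Heritability of liability of the disease (> 0).
#' @return The ratio `h2x / h2_liability`. Values above 1 (profile appears
#'   to explain more than the familial estimate of the genetic variance) are
#'   reported with a warning rather than clamped.
#' @examples
#' proportion_genetic(h2x_from_auc(0.01, 0.75),
#'                    h2_liability_from_sib(0.01, 1.7))  # 0.74, bladder cancer
#' @export
proportion_genetic <- function(h2x, h2_liability) {
  check_proportion(h2x, "h2x")
  if (!is.numeric(h2_liability) || anyNA(h2_liability) ||
      any(h2_liability <= 0))
    domain_error("h2_liability must be > 0 to form a proportion")
  ratio <- h2x / h2_liability
  if (any(ratio > 1 + 1e-9))
    warning(sprintf(paste(
      "profile explains more variance than the heritability of liability",
      "(ratio %s); check K, lambda_S and AUC inputs"),
      fmt_vals(ratio[ratio > 1 + 1e-9])), call. = FALSE)
  ratio
}

#' Sibling recurrence risk generated by a profile's captured variance
#'
#' A profile explaining \eqn{h^2_x} of the liability variance would, on its
#' own, generate a sibling recurrence risk
#' \eqn{\lambda_{S[x]} = (1 - \Phi(T_{1[x]}))/K} with
#' \deqn{T_{1[x]} = \frac{T - i\,h^2_x/2}{\sqrt{1 - (h^2_x/2)^2\, i(i-T)}}.}
#' The proportion of the observed sibling risk explained is
#' \eqn{(\lambda_{S[x]}-1)/(\lambda_S-1)}.
#'
#' @param K Disease prevalence in (0, 1).
#' @param h2x Variance explained by the profile on the liability scale.
#' @param lambda_s Observed sibling recurrence risk ratio (> 1). May be
#'   `NULL`, in which case only `lambda_s_x` is returned and the proportion
#'   is `NA`.
#' @return A list with `T1_x`, `lambda_s_x` and `prop_sib`.
#' @examples
#' sib_risk_explained(0.118, h2x_from_auc(0.118, 0.69), 2.2)$prop_sib # 0.15
#' @export
sib_risk_explained <- function(K, h2x, lambda_s = NULL) {
  check_prevalence(K)
  check_proportion(h2x, "h2x")
  tq <- threshold_quantities(K)
  T1_x <- (tq$T - tq$i * h2x / 2) /
    sqrt(1 - (h2x / 2)^2 * tq$i * (tq$i - tq$T))
  lambda_s_x <- (1 - stats::pnorm(T1_x)) / K
  prop <- NA_real_
  if (!is.null(lambda_s)) {
    check_ratio(lambda_s, K)
    if (any(lambda_s <= 1))
      domain_error(
        "proportion of sibling risk is undefined at lambda_S <= 1 (lambda_S = %s)",
        fmt_vals(lambda_s[lambda_s <= 1]))
    prop <- (lambda_s_x - 1) / (lambda_s - 1)
  }
  list(T1_x = T1_x, lambda_s_x = lambda_s_x, prop_sib = prop)
}

#' True and false positive rates of a liability-cutoff classifier
#'
#' Rates for the idealised classifier that declares disease whenever the true
#' genetic liability \eqn{A \sim N(0, h^2)} is at least `cutoff`. Conditioning
#' on disease status integrates the conditional disease probability
#' \eqn{G_{01}(a) = 1 - \Phi((T-a)/\sqrt{1-h^2})} over the genetic-liability
#' density \eqn{\phi(a; 0, h^2)}:
#' \deqn{TPR = \frac{1}{K}\int_{c}^{\infty} \phi(a;0,h^2)\, G_{01}(a)\, da,
#' \qquad
#' FPR = \frac{1}{1-K}\int_{c}^{\infty} \phi(a;0,h^2)\,(1-G_{01}(a))\, da.}
#' Integrals are evaluated by adaptive quadrature to absolute error 1e-8.
#'
#' @param K Disease prevalence in (0, 1).
#' @param h2 Heritability of liability, in (0, 1). `h2 = 1` makes the
#'   conditional probability a step function and is rejected; threshold
#'   `A > T` directly in that degenerate case.
#' @param liability_cutoff Classifier cutoff on the genetic-liability scale.
#' @return A list with `tpr` and `fpr`.
#' @examples
#' classifier_rates(0.5,  0.8, 1)  # TPR 0.26, FPR 0.00
#' classifier_rates(0.01, 0.8, 1)  # TPR 0.99, FPR 0.12
#' @export
classifier_rates <- function(K, h2, liability_cutoff) {
  check_prevalence(K)
  check_proportion(h2, "h2")
  if (length(h2) != 1L || length(liability_cutoff) != 1L)
    validation_error("h2 and liability_cutoff must be scalars")
  if (h2 == 1)
    domain_error(paste("h2 = 1 makes disease a step function of liability;",
                       "use the degenerate classifier A > T directly"))
  if (h2 == 0)
    domain_error("h2 = 0: genetic liability is degenerate at zero")
  T <- stats::qnorm(1 - K)
  sd_a <- sqrt(h2)
  sd_e <- sqrt(1 - h2)
  g01 <- function(a) 1 - stats::pnorm((T - a) / sd_e)
  f_case <- function(a) stats::dnorm(a, sd = sd_a) * g01(a)
  f_ctrl <- function(a) stats::dnorm(a, sd = sd_a) * (1 - g01(a))
  tpr <- stats::integrate(f_case, liability_cutoff, Inf, abs.tol = 1e-8,
                          rel.tol = 1e-10)$value / K
  fpr <- stats::integrate(f_ctrl, liability_cutoff, Inf, abs.tol = 1e-8,
                          rel.tol = 1e-10)$value / (1 - K)
  list(tpr = min(tpr, 1), fpr = min(fpr, 1))
}

#' Full AUC evaluation of genomic profiles for a disease
#'
#' The report engine behind the batch table: for a disease with known
#' prevalence and sibling recurrence risk (or heritability of liability),
#' evaluates profiles explaining given fractions of the known genetic
#' variance (forward direction) and/or a profile with an observed AUC
#' (inversion). Each row carries the variance explained on the liability
#' scale, the AUC and its normal deviate Q, the proportion of genetic
#' variance and of sibling risk explained, and the prediction accuracy
#' \eqn{\rho = \sqrt{h^2_x / h^2_L}}.
#'
#' @param model A [disease_model()].
#' @param auc_target Optional observed AUC to invert (e.g. 0.75).
#' @param fractions Fractions of the known genetic variance explained by the
#'   profile; the defaults give the maximum AUC (1), AUC at half (0.5) and
#'   at a quarter (0.25) of the genetic variance. Use `numeric(0)` to skip.
#' @return A data frame of class `"profile_evaluation"`, one row per
#'   requested fraction plus (if `auc_target` is given) one inversion row.
#' @examples
#' evaluate_profile(disease_model("AMD", 0.118, lambda_s = 2.2),
#'                  auc_target = 0.75)
#' @export
evaluate_profile <- function(model, auc_target = NULL,
                             fractions = c(1, 0.5, 0.25)) {
  if (!inherits(model, "disease_model"))
    validation_error("model must be a disease_model object")
  K <- model$K
  h2L <- model$h2_liability
  lam <- model$lambda_s
  lam_ok <- !is.null(lam) && lam > 1
  row_for <- function(h2x, label, frac = NA_real_) {
    auc <- auc_from_h2x(K, h2x)
    sib <- sib_risk_explained(K, h2x, if (lam_ok) lam else NULL)
    pg <- if (h2L > 0) h2x / h2L else NA_real_
    data.frame(name = model$name, scenario = label, K = K,
               lambda_s = if (is.null(lam)) NA_real_ else lam,
               h2_liability = h2L, fraction = frac, h2x = h2x, auc = auc,
               Q = stats::qnorm(auc), prop_genetic = pg,
               accuracy = if (is.na(pg)) NA_real_ else sqrt(pg),
               T1_x = sib$T1_x, lambda_s_x = sib$lambda_s_x,
               prop_sib = sib$prop_sib,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (f in fractions) {
    check_proportion(f, "fraction")
    rows[[length(rows) + 1L]] <-
      row_for(h2L * f, sprintf("fraction=%g", f), frac = f)
  }
  if (!is.null(auc_target)) {
    h2x <- h2x_from_auc(K, auc_target)
    r <- row_for(h2x, sprintf("auc=%g", auc_target),
                 frac = if (h2L > 0) h2x / h2L else NA_real_)
    rows[[length(rows) + 1L]] <- r
  }
  if (length(rows) == 0L)
    validation_error("nothing to evaluate: no fractions and no auc_target")
  out <- do.call(rbind, rows)
  class(out) <- c("profile_evaluation", "data.frame")
  out
}

#' @export
print.profile_evaluation <- function(x, digits = 3, ...) {
  cat("Profile evaluation:", x$name[1], sprintf("(K = %g", x$K[1]))
  if (!is.na(x$lambda_s[1])) cat(sprintf(", lambda_S = %g", x$lambda_s[1]))
  cat(sprintf(", h2_L = %s)\n", format(x$h2_liability[1], digits = digits)))
  cols <- c("scenario", "h2x", "auc", "prop_genetic", "accuracy",
            "lambda_s_x", "prop_sib")
  df <- as.data.frame(x)[, cols]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  print(df, row.names = FALSE)
  invisible(x)
}
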