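#' Standard-normal threshold quantities for a disease prevalence
#'
#' Under the liability-threshold model, disease corresponds to an unobserved
#' liability \eqn{P \sim N(0,1)} exceeding the threshold
#' \eqn{T = \Phi^{-1}(1-K)}, where \eqn{K} is the lifetime prevalence. This
#' function returns the selection-theory scalars attached to that truncation:
#' the threshold \eqn{T}, the normal density \eqn{z} at \eqn{T}, the mean
#' liability of affected individuals \eqn{i = z/K} and of unaffected
#' individuals \eqn{v = -iK/(1-K)}. When a sibling recurrence risk ratio is
#' supplied, the sibling threshold \eqn{T_1 = \Phi^{-1}(1-\lambda_S K)} is
#' included as well.
#'
#' @param K Lifetime disease prevalence, strictly in (0, 1). Values above 0.5
#'   are accepted with a warning (the affected tail is conventionally the
#'   upper tail).
#' @param lambda_s Optional sibling recurrence risk ratio (\eqn{\ge 1}, with
#'   \eqn{\lambda_S K \le 1}).
#' @return An object of class `"threshold_quantities"`: a list with elements
#'   `K`, `T`, `z`, `i`, `v` and (if `lambda_s` was given) `T1`.
#' @examples
#' tq <- threshold_quantities(0.05)
#' tq$T  # 1.645
#' tq$z  # 0.103
#' threshold_quantities(0.05, lambda_s = 2)$T1  # 1.282
#' @seealso [h2_liability_from_sib()], [group_moments()]
#' @export
threshold_quantities <- function(K, lambda_s = NULL) {
  check_prevalence(K)
  if (length(K) != 1L)
    validation_error("K must be a single prevalence, not a vector")
  T <- stats::qnorm(1 - K)
  z <- stats::dnorm(T)
  i <- z / K
  v <- -i * K / (1 - K)
  out <- list(K = K, T = T, z = z, i = i, v = v)
  if (!is.null(lambda_s)) {
    check_ratio(lambda_s, K)
    out$lambda_s <- lambda_s
    out$T1 <- stats::qnorm(1 - lambda_s * K)
  }
  structure(out, class = "threshold_quantities")
}

#' @export
print.threshold_quantities <- function(x, digits = 4, ...) {
  cat("Liability-threshold quantities (K =", format(x$K, digits = digits),
      ")\n")
  cat(sprintf("  T (threshold)            : %s\n", format(x$T, digits = digits)))
  cat(sprintf("  z (density at T)         : %s\n", format(x$z, digits = digits)))
  cat(sprintf("  i (mean liability, cases): %s\n", format(x$i, digits = digits)))
  cat(sprintf("  v (mean liability, ctrls): %s\n", format(x$v, digits = digits)))
  if (!is.null(x$T1))
    cat(sprintf("  T1 (sibling threshold)   : %s\n", format(x$T1, digits = digits)))
  invisible(x)
}

#' Heritability of liability from prevalence and sibling recurrence risk
#'
#' Converts the two directly estimable genetic-epidemiology parameters of a
#' disease -- prevalence \eqn{K} and sibling recurrence risk ratio
#' \eqn{\lambda_S} -- into the narrow-sense heritability of liability using
#' the Reich threshold estimator. With \eqn{T}, \eqn{i} from
#' [threshold_quantities()] and \eqn{T_1 = \Phi^{-1}(1-\lambda_S K)}, the
#' regression of a sibling's liability on the proband's is
#' \deqn{b = \frac{T - T_1\sqrt{1-(T^2-T_1^2)(1-T/i)}}{i + T_1^2(i-T)}}
#' and \eqn{h^2_L = b / a_S} with sibling relationship coefficient
#' \eqn{a_S = 1/2}.
#'
#' @param K Disease prevalence in (0, 1). Vectorised (recycled against
#'   `lambda_s`).
#' @param lambda_s Sibling recurrence risk ratio, \eqn{\ge 1} with
#'   \eqn{\lambda_S K \le 1}.
#' @return Heritability of liability in \[0, 1\].
#' @examples
#' h2_liability_from_sib(0.05, 2)      # 0.371
#' h2_liability_from_sib(0.118, 2.2)   # 0.68 (age-related macular degeneration)
#' h2_liability_from_sib(0.001, 26)    # 0.76 (Crohn's disease)
#' @seealso [lambda_s_from_h2()] for the (approximate) reverse conversion.
#' @export
h2_liability_from_sib <- function(K, lambda_s) {
  check_prevalence(K)
  check_ratio(lambda_s, K)
  tq_T <- stats::qnorm(1 - K)
  z <- stats::dnorm(tq_T)
  i <- z / K
  T1 <- stats::qnorm(1 - lambda_s * K)
  disc <- 1 - (tq_T^2 - T1^2) * (1 - tq_T / i)
  if (any(disc < 0))
    domain_error(
      "incompatible (K, lambda_S): discriminant negative for K = %s, lambda_S = %s",
      fmt_vals(K[disc < 0][1]), fmt_vals(rep(lambda_s, length.out = length(disc))[disc < 0][1]))
  b <- (tq_T - T1 * sqrt(disc)) / (i + T1^2 * (i - tq_T))
  h2 <- b / 0.5
  # clamp pure floating-point overshoot only
  h2[h2 > 1 & h2 <= 1 + 1e-9] <- 1
  h2[h2 < 0 & h2 >= -1e-9] <- 0
  if (any(h2 > 1 | h2 < 0))
    domain_error(
      "(K, lambda_S) imply a heritability of liability outside [0, 1]: %s",
      fmt_vals(h2[h2 > 1 | h2 < 0]))
  h2
}

#' Sibling recurrence risk implied by a heritability of liability
#'
#' The forward companion of [h2_liability_from_sib()]: given prevalence and a
#' heritability of liability (or, more generally, any variance explained on
#' the liability scale by a set of shared genetic factors), returns the
#' sibling recurrence risk ratio that variance would generate. The sibling
#' threshold is \deqn{T_1(h^2) = \frac{T - i\,h^2/2}{\sqrt{1 -
#' (h^2/2)^2\, i(i-T)}}} and \eqn{\lambda_S = (1-\Phi(T_1))/K}.
#'
#' @param K Disease prevalence in (0, 1).
#' @param h2 Variance explained on the liability scale, in \[0, 1\].
#'   Vectorised.
#' @return Sibling recurrence risk ratio (\eqn{\ge 1}).
#' @examples
#' lambda_s_from_h2(0.05, 0.371)  # ~2.0, reversing h2_liability_from_sib
#' lambda_s_from_h2(0.1, 0)       # exactly 1
#' @export
lambda_s_from_h2 <- function(K, h2) {
  check_prevalence(K)
  check_proportion(h2, "h2")
  T <- stats::qnorm(1 - K)
  i <- stats::dnorm(T) / K
  T1 <- (T - i * h2 / 2) / sqrt(1 - (h2 / 2)^2 * i * (i - T))
  (1 - stats::pnorm(T1)) / K
}

#' Broad-sense heritability on the observed (0/1) disease scale
#'
#' From the monozygotic-twin recurrence risk ratio:
#' \eqn{h^2_{01} = (\lambda_{MZ}-1)K/(1-K)}, assuming no common environmental
#' contribution to twin resemblance. This prevalence-dependent quantity lives
#' on the all-or-none disease scale, not the liability scale.
#'
#' @param K Disease prevalence in (0, 1).
#' @param lambda_mz Monozygotic-twin recurrence risk ratio (\eqn{\ge 1},
#'   \eqn{\lambda_{MZ} K \le 1}).
#' @return Broad-sense heritability on the observed scale, in \[0, 1\].
#' @examples
#' h2_observed_from_mz(0.5, 1.5)  # 0.5
#' @export
h2_observed_from_mz <- function(K, lambda_mz) {
  check_prevalence(K)
  check_ratio(lambda_mz, K, what = "lambda_MZ")
  (lambda_mz - 1) * K / (1 - K)
}

#' Recurrence risk ratio from a covariance on the observed scale
#'
#' James' relation: the recurrence risk ratio to relatives of type R is
#' \eqn{\lambda_R = 1 + \mathrm{cov}(X, R)/K^2}, where the covariance is
#' between 0/1 disease status of probands and relatives. For monozygotic
#' twins the covariance equals the genetic variance on the observed scale.
#'
#' @param cov01 Covariance of 0/1 disease status between relatives
#'   (\eqn{\ge 0}).
#' @param K Disease prevalence in (0, 1).
#' @return Recurrence risk ratio \eqn{\lambda_R}.
#' @examples
#' lambda_from_covariance(0, 0.1)            # 1 (no familial resemblance)
#' lambda_from_covariance(0.1 * 0.9, 0.1)    # 1/K: perfect concordance
#' @export
lambda_from_covariance <- function(cov01, K) {
  check_prevalence(K)
  if (!is.numeric(cov01) || anyNA(cov01) || any(cov01 < 0))
    domain_error("cov01 must be a non-negative covariance")
  lambda <- 1 + cov01 / K^2
  K_R <- lambda * K
  if (any(K_R > 1 + 1e-12))
    domain_error(
      "cov01 = %s implies a relative prevalence K_R = %s > 1 at K = %s",
      fmt_vals(cov01[K_R > 1]), fmt_vals(K_R[K_R > 1]), format(K, digits = 6))
  lambda
}

#' Bundle a disease's genetic-epidemiology parameters
#'
#' Validates and stores prevalence, recurrence risks and heritability of
#' liability for one disease. When `lambda_s` is supplied it is treated as
#' authoritative and the heritability of liability is (re)computed from it
#' via [h2_liability_from_sib()]; a user-supplied `h2_liability` that
#' disagrees by more than `1e-3` triggers a warning. When only
#' `h2_liability` is supplied, the implied `lambda_s` is derived via
#' [lambda_s_from_h2()].
#'
#' @param name Disease label (free text).
#' @param K Lifetime prevalence in (0, 1).
#' @param lambda_s Optional sibling recurrence risk ratio.
#' @param lambda_mz Optional monozygotic-twin recurrence risk ratio.
#' @param h2_liability Optional heritability of liability in \[0, 1\].
#' @return An object of class `"disease_model"`.
#' @examples
#' amd <- disease_model("AMD", K = 0.118, lambda_s = 2.2)
#' amd$h2_liability  # 0.68
#' @export
disease_model <- function(name, K, lambda_s = NULL, lambda_mz = NULL,
                          h2_liability = NULL) {
  if (!is.character(name) || length(name) != 1L || is.na(name) ||
      !nzchar(name))
    validation_error("name must be a non-empty string")
  check_prevalence(K)
  if (is.null(lambda_s) && is.null(h2_liability))
    validation_error("disease '%s': supply lambda_s and/or h2_liability", name)
  derived_from <- NULL
  if (!is.null(lambda_s)) {
    check_ratio(lambda_s, K)
    h2 <- h2_liability_from_sib(K, lambda_s)
    if (!is.null(h2_liability)) {
      check_proportion(h2_liability, "h2_liability")
      if (abs(h2_liability - h2) > 1e-3)
        warning(sprintf(paste(
          "disease '%s': supplied h2_liability (%.4f) disagrees with the",
          "value implied by lambda_S (%.4f); lambda_S is authoritative"),
          name, h2_liability, h2), call. = FALSE)
    }
    derived_from <- "lambda_s"
  } else {
    check_proportion(h2_liability, "h2_liability")
    h2 <- h2_liability
    lambda_s <- lambda_s_from_h2(K, h2)
    derived_from <- "h2_liability"
  }
  if (!is.null(lambda_mz)) check_ratio(lambda_mz, K, what = "lambda_MZ")
  structure(list(name = name, K = K, lambda_s = lambda_s,
                 lambda_mz = lambda_mz, h2_liability = h2,
                 derived_from = derived_from),
            class = "disease_model")
}

#' @export
print.disease_model <- function(x, digits = 3, ...) {
  cat("Disease model:", x$name, "\n")
  cat(sprintf("  prevalence K            : %s\n", format(x$K, digits = digits)))
  cat(sprintf("  sibling risk lambda_S   : %s%s\n",
              format(x$lambda_s, digits = digits),
              if (identical(x$derived_from, "h2_liability")) " (derived)" else ""))
  if (!is.null(x$lambda_mz))
    cat(sprintf("  MZ risk lambda_MZ       : %s\n",
                format(x$lambda_mz, digits = digits)))
  cat(sprintf("  heritability of liability: %s%s\n",
              format(x$h2_liability, digits = digits),
              if (identical(x$derived_from, "lambda_s")) " (derived)" else ""))
  invisible(x)
}
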