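# Condition classes: model-domain errors (parameters outside the threshold
# model's admissible region) vs validation errors (malformed input). The CLI
# maps them to exit codes 3 and 2 respectively.

domain_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("liability_domain_error", "liability_error")))
}

validation_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("liability_validation_error", "liability_error")))
}

fmt_vals <- function(x, max = 3L) {
  bad <- format(x[seq_len(min(length(x), max))], digits = 6)
  paste0(paste(bad, collapse = ", "), if (length(x) > max) ", ...")
}

check_prevalence <- function(K, what = "K") {
  if (!is.numeric(K) || length(K) == 0 || anyNA(K) || any(!is.finite(K)))
    domain_error("%s must be a finite probability in (0, 1)", what)
  bad <- K <= 0 | K >= 1
  if (any(bad))
    domain_error("%s must lie strictly within (0, 1); offending value(s): %s",
                 what, fmt_vals(K[bad]))
  if (any(K > 0.5))
    warning(sprintf(paste("%s > 0.5: the threshold model places the affected",
                          "tail above the threshold; interpret with care"),
                    what), call. = FALSE)
  invisible(K)
}

check_proportion <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x) || any(!is.finite(x)))
    domain_error("%s must be a finite proportion in [0, 1]", what)
  bad <- x < 0 | x > 1
  if (any(bad))
    domain_error("%s must lie in [0, 1]; offending value(s): %s",
                 what, fmt_vals(x[bad]))
  invisible(x)
}

check_ratio <- function(lambda, K, what = "lambda_S") {
  if (!is.numeric(lambda) || length(lambda) == 0 || anyNA(lambda) ||
      any(!is.finite(lambda)))
    domain_error("%s must be a finite recurrence-risk ratio >= 1", what)
  if (any(lambda < 1))
    domain_error("%s must be >= 1; offending value(s): %s",
                 what, fmt_vals(lambda[lambda < 1]))
  bad <- lambda * K > 1
  if (any(bad))
    domain_error(
      "%s * K exceeds 1 (a relative's prevalence is a probability); offending %s: %s",
      what, what, fmt_vals(lambda[bad]))
  invisible(lambda)
}
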