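#' A scored, labeled case-control cohort with ranks
#'
#' Stores 0/1 disease status and a risk score per individual and attaches
#' ascending ranks (highest score = rank n), with ties resolved to midranks.
#' Midranks preserve the pairwise-probability definition of the AUC: a tied
#' case-control pair counts one half.
#'
#' @param status Integer/numeric vector of 0 (non-diseased) and 1 (diseased).
#' @param score Numeric vector of risk scores, ascending with risk.
#' @return An object of class `"ranked_cohort"`: a list with `status`,
#'   `score`, `rank`, `n_d`, `n_dprime` and `mean_case_rank`.
#' @examples
#' rc <- ranked_cohort(c(1, 1, 0, 0), c(3.2, 1.4, 2.0, 0.1))
#' rc$mean_case_rank
#' auc_from_ranks(rc)
#' @export
ranked_cohort <- function(status, score) {
  if (length(status) != length(score))
    validation_error("status and score differ in length (%d vs %d)",
                     length(status), length(score))
  if (anyNA(status) || !all(status %in% c(0, 1)))
    validation_error("status must contain only 0 and 1")
  if (!is.numeric(score) || anyNA(score) || any(!is.finite(score)))
    validation_error("score must be finite and numeric")
  status <- as.integer(status)
  n_d <- sum(status == 1L)
  n_dprime <- sum(status == 0L)
  if (n_d == 0L || n_dprime == 0L)
    validation_error(
      "cohort must contain at least one case and one control (n_d = %d, n_d' = %d)",
      n_d, n_dprime)
  r <- rank(score, ties.method = "average")
  structure(list(status = status, score = score, rank = r, n_d = n_d,
                 n_dprime = n_dprime,
                 mean_case_rank = mean(r[status == 1L])),
            class = "ranked_cohort")
}

#' @export
print.ranked_cohort <- function(x, ...) {
  cat(sprintf("Ranked cohort: %d cases, %d controls, mean case rank %.3f\n",
              x$n_d, x$n_dprime, x$mean_case_rank))
  cat(sprintf("  rank AUC %.4f, Somers' D %.4f\n",
              auc_from_ranks(x), somers_d(x)))
  invisible(x)
}

#' Empirical AUC from the mean rank of cases
#'
#' The rank-based (Mann-Whitney) estimator of the AUC: with ascending ranks
#' over the whole cohort and \eqn{\bar r} the mean rank of the \eqn{n_d}
#' cases among \eqn{n_{d'}} controls,
#' \deqn{AUC = \frac{\bar r - (n_d + 1)/2}{n_{d'}}.}
#' With midranks for ties this equals the fraction of case-control pairs
#' ranked concordantly, counting ties as one half. The estimate does not
#' depend on the case:control mix except through sampling error.
#'
#' @param cohort A [ranked_cohort()].
#' @return The empirical AUC, in \[0, 1\].
#' @examples
#' auc_from_mean_rank(9, 10, 13.2)  # 0.82
#' @seealso [auc_from_mean_rank()] for the closed form on summary values,
#'   [somers_d()], [roc_points()].
#' @export
auc_from_ranks <- function(cohort) {
  if (!inherits(cohort, "ranked_cohort"))
    validation_error("cohort must be a ranked_cohort object")
  auc_from_mean_rank(cohort$n_d, cohort$n_dprime, cohort$mean_case_rank)
}

#' @rdname auc_from_ranks
#' @param n_d Number of cases (>= 1).
#' @param n_dprime Number of controls (>= 1).
#' @param mean_case_rank Mean ascending rank of the cases, \eqn{\bar r}.
#' @export
auc_from_mean_rank <- function(n_d, n_dprime, mean_case_rank) {
  if (n_d < 1 || n_dprime < 1)
    validation_error("need at least one case and one control")
  (mean_case_rank - (n_d + 1) / 2) / n_dprime
}

#' Somers' D rank correlation between score and disease status
#'
#' Related to the AUC by \eqn{AUC = (1 + D)/2}, i.e. \eqn{D = 2\,AUC - 1}.
#'
#' @inheritParams auc_from_ranks
#' @return Somers' D, in \[-1, 1\].
#' @export
somers_d <- function(cohort) {
  2 * auc_from_ranks(cohort) - 1
}

#' Empirical ROC curve of a scored cohort
#'
#' Sweeps the score from highest to lowest, emitting cumulative
#' (FPR, TPR) points: a control moves the curve right by
#' \eqn{1/n_{d'}}, a case moves it up by \eqn{1/n_d}, and a block of tied
#' scores is emitted as a single diagonal step.
#'
#' @inheritParams auc_from_ranks
#' @return A data frame of class `"roc_curve"` with columns `fpr` and `tpr`,
#'   starting at (0, 0) and ending at (1, 1).
#' @examples
#' rc <- ranked_cohort(c(1, 0, 1, 0), c(4, 3, 2, 1))
#' roc_points(rc)
#' @export
roc_points <- function(cohort) {
  if (!inherits(cohort, "ranked_cohort"))
    validation_error("cohort must be a ranked_cohort object")
  ord <- order(cohort$score, decreasing = TRUE)
  s <- cohort$score[ord]
  y <- cohort$status[ord]
  # one step per block of tied scores
  blocks <- cumsum(!duplicated(s))
  cases <- tapply(y, blocks, sum)
  totals <- tapply(y, blocks, length)
  tpr <- c(0, cumsum(cases) / cohort$n_d)
  fpr <- c(0, cumsum(totals - cases) / cohort$n_dprime)
  out <- data.frame(fpr = unname(fpr), tpr = unname(tpr))
  class(out) <- c("roc_curve", "data.frame")
  out
}

# trapezoid area under an roc_curve; equals the rank AUC under midranks
roc_trapezoid_area <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                           utils::tail(curve$tpr, -1)) / 2)
}

#' Read a two-column status/score TSV into a ranked cohort
#'
#' Expects tab-separated lines with disease status (0/1) in column 1 and a
#' finite risk score in column 2. A header line is auto-detected (present
#' when the first line does not parse as a status/score pair).
#'
#' @param path Path to the TSV file.
#' @param invert If `TRUE`, scores are negated on read, for scores where
#'   lower values mean higher risk.
#' @return A [ranked_cohort()].
#' @export
read_score_file <- function(path, invert = FALSE) {
  if (!file.exists(path))
    validation_error("score file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L)
    validation_error("score file is empty: %s", path)
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  nums <- suppressWarnings(as.numeric(fields))
  has_header <- length(fields) < 2L || anyNA(nums[1:2]) ||
    !(nums[1] %in% c(0, 1))
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          quote = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    validation_error("score file must have two tab-separated columns: %s", path)
  status <- suppressWarnings(as.numeric(df[[1]]))
  score <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(status) || anyNA(score))
    validation_error("unparsable status/score values in %s (rows: %s)",
                     path, fmt_vals(which(is.na(status) | is.na(score))))
  if (invert) score <- -score
  ranked_cohort(status, score)
}

#' Write a ranked cohort as a two-column status/score TSV
#'
#' @param cohort A [ranked_cohort()].
#' @param path Output path.
#' @param header Write a `status<TAB>score` header line (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_score_file <- function(cohort, path, header = TRUE) {
  if (!inherits(cohort, "ranked_cohort"))
    validation_error("cohort must be a ranked_cohort object")
  df <- data.frame(status = cohort$status, score = cohort$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Write an ROC curve as a TSV of (FPR, TPR) points
#'
#' @param curve A `"roc_curve"` data frame from [roc_points()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roc_points <- function(curve, path) {
  if (!inherits(curve, "roc_curve"))
    validation_error("curve must be an roc_curve object")
  utils::write.table(data.frame(fpr = curve$fpr, tpr = curve$tpr), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
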