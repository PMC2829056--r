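#' Read a disease parameter table (TSV/CSV)
#'
#' Reads a table with one row per disease carrying prevalence and sibling
#' recurrence risk and/or heritability of liability, validating every row
#' through [disease_model()]. Column names are matched case-insensitively:
#' `name` (or `disease`), `K` (or `prevalence`, `prevalence_percent`),
#' `lambda_s`, `h2` (or `h2_liability`). Published tables often print
#' prevalence as a percentage (K x 100); pass `percent = TRUE` to convert.
#'
#' @param path Path to a TSV (`.tsv`/`.txt`) or CSV (`.csv`) file with a
#'   header row. Lines starting with `#` are ignored.
#' @param percent If `TRUE`, the prevalence column is divided by 100.
#' @return A data frame of class `"disease_table"` with columns `name`, `K`,
#'   `lambda_s`, `h2_liability`; the validated [disease_model()] objects are
#'   attached as `attr(, "models")`.
#' @examples
#' tab <- example_disease_table()
#' nrow(tab)  # 19
#' @export
read_disease_table <- function(path, percent = FALSE) {
  if (!file.exists(path))
    validation_error("disease table not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                      quote = "", stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) validation_error("cannot parse %s: %s", path,
                                         conditionMessage(e)))
  if (nrow(df) == 0L)
    validation_error("disease table %s contains no data rows", path)
  nm <- tolower(trimws(names(df)))
  pick <- function(...) {
    idx <- which(nm %in% c(...))
    if (length(idx)) idx[1] else NA_integer_
  }
  i_name <- pick("name", "disease")
  i_k <- pick("k", "prevalence", "prevalence_percent", "k_percent")
  i_lam <- pick("lambda_s", "lambdas", "lambda")
  i_h2 <- pick("h2", "h2_liability", "h2l")
  if (is.na(i_name) || is.na(i_k) || (is.na(i_lam) && is.na(i_h2)))
    validation_error(
      "%s: need columns 'name', 'prevalence' (or 'K'), and 'lambda_s' and/or 'h2'",
      path)
  num_col <- function(i, what) {
    if (is.na(i)) return(rep(NA_real_, nrow(df)))
    x <- suppressWarnings(as.numeric(df[[i]]))
    bad <- which(is.na(x) & !(is.na(df[[i]]) | df[[i]] == ""))
    if (length(bad))
      validation_error("%s: unparsable %s in row(s) %s", path, what,
                       fmt_vals(bad))
    x
  }
  name <- trimws(as.character(df[[i_name]]))
  K <- num_col(i_k, "prevalence")
  if (percent) K <- K / 100
  lam <- num_col(i_lam, "lambda_s")
  h2 <- num_col(i_h2, "h2")
  if (anyDuplicated(name))
    validation_error("%s: duplicated disease name(s): %s", path,
                     paste(unique(name[duplicated(name)]), collapse = ", "))
  models <- vector("list", nrow(df))
  for (r in seq_len(nrow(df))) {
    models[[r]] <- tryCatch(
      disease_model(name[r], K[r],
                    lambda_s = if (is.na(lam[r])) NULL else lam[r],
                    h2_liability = if (is.na(h2[r])) NULL else h2[r]),
      error = function(e)
        validation_error("%s: row %d ('%s'): %s", path, r, name[r],
                         conditionMessage(e)))
  }
  out <- data.frame(
    name = name, K = K,
    lambda_s = vapply(models, function(m) m$lambda_s, numeric(1)),
    h2_liability = vapply(models, function(m) m$h2_liability, numeric(1)),
    stringsAsFactors = FALSE)
  attr(out, "models") <- models
  class(out) <- c("disease_table", "data.frame")
  out
}

#' Packaged disease parameter table
#'
#' Published lifetime prevalence and sibling recurrence risk estimates for
#' 17 complex genetic diseases (19 rows: schizophrenia and bipolar disorder
#' each appear twice with estimates from independent studies), shipped as
#' `inst/extdata/complex_disease_params.tsv` with prevalence printed as a
#' percentage.
#'
#' @return The parsed `"disease_table"`.
#' @export
example_disease_table <- function() {
  read_disease_table(
    system.file("extdata", "complex_disease_params.tsv",
                package = "liabilityAUC", mustWork = TRUE),
    percent = TRUE)
}

# round half away from zero, the convention used in rendered reports
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

#' Batch AUC report for a disease table
#'
#' For every disease in the table, computes the heritability of liability,
#' the AUC when a genomic profile explains all, half and a quarter of the
#' known genetic variance, and -- at the requested observed AUC -- the
#' variance explained on the liability scale, the proportion of the known
#' genetic variance, and the proportion of the sibling recurrence risk
#' explained.
#'
#' @param table A `"disease_table"` from [read_disease_table()], or a single
#'   [disease_model()].
#' @param auc_target Observed AUC at which to invert (default 0.75).
#' @return A data frame of class `"disease_report"` (full precision) with
#'   columns `name`, `K`, `lambda_s`, `h2_liability`, `auc_max`, `auc_half`,
#'   `auc_quar`, `h2x_at_target`, `prop_genetic`, `lambda_s_x`, `prop_sib`.
#'   Rendered output ([format()][format.disease_report], [write_report()])
#'   rounds to 2 decimals, halves away from zero.
#' @examples
#' rep <- render_report(example_disease_table(), auc_target = 0.75)
#' rep[rep$name == "Bladder cancer", c("auc_max", "prop_genetic", "prop_sib")]
#' @export
render_report <- function(table, auc_target = 0.75) {
  models <- if (inherits(table, "disease_model")) list(table)
  else if (inherits(table, "disease_table")) attr(table, "models")
  else validation_error("table must be a disease_table or disease_model")
  if (!is.null(auc_target)) {
    if (!is.numeric(auc_target) || length(auc_target) != 1L ||
        is.na(auc_target))
      validation_error("auc_target must be a single number")
    if (auc_target < 0.5 || auc_target >= 1)
      domain_error("auc_target must lie in [0.5, 1); got %g", auc_target)
  }
  one <- function(m) {
    tryCatch({
      K <- m$K; h2L <- m$h2_liability; lam <- m$lambda_s
      aucs <- auc_from_h2x(K, h2L * c(1, 0.5, 0.25))
      if (!is.null(auc_target)) {
        h2x <- h2x_from_auc(K, auc_target)
        sib <- sib_risk_explained(K, h2x, if (lam > 1) lam else NULL)
        pg <- if (h2L > 0) h2x / h2L else NA_real_
      } else {
        h2x <- NA_real_; pg <- NA_real_
        sib <- list(lambda_s_x = NA_real_, prop_sib = NA_real_)
      }
      data.frame(name = m$name, K = K, lambda_s = lam, h2_liability = h2L,
                 auc_max = aucs[1], auc_half = aucs[2], auc_quar = aucs[3],
                 h2x_at_target = h2x, prop_genetic = pg,
                 lambda_s_x = sib$lambda_s_x, prop_sib = sib$prop_sib,
                 stringsAsFactors = FALSE)
    }, liability_error = function(e)
      stop(errorCondition(sprintf("disease '%s': %s", m$name,
                                  conditionMessage(e)),
                          class = class(e))))
  }
  out <- do.call(rbind, lapply(models, one))
  attr(out, "auc_target") <- auc_target
  class(out) <- c("disease_report", "data.frame")
  out
}

#' @export
format.disease_report <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v)
    formatC(round_half_away(v, digits), format = "f", digits = digits))
  df[] <- lapply(df, as.character)
  widths <- pmax(nchar(names(df)),
                 vapply(df, function(v) max(nchar(v)), integer(1)))
  pad <- function(v, w, left) formatC(v, width = w, flag = if (left) "-" else "")
  cells <- mapply(pad, df, widths, !num, SIMPLIFY = FALSE)
  header <- mapply(pad, names(df), widths, !num)
  c(paste(header, collapse = "  "),
    apply(do.call(cbind, cells), 1, paste, collapse = "  "))
}

#' @export
print.disease_report <- function(x, ...) {
  cat(format(x, ...), sep = "\n")
  invisible(x)
}

#' Write a disease report to file
#'
#' @param report A `"disease_report"` from [render_report()].
#' @param path Output path.
#' @param format `"tsv"` (machine-readable, 2-decimal rounding) or `"text"`
#'   (aligned columns).
#' @param digits Decimal places for rounding (half away from zero).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "text"),
                         digits = 2) {
  format <- match.arg(format)
  if (!inherits(report, "disease_report"))
    validation_error("report must come from render_report()")
  if (format == "text") {
    writeLines(format.disease_report(report, digits = digits), path)
  } else {
    df <- as.data.frame(report)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round_half_away, digits = digits)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
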