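#' Read a coded-statement table from a delimited file
#'
#' Loads a CSV or TSV of manually coded statements -- one row per
#' statement, numeric criterion columns, and one binary veracity column --
#' into the tidy form the audit functions consume.  The delimiter is taken
#' from the file extension (`.tsv`/`.tab` = tab, otherwise comma) unless
#' given.  Rows containing missing values are dropped with a message; the
#' label column must hold exactly two distinct values, which are mapped to
#' 0 (lower / first) and 1 (higher / second).
#'
#' @param path Path to the delimited file (header row required).
#' @param label_col Name of the veracity column.  Default `"label"`.
#' @param delim Field delimiter; `NULL` (default) infers from the
#'   extension.
#' @return A tibble with integer `label` first and the numeric criterion
#'   columns after it.
#' @export
read_coded_table <- function(path, label_col = "label", delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t"
             else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(raw) == 0L) {
    stop("No data rows in `", path, "`.", call. = FALSE)
  }
  if (!label_col %in% names(raw)) {
    stop("Label column `", label_col, "` not found in `", path, "`; ",
         "columns are: ", paste(names(raw), collapse = ", "),
         call. = FALSE)
  }
  complete <- stats::complete.cases(raw)
  if (any(!complete)) {
    message("Dropped ", sum(!complete), " row(s) with missing values.")
    raw <- raw[complete, , drop = FALSE]
    if (nrow(raw) == 0L) {
      stop("All rows had missing values.", call. = FALSE)
    }
  }
  vals <- sort(unique(raw[[label_col]]))
  if (length(vals) != 2L) {
    stop("Label column `", label_col, "` must take exactly 2 values; ",
         "found ", length(vals), ".", call. = FALSE)
  }
  label <- as.integer(raw[[label_col]] == vals[2L])
  crit <- raw[setdiff(names(raw), label_col)]
  if (!all(vapply(crit, is.numeric, logical(1)))) {
    bad <- names(crit)[!vapply(crit, is.numeric, logical(1))]
    stop("Non-numeric criterion column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dplyr::bind_cols(tibble::tibble(label = label), tibble::as_tibble(crit))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a proportion from `correct` successes in
#' `total` trials, via the beta-quantile identity: the lower bound is the
#' `alpha/2` quantile of `Beta(k, n - k + 1)` (0 when `k = 0`) and the
#' upper bound the `1 - alpha/2` quantile of `Beta(k + 1, n - k)` (1 when
#' `k = n`).  Conservative: coverage is at least the nominal level.
#'
#' @param correct Number of successes, `0 <= correct <= total`.
#' @param total Number of trials, `>= 1`.
#' @param level Confidence level in `(0, 1)`.  Default 0.95.
#' @return A one-row tibble: `estimate`, `ci_lower`, `ci_upper`, `level`.
#' @examples
#' clopper_pearson(144, 234)  # approximately [0.5498, 0.6780]
#' @export
clopper_pearson <- function(correct, total, level = 0.95) {
  if (!is.numeric(correct) || !is.numeric(total) || length(correct) != 1L ||
      length(total) != 1L || is.na(correct) || is.na(total) ||
      total < 1 || correct < 0 || correct > total) {
    stop("Need 0 <= correct <= total with total >= 1.", call. = FALSE)
  }
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level >= 1) {
    stop("`level` must lie in (0, 1).", call. = FALSE)
  }
  alpha <- 1 - level
  k <- correct
  n <- total
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  tibble::tibble(estimate = k / n, ci_lower = lower, ci_upper = upper,
                 level = level)
}

#' Audit classifier accuracy on a coded-statement table
#'
#' The accuracy audit contrasting the field's dominant practice with
#' cross-validation: for each requested scheme, fits the pooled-covariance
#' linear discriminant, counts correct classifications, attaches an exact
#' (Clopper-Pearson) binomial confidence interval to the proportion
#' correct, and issues a chance-level verdict -- `"better-than-chance"`
#' only when the whole interval lies above 0.5, else
#' `"not-better-than-chance"`.  On weak-signal data the resubstitution row
#' will often claim better-than-chance classification while the
#' leave-one-out row, a nearly unbiased estimate of out-of-sample
#' accuracy, does not.
#'
#' @param data A coded-statement table (from [read_coded_table()],
#'   [simulate_statements()], or any data frame with a binary label and
#'   numeric criteria).
#' @param label_col Name of the label column.  Default `"label"`.
#' @param schemes Character subset of `"resubstitution"`, `"loocv"`,
#'   `"kfold"`; default the first two (the audit's two printed columns).
#' @param ci_level Confidence level for the exact interval.  Default 0.95.
#' @param priors `"empirical"` (default) uses the table's class
#'   proportions as priors; `"equal"` forces 0.5/0.5; or a length-2
#'   numeric vector.
#' @param k Folds for the k-fold scheme (only used if requested).
#' @param seed Seed for the k-fold fold assignment.
#' @return A tibble of class `"accuracy_audit"`, one row per scheme:
#'   `scheme`, `accuracy`, `correct`, `n_evaluated`, `ci_level`,
#'   `ci_lower`, `ci_upper`, `verdict`.
#' @examples
#' sim <- simulate_statements(100, p = 12, r = 0, seed = 42)
#' audit_accuracy(sim)
#' @export
audit_accuracy <- function(data, label_col = "label",
                           schemes = c("resubstitution", "loocv"),
                           ci_level = 0.95, priors = "empirical",
                           k = 10, seed = NULL) {
  schemes <- match.arg(schemes, c("resubstitution", "loocv", "kfold"),
                       several.ok = TRUE)
  tab <- check_statement_table(data, label_col)
  pri <- resolve_priors(priors, tab$label)
  rows <- purrr::map_dfr(schemes, function(sch) {
    switch(sch,
      resubstitution = accuracy_resubstitution(data, label_col, pri),
      loocv = accuracy_loocv(data, label_col, pri),
      kfold = accuracy_kfold(data, k, label_col, pri, seed)
    )
  })
  ci <- purrr::map2_dfr(rows$correct, rows$n_evaluated,
                        clopper_pearson, level = ci_level)
  out <- dplyr::mutate(
    dplyr::select(rows, "scheme", "accuracy", "correct", "n_evaluated"),
    ci_level = ci_level,
    ci_lower = ci$ci_lower,
    ci_upper = ci$ci_upper,
    verdict = chance_verdict(ci$ci_lower)
  )
  class(out) <- c("accuracy_audit", class(out))
  out
}

# better-than-chance iff the whole CI lies above 0.5
chance_verdict <- function(ci_lower) {
  ifelse(ci_lower > 0.5, "better-than-chance", "not-better-than-chance")
}

resolve_priors <- function(priors, label) {
  if (is.numeric(priors)) {
    check_priors(priors)
    return(priors)
  }
  if (is.character(priors) && length(priors) == 1L) {
    if (priors == "equal") return(c(0.5, 0.5))
    if (priors == "empirical") {
      p1 <- mean(label == 1L)
      return(c(1 - p1, p1))
    }
  }
  stop('`priors` must be "empirical", "equal", or two probabilities.',
       call. = FALSE)
}

#' @export
print.accuracy_audit <- function(x, ...) {
  cat("Accuracy audit (exact binomial ",
      format(100 * x$ci_level[1L]), "% CIs)\n", sep = "")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-16s %6.2f%%  [%.2f-%.2f]  %s  (%d/%d)\n",
                x$scheme[i], 100 * x$accuracy[i], 100 * x$ci_lower[i],
                100 * x$ci_upper[i], x$verdict[i], x$correct[i],
                x$n_evaluated[i]))
  }
  invisible(x)
}
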