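#' Class-mean shift implied by a point-biserial correlation
#'
#' For balanced two-class data with unit within-class standard deviation, a
#' standardized class-mean difference (Cohen's d) of `delta` yields a
#' population point-biserial correlation `r = delta / sqrt(delta^2 + 4)`
#' between each predictor and the 0/1 class label.  This function inverts
#' that relationship: given the target correlation `r`, it returns the mean
#' shift `delta = 2 r / sqrt(1 - r^2)` the generator must apply.
#'
#' @param r Target point-biserial correlation, in `[0, 1)`.
#' @return The class-mean separation in within-class standard-deviation
#'   units (Cohen's d), a non-negative scalar.
#' @seealso [r_from_effect_shift()] for the forward conversion,
#'   [simulate_statements()] for the generator that consumes it.
#' @examples
#' effect_shift_from_r(0)      # no association, identical class means
#' effect_shift_from_r(0.124)  # approximately 0.25 SD separation
#' @export
effect_shift_from_r <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r >= 1) {
    stop("`r` must be a single correlation in [0, 1).", call. = FALSE)
  }
  2 * r / sqrt(1 - r^2)
}

#' Point-biserial correlation implied by a class-mean shift
#'
#' Forward companion of [effect_shift_from_r()]: for balanced classes with
#' unit within-class variance, a standardized mean difference `d` gives a
#' population point-biserial correlation `d / sqrt(d^2 + 4)`.
#'
#' @param d Standardized mean difference (Cohen's d), `d >= 0`.
#' @return The population point-biserial correlation in `[0, 1)`.
#' @export
r_from_effect_shift <- function(d) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0) {
    stop("`d` must be a single non-negative number.", call. = FALSE)
  }
  d / sqrt(d^2 + 4)
}

#' Simulate a coded-statement table with a prescribed predictor-outcome
#' correlation
#'
#' Generates `n` observations split exactly 50/50 over a binary outcome
#' (`label`: 0 = truthful-proxy, 1 = deceptive-proxy) with `p` continuous
#' criterion scores.  Conditional on class, every criterion is an
#' independent Normal with unit variance; the two class means differ by
#' `effect_shift_from_r(r)` standard deviations (centered at
#' `-delta/2` and `+delta/2`), so the population point-biserial correlation
#' of each criterion with the label is exactly `r`.  This emulates
#' verbal-credibility criterion tables (e.g. 19 CBCA-like, 12 SCAN-like or
#' 8 reality-monitoring-like columns) without any real data.
#'
#' Criteria are conditionally independent given the class; marginally this
#' induces an inter-criterion correlation of `r^2`.
#'
#' @param n Sample size; must be even and at least 4 so the class split is
#'   exactly `n/2` / `n/2`.
#' @param p Number of criterion columns, at least 1.
#' @param r Target point-biserial correlation of each criterion with the
#'   label, in `[0, 1)`.
#' @param seed Optional integer seed.  Identical `(n, p, r, seed)` calls
#'   return bit-identical tables; the caller's RNG state is untouched.
#' @return A tibble with columns `label` (integer 0/1) and `c1 ... cp`
#'   (doubles), carrying the generating design as the `"design"` attribute.
#' @examples
#' sim <- simulate_statements(40, p = 19, r = 0, seed = 1)
#' table(sim$label)
#' @export
simulate_statements <- function(n, p, r, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 4 || n %% 2 != 0) {
    stop("`n` must be an even sample size of at least 4 (exact 50/50 balance).",
         call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 1) {
    stop("`p` must be a positive number of criteria.", call. = FALSE)
  }
  n <- as.integer(n)
  p <- as.integer(p)
  delta <- effect_shift_from_r(r)

  draw <- function() {
    label <- rep(c(0L, 1L), each = n %/% 2L)
    center <- ifelse(label == 1L, delta / 2, -delta / 2)
    features <- matrix(stats::rnorm(n * p), nrow = n, ncol = p) + center
    colnames(features) <- paste0("c", seq_len(p))
    out <- dplyr::bind_cols(tibble::tibble(label = label),
                            tibble::as_tibble(features))
    attr(out, "design") <- list(n = n, p = p, r = r, balance = 0.5,
                                seed = seed)
    out
  }

  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Per-criterion point-biserial correlation with the class label
#'
#' Pearson correlation of every criterion column with the 0/1 label vector
#' -- the empirical counterpart of the `r` the generator targets.
#'
#' @param data A data frame with a binary label column and numeric
#'   criterion columns (e.g. from [simulate_statements()]).
#' @param label_col Name of the label column.  Default `"label"`.
#' @return A tibble with one row per criterion: `column`, `r_pb`.
#' @export
point_biserial <- function(data, label_col = "label") {
  tab <- check_statement_table(data, label_col)
  y <- tab$label
  if (length(unique(y)) < 2L) {
    stop("Correlation with the label is undefined: only one class present.",
         call. = FALSE)
  }
  x <- tab$features
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("Correlation is undefined for constant criterion column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    column = colnames(x),
    r_pb = as.numeric(stats::cor(x, y))
  )
}

#' Write a simulated coded-statement table to CSV
#'
#' Convenience wrapper that simulates a table with [simulate_statements()]
#' and writes it as a plain CSV (`c1 ... cp` columns plus `label`), the
#' format [read_coded_table()] consumes -- a synthetic stand-in for real
#' coded-statement exports.
#'
#' @inheritParams simulate_statements
#' @param path File path to write.
#' @return The simulated tibble, invisibly.
#' @export
simulate_fixture_csv <- function(n, p, r, seed = NULL, path) {
  sim <- simulate_statements(n, p, r, seed)
  readr::write_csv(dplyr::relocate(sim, "label", .after = dplyr::last_col()),
                   path)
  invisible(sim)
}

# Split a statement table into label vector + feature matrix, validating
# shape: the label column exists, is binary 0/1 (or coercible two-level),
# and no values are missing.
check_statement_table <- function(data, label_col) {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    stop("`data` must be a non-empty data frame.", call. = FALSE)
  }
  if (!label_col %in% names(data)) {
    stop("Label column `", label_col, "` not found.", call. = FALSE)
  }
  y <- data[[label_col]]
  vals <- sort(unique(y))
  if (length(vals) > 2L) {
    stop("Label column `", label_col, "` must be binary; found ",
         length(vals), " distinct values.", call. = FALSE)
  }
  y <- if (length(vals) == 2L) {
    as.integer(y == vals[2L])
  } else {
    # single-class table: preserve 0/1 coding where possible, else code as 0
    rep(as.integer(isTRUE(vals[1L] == 1)), length(y))
  }
  feat_cols <- setdiff(names(data), label_col)
  x <- as.matrix(data[feat_cols])
  if (!is.numeric(x)) {
    stop("All criterion columns must be numeric.", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("Missing values are not allowed.", call. = FALSE)
  }
  list(label = y, features = x, levels = vals)
}
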