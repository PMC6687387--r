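#' Fit a two-class pooled-covariance linear discriminant
#'
#' The classifier every accuracy-estimation scheme in this package
#' evaluates: class means are the per-class feature averages, the shared
#' covariance is the pooled within-class covariance with divisor `n - 2`,
#' and class priors are explicit (equal by default, matching a balanced
#' design).  A numerically singular pooled covariance is handled by a
#' Moore-Penrose pseudo-inverse with a warning rather than failure, so
#' leave-one-out fits at small `n` relative to `p` remain usable.
#'
#' @param data Data frame with a binary label column and numeric criterion
#'   columns.
#' @param label_col Name of the label column.  Default `"label"`.
#' @param priors Length-2 numeric vector of class priors `(class 0,
#'   class 1)`, each in `(0, 1)`, summing to 1.  Default `c(0.5, 0.5)`.
#' @return An object of class `"lda_pooled"`: class means, pooled
#'   covariance and its (pseudo-)inverse, priors, and feature names.
#' @examples
#' sim <- simulate_statements(100, p = 5, r = 0.3, seed = 7)
#' fit <- fit_lda(sim)
#' tidy(fit)
#' @export
fit_lda <- function(data, label_col = "label", priors = c(0.5, 0.5)) {
  tab <- check_statement_table(data, label_col)
  check_priors(priors)
  if (nrow(tab$features) < 3L) {
    stop("Need at least 3 observations to pool a within-class covariance.",
         call. = FALSE)
  }
  fit <- fit_lda_matrix(tab$features, tab$label, priors)
  fit$levels <- tab$levels
  fit
}

check_priors <- function(priors) {
  if (!is.numeric(priors) || length(priors) != 2L || anyNA(priors) ||
      any(priors <= 0) || any(priors >= 1) ||
      abs(sum(priors) - 1) > 1e-8) {
    stop("`priors` must be two probabilities in (0, 1) summing to 1.",
         call. = FALSE)
  }
  invisible(priors)
}

#' Predict classes or posteriors from a pooled-covariance discriminant
#'
#' Applies the linear rule: assign the class maximising
#' `x' S^{-1} mu_k - mu_k' S^{-1} mu_k / 2 + log prior_k`.  Exact ties in
#' the two discriminant scores go to class 0, so predictions are fully
#' deterministic.
#'
#' @param object A fitted `"lda_pooled"` model.
#' @param newdata Data frame or matrix of criterion columns; must contain
#'   the model's features.
#' @param type `"class"` (default) for integer 0/1 labels, `"posterior"`
#'   for the class-1 posterior probability, `"score"` for the raw
#'   discriminant-score difference (class 1 minus class 0).
#' @param ... Unused.
#' @return A vector of length `nrow(newdata)`.
#' @export
predict.lda_pooled <- function(object, newdata,
                               type = c("class", "posterior", "score"),
                               ...) {
  type <- match.arg(type)
  x <- if (is.matrix(newdata)) newdata else {
    nd <- as.data.frame(newdata)
    missing <- setdiff(object$features, names(nd))
    if (length(missing) > 0L) {
      stop("`newdata` lacks model feature(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    as.matrix(nd[object$features])
  }
  if (ncol(x) != object$p) {
    stop("Feature dimension mismatch: model has ", object$p,
         ", data has ", ncol(x), ".", call. = FALSE)
  }
  w <- object$pooled_inv %*% (object$mean1 - object$mean0)
  # score difference d1 - d0; the decision boundary is score == 0
  offset <- -0.5 * sum((object$mean1 + object$mean0) * w) +
    log(object$prior1 / object$prior0)
  score <- drop(x %*% w) + offset
  switch(type,
    class = as.integer(score > 0),  # ties (score == 0) resolve to class 0
    posterior = stats::plogis(score),
    score = score
  )
}

#' Proportion of correct predictions
#'
#' @param predicted,truth Equal-length label vectors.
#' @return Proportion of positions where the two agree, in `[0, 1]`.
#' @export
classification_accuracy <- function(predicted, truth) {
  if (length(predicted) == 0L || length(truth) == 0L) {
    stop("Cannot score accuracy of empty label vectors.", call. = FALSE)
  }
  if (length(predicted) != length(truth)) {
    stop("`predicted` and `truth` must have equal length.", call. = FALSE)
  }
  mean(predicted == truth)
}

#' @export
print.lda_pooled <- function(x, ...) {
  cat("Two-class pooled-covariance linear discriminant\n")
  cat(sprintf("  features: %d   n: %d (%d / %d per class)\n",
              x$p, x$n, x$n0, x$n1))
  cat(sprintf("  priors:   %.3f / %.3f%s\n", x$prior0, x$prior1,
              if (x$singular) "   [pseudo-inverse fit]" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted pooled-covariance discriminant
#'
#' One row per feature: the two class means and the discriminant
#' coefficient (the weight of the linear rule,
#' `S^{-1} (mu_1 - mu_0)`).
#'
#' @param x A `"lda_pooled"` model.
#' @param ... Unused.
#' @return A tibble with columns `term`, `mean_0`, `mean_1`, `coefficient`.
#' @export
tidy.lda_pooled <- function(x, ...) {
  tibble::tibble(
    term = x$features,
    mean_0 = unname(x$mean0),
    mean_1 = unname(x$mean1),
    coefficient = drop(x$pooled_inv %*% (x$mean1 - x$mean0))
  )
}

#' Glance at a fitted pooled-covariance discriminant
#'
#' @param x A `"lda_pooled"` model.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `n_class0`, `n_class1`, `p`, `prior0`,
#'   `prior1`, `singular`.
#' @export
glance.lda_pooled <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_class0 = x$n0, n_class1 = x$n1, p = x$p,
    prior0 = x$prior0, prior1 = x$prior1, singular = x$singular
  )
}
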