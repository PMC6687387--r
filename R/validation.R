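#' Accuracy-estimation schemes for the pooled-covariance discriminant
#'
#' Four ways of estimating the accuracy of a two-class linear discriminant,
#' each returning a one-row tibble (`scheme`, `accuracy`, `correct`,
#' `n_evaluated`, `k`) so results bind into audit tables:
#'
#' * `accuracy_resubstitution()` -- the "training-set optimisation"
#'   practice: fit on all rows and score the same rows.  Optimistically
#'   biased, badly so when `n` is small relative to `p`.
#' * `accuracy_loocv()` -- leave-one-out cross-validation: `n` fits, each
#'   on `n - 1` rows, scoring the single held-out row.  A deterministic
#'   function of the data (no fold randomness).
#' * `accuracy_kfold()` -- stratified k-fold cross-validation: rows of
#'   each class are shuffled and dealt round-robin into `k` folds, so
#'   per-class fold counts differ by at most 1; each fold is held out
#'   once.  The estimate is the pooled proportion of correct held-out
#'   predictions (an exact count ratio; identical to the mean of per-fold
#'   accuracies whenever the strata divide `k` evenly, e.g. 100 balanced
#'   statements in 10 folds of 5 + 5).
#' * `accuracy_independent()` -- independent-sample validation: fit on
#'   `train`, score on `test` only.
#'
#' @param data,train,test Data frames with a binary label column and
#'   numeric criterion columns.
#' @param label_col Name of the label column.  Default `"label"`.
#' @param priors Class priors passed to [fit_lda()].  Default equal.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Optional seed fixing the fold assignment; with a given
#'   seed the k-fold estimate is reproducible.
#' @return A one-row tibble: `scheme`, `accuracy`, `correct`,
#'   `n_evaluated`, `k` (`NA` except for k-fold).  The k-fold result also
#'   carries its fold assignment as the `"folds"` attribute.
#' @name accuracy_schemes
#' @examples
#' sim <- simulate_statements(60, p = 4, r = 0.3, seed = 2)
#' accuracy_resubstitution(sim)
#' accuracy_loocv(sim)
NULL

estimate_row <- function(scheme, correct, n_evaluated, k = NA_integer_) {
  tibble::tibble(
    scheme = scheme,
    accuracy = correct / n_evaluated,
    correct = as.integer(correct),
    n_evaluated = as.integer(n_evaluated),
    k = as.integer(k)
  )
}

#' @rdname accuracy_schemes
#' @export
accuracy_resubstitution <- function(data, label_col = "label",
                                    priors = c(0.5, 0.5)) {
  tab <- check_statement_table(data, label_col)
  fit <- fit_lda(data, label_col, priors)
  pred <- predict(fit, tab$features)
  estimate_row("resubstitution", sum(pred == tab$label), length(pred))
}

#' @rdname accuracy_schemes
#' @export
accuracy_loocv <- function(data, label_col = "label", priors = c(0.5, 0.5)) {
  tab <- check_statement_table(data, label_col)
  y <- tab$label
  x <- tab$features
  n <- length(y)
  if (n < 3L) stop("Leave-one-out needs at least 3 observations.",
                   call. = FALSE)
  correct <- 0L
  for (i in seq_len(n)) {
    if (sum(y[-i] == y[i]) == 0L) {
      stop("Leaving out row ", i, " empties its class; ",
           "leave-one-out is not defined for this table.", call. = FALSE)
    }
    fit <- fit_lda_matrix(x[-i, , drop = FALSE], y[-i], priors)
    pred <- predict(fit, x[i, , drop = FALSE])
    correct <- correct + as.integer(pred == y[i])
  }
  estimate_row("loocv", correct, n)
}

#' @rdname accuracy_schemes
#' @export
accuracy_kfold <- function(data, k, label_col = "label",
                           priors = c(0.5, 0.5), seed = NULL) {
  tab <- check_statement_table(data, label_col)
  y <- tab$label
  x <- tab$features
  n <- length(y)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 2 || k > n) {
    stop("`k` must satisfy 2 <= k <= n.", call. = FALSE)
  }
  k <- as.integer(k)
  assign_folds <- function() {
    folds <- integer(n)
    offset <- 0L
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      # round-robin deal, continuing across classes so per-class and
      # overall fold counts each differ by at most 1 (and k = n gives
      # singleton folds, making the estimate coincide with loocv)
      folds[idx] <- (offset + seq_along(idx) - 1L) %% k + 1L
      offset <- offset + length(idx)
    }
    folds
  }
  folds <- if (is.null(seed)) assign_folds() else
    withr::with_seed(seed, assign_folds())

  correct <- 0L
  scored <- 0L
  for (f in seq_len(k)) {
    hold <- which(folds == f)
    if (length(hold) == 0L) next
    fit <- fit_lda_matrix(x[-hold, , drop = FALSE], y[-hold], priors)
    pred <- predict(fit, x[hold, , drop = FALSE])
    correct <- correct + sum(pred == y[hold])
    scored <- scored + length(hold)
  }
  out <- estimate_row("kfold", correct, scored, k = k)
  attr(out, "folds") <- folds
  out
}

#' @rdname accuracy_schemes
#' @export
accuracy_independent <- function(train, test, label_col = "label",
                                 priors = c(0.5, 0.5)) {
  fit <- fit_lda(train, label_col, priors)
  tab <- check_statement_table(test, label_col)
  if (ncol(tab$features) != fit$p) {
    stop("Train and test feature dimensions differ (", fit$p, " vs ",
         ncol(tab$features), ").", call. = FALSE)
  }
  pred <- predict(fit, tab$features)
  estimate_row("independent_test", sum(pred == tab$label), length(pred))
}

# Matrix-level fit used in the cross-validation inner loops, skipping the
# data-frame validation that fit_lda repeats.
fit_lda_matrix <- function(x, y, priors) {
  n0 <- sum(y == 0L)
  n1 <- sum(y == 1L)
  if (n0 == 0L || n1 == 0L) {
    stop("Cannot fit a two-class discriminant: only one class present.",
         call. = FALSE)
  }
  n <- n0 + n1
  mean0 <- colMeans(x[y == 0L, , drop = FALSE])
  mean1 <- colMeans(x[y == 1L, , drop = FALSE])
  c0 <- sweep(x[y == 0L, , drop = FALSE], 2L, mean0)
  c1 <- sweep(x[y == 1L, , drop = FALSE], 2L, mean1)
  pooled <- (crossprod(c0) + crossprod(c1)) / (n - 2)
  inv <- tryCatch(chol2inv(chol(pooled)), error = function(e) NULL)
  singular <- is.null(inv)
  if (singular) {
    warning("Pooled covariance is numerically singular; ",
            "using a Moore-Penrose pseudo-inverse.", call. = FALSE)
    inv <- MASS::ginv(pooled)
  }
  structure(
    list(mean0 = mean0, mean1 = mean1, pooled_cov = pooled,
         pooled_inv = inv, prior0 = priors[1L], prior1 = priors[2L],
         p = ncol(x), n = n, n0 = n0, n1 = n1,
         features = colnames(x), levels = c(0L, 1L), singular = singular),
    class = "lda_pooled"
  )
}
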