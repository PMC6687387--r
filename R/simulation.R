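#' Configure a factorial accuracy simulation
#'
#' Bundles the design of a Monte-Carlo accuracy study: a grid of even
#' sample sizes, predictor counts, target point-biserial correlations, the
#' number of replicate datasets per design cell, and a master seed from
#' which every cell/replicate sub-seed is derived deterministically (so any
#' cell is reproducible in isolation and results do not depend on
#' execution order).
#'
#' The defaults reproduce the headline study conditions: `n` from 40 to
#' 1000 in steps of 10, 100 replicates per cell, balanced classes and
#' equal priors throughout.
#'
#' @param n_min,n_max,n_step Sample-size grid (all even, strictly
#'   increasing).  Defaults 40, 1000, 10.
#' @param p_list Predictor counts, one curve per value.  Default
#'   `c(8, 12, 19)` (reality-monitoring-, SCAN- and CBCA-sized batteries).
#' @param r_list Target predictor-outcome correlations.  Default
#'   `c(0, 0.1)` (a non-diagnostic and a weakly diagnostic battery).
#' @param reps Replicate datasets per design cell.  Default 100.
#' @param schemes Accuracy-estimation schemes to run, a subset of
#'   `"resubstitution"`, `"loocv"`.
#' @param seed Master seed (integer).  Default 1.
#' @return A `"study_config"` list.
#' @export
study_config <- function(n_min = 40, n_max = 1000, n_step = 10,
                         p_list = c(8, 12, 19), r_list = c(0, 0.1),
                         reps = 100,
                         schemes = c("resubstitution", "loocv"),
                         seed = 1) {
  if (!is.numeric(n_step) || length(n_step) != 1L || is.na(n_step) ||
      n_step <= 0) {
    stop("`n_step` must be a positive step size.", call. = FALSE)
  }
  n_grid <- seq(n_min, n_max, by = n_step)
  if (length(n_grid) == 0L || any(n_grid %% 2 != 0) || any(n_grid < 4)) {
    stop("The sample-size grid must contain even values >= 4.",
         call. = FALSE)
  }
  if (any(diff(n_grid) <= 0)) {
    stop("The sample-size grid must be strictly increasing.", call. = FALSE)
  }
  if (!is.numeric(reps) || reps < 1) {
    stop("`reps` must be at least 1.", call. = FALSE)
  }
  schemes <- match.arg(schemes, c("resubstitution", "loocv"),
                       several.ok = TRUE)
  structure(
    list(n_grid = as.integer(n_grid), p_list = as.integer(p_list),
         r_list = as.numeric(r_list), reps = as.integer(reps),
         schemes = schemes, seed = as.integer(seed)),
    class = "study_config"
  )
}

# Deterministic sub-seed for one (study, p, r, n, replicate, role) cell,
# folded into [0, 2^31).  All randomness in a study flows through these.
cell_seed <- function(master, study, p, r, n, rep, role = 0L) {
  parts <- c(master, study, p, round(r * 1e6), n, rep, role)
  acc <- 0
  for (v in parts) acc <- (acc * 1000003 + (v %% 2147483647)) %% 2147483647
  as.integer(acc)
}

#' Resubstitution accuracy curves over sample size (study 1)
#'
#' For every cell of the factorial design `(p, r, n)`, simulates `reps`
#' independent balanced datasets, fits the pooled-covariance discriminant
#' with equal priors on each, scores it on the same data (resubstitution),
#' and averages the accuracies.  The resulting curves show how strongly
#' the training-set optimisation practice inflates accuracy at small `n`
#' -- most dramatically for many predictors with no true signal.
#'
#' @param config A [study_config()].
#' @return A tibble of class `"accuracy_curves"`: one row per `(p, r, n)`
#'   with `scheme`, `mean_accuracy`, `sd_accuracy`, `reps`.
#' @examples
#' cfg <- study_config(n_max = 100, p_list = 8, r_list = 0, reps = 5)
#' run_study1(cfg)
#' @export
run_study1 <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cells <- tidyr::expand_grid(p = config$p_list, r = config$r_list,
                              n = config$n_grid)
  res <- purrr::pmap(cells, function(p, r, n) {
    accs <- vapply(seq_len(config$reps), function(rep) {
      sim <- simulate_statements(
        n, p, r, seed = cell_seed(config$seed, 1L, p, r, n, rep))
      accuracy_resubstitution(sim)$accuracy
    }, numeric(1))
    tibble::tibble(p = p, r = r, n = n, scheme = "resubstitution",
                   mean_accuracy = mean(accs),
                   sd_accuracy = stats::sd(accs),
                   reps = config$reps)
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("accuracy_curves", class(out))
  out
}

#' Estimator-minus-test accuracy difference curves (study 2)
#'
#' The paired design contrasting accuracy estimators against independent
#' validation.  For each replicate at each grid `n`: one training dataset
#' and one independently simulated test dataset of the same size and
#' design are drawn; the discriminant is fitted once on the full training
#' data and scored on the test set (the reference accuracy); the
#' resubstitution estimate and (optionally) the leave-one-out estimate are
#' computed on the training data; and the per-replicate differences
#' (estimator minus independent-test accuracy) are averaged per `n`.
#' Positive values mean the estimator overstates out-of-sample accuracy.
#'
#' Defaults for this study follow [study2_config()]: `p = 19` CBCA-sized
#' batteries with per-criterion `r = 0.124`.
#'
#' @param config A [study_config()]; its `schemes` field selects which
#'   difference curves to compute.
#' @return A tibble of class `"difference_curves"`: one row per
#'   `(scheme, n)` with `mean_diff`, `sd_diff`, `mean_scheme`,
#'   `mean_test`, `reps`, `p`, `r`.
#' @export
run_study2 <- function(config) {
  stopifnot(inherits(config, "study_config"))
  if (length(config$p_list) != 1L || length(config$r_list) != 1L) {
    stop("The paired-difference study uses a single (p, r) cell; ",
         "got multiple.", call. = FALSE)
  }
  p <- config$p_list
  r <- config$r_list
  res <- purrr::map(config$n_grid, function(n) {
    diffs <- purrr::map(seq_len(config$reps), function(rep) {
      train <- simulate_statements(
        n, p, r, seed = cell_seed(config$seed, 2L, p, r, n, rep, role = 0L))
      test <- simulate_statements(
        n, p, r, seed = cell_seed(config$seed, 2L, p, r, n, rep, role = 1L))
      test_acc <- accuracy_independent(train, test)$accuracy
      out <- list(test = test_acc)
      if ("resubstitution" %in% config$schemes) {
        out$resubstitution <- accuracy_resubstitution(train)$accuracy
      }
      if ("loocv" %in% config$schemes) {
        out$loocv <- accuracy_loocv(train)$accuracy
      }
      out
    })
    test_acc <- purrr::map_dbl(diffs, "test")
    purrr::map_dfr(config$schemes, function(sch) {
      est <- purrr::map_dbl(diffs, sch)
      d <- est - test_acc
      tibble::tibble(scheme = sch, n = n,
                     mean_diff = mean(d), sd_diff = stats::sd(d),
                     mean_scheme = mean(est), mean_test = mean(test_acc),
                     reps = config$reps, p = p, r = r)
    })
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("difference_curves", class(out))
  out
}

#' @rdname run_study2
#' @param ... Overrides passed to [study_config()].
#' @export
study2_config <- function(...) {
  defaults <- list(p_list = 19, r_list = 0.124)
  args <- utils::modifyList(defaults, list(...))
  do.call(study_config, args)
}

#' Write and re-read simulation curves
#'
#' `export_curves()` writes any curve tibble (study-1 accuracy curves or
#' study-2 difference curves) as a plain CSV that round-trips losslessly;
#' `read_curves()` reads it back, restoring the curve class from the
#' columns present.
#'
#' @param curves A tibble from [run_study1()] or [run_study2()].
#' @param path File path for the CSV.
#' @return `export_curves()` returns `path` invisibly; `read_curves()`
#'   returns the curves tibble.
#' @export
export_curves <- function(curves, path) {
  if (!is.data.frame(curves)) {
    stop("`curves` must be a data frame of simulation curves.",
         call. = FALSE)
  }
  readr::write_csv(curves, path)
  invisible(path)
}

#' @rdname export_curves
#' @export
read_curves <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         progress = FALSE)
  cls <- if ("mean_diff" %in% names(out)) "difference_curves"
         else if ("mean_accuracy" %in% names(out)) "accuracy_curves"
         else NULL
  if (!is.null(cls)) class(out) <- c(cls, class(out))
  out
}
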