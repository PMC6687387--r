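test_that("the hand-computable 1-D fit recovers means, variance and boundary", {
  fit <- fit_lda(hand_table_1d())
  expect_equal(unname(fit$mean0), 0)
  expect_equal(unname(fit$mean1), 2)
  expect_equal(unname(drop(fit$pooled_cov)), 1)

  # equal priors put the boundary at the mean midpoint, ties to class 0
  newx <- matrix(c(0.9, 1.1, 1.0), ncol = 1,
                 dimnames = list(NULL, "c1"))
  expect_identical(predict(fit, newx), c(0L, 1L, 0L))
})

test_that("tidy() and glance() summarise the fitted discriminant", {
  fit <- fit_lda(hand_table_1d())
  td <- tidy(fit)
  expect_identical(td$term, "c1")
  expect_equal(td$coefficient, 2)  # S^{-1}(mu1 - mu0) = 2 / 1
  gl <- glance(fit)
  expect_identical(gl$n, 6L)
  expect_identical(gl$p, 1L)
  expect_false(gl$singular)
})

test_that("predictions and posteriors match a brute-force density oracle", {
  withr::local_seed(42)
  for (i in 1:20) {
    inst <- random_labeled_matrix(30, 3, shift = runif(1, 0, 1.5))
    fit <- fit_lda(inst$data)
    xte <- matrix(rnorm(15 * 3), 15, 3, dimnames = list(NULL, paste0("c", 1:3)))
    oracle <- brute_gaussian_classify(inst$x, inst$y, xte)
    expect_identical(predict(fit, xte), oracle$class)
    expect_equal(predict(fit, xte, type = "posterior"), oracle$posterior1,
                 tolerance = 1e-10)
  }
})

test_that("predictions agree with an established LDA implementation", {
  withr::local_seed(7)
  for (i in 1:5) {
    inst <- random_labeled_matrix(40, 4, shift = 0.8)
    fit <- fit_lda(inst$data)
    ref <- MASS::lda(inst$x, grouping = inst$y, prior = c(0.5, 0.5))
    xte <- matrix(rnorm(25 * 4), 25, 4, dimnames = list(NULL, paste0("c", 1:4)))
    expect_identical(predict(fit, xte),
                     as.integer(as.character(predict(ref, xte)$class)))
  }
})

test_that("predictions are invariant under a common affine rescaling", {
  withr::local_seed(13)
  inst <- random_labeled_matrix(30, 3, shift = 0.5)
  xte <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, paste0("c", 1:3)))
  base <- predict(fit_lda(inst$data), xte)

  scaled <- inst$data
  scaled[paste0("c", 1:3)] <- 10 * scaled[paste0("c", 1:3)] + 3
  expect_identical(predict(fit_lda(scaled), 10 * xte + 3), base)
})

test_that("spherical pooled covariance reduces the rule to nearest class mean", {
  # per-class cross pattern: pooled covariance is exactly a multiple of I
  cross <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  m0 <- c(0, 0)
  m1 <- c(1.5, 0.5)
  x <- rbind(sweep(cross, 2, m0, "+"), sweep(cross, 2, m1, "+"))
  colnames(x) <- c("c1", "c2")
  d <- dplyr::bind_cols(tibble::tibble(label = rep(0:1, each = 4)),
                        tibble::as_tibble(x))
  fit <- fit_lda(d)
  expect_equal(fit$pooled_cov, diag(2/3, 2), ignore_attr = TRUE)

  xte <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("c1", "c2")))
  d0 <- rowSums(sweep(xte, 2, m0)^2)
  d1 <- rowSums(sweep(xte, 2, m1)^2)
  expect_identical(predict(fit, xte), as.integer(d1 < d0))
})

test_that("identical class distributions give a near-zero discriminant", {
  pts <- rbind(diag(3), -diag(3))
  colnames(pts) <- paste0("c", 1:3)
  # the same six points in both classes: means and covariances coincide
  d <- dplyr::bind_cols(tibble::tibble(label = rep(0:1, each = 6)),
                        tibble::as_tibble(rbind(pts, pts)))
  fit <- fit_lda(d)
  expect_lt(max(abs(tidy(fit)$coefficient)), 1e-10)
})

test_that("a singular pooled covariance falls back to a pseudo-inverse", {
  withr::local_seed(3)
  inst <- random_labeled_matrix(6, 10)  # p > n forces singularity
  expect_warning(fit <- fit_lda(inst$data), "singular")
  expect_true(fit$singular)
  pred <- suppressWarnings(predict(fit, inst$x))
  expect_true(all(pred %in% c(0L, 1L)))
})

test_that("fit and predict reject malformed inputs", {
  expect_error(fit_lda(tibble::tibble(label = rep(1L, 5), c1 = rnorm(5))),
               "one class")
  expect_error(fit_lda(hand_table_1d(), priors = c(0.7, 0.7)), "priors")
  fit <- fit_lda(hand_table_1d())
  bad <- matrix(0, 2, 2, dimnames = list(NULL, c("c1", "c2")))
  expect_error(predict(fit, bad), "dimension|lacks")
  expect_error(predict(fit, tibble::tibble(x = 1)), "lacks")
})

test_that("accuracy is the exact fraction of agreements", {
  expect_equal(classification_accuracy(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(classification_accuracy(c(1, 0), c(0, 1)), 0)
  pred <- c(rep(1, 144), rep(0, 90))
  truth <- c(rep(1, 144), rep(1, 90))
  expect_equal(classification_accuracy(pred, truth), 144 / 234)
  expect_equal(round(100 * classification_accuracy(pred, truth), 2), 61.54)
  expect_error(classification_accuracy(numeric(0), numeric(0)), "empty")
  expect_error(classification_accuracy(1, c(1, 0)), "equal length")
})
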