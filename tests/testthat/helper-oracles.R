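# Independent oracles the implementation is checked against.

# Brute-force two-class Gaussian classifier: estimates the same pooled
# model parameters but classifies by evaluating each class's full
# multivariate-normal log-density per point (Mahalanobis distance +
# log-determinant + log prior), with ties to class 0.  No linear-score
# shortcut, so it exercises a different code path than predict().
brute_gaussian_classify <- function(xtr, ytr, xte, priors = c(0.5, 0.5)) {
  mu0 <- colMeans(xtr[ytr == 0, , drop = FALSE])
  mu1 <- colMeans(xtr[ytr == 1, , drop = FALSE])
  c0 <- sweep(xtr[ytr == 0, , drop = FALSE], 2, mu0)
  c1 <- sweep(xtr[ytr == 1, , drop = FALSE], 2, mu1)
  S <- (crossprod(c0) + crossprod(c1)) / (nrow(xtr) - 2)
  logdet <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  ld <- function(mu, prior) {
    -0.5 * stats::mahalanobis(xte, mu, S) - 0.5 * logdet + log(prior)
  }
  l0 <- ld(mu0, priors[1])
  l1 <- ld(mu1, priors[2])
  list(
    class = as.integer(l1 > l0),
    posterior1 = 1 / (1 + exp(l0 - l1))
  )
}

# Brute-force point-of-stability: literally check every suffix.
brute_pos <- function(n, diff, half_width) {
  ord <- order(n)
  n <- n[ord]
  diff <- diff[ord]
  for (i in seq_along(n)) {
    if (all(abs(diff[i:length(diff)]) <= half_width)) return(n[i])
  }
  NA_integer_
}

# A tiny hand-separable 1-D table: class 0 at {-1, 0, 1}, class 1 at
# {1, 2, 3}; class means 0 and 2, pooled variance exactly 1.
hand_table_1d <- function() {
  tibble::tibble(label = rep(c(0L, 1L), each = 3),
                 c1 = c(-1, 0, 1, 1, 2, 3))
}

random_labeled_matrix <- function(n, p, shift = 0) {
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(stats::rnorm(n * p), n, p) + shift * y
  colnames(x) <- paste0("c", seq_len(p))
  list(x = x, y = y,
       data = dplyr::bind_cols(tibble::tibble(label = y),
                               tibble::as_tibble(x)))
}
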