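test_that("coded-statement tables round-trip through CSV and TSV", {
  csv <- withr::local_tempfile(fileext = ".csv")
  sim <- simulate_fixture_csv(60, p = 4, r = 0.2, seed = 20, path = csv)
  tab <- read_coded_table(csv)
  expect_identical(names(tab), c("label", paste0("c", 1:4)))
  expect_equal(tab$label, sim$label)
  expect_equal(tab$c1, sim$c1, tolerance = 1e-12)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(sim, tsv)
  expect_equal(read_coded_table(tsv), tab)
})

test_that("table loading rejects malformed files and logs dropped rows", {
  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(label = c(0, 1, 2), c1 = 1:3), bad)
  expect_error(read_coded_table(bad), "exactly 2 values")

  nofile <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(x = 1, y = 2), nofile)
  expect_error(read_coded_table(nofile), "not found")

  nas <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(label = c(0, 1, 0, 1),
                                  c1 = c(1, NA, 3, 4)), nas)
  expect_message(tab <- read_coded_table(nas), "Dropped 1 row")
  expect_identical(nrow(tab), 3L)

  txt <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,c1", "0,x", "1,y"), txt)
  expect_error(read_coded_table(txt), "Non-numeric")
})

test_that("exact binomial intervals reproduce the printed audit values", {
  hi <- clopper_pearson(144, 234)
  expect_equal(round(100 * hi$estimate, 2), 61.54)
  expect_equal(round(100 * hi$ci_lower, 2), 54.98)
  expect_equal(round(100 * hi$ci_upper, 2), 67.80)

  lo <- clopper_pearson(120, 234)
  expect_equal(round(100 * lo$estimate, 2), 51.28)
  expect_equal(round(100 * lo$ci_lower, 2), 44.68)
  expect_equal(round(100 * lo$ci_upper, 2), 57.85)
})

test_that("exact intervals agree with binom.test and handle the edges", {
  for (case in list(c(0, 10), c(10, 10), c(3, 7), c(144, 234),
                    c(50, 1000))) {
    k <- case[1]; n <- case[2]
    got <- clopper_pearson(k, n)
    want <- stats::binom.test(k, n)$conf.int
    expect_equal(c(got$ci_lower, got$ci_upper), as.numeric(want),
                 tolerance = 1e-12)
  }
  expect_identical(clopper_pearson(0, 5)$ci_lower, 0)
  expect_identical(clopper_pearson(5, 5)$ci_upper, 1)
  expect_error(clopper_pearson(6, 5), "correct <= total")
  expect_error(clopper_pearson(3, 10, level = 1), "level")
})

test_that("exact intervals are conservative at chance level", {
  withr::local_seed(123)
  k <- stats::rbinom(2000, 234, 0.5)
  covered <- vapply(k, function(ki) {
    ci <- clopper_pearson(ki, 234)
    ci$ci_lower <= 0.5 && 0.5 <= ci$ci_upper
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("the audit reports counts, intervals and a CI-driven verdict", {
  sim <- simulate_statements(60, p = 4, r = 0.6, seed = 30)
  rep <- audit_accuracy(sim)
  expect_s3_class(rep, "accuracy_audit")
  expect_identical(rep$scheme, c("resubstitution", "loocv"))
  expect_true(all(rep$ci_lower <= rep$accuracy &
                    rep$accuracy <= rep$ci_upper))
  expect_equal(rep$accuracy, rep$correct / rep$n_evaluated)
  # the verdict is a pure function of the interval and 0.5
  expect_identical(rep$verdict,
                   ifelse(rep$ci_lower > 0.5, "better-than-chance",
                          "not-better-than-chance"))

  sep <- tibble::tibble(label = rep(0:1, each = 5),
                        c1 = c(rnorm(5, -8), rnorm(5, 8)))
  perfect <- audit_accuracy(sep, schemes = "resubstitution")
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$ci_upper, 1)
  expect_identical(perfect$verdict, "better-than-chance")
})

test_that("audit priors resolve empirically, equally, or explicitly", {
  sim <- simulate_statements(40, p = 3, r = 0.3, seed = 31)
  unbal <- sim[c(1:20, 21:30), ]  # 20 / 10 split
  emp <- audit_accuracy(unbal, schemes = "resubstitution")
  eq <- audit_accuracy(unbal, schemes = "resubstitution", priors = "equal")
  num <- audit_accuracy(unbal, schemes = "resubstitution",
                        priors = c(2 / 3, 1 / 3))
  expect_identical(emp$correct, num$correct)  # empirical = 20/30, 10/30
  expect_s3_class(eq, "accuracy_audit")
  expect_error(audit_accuracy(unbal, priors = "weird"), "priors")
})

test_that("resubstitution claims validity on non-diagnostic tables; loocv does not", {
  reps <- 200
  verdicts <- purrr::map_dfr(seq_len(reps), function(i) {
    sim <- simulate_statements(100, p = 12, r = 0, seed = 40000 + i)
    audit_accuracy(sim, priors = "equal")
  })
  freq <- tapply(verdicts$verdict == "better-than-chance",
                 verdicts$scheme, mean)
  expect_gt(freq[["resubstitution"]], freq[["loocv"]] + 0.3)
  expect_gt(freq[["resubstitution"]], 0.5)
  expect_lt(freq[["loocv"]], 0.25)
})
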