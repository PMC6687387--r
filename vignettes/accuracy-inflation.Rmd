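---
title: "Quantifying resubstitution bias in small-sample classifier accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying resubstitution bias in small-sample classifier accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvaudit)
```

## The problem

Much applied classification research — verbal credibility assessment
being the motivating case — reports the accuracy of a linear
discriminant that was fitted and scored on the same dataset. This
"apparent" or resubstitution accuracy rewards the model for memorising
sample idiosyncrasies: with many predictors and few observations, even
pure noise separates well in-sample. `cvaudit` exists to measure that
inflation under controlled conditions, to show that leave-one-out
cross-validation removes it, and to give practitioners an audit tool
that makes the contrast visible on their own coded tables.

## The generative model

The simulated world is deliberately minimal. Each dataset has `n`
statements, split exactly `n/2` truthful-proxy / `n/2` deceptive-proxy,
and `p` continuous criterion scores. Conditional on class, every
criterion is an independent unit-variance Gaussian whose class means
differ by

$$\delta = \frac{2r}{\sqrt{1 - r^2}},$$

so that the population point-biserial correlation between the criterion
and the 0/1 label is exactly `r` (equivalently
$r = \delta/\sqrt{\delta^2 + 4}$ for balanced classes — the usual
Cohen's-d-to-r conversion). `r`, not `d`, is the primitive parameter
because the study design holds the predictor–outcome correlation
constant; `effect_shift_from_r()` and `r_from_effect_shift()` expose
both directions of the conversion.

What the generator emulates: criterion batteries of the sizes used by
real instruments (19 CBCA-like, 12 SCAN-like, 8 reality-monitoring-like
columns), per-criterion effect sizes at the weak end typical of the
field (`r = 0.1` or `0.124`, i.e. d ≈ 0.2–0.25), exact class balance,
and — via conditional independence given class — a marginal
inter-criterion correlation of `r²`. What it does not emulate: ordinal
or integer criterion scales (real CBCA/SCAN scores are ordinal ratings),
heteroskedastic or skewed criteria, correlated raters, and any
inter-criterion correlation beyond the induced `r²`. Passing tests
therefore demonstrate the statistical behaviour of the estimation
schemes, not the validity of any real instrument.

## The classifier

`fit_lda()` is two-class LDA with pooled within-class covariance
(divisor `n − 2`, the conventional unbiased pooling) and explicit
priors, equal by default to match the balanced design. Numerical
choices:

* a numerically singular pooled covariance (possible when a
  leave-one-out fit approaches `p ≈ n`) falls back to a Moore–Penrose
  pseudo-inverse with a warning rather than failing, so whole
  simulation cells never die on one degenerate draw;
* exact ties in the two discriminant scores are assigned to class 0, so
  every scheme is bit-reproducible;
* a class reduced to a single observation during leave-one-out still
  fits: it contributes zero scatter while the other class carries the
  pooled estimate. This keeps leave-one-out well defined for every
  balanced dataset with `n ≥ 4`.

Tests check the classifier two independent ways: against a brute-force
implementation that evaluates both class Gaussian log-densities per
point (Mahalanobis distance + log-determinant + log prior), and against
`MASS::lda()`.

## Accuracy estimation schemes

Every estimate is an exact count ratio `correct / n_evaluated`. For
stratified k-fold, fold assignment deals shuffled class members
round-robin, continuing the deal across classes, which bounds per-class
and overall fold-size differences by 1 and makes `k = n` literally
coincide with leave-one-out. When fold sizes are unequal the package
reports the pooled proportion of correct held-out predictions rather
than the mean of per-fold accuracies — the two coincide whenever the
strata divide `k` evenly, and the pooled count keeps the estimate an
exact rational number with a well-defined binomial interval.

The factorial harness pairs designs deliberately: in the
difference-curve study (`run_study2()`), each replicate draws one
training set and one independently simulated test set of the same size;
resubstitution and leave-one-out estimates computed on the training set
are compared against the accuracy of the full-training-set model on the
test set, and per-replicate differences are averaged per `n`. The
leave-one-out estimate is compared against that same full-model test
accuracy because it estimates precisely that model's expected
out-of-sample performance. Pairing means the mean difference equals the
difference of means exactly (tested to 1e-12).

All randomness descends from a single master seed through a
deterministic per-(study, p, r, n, replicate) hash, so any cell is
reproducible in isolation and results are independent of execution
order.

## Stability corridor

`point_of_stability()` scans a difference curve for the smallest grid
`n` such that *all* later grid values stay inside
`[-half_width, +half_width]` (default ±0.05, i.e. five accuracy points).
Values exactly on the boundary count as inside; the point is reported on
the simulation grid without interpolation; a curve whose final point is
outside the corridor has no point of stability (`NA`). The scan is
verified against a brute-force check-every-suffix oracle on 1,000 random
curves.

## The accuracy audit

`audit_accuracy()` reproduces, for any coded-statement table, the
comparison that matters in practice: resubstitution versus leave-one-out
accuracy, each with a two-sided exact (Clopper–Pearson) binomial
interval computed from the beta-quantile identity. The exact interval
was chosen because it is conservative at small `n` and reproduces
printed audit rows exactly at their underlying counts; the verdict is
`better-than-chance` only when the whole interval lies above 0.5, so the
conclusion is a pure function of the interval. Priors default to the
table's empirical class proportions (real tables need not be balanced),
with an equal-priors switch for design-balanced analyses.

## Problem sizes and default parameters

The full study design is an `n` grid from 40 to 1000 in steps of 10 with
100 replicate datasets per cell — those are the `study_config()`
defaults. The package's own acceptance checks use the windows where the
conclusions live: the typical-sample-size window `n = 40–240` (step 10,
100 replicates, resubstitution only) for the inflation summaries, and a
thinned wider grid `n = 40–600` (step 20) for the corridor scan with
leave-one-out included. That wider run uses 50 replicates per cell: the
corridor decision is made at one-grid-step resolution, and 50 replicates
bring the per-cell Monte-Carlo standard error of the mean difference
(~0.7 points near the corridor boundary) safely below the 5-point
corridor scale while keeping the run to a few minutes on one CPU.

## Limitations

* The Gaussian, conditionally independent generator is a lower bound on
  real-world messiness; real criterion batteries with correlated,
  ordinal criteria can behave worse, not better.
* Only two-class pooled-covariance LDA is studied; the inflation
  mechanism is generic, but the numbers are classifier-specific.
* The audit's chance-level verdict is a fixed-level interval check, not
  a power analysis; a `not-better-than-chance` verdict on a tiny table
  may reflect low power rather than a useless instrument.
* Repeated, nested, and re-usable-holdout cross-validation variants are
  out of scope.
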