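test_that("confusion tallies are exact and reject undecided calls", {
  d <- expand_confusion(39, 8, 3, 224)
  cc <- build_confusion(d$call, d$ref)
  expect_equal(c(cc$tp, cc$fp, cc$fn, cc$tn), c(39, 8, 3, 224))
  expect_equal(cc$n, 274)
  same <- build_confusion(d$ref, d$ref)
  expect_equal(c(same$fp, same$fn), c(0, 0))
  expect_error(build_confusion(c("PJI", "undecided"), c("PJI", "PJI")),
               "undecided")
  expect_error(confusion_counts(-1, 0, 0, 5), "tp")
  expect_error(confusion_counts(0, 0, 0, 0), "at least 1")
})

test_that("percent agreement reproduces the study values at printed rounding", {
  cc <- syn_counts()
  expect_equal(round(100 * opa(cc), 1), 96.0)
  expect_equal(round(100 * ppa(cc), 1), 92.9)
  expect_equal(round(100 * npa(cc), 1), 96.6)
  expect_equal(round(100 * opa(phys_counts()), 1), 90.8)
  perfect <- confusion_counts(5, 0, 0, 7)
  expect_equal(c(opa(perfect), ppa(perfect), npa(perfect)), c(1, 1, 1))
  expect_error(ppa(confusion_counts(0, 2, 0, 5)), "no reference positives")
  expect_error(npa(confusion_counts(3, 0, 1, 0)), "no reference negatives")
})

test_that("overall agreement is the prevalence-weighted mix of PPA and NPA", {
  set.seed(42)
  for (i in 1:25) {
    cc <- confusion_counts(sample(1:30, 1), sample(0:10, 1),
                           sample(0:10, 1), sample(1:50, 1))
    w <- (cc$tp + cc$fn) / cc$n
    expect_equal(opa(cc), w * ppa(cc) + (1 - w) * npa(cc))
  }
})

test_that("Wilson intervals match printed CIs and prop.test", {
  expect_equal(round(100 * wilson_interval(263, 274), 1),
               c(low = 93.0, high = 97.7))
  expect_equal(round(100 * wilson_interval(39, 42), 1),
               c(low = 81.0, high = 97.5))
  expect_equal(round(100 * wilson_interval(224, 232), 1),
               c(low = 93.3, high = 98.2))
  expect_equal(wilson_interval(0, 20)[["low"]], 0)
  expect_error(wilson_interval(5, 4), "k")
  set.seed(7)
  for (i in 1:20) {
    n <- sample(5:500, 1)
    k <- sample(0:n, 1)
    ours <- wilson_interval(k, n)
    ref <- stats::prop.test(k, n, correct = FALSE)$conf.int
    expect_equal(unname(ours), as.numeric(ref), tolerance = 1e-9)
    expect_true(ours[["low"]] <= k / n && k / n <= ours[["high"]])
  }
  # width shrinks in n at fixed proportion
  w <- function(k, n) diff(wilson_interval(k, n))
  expect_true(w(8, 10) > w(80, 100) && w(80, 100) > w(800, 1000))
})

test_that("AC1 matches the study coefficients and its invariants", {
  expect_equal(round(gwet_ac1(syn_counts()), 2), 0.94)
  expect_equal(round(gwet_ac1(phys_counts()), 2), 0.87)
  expect_equal(gwet_ac1(confusion_counts(10, 0, 0, 40)), 1)
  set.seed(11)
  for (i in 1:50) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1)
    fn <- sample(0:20, 1); tn <- sample(0:20, 1)
    if (tp + fp + fn + tn == 0) next
    cc <- confusion_counts(tp, fp, fn, tn)
    pe_ok <- tryCatch({ gwet_ac1(cc); TRUE }, error = function(e) FALSE)
    if (!pe_ok) next
    a <- gwet_ac1(cc)
    expect_lte(a, 1)
    expect_equal(a == 1, fp == 0 && fn == 0)
    # simultaneous label swap: tp <-> tn, fp <-> fn
    expect_equal(gwet_ac1(confusion_counts(tn, fn, fp, tp)), a)
    # equals the brute-force computation from raw paired labels
    d <- expand_confusion(tp, fp, fn, tn)
    expect_equal(a, brute_ac1(d$call, d$ref))
  }
})

test_that("bootstrap intervals behave on degenerate and reference data", {
  con <- bootstrap_interval(mean, rep(3.5, 40), B = 200, seed = 1)
  expect_equal(c(con$low, con$high), c(3.5, 3.5))
  # reproducible under the same seed
  d <- expand_confusion(39, 8, 3, 224)
  b1 <- bootstrap_interval(function(x) gwet_ac1(build_confusion(x$call, x$ref)),
                           d, B = 300, seed = 5)
  b2 <- bootstrap_interval(function(x) gwet_ac1(build_confusion(x$call, x$ref)),
                           d, B = 300, seed = 5)
  expect_identical(b1[c("low", "high")], b2[c("low", "high")])
  # degenerate replicates are skipped and counted; all-degenerate fails
  tiny <- expand_confusion(1, 0, 0, 9)
  bs <- bootstrap_interval(function(x) ppa(build_confusion(x$call, x$ref)),
                           tiny, B = 300, seed = 2)
  expect_gt(bs$n_skipped, 0)
  expect_error(bootstrap_interval(function(x) stop("nope"), 1:5, B = 10,
                                  seed = 1), "half")
})

test_that("the AC1 bootstrap interval on the study tally matches its report", {
  d <- expand_confusion(39, 8, 3, 224)
  bs <- bootstrap_interval(function(x) gwet_ac1(build_confusion(x$call, x$ref)),
                           d, B = 2000, seed = 3)
  expect_lt(abs(bs$low - 0.91), 0.02)
  expect_lt(abs(bs$high - 0.98), 0.02)
})

test_that("pooling sums per-rater tallies over a shared vignette set", {
  co <- generate_cohort(cohort_spec(274, seed = 1))
  truth <- co$clinical_dx
  names(truth) <- co$id
  calls <- simulate_raters(co, default_rater_profiles(), seed = 2)
  cc <- pool_calls(calls, truth)
  expect_equal(cc$n, 12 * 274)
  # single rater pooling is that rater's own tally
  one <- calls[calls$rater_id == "AS1", ]
  cc1 <- pool_calls(one, truth)
  expect_equal(unclass(cc1),
               unclass(build_confusion(one$stage2, truth[one$vignette_id])))
  # pooled OPA equals the response-weighted mean of per-rater OPAs
  per <- vapply(split(calls, calls$rater_id), function(d) {
    opa(build_confusion(d$stage2, truth[d$vignette_id]))
  }, numeric(1))
  expect_equal(opa(cc), mean(per))
  # mismatched vignette sets are rejected
  bad <- calls[-1, ]
  expect_error(pool_calls(bad, truth), "same vignette set")
})

test_that("indecision rates count undecided Stage-I calls", {
  s1 <- rep(c("undecided", "PJI", "aseptic"), c(754, 597, 1937))
  expect_equal(round(100 * indecision_rate(s1), 1), 22.9)
  expect_equal(indecision_rate(c("PJI", "aseptic")), 0)
  expect_error(indecision_rate(character(0)), "non-empty")
})

test_that("agreement_summary assembles a coherent table row", {
  d <- expand_confusion(39, 8, 3, 224)
  out <- agreement_summary(d$call, d$ref, B = 300, seed = 1)
  expect_equal(out$statistic, c("opa", "ppa", "npa", "ac1"))
  expect_true(all(out$ci_low <= out$estimate & out$estimate <= out$ci_high))
  expect_equal(out$n, c(274, 42, 232, 274))
  expect_equal(round(100 * out$estimate[1:3], 1), c(96.0, 92.9, 96.6))
})
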