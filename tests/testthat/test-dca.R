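test_that("net benefit matches its closed form on the study tallies", {
  cc_s <- syn_counts()
  cc_p <- phys_counts()
  expect_equal(net_benefit(cc_s, 0.55),
               39 / 274 - (8 / 274) * 0.55 / 0.45)
  expect_equal(net_benefit(cc_p, 0.55),
               496 / 3288 - (294 / 3288) * 0.55 / 0.45)
  expect_equal(net_benefit(cc_s, 0.55) - net_benefit(cc_p, 0.55),
               0.0651, tolerance = 1e-3)
  # vanishing threshold puts no weight on false positives
  expect_equal(net_benefit(cc_s, 1e-9), 39 / 274, tolerance = 1e-7)
  expect_error(net_benefit(cc_s, 0), "inside")
  expect_error(net_benefit(cc_s, 1), "inside")
})

test_that("net benefit is scale invariant and monotone in the threshold", {
  cc <- confusion_counts(12, 7, 4, 77)
  cc10 <- confusion_counts(120, 70, 40, 770)
  pts <- seq(0.05, 0.95, by = 0.05)
  expect_equal(net_benefit(cc, pts), net_benefit(cc10, pts))
  expect_true(all(diff(net_benefit(cc, pts)) < 0))  # fp > 0
})

test_that("decision curves include coherent reference policies", {
  truth <- rep(c("PJI", "aseptic"), c(42, 232))
  calls <- rep(c("PJI", "aseptic", "PJI", "aseptic"), c(39, 3, 8, 224))
  dc <- decision_curve(list(score = calls), truth,
                       grid = seq(0.05, 0.95, by = 0.05))
  none <- dc[dc$strategy == "treat_none", ]
  expect_true(all(none$net_benefit == 0))
  prev <- 42 / 274
  all_row <- dc[dc$strategy == "treat_all" &
                  abs(dc$threshold - 0.15) < 1e-9, ]
  expect_equal(all_row$net_benefit,
               prev - (1 - prev) * 0.15 / 0.85, tolerance = 1e-12)
  # treat-all crosses zero at pt = prevalence
  ta <- function(pt) prev - (1 - prev) * pt / (1 - pt)
  expect_equal(ta(prev), 0)
  expect_error(decision_curve(list(score = calls), truth, grid = numeric(0)),
               "non-empty")
  expect_error(decision_curve(list(score = calls), truth, grid = c(0, 0.5)),
               "inside")
})

test_that("the score strategy dominates pooled physicians beyond pt = 0.20", {
  grid <- seq(0.20, 0.95, by = 0.05)
  nb_s <- net_benefit(syn_counts(), grid)
  nb_p <- net_benefit(phys_counts(), grid)
  expect_true(all(nb_s > nb_p))
})

test_that("score strategies support fixed-call and thresholded modes", {
  truth <- rep(c("PJI", "aseptic"), c(30, 70))
  scores <- c(stats::runif(30, 40, 100), stats::runif(70, 0, 15))
  grid <- c(0.1, 0.3, 0.5, 0.7)
  fixed <- decision_curve(list(s = scores), truth, grid = grid)
  thr <- decision_curve(list(s = scores), truth, grid = grid,
                        score_threshold = TRUE)
  # fixed-call mode: the same confusion matrix along the whole grid, so
  # NB follows the single-matrix closed form
  cc <- build_confusion(ifelse(scores >= 20, "PJI", "aseptic"), truth)
  expect_equal(fixed$net_benefit[fixed$strategy == "s"],
               net_benefit(cc, grid))
  # thresholded mode re-dichotomises at each pt
  cc50 <- build_confusion(ifelse(scores / 100 >= 0.5, "PJI", "other"),
                          truth)
  expect_equal(thr$net_benefit[thr$strategy == "s" & thr$threshold == 0.5],
               net_benefit(cc50, 0.5))
})

test_that("pooled net benefit is the response-weighted mean over raters", {
  co <- generate_cohort(cohort_spec(120, seed = 3))
  calls <- simulate_raters(co, default_rater_profiles(), seed = 4)
  truth <- co$clinical_dx
  names(truth) <- co$id
  mat <- matrix(calls$stage2, nrow = nrow(co))
  pooled <- build_confusion(as.vector(mat), rep(truth, ncol(mat)))
  for (pt in c(0.2, 0.55, 0.8)) {
    per <- apply(mat, 2L, function(col) {
      net_benefit(build_confusion(col, truth), pt)
    })
    expect_equal(net_benefit(pooled, pt), mean(per), tolerance = 1e-14)
  }
})

test_that("net-benefit improvement is zero against itself and bootstraps", {
  truth <- rep(c("PJI", "aseptic"), c(20, 80))
  calls <- rep(c("PJI", "aseptic", "PJI", "aseptic"), c(18, 2, 10, 70))
  self <- nb_improvement(calls, calls, truth, pt = 0.5, B = 100, seed = 1)
  expect_equal(self$estimate, 0)
  expect_equal(c(self$ci_low, self$ci_high), c(0, 0))
})

test_that("the economic threshold derivation follows the cost ratio", {
  thr <- economic_threshold(75000, 62375)
  expect_equal(thr$pt_star, 75000 / 137375)
  expect_equal(round(thr$pt_star, 2), 0.55)
  expect_equal(economic_threshold(100, 100)$pt_star, 0.5)
  expect_gt(economic_threshold(100, 1e-9)$pt_star, 0.999)
  expect_error(economic_threshold(0, 100), "positive")
  expect_error(economic_threshold(100, -5), "positive")
})

test_that("interventions-avoided conversions agree at 0.5 and differ elsewhere", {
  expect_equal(interventions_avoided_per100(0.06, 0.5), 6)
  expect_equal(interventions_avoided_per100(0.06, 0.5,
                                            mode = "reciprocal_odds"), 6)
  expect_equal(interventions_avoided_per100(0.09, 0.55,
                                            mode = "reciprocal_odds"),
               11, tolerance = 1e-2)
  expect_equal(interventions_avoided_per100(0.06, 0.55), 4.909,
               tolerance = 1e-3)
  expect_error(interventions_avoided_per100(0.06, 1), "inside")
})
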