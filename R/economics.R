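#' Misdiagnosis cost parameters
#'
#' U.S.-payer cost inputs for the decision-analytic model. A false
#' negative follows one of two downstream pathways with probability
#' `pathway_weight` / `1 - pathway_weight`: a repeat non-operative
#' diagnostic episode (aspiration, laboratory testing, follow-up) or
#' delayed operative management (a failed aseptic revision followed by a
#' two-stage septic revision). A false positive is costed as an
#' unnecessary two-stage septic revision.
#'
#' @param c_repeat_workup USD cost of a repeat diagnostic episode
#'   (default 1000).
#' @param c_delayed_surgical USD cost of the delayed-surgery pathway
#'   (default 123750).
#' @param pathway_weight Probability of the repeat-workup pathway
#'   (default 0.5, equal weighting).
#' @param c_fp USD cost of a false positive (default 75000).
#' @return An object of class `"cost_parameters"`.
#' @export
cost_parameters <- function(c_repeat_workup = 1000,
                            c_delayed_surgical = 123750,
                            pathway_weight = 0.5,
                            c_fp = 75000) {
  for (nm in c("c_repeat_workup", "c_delayed_surgical", "c_fp")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop(sprintf("`%s` must be a non-negative cost", nm), call. = FALSE)
    }
  }
  check_fraction(pathway_weight, "pathway_weight")
  structure(list(c_repeat_workup = c_repeat_workup,
                 c_delayed_surgical = c_delayed_surgical,
                 pathway_weight = pathway_weight, c_fp = c_fp),
            class = "cost_parameters")
}

#' Expected cost of one false-negative diagnosis
#'
#' Scenario-weighted mean over the two downstream pathways:
#' `w * c_repeat_workup + (1 - w) * c_delayed_surgical`. At the defaults
#' (equal weighting of $1,000 and $123,750) this is $62,375 per case.
#'
#' @param p A [cost_parameters()] object.
#' @return USD cost per false-negative case.
#' @export
expected_fn_cost <- function(p = cost_parameters()) {
  stopifnot(inherits(p, "cost_parameters"))
  p$pathway_weight * p$c_repeat_workup +
    (1 - p$pathway_weight) * p$c_delayed_surgical
}

#' Decision-analytic misdiagnosis cost of a strategy
#'
#' Expected misdiagnosis counts and costs for a hypothetical cohort:
#' `n_pji = round(n_cohort * prevalence)` PJI and the rest aseptic, with
#' `n_fn = round(n_pji * (1 - ppa))` false negatives and
#' `n_fp = round(n_aseptic * (1 - npa))` false positives (all rounding
#' half away from zero, which is what fixed-composition cohort tallies
#' use). Totals are computed in integer cents to avoid floating-point
#' drift. The unrounded expected counts are reported alongside.
#'
#' @param n_cohort Cohort size (>= 1).
#' @param prevalence PJI prevalence in [0, 1].
#' @param ppa,npa Positive / negative percent agreement of the strategy,
#'   as fractions in [0, 1] (conventionally the printed, rounded values).
#' @param p A [cost_parameters()] object.
#' @param round_counts Round expected counts to whole cases (default);
#'   `FALSE` costs the unrounded expectations.
#' @return An object of class `"pji_econ"`: a list with fields
#'   `n_cohort, n_pji, n_aseptic, n_fn, n_fp, n_fn_expected,
#'   n_fp_expected, c_fn_unit, cost_fn_total, cost_fp_total, cost_total`.
#' @export
misdiagnosis_cost <- function(n_cohort, prevalence, ppa, npa,
                              p = cost_parameters(), round_counts = TRUE) {
  n_cohort <- check_count(n_cohort, "n_cohort", min = 1L)
  check_fraction(prevalence, "prevalence")
  check_fraction(ppa, "ppa")
  check_fraction(npa, "npa")
  n_pji <- as.integer(round_half_away(n_cohort * prevalence))
  n_aseptic <- n_cohort - n_pji
  fn_exp <- n_pji * (1 - ppa)
  fp_exp <- n_aseptic * (1 - npa)
  n_fn <- if (round_counts) round_half_away(fn_exp) else fn_exp
  n_fp <- if (round_counts) round_half_away(fp_exp) else fp_exp
  c_fn_unit <- expected_fn_cost(p)
  fn_cents <- round_half_away(n_fn * c_fn_unit * 100)
  fp_cents <- round_half_away(n_fp * p$c_fp * 100)
  structure(list(
    n_cohort = n_cohort, n_pji = n_pji, n_aseptic = n_aseptic,
    n_fn = n_fn, n_fp = n_fp,
    n_fn_expected = fn_exp, n_fp_expected = fp_exp,
    c_fn_unit = c_fn_unit,
    cost_fn_total = fn_cents / 100, cost_fp_total = fp_cents / 100,
    cost_total = (fn_cents + fp_cents) / 100,
    params = p
  ), class = "pji_econ")
}

#' @export
print.pji_econ <- function(x, ...) {
  usd <- function(v) paste0("$", format(v, big.mark = ",",
                                        scientific = FALSE))
  cat(sprintf("Misdiagnosis cost model: %d cases (%d PJI / %d aseptic)\n",
              x$n_cohort, x$n_pji, x$n_aseptic))
  cat(sprintf("  false negatives: %g  (expected %.2f)  x %s = %s\n",
              x$n_fn, x$n_fn_expected, usd(x$c_fn_unit),
              usd(x$cost_fn_total)))
  cat(sprintf("  false positives: %g  (expected %.2f)  x %s = %s\n",
              x$n_fp, x$n_fp_expected, usd(x$params$c_fp),
              usd(x$cost_fp_total)))
  cat(sprintf("  total misdiagnosis cost: %s\n", usd(x$cost_total)))
  invisible(x)
}

#' Compare the misdiagnosis costs of two strategies
#'
#' Savings of strategy `a` relative to strategy `b` on the same cohort:
#' `savings_total = cost_total(b) - cost_total(a)`, and per suspected
#' case. Antisymmetric in its arguments.
#'
#' @param a,b [misdiagnosis_cost()] results with equal `n_cohort`.
#' @return List with `savings_total` and `savings_per_case` (USD).
#' @export
compare_strategies <- function(a, b) {
  stopifnot(inherits(a, "pji_econ"), inherits(b, "pji_econ"))
  if (a$n_cohort != b$n_cohort) {
    stop("strategies must be costed on the same cohort size", call. = FALSE)
  }
  total <- b$cost_total - a$cost_total
  list(savings_total = total, savings_per_case = total / a$n_cohort)
}

#' Monte-Carlo patient-level check of the cost model
#'
#' Simulates the cohort patient by patient -- Bernoulli disease status at
#' the given prevalence, then Bernoulli test errors at `1 - ppa` /
#' `1 - npa` -- and returns the replicate total costs. Serves as an
#' independent stochastic check of the closed-form expectation.
#'
#' @param n_cohort Cohort size.
#' @param prevalence,ppa,npa As in [misdiagnosis_cost()].
#' @param p A [cost_parameters()] object.
#' @param reps Number of replicates (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of `reps` total costs (USD).
#' @export
monte_carlo_costs <- function(n_cohort, prevalence, ppa, npa,
                              p = cost_parameters(), reps = 1000L,
                              seed = 1L) {
  reps <- check_count(reps, "reps", min = 1L)
  check_fraction(prevalence, "prevalence")
  check_fraction(ppa, "ppa")
  check_fraction(npa, "npa")
  c_fn_unit <- expected_fn_cost(p)
  set.seed(derive_seed(seed, 8L))
  n_pji <- stats::rbinom(reps, n_cohort, prevalence)
  n_fn <- stats::rbinom(reps, n_pji, 1 - ppa)
  n_fp <- stats::rbinom(reps, n_cohort - n_pji, 1 - npa)
  n_fn * c_fn_unit + n_fp * p$c_fp
}
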