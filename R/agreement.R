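#' Construct a 2x2 confusion tally
#'
#' Counts of a binary diagnostic call against the clinical reference:
#' true positives, false positives, false negatives, true negatives.
#'
#' @param tp,fp,fn,tn Non-negative integer counts; total must be >= 1.
#' @return An object of class `"pji_confusion"`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  for (nm in c("tp", "fp", "fn", "tn")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != trunc(v)) {
      stop(sprintf("`%s` must be a single non-negative integer", nm),
           call. = FALSE)
    }
  }
  n <- tp + fp + fn + tn
  if (n < 1) stop("confusion counts must total at least 1", call. = FALSE)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = n),
            class = "pji_confusion")
}

#' @export
print.pji_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2L, 2L,
              dimnames = list(call = c("PJI", "aseptic"),
                              reference = c("PJI", "aseptic")))
  print(m)
  invisible(x)
}

#' Tally binary calls against the clinical reference
#'
#' @param calls Binary calls (Stage-II or forced-call form); any
#'   `undecided` entry is an error -- indecision must be resolved before a
#'   2x2 tally is meaningful.
#' @param reference Clinical reference labels, same length.
#' @param positive The positive label (default `"PJI"`).
#' @return A [confusion_counts()] object.
#' @export
build_confusion <- function(calls, reference, positive = "PJI") {
  calls <- as.character(calls); reference <- as.character(reference)
  if (length(calls) != length(reference)) {
    stop("calls and reference must have equal length", call. = FALSE)
  }
  if (any(calls == "undecided")) {
    stop("undecided calls present; a binary (Stage-II / forced-call) vector is required",
         call. = FALSE)
  }
  cp <- calls == positive; rp <- reference == positive
  confusion_counts(sum(cp & rp), sum(cp & !rp), sum(!cp & rp),
                   sum(!cp & !rp))
}

#' Percent-agreement statistics
#'
#' Overall, positive and negative percent agreement of a binary call
#' against the reference: `opa = (tp + tn) / n`, `ppa = tp / (tp + fn)`,
#' `npa = tn / (tn + fp)`. A zero denominator is an error rather than a
#' silent `NaN`.
#'
#' @param c A [confusion_counts()] object.
#' @return Fraction in [0, 1].
#' @export
opa <- function(c) {
  stopifnot(inherits(c, "pji_confusion"))
  (c$tp + c$tn) / c$n
}

#' @rdname opa
#' @export
ppa <- function(c) {
  stopifnot(inherits(c, "pji_confusion"))
  if (c$tp + c$fn == 0) {
    stop("PPA undefined: no reference positives", call. = FALSE)
  }
  c$tp / (c$tp + c$fn)
}

#' @rdname opa
#' @export
npa <- function(c) {
  stopifnot(inherits(c, "pji_confusion"))
  if (c$tn + c$fp == 0) {
    stop("NPA undefined: no reference negatives", call. = FALSE)
  }
  c$tn / (c$tn + c$fp)
}

#' Wilson score interval for a binomial proportion
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(low, high)`, both in [0, 1].
#' @export
wilson_interval <- function(k, n, conf = 0.95) {
  n <- check_count(n, "n", min = 1L)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0 || k > n) {
    stop("`k` must satisfy 0 <= k <= n", call. = FALSE)
  }
  check_fraction(conf, "conf")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = max(0, ctr - hw), high = min(1, ctr + hw))
}

#' Gwet's AC1 chance-corrected agreement coefficient
#'
#' `AC1 = (pa - pe) / (1 - pe)` with observed agreement
#' `pa = (tp + tn) / n` and chance agreement `pe = 2 * pi * (1 - pi)`,
#' where `pi` is the mean of the two marginal positive proportions (the
#' call's and the reference's). Unlike kappa, the chance term stays
#' well-behaved at extreme prevalence. Degenerate `pe = 1` is an error.
#'
#' @param c A [confusion_counts()] object.
#' @return Coefficient `<= 1`; equals 1 exactly when `fp = fn = 0`.
#' @export
gwet_ac1 <- function(c) {
  stopifnot(inherits(c, "pji_confusion"))
  pa <- (c$tp + c$tn) / c$n
  pi_bar <- ((c$tp + c$fp) / c$n + (c$tp + c$fn) / c$n) / 2
  pe <- 2 * pi_bar * (1 - pi_bar)
  if (pe >= 1) stop("AC1 undefined: chance agreement is 1", call. = FALSE)
  (pa - pe) / (1 - pe)
}

#' Percentile bootstrap interval by case resampling
#'
#' Resamples the rows (or elements) of `data` with replacement `B` times,
#' recomputes `statistic` on each replicate and returns the percentile
#' interval. A replicate on which the statistic is undefined (errors or
#' returns `NA`) is skipped and counted; more than 50% skipped is a
#' failure.
#'
#' @param statistic Function of a resampled `data` returning one number.
#' @param data Data frame (resampled by row) or vector.
#' @param B Number of replicates (default 2000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return List with `low`, `high`, `replicates`, `n_skipped`.
#' @export
bootstrap_interval <- function(statistic, data, B = 2000L, seed = 1L,
                               conf = 0.95) {
  B <- check_count(B, "B", min = 1L)
  n <- if (is.data.frame(data) || is.matrix(data)) nrow(data) else
    length(data)
  if (n < 1) stop("`data` must be non-empty", call. = FALSE)
  take <- if (is.data.frame(data) || is.matrix(data)) {
    function(idx) data[idx, , drop = FALSE]
  } else {
    function(idx) data[idx]
  }
  set.seed(derive_seed(seed, 7L))
  reps <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(as.numeric(statistic(take(idx))), error = function(e) NA_real_)
  }, numeric(1L))
  skipped <- sum(is.na(reps))
  if (skipped > B / 2) {
    stop("statistic undefined on more than half of the bootstrap replicates",
         call. = FALSE)
  }
  qs <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE, type = 7)
  list(low = qs[1], high = qs[2], replicates = reps[!is.na(reps)],
       n_skipped = skipped)
}

#' Pool per-rater calls into one response-level tally
#'
#' Treats each rater x vignette response as one observation and sums the
#' per-rater confusion counts. All raters must have scored the same
#' vignette set.
#'
#' @param calls Data frame with `rater_id`, `vignette_id` and a binary
#'   call column (`stage2` by default).
#' @param reference Named vector of reference labels indexed by
#'   vignette id.
#' @param call_col Which column holds the binary call.
#' @param positive Positive label.
#' @return A [confusion_counts()] object over all responses.
#' @export
pool_calls <- function(calls, reference, call_col = "stage2",
                       positive = "PJI") {
  sets <- split(calls$vignette_id, calls$rater_id)
  base <- sort(sets[[1L]])
  same <- vapply(sets, function(s) identical(sort(s), base), logical(1L))
  if (!all(same)) {
    stop("all raters must have scored the same vignette set", call. = FALSE)
  }
  ref <- reference[calls$vignette_id]
  if (anyNA(ref)) stop("reference missing for some vignette ids",
                       call. = FALSE)
  build_confusion(calls[[call_col]], ref, positive = positive)
}

#' Stage-I indecision rate
#'
#' @param stage1 Vector of Stage-I calls in `{PJI, aseptic, undecided}`.
#' @return Fraction of `undecided` calls.
#' @export
indecision_rate <- function(stage1) {
  if (!length(stage1)) stop("`stage1` must be non-empty", call. = FALSE)
  mean(as.character(stage1) == "undecided")
}

#' Agreement summary of one strategy against the reference
#'
#' Computes OPA/PPA/NPA with Wilson intervals and Gwet's AC1 with a
#' case-resampled bootstrap interval, in the layout of an agreement table
#' row.
#'
#' @param calls Binary calls per vignette.
#' @param reference Reference labels per vignette.
#' @param positive Positive label.
#' @param B Bootstrap replicates for the AC1 interval.
#' @param seed Bootstrap seed.
#' @param conf Confidence level.
#' @return Data frame of class `"pji_agreement"`: one row per statistic
#'   with columns `statistic, estimate, ci_low, ci_high, method, n`.
#' @export
agreement_summary <- function(calls, reference, positive = "PJI",
                              B = 2000L, seed = 1L, conf = 0.95) {
  cc <- build_confusion(calls, reference, positive)
  w_opa <- wilson_interval(cc$tp + cc$tn, cc$n, conf)
  w_ppa <- wilson_interval(cc$tp, cc$tp + cc$fn, conf)
  w_npa <- wilson_interval(cc$tn, cc$tn + cc$fp, conf)
  dat <- data.frame(call = as.character(calls),
                    ref = as.character(reference),
                    stringsAsFactors = FALSE)
  bs <- bootstrap_interval(function(d) {
    gwet_ac1(build_confusion(d$call, d$ref, positive))
  }, dat, B = B, seed = seed, conf = conf)
  out <- data.frame(
    statistic = c("opa", "ppa", "npa", "ac1"),
    estimate = c(opa(cc), ppa(cc), npa(cc), gwet_ac1(cc)),
    ci_low = c(w_opa[1], w_ppa[1], w_npa[1], bs$low),
    ci_high = c(w_opa[2], w_ppa[2], w_npa[2], bs$high),
    method = c("wilson", "wilson", "wilson", "bootstrap"),
    n = c(cc$n, cc$tp + cc$fn, cc$tn + cc$fp, cc$n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("pji_agreement", "data.frame")
  out
}

#' @export
print.pji_agreement <- function(x, ...) {
  fmt <- function(row) {
    if (row$statistic == "ac1") {
      sprintf("%.2f (%.2f-%.2f)", row$estimate, row$ci_low, row$ci_high)
    } else {
      sprintf("%.1f%% (%.1f-%.1f%%)", 100 * row$estimate, 100 * row$ci_low,
              100 * row$ci_high)
    }
  }
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-4s %s  [n = %d]\n", toupper(x$statistic[i]),
                fmt(x[i, ]), x$n[i]))
  }
  invisible(x)
}
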