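#' Net benefit of a diagnostic strategy at a threshold probability
#'
#' The decision-curve-analysis utility
#' `NB(pt) = tp/n - (fp/n) * pt / (1 - pt)`: the true-positive rate
#' penalized by the false-positive rate weighted at the odds of the
#' threshold probability `pt`, the disease probability at which treating
#' and not treating are equally acceptable. May be negative. Vectorized
#' over `pt`.
#'
#' @param c A [confusion_counts()] object.
#' @param pt Threshold probabilities, each strictly inside (0, 1).
#' @return Numeric vector of net benefit values.
#' @export
net_benefit <- function(c, pt) {
  stopifnot(inherits(c, "pji_confusion"))
  if (!is.numeric(pt) || anyNA(pt) || any(pt <= 0 | pt >= 1)) {
    stop("`pt` must lie strictly inside (0, 1)", call. = FALSE)
  }
  c$tp / c$n - (c$fp / c$n) * pt / (1 - pt)
}

strategy_confusion <- function(strategy, truth, positive = "PJI") {
  if (is.matrix(strategy) ||
      (is.data.frame(strategy) && ncol(strategy) > 1L)) {
    # one column per rater: response-level pooling
    m <- as.matrix(strategy)
    stopifnot(nrow(m) == length(truth))
    build_confusion(as.vector(m), rep(as.character(truth), ncol(m)),
                    positive)
  } else {
    build_confusion(as.character(unlist(strategy)), as.character(truth),
                    positive)
  }
}

#' Decision curve over a grid of threshold probabilities
#'
#' Computes net benefit per strategy and threshold, plus the `treat_all`
#' and `treat_none` reference policies. A strategy is a vector of fixed
#' binary calls (one per case), a matrix of calls (cases x raters, pooled
#' at the response level), or a numeric 0-100 score. Scores are
#' binarized with the fixed forced-call cutoff by default -- the call is
#' held constant across the grid -- or thresholded at `score/100 >= pt`
#' when `score_threshold = TRUE`.
#'
#' @param strategies Named list of strategies.
#' @param truth Reference labels, one per case.
#' @param grid Threshold grid inside (0, 1); default 0.01-0.99 step 0.01.
#' @param score_threshold Logical; threshold continuous scores at each
#'   grid point instead of holding the forced call fixed.
#' @param cutoff Forced-call cutoff for fixed-call binarization.
#' @param positive Positive label.
#' @return Long data frame of class `"pji_dca"`: columns
#'   `strategy, threshold, net_benefit`; attributes `n` and `prevalence`.
#' @export
decision_curve <- function(strategies, truth,
                           grid = seq(0.01, 0.99, by = 0.01),
                           score_threshold = FALSE, cutoff = 20,
                           positive = "PJI") {
  if (!length(grid)) stop("threshold grid must be non-empty", call. = FALSE)
  if (!is.numeric(grid) || any(grid <= 0 | grid >= 1)) {
    stop("threshold grid must lie strictly inside (0, 1)", call. = FALSE)
  }
  truth <- as.character(truth)
  n <- length(truth)
  prev <- mean(truth == positive)
  rows <- list()
  for (nm in names(strategies)) {
    s <- strategies[[nm]]
    if (is.numeric(s) && !is.matrix(s) && score_threshold) {
      nb <- vapply(grid, function(pt) {
        calls <- ifelse(s / 100 >= pt, positive, "other")
        net_benefit(build_confusion(calls, truth, positive), pt)
      }, numeric(1L))
    } else {
      if (is.numeric(s) && !is.matrix(s)) {
        s <- as.character(forced_call(s, cutoff))
      }
      cc <- strategy_confusion(s, truth, positive)
      nb <- net_benefit(cc, grid)
    }
    rows[[nm]] <- data.frame(strategy = nm, threshold = grid,
                             net_benefit = nb, stringsAsFactors = FALSE)
  }
  pos_n <- sum(truth == positive)
  all_cc <- confusion_counts(pos_n, n - pos_n, 0L, 0L)
  rows[["treat_all"]] <- data.frame(strategy = "treat_all", threshold = grid,
                                    net_benefit = net_benefit(all_cc, grid),
                                    stringsAsFactors = FALSE)
  rows[["treat_none"]] <- data.frame(strategy = "treat_none",
                                     threshold = grid, net_benefit = 0,
                                     stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n") <- n
  attr(out, "prevalence") <- prev
  class(out) <- c("pji_dca", "data.frame")
  out
}

#' @export
plot.pji_dca <- function(x, ...) {
  strategies <- unique(x$strategy)
  cols <- grDevices::hcl.colors(length(strategies), "Dark 3")
  graphics::plot(NA, xlim = range(x$threshold),
                 ylim = range(x$net_benefit, 0),
                 xlab = "threshold probability",
                 ylab = "net benefit", main = "Decision curve analysis",
                 ...)
  for (i in seq_along(strategies)) {
    d <- x[x$strategy == strategies[i], ]
    graphics::lines(d$threshold, d$net_benefit, col = cols[i],
                    lty = if (strategies[i] %in%
                              c("treat_all", "treat_none")) 2 else 1,
                    lwd = 2)
  }
  graphics::legend("topright", legend = strategies, col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Net-benefit improvement of one strategy over another
#'
#' Point improvement `NB(a) - NB(b)` at a threshold probability, with a
#' percentile bootstrap interval from joint case resampling: each
#' replicate resamples vignettes and carries *both* strategies' calls for
#' the resampled cases (all raters' calls jointly when a strategy is a
#' call matrix), preserving within-case correlation.
#'
#' @param a,b Strategy calls: vector (one call per case) or matrix
#'   (cases x raters, pooled).
#' @param truth Reference labels per case; the same cases underlie both
#'   strategies.
#' @param pt Threshold probability in (0, 1).
#' @param B Bootstrap replicates.
#' @param seed Bootstrap seed.
#' @param conf Confidence level.
#' @param positive Positive label.
#' @return List with `estimate`, `ci_low`, `ci_high`, `pt`, `B`.
#' @export
nb_improvement <- function(a, b, truth, pt, B = 2000L, seed = 1L,
                           conf = 0.95, positive = "PJI") {
  truth <- as.character(truth)
  a <- if (is.matrix(a)) a else matrix(as.character(a), ncol = 1L)
  b <- if (is.matrix(b)) b else matrix(as.character(b), ncol = 1L)
  stopifnot(nrow(a) == length(truth), nrow(b) == length(truth))
  delta <- function(idx) {
    nb_a <- net_benefit(strategy_confusion(a[idx, , drop = FALSE],
                                           truth[idx], positive), pt)
    nb_b <- net_benefit(strategy_confusion(b[idx, , drop = FALSE],
                                           truth[idx], positive), pt)
    nb_a - nb_b
  }
  est <- delta(seq_along(truth))
  bs <- bootstrap_interval(function(d) delta(d$idx),
                           data.frame(idx = seq_along(truth)),
                           B = B, seed = seed, conf = conf)
  list(estimate = est, ci_low = bs$low, ci_high = bs$high, pt = pt, B = B)
}

#' Economically derived threshold probability
#'
#' The threshold at which the expected cost of treating equals the
#' expected cost of not treating: the ratio of the false-positive cost to
#' the combined false-positive and false-negative costs,
#' `pt* = c_fp / (c_fp + c_fn)`.
#'
#' @param c_fp Cost of a false-positive decision (> 0).
#' @param c_fn Cost of a false-negative decision (> 0).
#' @return List of class `"threshold_derivation"` with `c_fp`, `c_fn`,
#'   `pt_star`.
#' @export
economic_threshold <- function(c_fp, c_fn) {
  check_positive(c_fp, "c_fp")
  check_positive(c_fn, "c_fn")
  structure(list(c_fp = c_fp, c_fn = c_fn,
                 pt_star = c_fp / (c_fp + c_fn)),
            class = "threshold_derivation")
}

#' @export
print.threshold_derivation <- function(x, ...) {
  cat(sprintf("Economically derived threshold probability\n"))
  cat(sprintf("  pt* = %s / (%s + %s) = %.3f\n",
              format(x$c_fp, big.mark = ","), format(x$c_fp, big.mark = ","),
              format(x$c_fn, big.mark = ","), x$pt_star))
  invisible(x)
}

#' Convert a net-benefit difference into interventions avoided per 100
#'
#' The standard decision-curve conversion of a net-benefit improvement
#' into unnecessary interventions (false positives) avoided per 100
#' patients is `delta_nb * (1 - pt) / pt * 100`. An alternate,
#' non-standard mode multiplying by the reciprocal odds
#' (`delta_nb * pt / (1 - pt) * 100`) is also exposed because some reports
#' print numbers in that direction; the two agree only at `pt = 0.5`.
#'
#' @param delta_nb Net-benefit improvement.
#' @param pt Threshold probability in (0, 1).
#' @param mode `"standard"` (default) or `"reciprocal_odds"`
#'   (non-standard).
#' @return Interventions avoided per 100 patients.
#' @export
interventions_avoided_per100 <- function(delta_nb, pt,
                                         mode = c("standard",
                                                  "reciprocal_odds")) {
  mode <- match.arg(mode)
  if (!is.numeric(pt) || anyNA(pt) || any(pt <= 0 | pt >= 1)) {
    stop("`pt` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (mode == "standard") {
    delta_nb * (1 - pt) / pt * 100
  } else {
    delta_nb * pt / (1 - pt) * 100
  }
}
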