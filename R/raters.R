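#' Define a simulated physician rater
#'
#' A rater is parameterized by the marginal rates the simulation must
#' reproduce: the overall Stage-I indecision rate, a (usually much higher)
#' indecision rate on criteria-inconclusive cases, and Stage-II positive /
#' negative percent agreement targets against the clinical reference.
#'
#' @param rater_id Identifier, e.g. `"AS1"`.
#' @param group One of `"academic_surgeon"`, `"community_surgeon"`,
#'   `"id_physician"`.
#' @param stage1_indecision_rate Overall fraction of Stage-I `undecided`
#'   calls across the whole cohort.
#' @param target_ppa,target_npa Stage-II agreement targets in [0, 1].
#' @param inconclusive_indecision_rate Stage-I indecision rate applied to
#'   vignettes whose criteria class is `inconclusive`; the rate on the
#'   remaining vignettes is solved so the overall expectation equals
#'   `stage1_indecision_rate`.
#' @return An object of class `"rater_profile"`.
#' @export
rater_profile <- function(rater_id, group,
                          stage1_indecision_rate,
                          target_ppa, target_npa,
                          inconclusive_indecision_rate =
                            stage1_indecision_rate) {
  group <- match.arg(group, c("academic_surgeon", "community_surgeon",
                              "id_physician"))
  check_fraction(stage1_indecision_rate, "stage1_indecision_rate")
  check_fraction(target_ppa, "target_ppa")
  check_fraction(target_npa, "target_npa")
  check_fraction(inconclusive_indecision_rate, "inconclusive_indecision_rate")
  structure(list(rater_id = rater_id, group = group,
                 stage1_indecision_rate = stage1_indecision_rate,
                 target_ppa = target_ppa, target_npa = target_npa,
                 inconclusive_indecision_rate = inconclusive_indecision_rate),
            class = "rater_profile")
}

#' The default twelve-physician survey panel
#'
#' Four academic arthroplasty surgeons (AS), four community arthroplasty
#' surgeons (CS) and four infectious-disease physicians (ID), each with
#' their observed overall Stage-I indecision rate and Stage-II PPA/NPA
#' against the clinical reference; group-level indecision rates on
#' criteria-inconclusive cases (0.383 AS, 0.483 CS, 0.475 ID) are applied
#' to every rater of the group.
#'
#' Pooled over 274 vignettes these profiles yield expected Stage-II counts
#' of 496 true positives and 2490 true negatives out of 504 and 2784
#' reference positives/negatives (pooled PPA 98.4%, NPA 89.4%) and an
#' overall indecision rate near 22.9%.
#'
#' @return List of twelve [rater_profile()] objects.
#' @export
default_rater_profiles <- function() {
  tab <- data.frame(
    rater_id = c("AS1", "AS2", "AS3", "AS4",
                 "CS1", "CS2", "CS3", "CS4",
                 "ID1", "ID2", "ID3", "ID4"),
    group = rep(c("academic_surgeon", "community_surgeon", "id_physician"),
                each = 4L),
    undecided = c(0.153, 0.051, 0.058, 0.369,
                  0.208, 0.219, 0.332, 0.383,
                  0.186, 0.434, 0.102, 0.255),
    ppa = c(1, 1, 0.952, 0.976,
            1, 1, 0.952, 1,
            0.976, 0.976, 0.976, 1),
    npa = c(0.970, 0.948, 0.978, 0.836,
            0.832, 0.918, 0.935, 0.858,
            0.858, 0.879, 0.858, 0.862),
    stringsAsFactors = FALSE
  )
  inc <- c(academic_surgeon = 0.383, community_surgeon = 0.483,
           id_physician = 0.475)
  lapply(seq_len(nrow(tab)), function(i) {
    rater_profile(tab$rater_id[i], tab$group[i],
                  stage1_indecision_rate = tab$undecided[i],
                  target_ppa = tab$ppa[i], target_npa = tab$npa[i],
                  inconclusive_indecision_rate = inc[[tab$group[i]]])
  })
}

#' Simulate two-stage physician calls on a vignette cohort
#'
#' For each rater x vignette, a definitive Stage-II diagnosis is drawn so
#' that the rater's expected PPA and NPA against `clinical_dx` equal the
#' profile targets; Stage I is then `undecided` with the class-specific
#' indecision rate and otherwise equals the Stage-II call, so no simulated
#' response can have a decided Stage I that flips at Stage II.
#'
#' The indecision rate on criteria-inconclusive vignettes is the profile's
#' `inconclusive_indecision_rate`; on the remaining vignettes the rate is
#' solved (and clamped to [0, 1]) so that the expected overall rate equals
#' `stage1_indecision_rate` given the cohort's inconclusive fraction.
#'
#' Under the default `"fixed_counts"` mechanism each rater's error and
#' undecided counts are fixed at their rounded expectations (half away
#' from zero) within each stratum, with uniformly random placement across
#' vignettes -- the same fixed-composition philosophy the cohort generator
#' uses for prevalence, so pooled tallies are exactly reproducible.
#' `"bernoulli"` draws every response independently instead, adding
#' response-level sampling noise around the same expectations.
#'
#' @param vignettes Vignette data frame with `clinical_dx` (required) and
#'   optionally `icm_class`.
#' @param profiles List of [rater_profile()] objects; must be non-empty.
#' @param seed Integer seed (independent of the cohort's seed).
#' @param mechanism `"fixed_counts"` (default) or `"bernoulli"`.
#' @return Data frame of class `"pji_rater_calls"` with columns
#'   `rater_id, group, vignette_id, stage1, stage2`.
#' @export
simulate_raters <- function(vignettes, profiles, seed = 1L,
                            mechanism = c("fixed_counts", "bernoulli")) {
  mechanism <- match.arg(mechanism)
  if (length(profiles) == 0L) {
    stop("`profiles` must contain at least one rater", call. = FALSE)
  }
  if (!"clinical_dx" %in% names(vignettes) || anyNA(vignettes$clinical_dx)) {
    stop("every vignette must carry a clinical_dx", call. = FALSE)
  }
  n <- nrow(vignettes)
  is_pji <- vignettes$clinical_dx == "PJI"
  inconclusive <- if ("icm_class" %in% names(vignettes)) {
    !is.na(vignettes$icm_class) & vignettes$icm_class == "inconclusive"
  } else rep(FALSE, n)
  f_inc <- mean(inconclusive)

  # fix `k` of `n` slots at the rounded expectation, placed uniformly
  fixed_pick <- function(idx, rate) {
    k <- min(as.integer(round_half_away(length(idx) * rate)), length(idx))
    if (k == 0L) integer(0) else idx[sample.int(length(idx), k)]
  }

  set.seed(derive_seed(seed, 5L))
  out <- lapply(profiles, function(p) {
    stopifnot(inherits(p, "rater_profile"))
    if (mechanism == "bernoulli") {
      correct <- stats::rbinom(n, 1L,
                               ifelse(is_pji, p$target_ppa,
                                      p$target_npa)) == 1L
    } else {
      correct <- rep(TRUE, n)
      correct[fixed_pick(which(is_pji), 1 - p$target_ppa)] <- FALSE
      correct[fixed_pick(which(!is_pji), 1 - p$target_npa)] <- FALSE
    }
    stage2 <- ifelse(correct == is_pji, "PJI", "aseptic")
    r_inc <- p$inconclusive_indecision_rate
    r_other <- if (f_inc < 1) {
      (p$stage1_indecision_rate - f_inc * r_inc) / (1 - f_inc)
    } else r_inc
    r_other <- min(max(r_other, 0), 1)
    if (mechanism == "bernoulli") {
      undecided <- stats::runif(n) < ifelse(inconclusive, r_inc, r_other)
    } else {
      undecided <- rep(FALSE, n)
      undecided[fixed_pick(which(inconclusive), r_inc)] <- TRUE
      undecided[fixed_pick(which(!inconclusive), r_other)] <- TRUE
    }
    data.frame(rater_id = p$rater_id, group = p$group,
               vignette_id = vignettes$id,
               stage1 = ifelse(undecided, "undecided", stage2),
               stage2 = stage2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("pji_rater_calls", "data.frame")
  out
}

#' Read and write rater calls as CSV
#'
#' Columns `rater_id, group, vignette_id, stage1, stage2`.
#'
#' @param x Rater-call data frame.
#' @param path File path.
#' @export
write_rater_calls <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rater_calls
#' @export
read_rater_calls <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  class(x) <- c("pji_rater_calls", "data.frame")
  x
}
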