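#' Names of the synovial-fluid biomarker panel
#'
#' The eleven synovial-fluid (SF) biomarkers consumed by the probability
#' score: alpha-defensin signal-to-cutoff ratio (`ad`), SF white blood cell
#' count in cells/uL (`sf_wbc`), SF polymorphonuclear percentage (`sf_pmn_pct`),
#' SF red blood cell count in cells/uL (`sf_rbc`), C-reactive protein
#' (`crp`, unit carried separately in `crp_unit`), absorbance at 280 nm
#' (`a280`), and five microbial antigen signals: Candida (`cp`),
#' Enterococcus (`ef`), Staphylococcus (`spa`, `spb`) and Cutibacterium
#' acnes (`pac`).
#'
#' @return Character vector of the eleven biomarker column names.
#' @export
pji_biomarkers <- function() {
  c("ad", "sf_wbc", "sf_pmn_pct", "sf_rbc", "crp",
    "a280", "cp", "ef", "spa", "spb", "pac")
}

#' Default per-biomarker availability rates
#'
#' Fraction of vignettes in which each biomarker is observed (the rest are
#' flagged missing and later imputed). Defaults mirror the availability of
#' routinely collected markers in a suspected-PJI work-up: alpha-defensin,
#' cell counts and differential are nearly always present, SF-RBC and CRP
#' less often, and the research-only absorbance/antigen markers never.
#'
#' @return Named numeric vector over [pji_biomarkers()].
#' @export
default_availability <- function() {
  c(ad = 0.996, sf_wbc = 0.978, sf_pmn_pct = 0.967, sf_rbc = 0.635,
    crp = 0.869, a280 = 0, cp = 0, ef = 0, spa = 0, spb = 0, pac = 0)
}

#' Default per-class biomarker distributions
#'
#' Three generative classes: `aseptic`, `septic`, and `borderline` (a
#' clinically aseptic subgroup with moderately elevated inflammatory
#' markers that lands in the intermediate band of criteria-based scoring).
#' Counts and concentrations are log-normal, percentages scaled beta;
#' alpha-defensin has an aseptic mode near 0.2 and a septic mode well
#' above 1; antigen markers are baseline noise with a per-pathogen
#' Bernoulli spike in septic cases. CRP is in mg/dL.
#'
#' Each entry is a list with a `dist` tag (`lnorm`, `beta100`, or
#' `lnorm_spike`) and its parameters; all are overridable through
#' [cohort_spec()].
#'
#' @return Nested list: class -> biomarker -> distribution spec.
#' @export
default_class_distributions <- function() {
  antigen_base <- list(
    cp  = list(dist = "lnorm", meanlog = log(0.48), sdlog = 0.25),
    ef  = list(dist = "lnorm", meanlog = log(0.50), sdlog = 0.25),
    spa = list(dist = "lnorm", meanlog = log(0.73), sdlog = 0.25),
    spb = list(dist = "lnorm", meanlog = log(0.46), sdlog = 0.25),
    pac = list(dist = "lnorm", meanlog = log(0.10), sdlog = 0.25)
  )
  antigen_septic <- lapply(antigen_base, function(d) {
    list(dist = "lnorm_spike", meanlog = d$meanlog, sdlog = d$sdlog,
         spike_prob = 0.15, spike_meanlog = log(8), spike_sdlog = 0.5)
  })
  aseptic <- c(list(
    ad         = list(dist = "lnorm", meanlog = log(0.2),   sdlog = 0.45),
    sf_wbc     = list(dist = "lnorm", meanlog = log(500),   sdlog = 0.65),
    sf_pmn_pct = list(dist = "beta100", shape1 = 3, shape2 = 6),
    sf_rbc     = list(dist = "lnorm", meanlog = log(15000), sdlog = 1.2),
    crp        = list(dist = "lnorm", meanlog = log(0.25),  sdlog = 0.5),
    a280       = list(dist = "lnorm", meanlog = log(0.62),  sdlog = 0.15)
  ), antigen_base)
  septic <- c(list(
    ad         = list(dist = "lnorm", meanlog = log(3.5),   sdlog = 0.5),
    sf_wbc     = list(dist = "lnorm", meanlog = log(30000), sdlog = 0.7),
    sf_pmn_pct = list(dist = "beta100", shape1 = 10, shape2 = 1.8),
    sf_rbc     = list(dist = "lnorm", meanlog = log(25000), sdlog = 1.2),
    crp        = list(dist = "lnorm", meanlog = log(8),     sdlog = 0.7),
    a280       = list(dist = "lnorm", meanlog = log(0.75),  sdlog = 0.2)
  ), antigen_septic)
  borderline <- utils::modifyList(aseptic, list(
    ad         = list(dist = "lnorm", meanlog = log(0.45),  sdlog = 0.3),
    sf_wbc     = list(dist = "lnorm", meanlog = log(1500),  sdlog = 0.4),
    sf_pmn_pct = list(dist = "beta100", shape1 = 16, shape2 = 4),
    crp        = list(dist = "lnorm", meanlog = log(3),     sdlog = 0.35)
  ))
  list(aseptic = aseptic, septic = septic, borderline = borderline)
}

#' Specify a synthetic vignette cohort
#'
#' Bundles everything [generate_cohort()] needs: cohort size, disease
#' prevalence (enforced as a deterministic count so tallies are exactly
#' reproducible), the fraction of clinically aseptic cases drawn from the
#' borderline distribution, per-biomarker availability, per-class biomarker
#' distributions, culture behaviour, and the seed.
#'
#' @param n_cases Number of vignettes (>= 1).
#' @param prevalence Fraction of cases with clinical diagnosis PJI;
#'   the PJI count is `round(n_cases * prevalence)`, half away from zero.
#' @param p_inconclusive Fraction of the whole cohort drawn from the
#'   borderline aseptic distribution (deterministic count, taken from the
#'   aseptic stratum); these cases are constrained culture-negative.
#' @param availability Named availability fractions, see
#'   [default_availability()]. Missingness is independent per biomarker.
#' @param class_distributions See [default_class_distributions()].
#' @param culture_sensitivity Probability a septic case cultures positive.
#' @param culture_done_rate Probability SF culture was performed at all.
#' @param seed Integer seed; identical specs generate identical cohorts.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_cases,
                        prevalence = 0.153,
                        p_inconclusive = 0.109,
                        availability = default_availability(),
                        class_distributions = default_class_distributions(),
                        culture_sensitivity = 0.70,
                        culture_done_rate = 0.97,
                        seed = 1L) {
  n_cases <- check_count(n_cases, "n_cases", min = 1L)
  check_fraction(prevalence, "prevalence")
  check_fraction(p_inconclusive, "p_inconclusive")
  av <- default_availability()
  av[names(availability)] <- availability
  missing_bm <- setdiff(pji_biomarkers(), names(av))
  if (length(missing_bm)) {
    stop("availability missing biomarkers: ", paste(missing_bm, collapse = ", "),
         call. = FALSE)
  }
  check_fraction(av, "availability")
  check_fraction(culture_sensitivity, "culture_sensitivity")
  check_fraction(culture_done_rate, "culture_done_rate")
  structure(list(
    n_cases = n_cases, prevalence = prevalence,
    p_inconclusive = p_inconclusive, availability = av,
    class_distributions = class_distributions,
    culture_sensitivity = culture_sensitivity,
    culture_done_rate = culture_done_rate,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

draw_biomarker <- function(n, cfg) {
  switch(cfg$dist,
    lnorm = stats::rlnorm(n, cfg$meanlog, cfg$sdlog),
    beta100 = 100 * stats::rbeta(n, cfg$shape1, cfg$shape2),
    lnorm_spike = {
      base <- stats::rlnorm(n, cfg$meanlog, cfg$sdlog)
      spike <- stats::rbinom(n, 1L, cfg$spike_prob) *
        stats::rlnorm(n, cfg$spike_meanlog, cfg$spike_sdlog)
      base + spike
    },
    stop("unknown distribution tag: ", cfg$dist, call. = FALSE)
  )
}

#' Generate a synthetic suspected-PJI vignette cohort
#'
#' Draws one row per suspected-PJI case: joint, the eleven-biomarker
#' synovial-fluid panel with independent per-biomarker missingness
#' (missing entries are `NA`), SF culture result, the binary clinical
#' reference diagnosis, and a criteria-based ternary class computed from
#' the observed panel with [icm2018_classify()].
#'
#' Class labels are deterministic counts: exactly
#' `round(n_cases * prevalence)` cases are PJI for every seed, and the
#' borderline aseptic subgroup likewise has a fixed count. Random draws are
#' split across independent sub-streams (row order, biomarkers, culture,
#' missingness) so changing one consumer does not perturb the others.
#'
#' @param spec A [cohort_spec()].
#' @return A `data.frame` of class `"pji_cohort"` with columns
#'   `id, joint, ad, sf_wbc, sf_pmn_pct, sf_rbc, crp, crp_unit, a280, cp,
#'   ef, spa, spb, pac, sf_culture, clinical_dx, icm_class`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_cases
  n_pji <- as.integer(round_half_away(n * spec$prevalence))
  n_aseptic <- n - n_pji
  n_border <- min(as.integer(round_half_away(n * spec$p_inconclusive)),
                  n_aseptic)
  gen_class <- c(rep("septic", n_pji), rep("borderline", n_border),
                 rep("aseptic", n_aseptic - n_border))

  set.seed(derive_seed(spec$seed, 1L))  # row order / joint
  ord <- sample.int(n)
  gen_class <- gen_class[ord]
  joint <- sample(c("hip", "knee"), n, replace = TRUE)

  panel <- matrix(NA_real_, n, length(pji_biomarkers()),
                  dimnames = list(NULL, pji_biomarkers()))
  set.seed(derive_seed(spec$seed, 2L))  # biomarker values
  for (cls in c("aseptic", "septic", "borderline")) {
    idx <- which(gen_class == cls)
    if (!length(idx)) next
    dists <- spec$class_distributions[[cls]]
    for (bm in pji_biomarkers()) {
      panel[idx, bm] <- draw_biomarker(length(idx), dists[[bm]])
    }
  }

  set.seed(derive_seed(spec$seed, 3L))  # culture
  done <- stats::rbinom(n, 1L, spec$culture_done_rate) == 1L
  pos <- gen_class == "septic" &
    stats::rbinom(n, 1L, spec$culture_sensitivity) == 1L
  sf_culture <- ifelse(!done, "not_done", ifelse(pos, "positive", "negative"))

  set.seed(derive_seed(spec$seed, 4L))  # missingness, independent per marker
  for (bm in pji_biomarkers()) {
    miss <- stats::runif(n) >= spec$availability[[bm]]
    panel[miss, bm] <- NA_real_
  }

  out <- data.frame(
    id = sprintf("V%04d", seq_len(n)),
    joint = joint,
    as.data.frame(panel),
    crp_unit = "mg/dL",
    sf_culture = sf_culture,
    clinical_dx = ifelse(gen_class == "septic", "PJI", "aseptic"),
    stringsAsFactors = FALSE
  )
  out$icm_class <- icm2018_classify(out)
  attr(out, "spec") <- spec
  class(out) <- c("pji_cohort", "data.frame")
  out
}

#' @export
print.pji_cohort <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Synthetic suspected-PJI cohort: %d vignettes\n", n))
  cat(sprintf("  clinical diagnosis: %d PJI / %d aseptic (prevalence %.1f%%)\n",
              sum(x$clinical_dx == "PJI"), sum(x$clinical_dx == "aseptic"),
              100 * mean(x$clinical_dx == "PJI")))
  tab <- table(factor(x$icm_class,
                      levels = c("infected", "inconclusive", "aseptic")))
  cat(sprintf("  criteria class:     %d infected / %d inconclusive / %d aseptic\n",
              tab[["infected"]], tab[["inconclusive"]], tab[["aseptic"]]))
  avail <- round(100 * colMeans(!is.na(x[pji_biomarkers()])), 1)
  cat("  biomarker availability (%):\n")
  print(avail)
  invisible(x)
}

#' Read and write vignette cohorts as CSV
#'
#' One row per case, missing biomarkers as empty fields. `read_vignettes()`
#' restores the `"pji_cohort"` class; the pair round-trips exactly.
#'
#' @param x A vignette data frame.
#' @param path File path.
#' @return `read_vignettes()` returns the cohort data frame.
#' @export
write_vignettes <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_vignettes
#' @export
read_vignettes <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(id = "character"))
  for (bm in intersect(pji_biomarkers(), names(x))) {
    x[[bm]] <- as.numeric(x[[bm]])
  }
  class(x) <- c("pji_cohort", "data.frame")
  x
}
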