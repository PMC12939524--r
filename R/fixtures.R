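#' Built-in false-negative case fixtures
#'
#' Three reference cases in which the probability score disagreed with a
#' PJI clinical diagnosis: one with an extremely low SF-WBC despite a high
#' alpha-defensin, one driven almost entirely by an elevated CRP, and one
#' culture-negative case with a very high SF-RBC suggesting blood
#' contamination of the aspirate. Values not recorded for these cases
#' (SF-RBC in the first two, absorbance and antigen markers in all three)
#' are `NA`; the CRP unit is tagged `"unspecified"` because these reported
#' values carry no unit annotation. The ternary criteria class is computed
#' from the observed panel with the default [icm_rule_table()].
#'
#' @return A `"pji_cohort"` data frame of three rows, ids `FN-001..003`,
#'   all with `clinical_dx = "PJI"`.
#' @export
fixture_fn_cases <- function() {
  out <- data.frame(
    id = c("FN-001", "FN-002", "FN-003"),
    joint = c("hip", "knee", "hip"),
    ad = c(1.599, 0.34, 0.156),
    sf_wbc = c(40, 200, 5354),
    sf_pmn_pct = c(72, 42, 93),
    sf_rbc = c(NA, NA, 786000),
    crp = c(15, 200.4, 1),
    crp_unit = "unspecified",
    a280 = NA_real_, cp = NA_real_, ef = NA_real_,
    spa = NA_real_, spb = NA_real_, pac = NA_real_,
    sf_culture = c("positive", "positive", "negative"),
    clinical_dx = "PJI",
    stringsAsFactors = FALSE
  )
  out$icm_class <- icm2018_classify(out)
  out <- out[c("id", "joint", pji_biomarkers(), "crp_unit",
               "sf_culture", "clinical_dx", "icm_class")]
  class(out) <- c("pji_cohort", "data.frame")
  out
}
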