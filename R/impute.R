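#' Constant-value imputation table for missing biomarkers
#'
#' Missing biomarkers are replaced by fixed raw-scale constants
#' representing the central tendency of each marker in a large reference
#' population dominated by non-infected samples, so imputation cannot by
#' itself push a score toward infection. The `crp_substitution` flag
#' records the convention that an available serum CRP value stands in for
#' synovial-fluid CRP rather than the constant; since a vignette carries a
#' single `crp` field, substitution simply means an observed value is
#' always preferred over the constant.
#'
#' @param values Named numeric overrides of the per-biomarker constants.
#' @param crp_substitution Logical; prefer an observed (serum) CRP over
#'   the CRP constant.
#' @return An object of class `"imputation_table"`.
#' @export
imputation_table <- function(values = NULL, crp_substitution = TRUE) {
  defaults <- c(ad = 0.196, sf_wbc = 843, sf_pmn_pct = 48, sf_rbc = 18895,
                crp = 1.7, a280 = 0.643, cp = 0.48, ef = 0.5, spa = 0.73,
                spb = 0.46, pac = 0.1)
  if (!is.null(values)) {
    unknown <- setdiff(names(values), names(defaults))
    if (length(unknown)) {
      stop("unknown biomarker(s) in imputation table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    defaults[names(values)] <- values
  }
  if (any(defaults < 0)) stop("imputed values must be non-negative",
                              call. = FALSE)
  structure(list(values = defaults,
                 crp_substitution = isTRUE(crp_substitution)),
            class = "imputation_table")
}

#' Impute missing biomarkers in a vignette panel
#'
#' Replaces `NA` biomarker values by the table constants; observed values
#' are never touched, so the operation is idempotent. Every biomarker of
#' [pji_biomarkers()] must be either present as a column or covered by the
#' table; a biomarker absent from both is an error naming it.
#'
#' @param panel Vignette data frame (or any data frame with biomarker
#'   columns).
#' @param table An [imputation_table()].
#' @return The panel with all eleven biomarkers complete.
#' @export
impute_panel <- function(panel, table = imputation_table()) {
  stopifnot(inherits(table, "imputation_table"))
  for (bm in pji_biomarkers()) {
    have_col <- bm %in% names(panel)
    have_const <- bm %in% names(table$values)
    if (!have_const && (!have_col || anyNA(panel[[bm]]))) {
      stop(sprintf("biomarker '%s' is missing and not covered by the imputation table", bm),
           call. = FALSE)
    }
    if (!have_col) {
      panel[[bm]] <- table$values[[bm]]
    } else {
      miss <- is.na(panel[[bm]])
      panel[[bm]][miss] <- table$values[[bm]]
    }
  }
  panel
}
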