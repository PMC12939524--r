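#' Configure an end-to-end pipeline run
#'
#' Bundles every knob of the full synthetic analysis: cohort sizes and
#' prevalence, surrogate-model settings, rater profiles, triage /
#' forced-call thresholds, the decision-curve grid, bootstrap size, cost
#' parameters and the master seed. The master seed is split into
#' independent sub-streams for the training cohort, the vignette cohort,
#' the raters and the bootstrap.
#'
#' @param n_vignettes Evaluation cohort size (default 274).
#' @param prevalence Clinical PJI prevalence (default 0.153).
#' @param n_train Training cohort size for the surrogate (default 2000).
#' @param k_components Mixture components of the surrogate (default 2).
#' @param profiles Rater profiles (default [default_rater_profiles()]).
#' @param triage_low,triage_high,forced_cutoff Score thresholds.
#' @param dca_grid Decision-curve threshold grid.
#' @param boot_B Bootstrap replicates for interval estimates.
#' @param costs A [cost_parameters()] object.
#' @param econ_cohort Cohort size for the cost model (default 1000).
#' @param seed Master integer seed.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_vignettes = 274L, prevalence = 0.153,
                            n_train = 2000L, k_components = 2L,
                            profiles = default_rater_profiles(),
                            triage_low = 20, triage_high = 80,
                            forced_cutoff = 20,
                            dca_grid = seq(0.01, 0.99, by = 0.01),
                            boot_B = 500L,
                            costs = cost_parameters(),
                            econ_cohort = 1000L,
                            seed = 1L) {
  cfg <- list(n_vignettes = check_count(n_vignettes, "n_vignettes", 1L),
              prevalence = prevalence,
              n_train = check_count(n_train, "n_train", 2L),
              k_components = check_count(k_components, "k_components", 1L),
              profiles = profiles,
              triage_low = triage_low, triage_high = triage_high,
              forced_cutoff = forced_cutoff,
              dca_grid = dca_grid, boot_B = check_count(boot_B, "boot_B", 1L),
              costs = costs,
              econ_cohort = check_count(econ_cohort, "econ_cohort", 1L),
              seed = as.integer(seed))
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  check_fraction(cfg$prevalence, "prevalence")
  for (nm in c("triage_low", "triage_high", "forced_cutoff")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 100) {
      stop(sprintf("`%s` must be a score threshold in [0, 100]", nm),
           call. = FALSE)
    }
  }
  if (cfg$triage_low >= cfg$triage_high) {
    stop("`triage_low` must be below `triage_high`", call. = FALSE)
  }
  if (any(cfg$dca_grid <= 0 | cfg$dca_grid >= 1)) {
    stop("`dca_grid` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!all(vapply(cfg$profiles, inherits, logical(1L), "rater_profile"))) {
    stop("`profiles` must be a list of rater_profile objects",
         call. = FALSE)
  }
  stopifnot(inherits(cfg$costs, "cost_parameters"))
  invisible(cfg)
}

#' Read and write pipeline configuration as JSON
#'
#' The JSON form carries the scalar settings, the rater-profile table and
#' the cost parameters; it is validated on read, and unknown fields are
#' rejected.
#'
#' @param cfg A [pipeline_config()].
#' @param path File path.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  doc <- unclass(cfg)
  doc$profiles <- lapply(cfg$profiles, unclass)
  doc$costs <- unclass(cfg$costs)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  known <- c("n_vignettes", "prevalence", "n_train", "k_components",
             "profiles", "triage_low", "triage_high", "forced_cutoff",
             "dca_grid", "boot_B", "costs", "econ_cohort", "seed")
  unknown <- setdiff(names(doc), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  profiles <- lapply(doc$profiles, function(p) {
    rater_profile(p$rater_id, p$group, p$stage1_indecision_rate,
                  p$target_ppa, p$target_npa,
                  p$inconclusive_indecision_rate)
  })
  costs <- cost_parameters(doc$costs$c_repeat_workup,
                           doc$costs$c_delayed_surgical,
                           doc$costs$pathway_weight, doc$costs$c_fp)
  pipeline_config(n_vignettes = doc$n_vignettes, prevalence = doc$prevalence,
                  n_train = doc$n_train, k_components = doc$k_components,
                  profiles = profiles, triage_low = doc$triage_low,
                  triage_high = doc$triage_high,
                  forced_cutoff = doc$forced_cutoff,
                  dca_grid = unlist(doc$dca_grid), boot_B = doc$boot_B,
                  costs = costs, econ_cohort = doc$econ_cohort,
                  seed = doc$seed)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

agreement_row <- function(label, calls, reference, B, seed) {
  est <- agreement_summary(calls, reference, B = B, seed = seed)
  data.frame(strategy = label, est, stringsAsFactors = FALSE)
}

#' Run the full synthetic comparison pipeline
#'
#' Generates a training cohort, fits the surrogate score, generates an
#' evaluation vignette cohort, scores it (triage + forced call),
#' simulates the physician panel, and produces four report tables: the
#' Stage-I indecision distribution, the agreement table (score and pooled
#' physician groups, with Wilson and bootstrap intervals), the long-format
#' decision curve, and the misdiagnosis cost comparison. Deterministic for
#' a fixed configuration.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory; when given, every table is also
#'   written as CSV (`vignettes.csv`, `scores.csv`, `rater_calls.csv`,
#'   `indecision.csv`, `agreement.csv`, `decision_curve.csv`,
#'   `economics.csv`).
#' @return List of class `"pji_report"`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL) {
  validate_pipeline_config(cfg)
  train <- stage("generate_training_cohort",
                 generate_cohort(cohort_spec(cfg$n_train, cfg$prevalence,
                                             seed = derive_seed(cfg$seed,
                                                                11L))))
  model <- stage("fit_surrogate", {
    m <- fit_pji_score(train, k_components = cfg$k_components,
                       seed = derive_seed(cfg$seed, 12L))
    m$thresholds <- list(low = cfg$triage_low, high = cfg$triage_high,
                         forced = cfg$forced_cutoff)
    m
  })
  cohort <- stage("generate_vignette_cohort",
                  generate_cohort(cohort_spec(cfg$n_vignettes,
                                              cfg$prevalence,
                                              seed = derive_seed(cfg$seed,
                                                                 13L))))
  scored <- stage("score_vignettes", score_vignettes(model, cohort))
  calls <- stage("simulate_raters",
                 simulate_raters(cohort, cfg$profiles,
                                 seed = derive_seed(cfg$seed, 14L)))

  truth <- cohort$clinical_dx
  names(truth) <- cohort$id

  indecision <- stage("indecision_table", {
    score_row <- data.frame(
      method = "surrogate_score", group = "score",
      n_pji = sum(scored$triage == "high"),
      n_aseptic = sum(scored$triage == "low"),
      n_undecided = sum(scored$triage == "equivocal"),
      indecision_rate = mean(scored$triage == "equivocal"),
      stringsAsFactors = FALSE)
    by_unit <- function(d, method, grp) data.frame(
      method = method, group = grp,
      n_pji = sum(d$stage1 == "PJI"),
      n_aseptic = sum(d$stage1 == "aseptic"),
      n_undecided = sum(d$stage1 == "undecided"),
      indecision_rate = indecision_rate(d$stage1),
      stringsAsFactors = FALSE)
    rows <- list(score_row, by_unit(calls, "all_physicians", "all"))
    for (g in unique(calls$group)) {
      rows[[length(rows) + 1L]] <-
        by_unit(calls[calls$group == g, ], g, g)
    }
    for (r in unique(calls$rater_id)) {
      d <- calls[calls$rater_id == r, ]
      rows[[length(rows) + 1L]] <- by_unit(d, r, d$group[1L])
    }
    do.call(rbind, rows)
  })

  agreement <- stage("agreement_table", {
    rows <- list(
      agreement_row("surrogate_score", scored$forced_call, truth[scored$id],
                    cfg$boot_B, cfg$seed),
      agreement_row("all_physicians", calls$stage2,
                    truth[calls$vignette_id], cfg$boot_B, cfg$seed)
    )
    for (g in unique(calls$group)) {
      d <- calls[calls$group == g, ]
      rows[[length(rows) + 1L]] <-
        agreement_row(g, d$stage2, truth[d$vignette_id], cfg$boot_B,
                      cfg$seed)
    }
    do.call(rbind, rows)
  })

  dca <- stage("decision_curve", {
    phys <- matrix(calls$stage2, nrow = cfg$n_vignettes,
                   dimnames = list(NULL, unique(calls$rater_id)))
    decision_curve(list(surrogate_score = scored$forced_call,
                        all_physicians = phys),
                   truth, grid = cfg$dca_grid)
  })

  econ <- stage("economics", {
    cc_s <- build_confusion(scored$forced_call, truth[scored$id])
    cc_p <- pool_calls(calls, truth)
    a <- misdiagnosis_cost(cfg$econ_cohort, cfg$prevalence,
                           ppa(cc_s), npa(cc_s), cfg$costs)
    b <- misdiagnosis_cost(cfg$econ_cohort, cfg$prevalence,
                           ppa(cc_p), npa(cc_p), cfg$costs)
    list(surrogate_score = a, physicians = b,
         comparison = compare_strategies(a, b),
         threshold = economic_threshold(cfg$costs$c_fp,
                                        expected_fn_cost(cfg$costs)))
  })

  provenance <- list(
    seed = cfg$seed,
    config_hash = fnv1a_hash(as.character(jsonlite::toJSON(
      unclass(cfg)[setdiff(names(unclass(cfg)), "profiles")],
      auto_unbox = TRUE, digits = NA, force = TRUE))),
    package_version = as.character(utils::packageVersion("pjiscore")),
    thresholds = list(low = cfg$triage_low, high = cfg$triage_high,
                      forced = cfg$forced_cutoff),
    costs = unclass(cfg$costs)
  )

  report <- structure(list(
    cohort = cohort, scores = scored, rater_calls = calls, model = model,
    indecision = indecision, agreement = agreement, dca = dca, econ = econ,
    provenance = provenance
  ), class = "pji_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_vignettes(cohort, file.path(out_dir, "vignettes.csv"))
    utils::write.csv(scored, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
    write_rater_calls(calls, file.path(out_dir, "rater_calls.csv"))
    utils::write.csv(indecision, file.path(out_dir, "indecision.csv"),
                     row.names = FALSE)
    utils::write.csv(agreement, file.path(out_dir, "agreement.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(dca),
                     file.path(out_dir, "decision_curve.csv"),
                     row.names = FALSE)
    econ_tab <- data.frame(
      strategy = c("surrogate_score", "physicians"),
      n_fn = c(econ$surrogate_score$n_fn, econ$physicians$n_fn),
      n_fp = c(econ$surrogate_score$n_fp, econ$physicians$n_fp),
      cost_total = c(econ$surrogate_score$cost_total,
                     econ$physicians$cost_total),
      stringsAsFactors = FALSE)
    utils::write.csv(econ_tab, file.path(out_dir, "economics.csv"),
                     row.names = FALSE)
  }
  report
}

#' @export
print.pji_report <- function(x, ...) {
  cat("Synthetic suspected-PJI comparison report\n")
  cat(sprintf("  cohort: %d vignettes, %d PJI / %d aseptic\n",
              nrow(x$cohort), sum(x$cohort$clinical_dx == "PJI"),
              sum(x$cohort$clinical_dx == "aseptic")))
  cat("\nStage-I indecision (method x group):\n")
  print(x$indecision[x$indecision$method %in%
                       c("surrogate_score", "all_physicians"), ],
        row.names = FALSE)
  cat("\nAgreement with the clinical reference:\n")
  for (s in unique(x$agreement$strategy)) {
    cat(sprintf(" %s\n", s))
    print(structure(x$agreement[x$agreement$strategy == s, -1L],
                    class = c("pji_agreement", "data.frame")))
  }
  cat("\nMisdiagnosis cost comparison:\n")
  print(x$econ$surrogate_score)
  print(x$econ$physicians)
  cat(sprintf("  savings: $%s total, $%.1f per suspected case\n",
              format(x$econ$comparison$savings_total, big.mark = ","),
              x$econ$comparison$savings_per_case))
  cat(sprintf("  provenance: seed %d, config %s, version %s\n",
              x$provenance$seed, x$provenance$config_hash,
              x$provenance$package_version))
  invisible(x)
}
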