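#' Fit the two-stage surrogate probability score
#'
#' Fits a desk-scale surrogate of a two-stage probability score for PJI:
#' stage one fits a Gaussian mixture (diagonal covariance, via
#' \pkg{mclust}) on the scaled, imputed biomarker panels *ignoring* the
#' class labels; stage two fits a logistic regression mapping the stage-one
#' component responsibilities together with the scaled features to the
#' binary clinical label. The emitted score is 100 times the logistic
#' probability, so it lives on a 0-100 scale with higher values indicating
#' a greater probability of infection.
#'
#' Feature scaling is log10(x + 1) on counts and concentrations (SF-WBC,
#' SF-RBC, CRP), identity on percentages and signal ratios, followed by
#' standardization to training mean and standard deviation. Features that
#' are constant after imputation (e.g. markers never observed in the
#' training data) carry no information and are excluded from both stages.
#'
#' This surrogate is *not* a deployed clinical model; its contract is
#' architectural (two-stage, culture-free, 0-100 output) and strong
#' discrimination on its own synthetic training distribution.
#'
#' @param data Vignette data frame with biomarker columns and a
#'   `clinical_dx` column (or supply `labels`).
#' @param labels Binary labels in `{PJI, aseptic}`; defaults to
#'   `data$clinical_dx`. Both classes must be present.
#' @param k_components Number of mixture components (default 2,
#'   a septic/aseptic reading); `k_components = 1` degenerates to a plain
#'   logistic model on the scaled features.
#' @param seed Integer seed (mixture initialisation is deterministic but
#'   the seed is fixed regardless so large-n subset initialisation stays
#'   reproducible).
#' @param impute An [imputation_table()] applied before scaling; stored in
#'   the model so prediction imputes identically.
#' @param log_features Biomarkers receiving the log10(x + 1) transform.
#' @return An object of class `"pji_score"` with `print()`, `summary()`,
#'   `coef()`, `predict()`, `residuals()` and `plot()` methods.
#' @seealso [predict.pji_score()], [triage()], [forced_call()],
#'   [write_pji_score()]
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_pji_score <- function(data, labels = data$clinical_dx,
                          k_components = 2L, seed = 1L,
                          impute = imputation_table(),
                          log_features = c("sf_wbc", "sf_rbc", "crp")) {
  k <- check_count(k_components, "k_components", min = 1L)
  if (is.null(labels)) stop("labels are required (clinical_dx)", call. = FALSE)
  y <- as.integer(labels == "PJI")
  if (length(unique(y)) < 2L) {
    stop("training cohort must contain both PJI and aseptic cases",
         call. = FALSE)
  }
  complete <- impute_panel(data, impute)
  feats <- pji_biomarkers()
  transform <- ifelse(feats %in% log_features, "log10p1", "identity")
  names(transform) <- feats
  raw <- as.matrix(complete[feats])
  tx <- apply_transform(raw, transform)
  center <- colMeans(tx)
  scale_ <- apply(tx, 2L, stats::sd)
  active <- scale_ > 0
  scale_[!active] <- 1
  X <- sweep(sweep(tx, 2L, center), 2L, scale_, "/")
  Xa <- X[, active, drop = FALSE]

  set.seed(derive_seed(seed, 6L))
  if (k > 1L) {
    fit <- mclust::Mclust(Xa, G = k, modelNames = "VVI", verbose = FALSE)
    if (is.null(fit)) stop("mixture fit failed", call. = FALSE)
    sig <- fit$parameters$variance$sigma
    mixture <- list(
      pro = as.numeric(fit$parameters$pro),
      mean = fit$parameters$mean,                       # d x k
      sd = vapply(seq_len(k), function(j) sqrt(diag(sig[, , j])),
                  numeric(sum(active)))
    )
  } else {
    mixture <- NULL
  }
  resp <- responsibilities(Xa, mixture, k)
  design <- stage2_design(resp, Xa, k)
  glm_fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, design), y,
                   family = stats::binomial())
  )
  coefs <- glm_fit$coefficients
  coefs[is.na(coefs)] <- 0

  model <- structure(list(
    features = feats, transform = transform,
    center = center, scale = scale_, active = active,
    k = k, mixture = mixture, coef = coefs,
    impute = impute,
    thresholds = list(low = 20, high = 80, forced = 20),
    n_train = nrow(data), seed = as.integer(seed),
    version = "1"
  ), class = "pji_score")
  model$train_score <- predict(model, complete)
  model$train_label <- ifelse(y == 1L, "PJI", "aseptic")
  model
}

apply_transform <- function(raw, transform) {
  for (bm in names(transform)) {
    if (transform[[bm]] == "log10p1") raw[, bm] <- log10(raw[, bm] + 1)
  }
  raw
}

# Posterior component membership under a diagonal Gaussian mixture,
# computed from stored parameters (log-sum-exp) so that a model written to
# JSON scores identically after reload.
responsibilities <- function(X, mixture, k) {
  if (k == 1L || is.null(mixture)) {
    return(matrix(1, nrow(X), 1L))
  }
  logd <- vapply(seq_len(k), function(j) {
    mu <- mixture$mean[, j]
    sd <- pmax(mixture$sd[, j], 1e-8)
    rowSums(stats::dnorm(X, rep(mu, each = nrow(X)),
                         rep(sd, each = nrow(X)), log = TRUE)) +
      log(mixture$pro[j])
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) logd <- matrix(logd, 1L)
  m <- apply(logd, 1L, max)
  w <- exp(logd - m)
  w / rowSums(w)
}

stage2_design <- function(resp, Xa, k) {
  if (k > 1L) {
    r <- resp[, -1L, drop = FALSE]
    colnames(r) <- paste0("resp", 2:k)
    cbind(r, Xa)
  } else {
    Xa
  }
}

#' Score biomarker panels with a fitted surrogate model
#'
#' Emits the 0-100 probability score for each row. Panels must be complete:
#' prediction refuses `NA` biomarkers rather than silently imputing, so
#' imputation is an explicit, auditable step ([impute_panel()]).
#'
#' @param object A fitted `"pji_score"` model.
#' @param newdata Data frame with the eleven biomarker columns, complete
#'   (post-imputation).
#' @param type `"score"` (0-100, default), `"probability"` (0-1),
#'   `"triage"` (low / equivocal / high) or `"forced"` (aseptic / PJI).
#' @param ... Unused.
#' @return Numeric vector, or factor for `"triage"` / `"forced"`.
#' @export
predict.pji_score <- function(object, newdata,
                              type = c("score", "probability", "triage",
                                       "forced"), ...) {
  type <- match.arg(type)
  feats <- object$features
  missing_cols <- setdiff(feats, names(newdata))
  if (length(missing_cols)) {
    stop("newdata lacks biomarker column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- as.matrix(as.data.frame(newdata)[feats])
  if (anyNA(raw)) {
    stop("panel is incomplete; impute_panel() it before scoring",
         call. = FALSE)
  }
  tx <- apply_transform(raw, object$transform)
  X <- sweep(sweep(tx, 2L, object$center), 2L, object$scale, "/")
  Xa <- X[, object$active, drop = FALSE]
  resp <- responsibilities(Xa, object$mixture, object$k)
  design <- cbind(1, stage2_design(resp, Xa, object$k))
  eta <- drop(design %*% object$coef)
  p <- stats::plogis(eta)
  score <- 100 * p
  switch(type,
         score = score,
         probability = p,
         triage = triage(score, object$thresholds$low,
                         object$thresholds$high),
         forced = forced_call(score, object$thresholds$forced))
}

#' Triage a 0-100 score into low / equivocal / high
#'
#' `score < low` is a low probability of infection (aseptic), `score >=
#' high` a high probability, and the half-open band `[low, high)` is
#' equivocal. The boundaries follow the "greater than or equal" convention
#' at both cutoffs, so exactly 20 is equivocal and exactly 80 is high
#' under the defaults.
#'
#' @param score Numeric scores in [0, 100].
#' @param low,high Band edges (defaults 20 and 80).
#' @return Factor with levels `low`, `equivocal`, `high`.
#' @export
triage <- function(score, low = 20, high = 80) {
  if (anyNA(score) || any(score < 0 | score > 100)) {
    stop("scores must lie in [0, 100]", call. = FALSE)
  }
  factor(ifelse(score < low, "low", ifelse(score < high, "equivocal",
                                           "high")),
         levels = c("low", "equivocal", "high"))
}

#' Binarize a score at the forced-call cutoff
#'
#' Reclassifies equivocal scores for settings where a definitive diagnosis
#' is required: `PJI` when the score is greater than or equal to the
#' cutoff, `aseptic` below it. With the default cutoff of 20 this is
#' coherent with [triage()]: forced `PJI` exactly when triage is not low.
#'
#' @param score Numeric scores in [0, 100].
#' @param cutoff Decision cutoff (default 20).
#' @return Factor with levels `aseptic`, `PJI`.
#' @export
forced_call <- function(score, cutoff = 20) {
  if (anyNA(score) || any(score < 0 | score > 100)) {
    stop("scores must lie in [0, 100]", call. = FALSE)
  }
  factor(ifelse(score >= cutoff, "PJI", "aseptic"),
         levels = c("aseptic", "PJI"))
}

#' Score a vignette cohort into the reporting schema
#'
#' Convenience wrapper: imputes with the model's stored table, scores and
#' returns the per-case table `id, score, triage, forced_call`.
#'
#' @param model A `"pji_score"` model.
#' @param vignettes Vignette data frame.
#' @return Data frame with one row per vignette.
#' @export
score_vignettes <- function(model, vignettes) {
  complete <- impute_panel(vignettes, model$impute)
  s <- predict(model, complete)
  data.frame(id = vignettes$id, score = s,
             triage = as.character(triage(s, model$thresholds$low,
                                          model$thresholds$high)),
             forced_call = as.character(forced_call(s,
                                                    model$thresholds$forced)),
             stringsAsFactors = FALSE)
}

#' @export
print.pji_score <- function(x, ...) {
  cat(sprintf("Two-stage surrogate PJI probability score (0-100)\n"))
  cat(sprintf("  stage 1: %d-component diagonal Gaussian mixture on %d active of %d features\n",
              x$k, sum(x$active), length(x$features)))
  cat(sprintf("  stage 2: logistic map, %d coefficients\n", length(x$coef)))
  cat(sprintf("  trained on %d vignettes (%.1f%% PJI)\n", x$n_train,
              100 * mean(x$train_label == "PJI")))
  cat(sprintf("  thresholds: low < %g <= equivocal < %g <= high; forced call at %g\n",
              x$thresholds$low, x$thresholds$high, x$thresholds$forced))
  invisible(x)
}

# Rank (Mann-Whitney) AUC used for the summary display only.
rank_auc <- function(score, label) {
  pos <- score[label == "PJI"]; neg <- score[label != "PJI"]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' @export
summary.pji_score <- function(object, ...) {
  print(object)
  s <- object$train_score
  cat(sprintf("  training AUC (rank): %.3f\n",
              rank_auc(s, object$train_label)))
  occ <- mean(s >= object$thresholds$low & s < object$thresholds$high)
  cat(sprintf("  equivocal-zone occupancy on training data: %.1f%%\n",
              100 * occ))
  if (object$k > 1L) {
    cat("  mixture weights: ",
        paste(sprintf("%.3f", object$mixture$pro), collapse = ", "), "\n")
  }
  cat("  logistic coefficients:\n")
  print(round(object$coef, 3))
  invisible(object)
}

#' @export
coef.pji_score <- function(object, ...) object$coef

#' @export
residuals.pji_score <- function(object, type = c("response", "deviance"),
                                ...) {
  type <- match.arg(type)
  y <- as.integer(object$train_label == "PJI")
  p <- object$train_score / 100
  if (type == "response") return(y - p)
  sign(y - p) * sqrt(-2 * (y * log(pmax(p, 1e-12)) +
                           (1 - y) * log(pmax(1 - p, 1e-12))))
}

#' @export
plot.pji_score <- function(x, ...) {
  s <- x$train_score
  lab <- x$train_label
  br <- seq(0, 100, by = 5)
  h1 <- graphics::hist(s[lab == "aseptic"], breaks = br, plot = FALSE)
  h2 <- graphics::hist(s[lab == "PJI"], breaks = br, plot = FALSE)
  ylim <- c(0, max(h1$counts, h2$counts))
  graphics::plot(h1, col = grDevices::adjustcolor("steelblue", 0.6),
                 xlim = c(0, 100), ylim = ylim,
                 main = "Training score distribution",
                 xlab = "probability score (0-100)", ...)
  graphics::plot(h2, col = grDevices::adjustcolor("firebrick", 0.6),
                 add = TRUE)
  graphics::abline(v = c(x$thresholds$low, x$thresholds$high), lty = 2)
  graphics::legend("top", fill = c("steelblue", "firebrick"),
                   legend = c("aseptic", "PJI"), bty = "n")
  invisible(x)
}

#' Serialize a fitted score model to JSON
#'
#' The full model (scaling, mixture, logistic coefficients, thresholds,
#' imputation table, version) is written as a JSON document at full
#' numeric precision; [read_pji_score()] restores an object whose scores
#' agree with the original to machine precision.
#'
#' @param model A `"pji_score"` model.
#' @param path Output file path.
#' @export
write_pji_score <- function(model, path) {
  doc <- list(
    version = model$version,
    features = model$features,
    transform = as.list(model$transform),
    center = as.list(model$center),
    scale = as.list(model$scale),
    active = as.list(model$active),
    k = model$k,
    mixture = if (model$k > 1L) list(
      pro = model$mixture$pro,
      mean = apply(model$mixture$mean, 2L, identity, simplify = FALSE),
      sd = apply(model$mixture$sd, 2L, identity, simplify = FALSE),
      feature_names = rownames(model$mixture$mean) %||%
        model$features[model$active]
    ),
    coef = as.list(model$coef),
    impute = list(values = as.list(model$impute$values),
                  crp_substitution = model$impute$crp_substitution),
    thresholds = model$thresholds,
    n_train = model$n_train,
    seed = model$seed
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pji_score
#' @export
read_pji_score <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = FALSE)
  k <- as.integer(doc$k)
  active <- unlist(doc$active)
  mixture <- if (k > 1L) {
    d <- sum(active)
    list(pro = as.numeric(doc$mixture$pro),
         mean = matrix(unlist(doc$mixture$mean), d, k,
                       dimnames = list(doc$mixture$feature_names, NULL)),
         sd = matrix(unlist(doc$mixture$sd), d, k))
  }
  structure(list(
    features = doc$features,
    transform = unlist(doc$transform),
    center = unlist(doc$center),
    scale = unlist(doc$scale),
    active = active,
    k = k, mixture = mixture,
    coef = unlist(doc$coef),
    impute = imputation_table(unlist(doc$impute$values),
                              doc$impute$crp_substitution),
    thresholds = doc$thresholds,
    n_train = doc$n_train, seed = doc$seed,
    version = doc$version
  ), class = "pji_score")
}
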