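# Shared fixtures and independent oracles used across test files.

# Brute-force Gwet AC1 from a raw paired label sequence (independent of
# the confusion-count implementation).
brute_ac1 <- function(call, ref, positive = "PJI") {
  pa <- mean(call == ref)
  pi_bar <- (mean(call == positive) + mean(ref == positive)) / 2
  pe <- 2 * pi_bar * (1 - pi_bar)
  (pa - pe) / (1 - pe)
}

# Expand a confusion tally back into paired (call, reference) vectors.
expand_confusion <- function(tp, fp, fn, tn) {
  data.frame(
    call = rep(c("PJI", "aseptic", "PJI", "aseptic"), c(tp, fn, fp, tn)),
    ref = rep(c("PJI", "aseptic"), c(tp + fn, fp + tn)),
    stringsAsFactors = FALSE
  )
}

# The study tallies every closed-form check runs from.
syn_counts <- function() confusion_counts(39L, 8L, 3L, 224L)
phys_counts <- function() confusion_counts(496L, 294L, 8L, 2490L)

# One shared surrogate model fitted on the default synthetic training
# cohort; fitting is deterministic so memoising is safe.
default_model <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      train <- generate_cohort(cohort_spec(2000, seed = 42))
      model <<- fit_pji_score(train, seed = 1)
    }
    model
  }
})
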