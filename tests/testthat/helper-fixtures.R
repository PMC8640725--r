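# Shared fixtures built in code.

# Minimal three-condition catalogue for toy chains.
toy_catalogue <- function() {
  data.frame(
    code = c("aaa", "bbb", "ccc"),
    name = c("A", "B", "C"),
    resolvable = c(TRUE, TRUE, FALSE),
    cluster = c("A", "A", "B"),
    stringsAsFactors = FALSE
  )
}

# One patient row for build_state_history tests.
mk_patient <- function(id = "p1", start = "2010-01-01", end = "2015-01-01",
                       died = FALSE) {
  data.frame(patient_id = id, follow_up_start = as.Date(start),
             follow_up_end = as.Date(end), died = died,
             stringsAsFactors = FALSE)
}

mk_events <- function(conditions, onsets, resolves = NULL) {
  if (is.null(resolves)) resolves <- rep(NA_character_, length(conditions))
  data.frame(condition = conditions, onset_date = as.Date(onsets),
             resolve_date = as.Date(resolves), stringsAsFactors = FALSE)
}

# Ground truth used by recovery-style tests: moderate rates everywhere plus
# a binary covariate multiplying the S1->S2 intensity by 1.5.
recovery_truth <- function(hr_s1s2 = 1.5) {
  intensity_model(
    c("S0->S1" = 0.10, "S1->S2" = 0.18, "S2->S3plus" = 0.22,
      "S1->S0" = 0.08, "S2->S1" = 0.09, "S3plus->S2" = 0.09,
      "S0->Death" = 0.020, "S1->Death" = 0.020,
      "S2->Death" = 0.025, "S3plus->Death" = 0.030),
    matrix(log(hr_s1s2), 1, 1, dimnames = list("S1->S2", "grp"))
  )
}

recovery_config <- function(n, seed, truth = recovery_truth()) {
  cv <- default_covariate_prevalences()
  cv$extra <- list(grp = c("0" = 0.5, "1" = 0.5))
  cohort_config(n, seed = seed, covariates = cv, truth = truth,
                initial_state_probs = c(0.4, 0.3, 0.2, 0.1))
}

# A random valid 5-state intensity matrix with the allowed sparsity.
random_Q <- function() {
  tr <- ltc_transitions()
  m <- intensity_model(stats::setNames(stats::runif(10, 0.01, 1), tr$label))
  make_intensity_matrix(m)
}
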