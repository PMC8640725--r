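#' Default covariate category prevalences for the synthetic cohort
#'
#' Marginal category probabilities emulating a deprived, young, multi-ethnic
#' urban primary-care population: mostly aged 18-39 at entry, a majority of
#' non-White ethnicities combined, deprivation concentrated in the lower
#' national IMD quintiles, and six clinical risk factors each classified
#' never / ever / resolved.
#'
#' @return Named list of probability vectors (`sex`, `age_group`,
#'   `ethnicity`, `imd_quintile`) plus `risk_factors`, a list of
#'   never/ever/resolved vectors for the six factors.
#' @export
default_covariate_prevalences <- function() {
  list(
    sex = c(Male = 0.48, Female = 0.52),
    age_group = c("18-39" = 0.747, "40-59" = 0.182,
                  "60-79" = 0.057, "80+" = 0.014),
    ethnicity = c(White = 0.539, Black = 0.138, Asian = 0.060,
                  Mixed = 0.038, Other = 0.029, Missing = 0.196),
    imd_quintile = c("1" = 0.174, "2" = 0.467, "3" = 0.264,
                     "4" = 0.069, "5" = 0.014, Missing = 0.012),
    risk_factors = list(
      alcohol = c(never = 0.9863, ever = 0.0121, resolved = 0.0016),
      cholesterol = c(never = 0.814, ever = 0.186, resolved = 0),
      obesity = c(never = 0.868, ever = 0.113, resolved = 0.019),
      smoking = c(never = 0.580, ever = 0.257, resolved = 0.163),
      substance = c(never = 0.971, ever = 0.029, resolved = 0),
      hypertension = c(never = 0.85, ever = 0.13, resolved = 0.02)
    )
  )
}

#' Default ground-truth intensity model for the synthetic cohort
#'
#' Baseline intensities (per year, reference pattern: age 18-39, male,
#' never-smoker) are chosen so that the simulated cohort qualitatively
#' matches the motivating descriptives -- a healthy patient takes well over
#' a decade on average to gain a first condition, acquisition accelerates
#' with the number of conditions, resolution is slower than acquisition,
#' and death is rare from the healthy state but rises steeply with
#' morbidity and age. Covariate effects cover age group (acquisition and
#' death rise with age, resolution falls), female sex (more movement up and
#' down, less death) and smoking (faster acquisition, resolved > ever).
#'
#' @return An [intensity_model()].
#' @export
default_truth_model <- function() {
  baseline <- c(
    "S0->S1" = 0.060, "S1->S2" = 0.120, "S2->S3plus" = 0.160,
    "S1->S0" = 0.050, "S2->S1" = 0.060, "S3plus->S2" = 0.050,
    "S0->Death" = 0.0015, "S1->Death" = 0.003,
    "S2->Death" = 0.005, "S3plus->Death" = 0.012
  )
  hr <- rbind(
    age_40_59   = c(1.7, 1.9, 1.3,  0.45, 1.3, 0.40,  3.0, 4.0, 3.2, 3.0),
    age_60_79   = c(3.6, 7.9, 2.2,  0.40, 4.9, 0.20,  12,  16,  9.7, 10),
    age_80plus  = c(4.0, 8.0, 4.5,  0.28, 4.9, 0.27,  34,  34,  30,  34),
    sex_Female  = c(1.50, 1.17, 1.02, 1.05, 1.02, 0.87, 0.75, 0.43, 0.65, 0.67),
    smoking_ever     = c(1.29, 1.40, 1.30, 0.89, 1.27, 0.80, 0.97, 3.0, 1.6, 1.8),
    smoking_resolved = c(2.12, 1.22, 1.21, 1.34, 1.02, 0.85, 0.50, 0.74, 0.34, 1.0)
  )
  lab <- c("S0->S1", "S1->S2", "S2->S3plus",
           "S1->S0", "S2->S1", "S3plus->S2",
           "S0->Death", "S1->Death", "S2->Death", "S3plus->Death")
  colnames(hr) <- lab
  intensity_model(baseline, t(log(hr)))
}

## Observed-median calibration of the follow-up duration distribution.
## Durations are lognormal but administratively censored at the study-window
## end; entry is a mixture (point mass at the window start, else uniform).
## Solves for the lognormal meanlog such that the *censored* median equals
## the target.
calibrate_duration_meanlog <- function(target_median, sdlog,
                                       frac_at_origin, window_years) {
  f <- function(m) {
    pd <- stats::plnorm(target_median, m, sdlog)
    pu <- pd + (1 - pd) * min(target_median / window_years, 1)
    frac_at_origin * pd + (1 - frac_at_origin) * pu - 0.5
  }
  lo <- log(target_median) - 4; hi <- log(target_median) + 4
  if (f(lo) < 0) return(lo)   # degenerate window: cannot push median higher
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Integer RNG seed; the generator is a pure function of
#'   (config, seed).
#' @param study_window Character or Date length-2 vector, study start and
#'   end; default 2005-04-01 to 2020-05-02.
#' @param registration List with `median` (target observed median follow-up,
#'   years), `iqr` (length-2 target interquartile range, sets the lognormal
#'   spread) and `frac_at_origin` (fraction of patients already registered
#'   at the study start).
#' @param initial_state_probs Probabilities of entering with 0/1/2/3+
#'   conditions; must sum to 1 within 1e-12.
#' @param covariates As [default_covariate_prevalences()]; every probability
#'   vector must sum to 1 within 1e-12. An optional `extra` sub-list adds
#'   bespoke categorical columns (e.g. a binary group for recovery studies).
#' @param truth Ground-truth [intensity_model()]; its covariate dummies must
#'   be derivable from the patient columns (see [covariate_design()]) or be
#'   `extra` columns.
#' @param preference List with `p_same` (probability that a newly acquired
#'   condition is drawn from the cluster of the most recent active onset;
#'   default 0.7) and optional `weights` (named base sampling weights over
#'   condition codes; default uniform).
#' @param catalogue Condition catalogue (default [default_catalogue()]).
#' @param include_prior_onsets Render conditions active at entry as events
#'   dated before follow-up start (default `TRUE`, the recording convention
#'   for pre-registration diagnoses).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, seed = 1L,
                          study_window = c("2005-04-01", "2020-05-02"),
                          registration = list(median = 4.2, iqr = c(1.8, 8.4),
                                              frac_at_origin = 0.36),
                          initial_state_probs = c(0.76, 0.15, 0.05, 0.04),
                          covariates = default_covariate_prevalences(),
                          truth = default_truth_model(),
                          preference = list(p_same = 0.7, weights = NULL),
                          catalogue = default_catalogue(),
                          include_prior_onsets = TRUE) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L ||
      is.na(n_patients) || n_patients < 1) {
    stop("n_patients must be a positive integer")
  }
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      stop(what, " probabilities must be non-negative and sum to 1 (got ",
           format(sum(p), digits = 15), ")")
    }
  }
  check_probs(initial_state_probs, "initial_state")
  for (v in c("sex", "age_group", "ethnicity", "imd_quintile")) {
    check_probs(covariates[[v]], v)
  }
  for (f in names(covariates$risk_factors)) {
    check_probs(covariates$risk_factors[[f]], paste0("risk factor ", f))
  }
  for (e in names(covariates$extra)) check_probs(covariates$extra[[e]], e)
  stopifnot(inherits(truth, "intensity_model"))
  window <- as.Date(study_window)
  if (anyNA(window) || window[2] <= window[1]) stop("invalid study window")
  if (is.null(preference$p_same)) preference$p_same <- 0.7
  stopifnot(preference$p_same >= 0, preference$p_same <= 1)
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         study_window = window, registration = registration,
         initial_state_probs = initial_state_probs,
         covariates = covariates, truth = truth, preference = preference,
         catalogue = catalogue,
         include_prior_onsets = isTRUE(include_prior_onsets)),
    class = "cohort_config"
  )
}

#' Resolve named covariate dummies from patient columns
#'
#' Builds the design columns a truth model's covariates refer to:
#' recognises the dummies produced by [covariate_design()] (age, sex,
#' ethnicity, IMD, risk-factor ever/resolved, `any_risk`) plus any raw
#' numeric 0/1 patient column (the generator's `extra` covariates).
#'
#' @param patients Patient data.frame.
#' @param dummy_names Character vector of dummy names (e.g. an
#'   [intensity_model()]'s `covariates`).
#' @return Numeric matrix, one row per patient, one named column per dummy.
#' @export
build_dummies <- function(patients, dummy_names) {
  if (!length(dummy_names)) {
    return(matrix(numeric(0), nrow(patients), 0))
  }
  one <- function(nm) {
    if (nm %in% names(patients)) {
      v <- suppressWarnings(as.numeric(as.character(patients[[nm]])))
      if (anyNA(v)) stop("column ", nm, " is not numeric 0/1")
      return(v)
    }
    if (grepl("^age_", nm)) {
      lv <- c(age_40_59 = "40-59", age_60_79 = "60-79", age_80plus = "80+")[nm]
      if (is.na(lv)) stop("unknown age dummy ", nm)
      return(as.numeric(patients$age_group == lv))
    }
    if (nm == "sex_Female") return(as.numeric(patients$sex == "Female"))
    if (grepl("^eth_", nm)) {
      return(as.numeric(patients$ethnicity == sub("^eth_", "", nm)))
    }
    if (grepl("^imd_", nm)) {
      return(as.numeric(patients$imd_quintile == sub("^imd_", "", nm)))
    }
    if (nm == "any_risk") {
      rf <- grep("^rf_", names(patients), value = TRUE)
      return(as.numeric(Reduce(`|`, lapply(rf, function(v) {
        patients[[v]] %in% c("ever", "resolved")
      }))))
    }
    m <- regmatches(nm, regexec("^(.*)_(ever|resolved)$", nm))[[1]]
    if (length(m) == 3L && paste0("rf_", m[2]) %in% names(patients)) {
      return(as.numeric(patients[[paste0("rf_", m[2])]] == m[3]))
    }
    stop("cannot derive covariate dummy '", nm, "' from patient columns")
  }
  out <- vapply(dummy_names, one, numeric(nrow(patients)))
  out <- matrix(out, nrow = nrow(patients),
                dimnames = list(NULL, dummy_names))
  out
}

#' Simulate one latent path through the five-state chain
#'
#' Gillespie simulation: from living state r the time to the next move is
#' exponential with rate \eqn{-q_{rr}(x)} and the destination is drawn
#' proportionally to the outgoing intensities. The path ends at `t_max`
#' (administrative censoring) or on absorption into Death. Uses the current
#' R RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @param model An [intensity_model()].
#' @param x Named covariate dummy vector (or `NULL`).
#' @param t_max Positive follow-up duration (years).
#' @param initial_state Starting living state, index 1..4 or label.
#' @return List with `times` (first element 0) and `states` (integer
#'   indices), consecutive entries one allowed transition apart.
#' @export
simulate_path <- function(model, x = NULL, t_max, initial_state = 1L) {
  if (is.character(initial_state)) {
    initial_state <- match(initial_state, ltc_states())
  }
  initial_state <- as.integer(initial_state)
  if (is.na(initial_state) || initial_state < 1L ||
      initial_state > N_LIVING) {
    stop("initial_state must be a living state (S0..S3plus)")
  }
  if (!is.numeric(t_max) || t_max <= 0) stop("t_max must be positive")
  Q <- make_intensity_matrix(model, x)
  tr <- ltc_transitions()
  rates <- Q[cbind(tr$from, tr$to)]
  simulate_path_rates(rates, t_max, initial_state)
}

## Fast inner loop shared with simulate_cohort: `rates` is the length-10
## vector of intensities in ltc_transitions() order.
simulate_path_rates <- function(rates, t_max, initial_state) {
  tr <- ltc_transitions()
  out_idx <- lapply(seq_len(N_LIVING), function(r) which(tr$from == r))
  t <- 0; s <- initial_state
  times <- 0; states <- initial_state
  repeat {
    idx <- out_idx[[s]]
    lam <- sum(rates[idx])
    if (lam <= 0) break
    t <- t + stats::rexp(1L, lam)
    if (t > t_max) break
    u <- stats::runif(1L) * lam
    k <- idx[findInterval(u, cumsum(rates[idx]), left.open = TRUE) + 1L]
    s <- tr$to[k]
    times <- c(times, t); states <- c(states, s)
    if (s == DEATH_STATE) break
  }
  list(times = times, states = states)
}

#' Render a latent path as dated condition events
#'
#' Each upward move becomes an onset of a condition drawn with
#' cluster-weighted preference (with probability `p_same` the new condition
#' comes from the cluster of the most recent active onset); each downward
#' move becomes the resolution of a currently active resolvable condition;
#' prior-onset conditions are supplied for a non-zero initial state. The
#' generator guarantees a resolvable condition is active before any
#' downward move: if a downward move would find none, the most recent
#' active onset is re-drawn as a resolvable condition (same cluster where
#' possible) before the move is rendered. Times are years relative to
#' follow-up start; prior onsets are negative. Uses the current R RNG
#' stream.
#'
#' @param path List from [simulate_path()].
#' @param catalogue Condition catalogue.
#' @param preference List (`p_same`, optional `weights` named over codes).
#' @param initial_count Active conditions at time 0 (default
#'   `states[1] - 1`, i.e. exactly 3 for S3plus).
#' @param prior_window Years before follow-up start over which prior onsets
#'   are spread (default 10).
#' @return data.frame with `condition`, `onset_time`, `resolve_time`
#'   (NA when unresolved), in onset order.
#' @export
render_events <- function(path, catalogue = default_catalogue(),
                          preference = list(p_same = 0.7, weights = NULL),
                          initial_count = NULL, prior_window = 10) {
  states <- path$states; times <- path$times
  if (is.null(initial_count)) initial_count <- states[1L] - 1L
  stopifnot(initial_count >= 0, count_to_state(initial_count) == states[1L])
  codes <- catalogue$code
  cluster <- stats::setNames(catalogue$cluster, codes)
  resolvable <- stats::setNames(catalogue$resolvable, codes)
  p_same <- if (is.null(preference$p_same)) 0.7 else preference$p_same
  weights <- preference$weights
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(codes)), codes)

  ev_cond <- character(); ev_on <- numeric(); ev_res <- numeric()
  active <- integer(0)       # indices into ev_* of active (unresolved) rows
  last_onset_row <- NA_integer_

  draw_condition <- function() {
    act_codes <- ev_cond[active]
    cand <- setdiff(codes, act_codes)
    if (!length(cand)) stop("no condition left to acquire")
    if (length(active) && stats::runif(1L) < p_same) {
      ref <- ev_cond[last_onset_row]
      same <- cand[cluster[cand] == cluster[ref]]
      if (length(same)) {
        return(same[sample.int(length(same), 1L)])
      }
    }
    w <- weights[cand]
    cand[sample.int(length(cand), 1L, prob = w)]
  }
  add_onset <- function(code, time) {
    ev_cond[length(ev_cond) + 1L] <<- code
    ev_on[length(ev_on) + 1L] <<- time
    ev_res[length(ev_res) + 1L] <<- NA_real_
    active <<- c(active, length(ev_cond))
    last_onset_row <<- length(ev_cond)
  }

  # prior-onset conditions for a non-zero initial state
  if (initial_count > 0L) {
    t_prior <- sort(-stats::runif(initial_count, 0, prior_window))
    for (j in seq_len(initial_count)) add_onset(draw_condition(), t_prior[j])
  }

  if (length(states) > 1L) {
    for (i in 2:length(states)) {
      s_from <- states[i - 1L]; s_to <- states[i]
      if (s_to == DEATH_STATE) break
      if (s_to == s_from + 1L) {
        add_onset(draw_condition(), times[i])
      } else if (s_to == s_from - 1L) {
        res_rows <- active[resolvable[ev_cond[active]]]
        if (!length(res_rows)) {
          # re-draw the most recent active onset as a resolvable condition
          row <- active[length(active)]
          old <- ev_cond[row]
          pool <- codes[resolvable & !(codes %in% ev_cond[active])]
          if (!length(pool)) stop("internal error: no resolvable condition available")
          same <- pool[cluster[pool] == cluster[old]]
          if (length(same)) pool <- same
          ev_cond[row] <- pool[sample.int(length(pool), 1L)]
          res_rows <- row
        }
        row <- res_rows[sample.int(length(res_rows), 1L)]
        ev_res[row] <- times[i]
        active <- setdiff(active, row)
        if (identical(last_onset_row, row)) {
          last_onset_row <- if (length(active)) active[length(active)] else NA_integer_
        }
      } else {
        stop("path contains a disallowed move")
      }
    }
  }
  data.frame(condition = ev_cond, onset_time = ev_on, resolve_time = ev_res,
             stringsAsFactors = FALSE)
}

#' Simulate a synthetic patient cohort with known transition intensities
#'
#' Draws covariates, entry times and follow-up durations, simulates each
#' patient's latent five-state path from the ground-truth intensity model
#' given their covariates, and renders the path as dated condition onset /
#' resolution events (administrative censoring at the study-window end,
#' death truncating follow-up). Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param keep_paths Attach the latent paths as attribute `"paths"` (for
#'   recovery testing; default `FALSE`).
#' @return List with `patients` (one row per patient: identifiers,
#'   follow-up dates, death flag, covariates) and `events` (patient_id,
#'   condition, onset_date, resolve_date).
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 50, seed = 42)
#' cohort <- simulate_cohort(cfg)
#' table(cohort$patients$died)
simulate_cohort <- function(config, keep_paths = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  cv <- config$covariates
  window_years <- as.numeric(diff(config$study_window)) / 365.25

  draw_cat <- function(p) names(p)[sample.int(length(p), n, TRUE, prob = p)]
  patients <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    sex = draw_cat(cv$sex),
    age_group = draw_cat(cv$age_group),
    ethnicity = draw_cat(cv$ethnicity),
    imd_quintile = draw_cat(cv$imd_quintile),
    stringsAsFactors = FALSE
  )
  for (f in names(cv$risk_factors)) {
    patients[[paste0("rf_", f)]] <- draw_cat(cv$risk_factors[[f]])
  }
  for (e in names(cv$extra)) patients[[e]] <- draw_cat(cv$extra[[e]])

  reg <- config$registration
  sdlog <- log(reg$iqr[2] / reg$iqr[1]) / (2 * stats::qnorm(0.75))
  meanlog <- calibrate_duration_meanlog(reg$median, sdlog,
                                        reg$frac_at_origin, window_years)
  at_origin <- stats::runif(n) < reg$frac_at_origin
  entry <- ifelse(at_origin, 0, stats::runif(n, 0, window_years))
  dur <- stats::rlnorm(n, meanlog, sdlog)
  dur <- pmin(dur, window_years - entry)
  dur <- pmax(dur, 2 / 365.25)   # no zero-length registrations

  init <- sample.int(4L, n, TRUE, prob = config$initial_state_probs)

  X <- build_dummies(patients, config$truth$covariates)
  if (ncol(X)) {
    pat_key <- apply(X, 1, paste, collapse = "\r")
    pat_idx <- match(pat_key, unique(pat_key))
  } else {
    pat_idx <- rep(1L, n)
  }
  tr <- ltc_transitions()
  n_pat <- max(pat_idx)
  rate_list <- vector("list", n_pat)
  for (g in seq_len(n_pat)) {
    i <- which(pat_idx == g)[1L]
    Q <- make_intensity_matrix(config$truth,
                               if (ncol(X)) X[i, ] else NULL)
    rate_list[[g]] <- Q[cbind(tr$from, tr$to)]
  }

  died <- logical(n)
  t_end <- dur
  paths <- if (keep_paths) vector("list", n)
  ev_pid <- vector("list", n)
  ev_tab <- vector("list", n)
  for (i in seq_len(n)) {
    path <- simulate_path_rates(rate_list[[pat_idx[i]]], dur[i], init[i])
    np <- length(path$states)
    if (path$states[np] == DEATH_STATE) {
      died[i] <- TRUE
      t_end[i] <- path$times[np]
    }
    if (keep_paths) paths[[i]] <- path
    ev <- render_events(path, config$catalogue, config$preference)
    if (!config$include_prior_onsets) {
      ev <- ev[ev$onset_time > 0, , drop = FALSE]
    }
    if (nrow(ev)) {
      ev_pid[[i]] <- rep(patients$patient_id[i], nrow(ev))
      ev_tab[[i]] <- ev
    }
  }

  start_date <- config$study_window[1] + round(entry * 365.25)
  end_date <- start_date + pmax(1, round(t_end * 365.25))
  patients$follow_up_start <- start_date
  patients$follow_up_end <- end_date
  patients$died <- died
  patients <- patients[, c("patient_id", "follow_up_start", "follow_up_end",
                           "died",
                           setdiff(names(patients),
                                   c("patient_id", "follow_up_start",
                                     "follow_up_end", "died")))]

  if (length(unlist(ev_pid))) {
    allev <- do.call(rbind, ev_tab)
    pid <- unlist(ev_pid)
    idx <- match(pid, patients$patient_id)
    events <- data.frame(
      patient_id = pid,
      condition = allev$condition,
      onset_date = patients$follow_up_start[idx] +
        round(allev$onset_time * 365.25),
      resolve_date = patients$follow_up_start[idx] +
        ifelse(is.na(allev$resolve_time), NA,
               round(allev$resolve_time * 365.25)),
      stringsAsFactors = FALSE
    )
    events$resolve_date <- as.Date(events$resolve_date,
                                   origin = "1970-01-01")
  } else {
    events <- data.frame(patient_id = character(), condition = character(),
                         onset_date = as.Date(character()),
                         resolve_date = as.Date(character()),
                         stringsAsFactors = FALSE)
  }
  out <- list(patients = patients, events = events)
  if (keep_paths) {
    attr(out, "paths") <- paths
    attr(out, "t_end") <- t_end      # latent follow-up years (pre-rounding)
  }
  out
}
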