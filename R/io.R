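#' Write cohort tables to CSV
#'
#' `patients.csv` has one row per patient (ISO-8601 dates, categoricals as
#' strings); `events.csv` has one row per condition event with an empty
#' `resolve_date` when unresolved.
#'
#' @param cohort List with `patients` and `events` (as from
#'   [simulate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pf <- file.path(dir, "patients.csv")
  ef <- file.path(dir, "events.csv")
  p <- cohort$patients
  p$follow_up_start <- format(as.Date(p$follow_up_start))
  p$follow_up_end <- format(as.Date(p$follow_up_end))
  utils::write.csv(p, pf, row.names = FALSE, quote = FALSE)
  e <- cohort$events
  e$onset_date <- format(as.Date(e$onset_date))
  e$resolve_date <- ifelse(is.na(e$resolve_date), "",
                           format(as.Date(e$resolve_date)))
  utils::write.csv(e, ef, row.names = FALSE, quote = FALSE)
  invisible(c(patients = pf, events = ef))
}

## Collect row-level validation problems into a structured error.
validation_error <- function(problems) {
  stop(structure(
    class = c("ltctraj_validation_error", "error", "condition"),
    list(message = paste0(
           "input validation failed (", nrow(problems), " problem(s)):\n",
           paste(utils::capture.output(print(utils::head(problems, 20))),
                 collapse = "\n")),
         call = NULL, problems = problems)
  ))
}

#' Read and validate cohort tables
#'
#' Reads `patients.csv` and `events.csv` (formats of [write_cohort()]) and
#' validates them against the catalogue; all violations are collected into
#' one structured error (class `ltctraj_validation_error` with a
#' `problems` data.frame of row / field / reason) rather than failing on
#' the first.
#'
#' Checks: required columns present; dates parseable and follow-up end
#' after start; death flag logical; event patient ids known; condition
#' codes in the catalogue; resolution dates only for resolvable conditions
#' and never before onset.
#'
#' @param patients_file,events_file CSV paths.
#' @param catalogue Condition catalogue.
#' @return List with validated `patients` (Date columns, logical `died`)
#'   and `events` (Date columns).
#' @export
read_cohort <- function(patients_file, events_file,
                        catalogue = default_catalogue()) {
  patients <- utils::read.csv(patients_file, stringsAsFactors = FALSE,
                              colClasses = "character")
  events <- utils::read.csv(events_file, stringsAsFactors = FALSE,
                            colClasses = "character")
  probs <- list()
  note <- function(table, row, field, reason) {
    probs[[length(probs) + 1L]] <<- data.frame(
      table = table, row = row, field = field, reason = reason,
      stringsAsFactors = FALSE)
  }

  need_p <- c("patient_id", "follow_up_start", "follow_up_end", "died")
  for (col in setdiff(need_p, names(patients))) {
    note("patients", NA_integer_, col, "missing required column")
  }
  need_e <- c("patient_id", "condition", "onset_date")
  for (col in setdiff(need_e, names(events))) {
    note("events", NA_integer_, col, "missing required column")
  }
  if (length(probs)) validation_error(do.call(rbind, probs))

  parse_date <- function(x, table, field, allow_empty = FALSE) {
    d <- as.Date(rep(NA_character_, length(x)))
    empty <- is.na(x) | x == ""
    well_formed <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
    conv <- suppressWarnings(as.Date(ifelse(well_formed & !empty, x, NA)))
    d[!empty & well_formed] <- conv[!empty & well_formed]
    bad <- !empty & (!well_formed | is.na(conv))  # e.g. impossible dates
    for (i in which(bad)) note(table, i, field, "unparseable date")
    if (!allow_empty) {
      for (i in which(empty)) note(table, i, field, "missing date")
    }
    d
  }
  patients$follow_up_start <- parse_date(patients$follow_up_start,
                                         "patients", "follow_up_start")
  patients$follow_up_end <- parse_date(patients$follow_up_end,
                                       "patients", "follow_up_end")
  bad_span <- which(!is.na(patients$follow_up_start) &
                      !is.na(patients$follow_up_end) &
                      patients$follow_up_end <= patients$follow_up_start)
  for (i in bad_span) {
    note("patients", i, "follow_up_end", "follow-up end not after start")
  }
  died <- tolower(patients$died) %in% c("true", "t", "1", "yes")
  bad_died <- which(!tolower(patients$died) %in%
                      c("true", "t", "1", "yes", "false", "f", "0", "no"))
  for (i in bad_died) note("patients", i, "died", "not interpretable as logical")
  patients$died <- died
  for (i in which(duplicated(patients$patient_id))) {
    note("patients", i, "patient_id", "duplicated patient id")
  }

  if (nrow(events)) {
    events$onset_date <- parse_date(events$onset_date, "events", "onset_date")
    if (!"resolve_date" %in% names(events)) events$resolve_date <- ""
    events$resolve_date <- parse_date(events$resolve_date, "events",
                                      "resolve_date", allow_empty = TRUE)
    unknown_pid <- which(!events$patient_id %in% patients$patient_id)
    for (i in unknown_pid) note("events", i, "patient_id", "unknown patient id")
    unknown_cond <- which(!events$condition %in% catalogue$code)
    for (i in unknown_cond) note("events", i, "condition", "unknown condition code")
    res_flag <- stats::setNames(catalogue$resolvable, catalogue$code)
    has_res <- !is.na(events$resolve_date)
    bad_res <- which(has_res & events$condition %in% catalogue$code &
                       !res_flag[events$condition])
    for (i in bad_res) {
      note("events", i, "resolve_date",
           "resolution recorded for a non-resolvable condition")
    }
    bad_order <- which(has_res & !is.na(events$onset_date) &
                         events$resolve_date < events$onset_date)
    for (i in bad_order) {
      note("events", i, "resolve_date", "resolution before onset")
    }
  } else {
    events$resolve_date <- as.Date(character())
    events$onset_date <- as.Date(events$onset_date)
  }

  if (length(probs)) validation_error(do.call(rbind, probs))
  list(patients = patients, events = events)
}

#' Build state histories for a whole cohort
#'
#' @param patients,events Validated cohort tables.
#' @param ... Passed to [build_state_history()].
#' @return List of [state_history()] objects, one per patient row.
#' @export
build_cohort_histories <- function(patients, events, ...) {
  pid <- as.character(patients$patient_id)
  ev <- data.frame(condition = as.character(events$condition),
                   onset_date = as.Date(events$onset_date),
                   resolve_date = as.Date(events$resolve_date),
                   stringsAsFactors = FALSE)
  ev_split <- split(ev, factor(as.character(events$patient_id), levels = pid))
  start <- as.Date(patients$follow_up_start)
  end <- as.Date(patients$follow_up_end)
  died <- as.logical(patients$died)
  lapply(seq_len(nrow(patients)), function(i) {
    build_state_history(list(patient_id = pid[i], follow_up_start = start[i],
                             follow_up_end = end[i], died = died[i]),
                        ev_split[[i]], ...)
  })
}

#' Write state histories to CSV
#'
#' One row per observation (`patient_id`, `time`, `state`), plus a final
#' row at the end of follow-up for every patient: Death for the deceased, a
#' repeat of the current state as an explicit censoring marker otherwise.
#'
#' @param histories List of [state_history()].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_histories <- function(histories, file) {
  st <- ltc_states()
  rows <- lapply(histories, function(h) {
    tt <- h$times; ss <- st[h$states]
    if (h$censored) {
      tt <- c(tt, h$t_end); ss <- c(ss, ss[length(ss)])
    }
    data.frame(patient_id = h$patient_id, time = tt, state = ss,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE,
                   quote = FALSE)
  invisible(file)
}

#' Read state histories from CSV
#'
#' Inverse of [write_histories()]: the trailing duplicate-state row marks
#' censoring time; a trailing Death row marks death.
#'
#' @param file CSV path.
#' @return List of [state_history()].
#' @export
read_histories <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  lapply(split(d, factor(d$patient_id, levels = unique(d$patient_id))),
         function(g) {
    g <- g[order(g$time), , drop = FALSE]
    n <- nrow(g)
    censored <- n > 1L && g$state[n] == g$state[n - 1L]
    obs <- if (censored) g[-n, , drop = FALSE] else g
    t_end <- g$time[n]
    if (n == 1L) t_end <- g$time[1L]   # degenerate single-row record
    state_history(g$patient_id[1L], obs$time, obs$state, t_end)
  })
}

#' Read a cohort configuration from YAML or JSON
#'
#' The file may specify any [cohort_config()] field; the truth model is
#' given as `truth: baseline:` (named intensities per year) and
#' `truth: hazard_ratios:` (transition label -> dummy -> HR). Omitted
#' fields take the package defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  to_named <- function(x) {
    if (is.list(x)) unlist(x) else x
  }
  args <- list(
    n_patients = raw$n_patients,
    seed = if (!is.null(raw$seed)) raw$seed else 1L
  )
  if (!is.null(raw$study_window)) args$study_window <- unlist(raw$study_window)
  if (!is.null(raw$registration)) {
    reg <- raw$registration
    args$registration <- list(
      median = reg$median, iqr = unlist(reg$iqr),
      frac_at_origin = reg$frac_at_origin)
  }
  if (!is.null(raw$initial_state_probs)) {
    args$initial_state_probs <- unlist(raw$initial_state_probs)
  }
  if (!is.null(raw$covariates)) {
    cv <- raw$covariates
    base <- default_covariate_prevalences()
    for (v in c("sex", "age_group", "ethnicity", "imd_quintile")) {
      if (!is.null(cv[[v]])) base[[v]] <- to_named(cv[[v]])
    }
    if (!is.null(cv$risk_factors)) {
      for (f in names(cv$risk_factors)) {
        base$risk_factors[[f]] <- to_named(cv$risk_factors[[f]])
      }
    }
    if (!is.null(cv$extra)) base$extra <- lapply(cv$extra, to_named)
    args$covariates <- base
  }
  if (!is.null(raw$truth)) {
    baseline <- to_named(raw$truth$baseline)
    coefs <- NULL
    if (!is.null(raw$truth$hazard_ratios)) {
      hrs <- raw$truth$hazard_ratios
      dummies <- unique(unlist(lapply(hrs, names)))
      coefs <- matrix(0, length(hrs), length(dummies),
                      dimnames = list(names(hrs), dummies))
      for (tr in names(hrs)) {
        v <- to_named(hrs[[tr]])
        coefs[tr, names(v)] <- log(v)
      }
    }
    args$truth <- intensity_model(baseline, coefs)
  }
  if (!is.null(raw$preference)) {
    args$preference <- list(
      p_same = if (!is.null(raw$preference$p_same)) raw$preference$p_same else 0.7,
      weights = if (!is.null(raw$preference$weights))
        to_named(raw$preference$weights) else NULL)
  }
  if (!is.null(raw$catalogue_file)) {
    args$catalogue <- read_catalogue(raw$catalogue_file)
  }
  if (!is.null(raw$include_prior_onsets)) {
    args$include_prior_onsets <- raw$include_prior_onsets
  }
  do.call(cohort_config, args)
}

## Sidecar metadata JSON for one output file.
write_sidecar <- function(file, stage, seed, inputs = character()) {
  meta <- list(
    stage = stage,
    seed = seed,
    package = "ltctraj",
    input_digests = if (length(inputs)) {
      as.list(tools::md5sum(inputs))
    } else {
      stats::setNames(list(), character())
    }
  )
  jsonlite::write_json(meta, paste0(file, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(NULL)
}

#' Run the full trajectory pipeline
#'
#' Orchestrates simulate (optional) -> build-states -> classify/summarise ->
#' MCF -> multistate fits (one per exposure) -> disease chain, writing every
#' stage's CSV outputs, a sidecar metadata JSON per output, and a run
#' manifest. The run is a pure function of (inputs, config, seed): rerunning
#' with the same seed reproduces the outputs byte for byte.
#'
#' @param out_dir Output directory.
#' @param config A [cohort_config()] to simulate from, or `NULL` when
#'   `patients_file`/`events_file` are given.
#' @param patients_file,events_file Optional existing cohort CSVs (skips the
#'   simulate stage).
#' @param exposures Exposure variables for the multistate fits (default
#'   `"sex"`).
#' @param mcf_by Stratifiers for the MCF stage.
#' @param seed Seed recorded in the manifest (defaults to `config$seed`).
#' @param suppress_below Optional low-number suppression threshold for the
#'   descriptive summary.
#' @return Invisibly, the manifest list (also written as `manifest.json`).
#' @export
run_pipeline <- function(out_dir, config = NULL,
                         patients_file = NULL, events_file = NULL,
                         exposures = "sex",
                         mcf_by = c("baseline_ltc", "age_group", "sex"),
                         seed = NULL, suppress_below = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  catalogue <- if (!is.null(config)) config$catalogue else default_catalogue()
  if (is.null(seed)) seed <- if (!is.null(config)) config$seed else NA_integer_

  if (!is.null(config)) {
    cohort <- simulate_cohort(config)
    files <- write_cohort(cohort, out_dir)
    for (f in files) write_sidecar(f, "simulate", seed)
    patients_file <- files[["patients"]]
    events_file <- files[["events"]]
    stages$simulate <- as.list(files)
  } else if (is.null(patients_file) || is.null(events_file)) {
    stop("either a config or both patients_file and events_file are required")
  }

  cohort <- read_cohort(patients_file, events_file, catalogue)
  patients <- cohort$patients; events <- cohort$events
  inputs <- c(patients_file, events_file)

  histories <- build_cohort_histories(patients, events)
  hf <- file.path(out_dir, "histories.csv")
  write_histories(histories, hf)
  write_sidecar(hf, "build-states", seed, inputs)
  stages$build_states <- list(histories = hf)

  classes <- classify_cohort(histories)
  cf <- file.path(out_dir, "classes.csv")
  utils::write.csv(classes, cf, row.names = FALSE, quote = FALSE)
  write_sidecar(cf, "classify", seed, inputs)
  summ <- summarize_cohort(patients, histories, classes$class,
                           suppress_below = suppress_below)
  sf <- file.path(out_dir, "summary.csv")
  utils::write.csv(data.frame(row = rownames(summ$rendered),
                              summ$rendered, check.names = FALSE),
                   sf, row.names = FALSE)
  write_sidecar(sf, "classify", seed, inputs)
  stages$classify <- list(classes = cf, summary = sf)

  mcf_files <- character()
  for (s in mcf_by) {
    curves <- estimate_mcf(patients, events,
                           mcf_group_vector(s, patients, events, catalogue))
    for (lv in names(curves)) {
      fn <- file.path(out_dir, paste0(
        "mcf_", s, "_", gsub("[^A-Za-z0-9]+", "_", lv), ".csv"))
      utils::write.csv(curves[[lv]]$steps, fn, row.names = FALSE,
                       quote = FALSE)
      write_sidecar(fn, "mcf", seed, inputs)
      mcf_files <- c(mcf_files, fn)
    }
  }
  stages$mcf <- list(curves = mcf_files)

  msm_out <- list()
  for (ex in exposures) {
    X <- covariate_design(patients, exposure = ex)
    fit <- msm_fit(histories, X, mode = "exact")
    hr <- hazard_ratios(fit)
    hrf <- file.path(out_dir, paste0("hazard_ratios_", ex, ".csv"))
    utils::write.csv(hr, hrf, row.names = FALSE, quote = FALSE)
    write_sidecar(hrf, "fit-msm", seed, inputs)
    rep1 <- one_year_report(fit)
    pf <- file.path(out_dir, paste0("pmatrix_1y_", ex, ".csv"))
    utils::write.csv(as.data.frame(rep1$P), pf, quote = FALSE)
    write_sidecar(pf, "fit-msm", seed, inputs)
    sjf <- file.path(out_dir, paste0("sojourn_", ex, ".csv"))
    utils::write.csv(data.frame(state = names(rep1$sojourn),
                                mean_sojourn_years = as.numeric(rep1$sojourn)),
                     sjf, row.names = FALSE, quote = FALSE)
    write_sidecar(sjf, "fit-msm", seed, inputs)
    ff <- file.path(out_dir, paste0("fit_", ex, ".json"))
    jsonlite::write_json(
      list(exposure = ex, loglik = fit$loglik, converged = fit$converged,
           mode = fit$mode,
           n_transitions = as.list(fit$n_transitions_observed),
           parameters = fit$par_table),
      ff, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    msm_out[[ex]] <- list(hazard_ratios = hrf, pmatrix = pf,
                          sojourn = sjf, fit = ff)
  }
  stages$fit_msm <- msm_out

  ch <- chain_analysis(patients, events, catalogue)
  tcf <- file.path(out_dir, "transition_counts.csv")
  utils::write.csv(as.data.frame(ch$chain$counts), tcf, quote = FALSE)
  tpf <- file.path(out_dir, "transition_probs.csv")
  utils::write.csv(as.data.frame(round(ch$chain$probs, 10)), tpf,
                   quote = FALSE)
  rpf <- file.path(out_dir, "top3_report.csv")
  utils::write.csv(ch$report, rpf, row.names = FALSE)
  for (f in c(tcf, tpf, rpf)) write_sidecar(f, "chain", seed, inputs)
  stages$chain <- list(counts = tcf, probs = tpf, report = rpf)

  manifest <- list(
    package = "ltctraj",
    package_version = as.character(utils::packageVersion("ltctraj")),
    seed = seed,
    input_digests = as.list(tools::md5sum(inputs)),
    stages = stages
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
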