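#' Construct a five-state history
#'
#' A state history is a patient's piecewise-constant path through the five
#' states over follow-up: observations are (time, state) change-points with
#' time in years since follow-up start. The first observation is at time 0;
#' consecutive states always differ and every consecutive pair is an allowed
#' transition (a one-count step or a move to Death); Death, if present, is
#' final and coincides with the end of follow-up.
#'
#' @param patient_id Identifier string.
#' @param times Numeric vector, strictly increasing, first element 0.
#' @param states Integer state indices (1 = S0 ... 5 = Death) or character
#'   labels, same length as `times`.
#' @param t_end Follow-up duration in years (>= last observation time; equal
#'   to it when the final state is Death).
#' @param start_ltc,end_ltc Optional uncapped active-condition counts at the
#'   start and end of follow-up (used by [classify_patient()]).
#' @param n_acquired,n_resolved Optional uncapped counts of onsets and
#'   resolutions during follow-up.
#' @return Object of class `state_history`.
#' @export
state_history <- function(patient_id, times, states, t_end,
                          start_ltc = NA_integer_, end_ltc = NA_integer_,
                          n_acquired = NA_integer_, n_resolved = NA_integer_) {
  if (is.character(states) || is.factor(states)) {
    states <- match(as.character(states), ltc_states())
    if (anyNA(states)) stop("unknown state label")
  }
  states <- as.integer(states)
  times <- as.numeric(times)
  if (length(times) != length(states) || !length(times)) {
    stop("times and states must be non-empty and of equal length")
  }
  if (times[1] != 0) stop("first observation must be at time 0")
  if (any(diff(times) <= 0)) stop("observation times must be strictly increasing")
  if (any(states < 1L | states > 5L)) stop("state index out of range")
  n <- length(states)
  if (n > 1L) {
    if (any(diff(states) == 0L)) stop("consecutive states must differ")
    from <- states[-n]; to <- states[-1L]
    if (any(from == DEATH_STATE)) stop("Death must be the final state")
    ok <- (to == DEATH_STATE) | (abs(to - from) == 1L & to <= N_LIVING)
    if (!all(ok)) stop("disallowed transition in state history")
  }
  died <- states[n] == DEATH_STATE
  if (died) {
    if (abs(t_end - times[n]) > 1e-12) {
      stop("for a deceased patient t_end must equal the death time")
    }
  } else if (t_end < times[n]) {
    stop("t_end must be >= the last observation time")
  }
  structure(
    list(patient_id = as.character(patient_id),
         times = times, states = states, t_end = as.numeric(t_end),
         censored = !died,
         start_ltc = as.integer(start_ltc), end_ltc = as.integer(end_ltc),
         n_acquired = as.integer(n_acquired),
         n_resolved = as.integer(n_resolved)),
    class = "state_history"
  )
}

#' @export
print.state_history <- function(x, ...) {
  st <- ltc_states()
  cat("State history for patient ", x$patient_id, ":\n", sep = "")
  cat(paste0("  t=", format(round(x$times, 4)), "  ", st[x$states]), sep = "\n")
  cat(if (x$censored) "  censored at t=" else "  died at t=",
      format(round(x$t_end, 4)), "\n", sep = "")
  invisible(x)
}

#' Build a five-state history from dated condition events
#'
#' Counts the conditions active at each instant of follow-up (active = onset
#' on or before, resolution absent or strictly after), caps the count at 3
#' ("3+"), and emits a change-point whenever the capped state changes.
#' Conditions with onset before follow-up start contribute to the starting
#' state; a condition resolved before follow-up start (as all cancer
#' resolutions were in the motivating cohort) is inactive throughout and
#' never generates a downward move. Death appends a final Death observation
#' at the end of follow-up.
#'
#' Events recorded on the same day are sequenced deterministically --
#' resolutions before onsets, then alphabetically by condition code -- and
#' separated by `epsilon` so that the single-step property (gain one, lose
#' one, or die) holds exactly regardless of input row order.
#'
#' @param patient One-row data.frame (or list) with `patient_id`,
#'   `follow_up_start`, `follow_up_end` (Date or ISO-8601 string) and `died`
#'   (logical).
#' @param events data.frame of this patient's condition events with columns
#'   `condition`, `onset_date`, `resolve_date` (NA when absent). May have
#'   zero rows.
#' @param epsilon Spacing (years) inserted between same-instant events;
#'   default one day.
#' @param late_events `"truncate"` (default) drops events dated after
#'   follow-up end with a warning; `"error"` rejects them.
#' @return A [state_history()] carrying uncapped start/end condition counts
#'   and uncapped within-follow-up acquisition/resolution counts.
#' @export
#' @examples
#' p <- data.frame(patient_id = "p1", follow_up_start = as.Date("2010-01-01"),
#'                 follow_up_end = as.Date("2015-01-01"), died = FALSE)
#' ev <- data.frame(condition = c("asthma", "ckd", "depression"),
#'                  onset_date = as.Date(c("2005-03-01", "2008-07-01", "2012-01-01")),
#'                  resolve_date = as.Date(c(NA, NA, "2013-06-01")))
#' h <- build_state_history(p, ev)   # S2 -> S3plus -> S2, censored
build_state_history <- function(patient, events,
                                epsilon = 1 / 365.25,
                                late_events = c("truncate", "error")) {
  late_events <- match.arg(late_events)
  patient <- as.list(patient)
  start <- as.Date(patient$follow_up_start)
  end <- as.Date(patient$follow_up_end)
  died <- isTRUE(as.logical(patient$died))
  if (is.na(start) || is.na(end)) stop("unparseable follow-up dates")
  if (end <= start) stop("follow_up_end must be after follow_up_start")
  t_end <- as.numeric(end - start) / 365.25

  if (is.null(events) || nrow(events) == 0L) {
    ev <- data.frame(condition = character(), onset = numeric(),
                     resolve = numeric())
  } else {
    onset <- as.Date(events$onset_date)
    resolve <- as.Date(events$resolve_date)
    if (anyNA(onset)) stop("unparseable onset date")
    if (any(!is.na(resolve) & resolve < onset)) {
      stop("resolution date precedes onset date")
    }
    ev <- data.frame(condition = as.character(events$condition),
                     onset = as.numeric(onset - start) / 365.25,
                     resolve = as.numeric(resolve - start) / 365.25)
  }

  # a same-day onset+resolution pair must sequence onset first
  same <- !is.na(ev$resolve) & ev$resolve == ev$onset
  ev$resolve[same] <- ev$onset[same] + epsilon / 2

  late_on <- ev$onset > t_end
  late_res <- !is.na(ev$resolve) & ev$resolve > t_end
  if (any(late_on) || any(late_res)) {
    if (late_events == "error") stop("event dated after follow-up end")
    if (any(late_on)) {
      warning(sum(late_on), " onset(s) after follow-up end truncated")
      ev <- ev[!late_on, , drop = FALSE]
      late_res <- !is.na(ev$resolve) & ev$resolve > t_end
    }
    if (any(late_res)) {
      warning(sum(late_res), " resolution(s) after follow-up end truncated")
      ev$resolve[late_res] <- NA_real_  # unresolved within window
    }
  }

  # active at start: onset <= 0 < resolution (or unresolved)
  base_active <- ev$onset <= 0 & (is.na(ev$resolve) | ev$resolve > 0)
  start_ltc <- sum(base_active)

  # change events strictly inside (0, t_end]
  on_in <- ev$onset > 0
  res_in <- !is.na(ev$resolve) & ev$resolve > 0
  c_time <- c(ev$onset[on_in], ev$resolve[res_in])
  c_delta <- c(rep(1L, sum(on_in)), rep(-1L, sum(res_in)))
  c_cond <- c(ev$condition[on_in], ev$condition[res_in])
  # deterministic same-day ordering: time, resolutions first, then code
  ord <- order(c_time, c_delta, c_cond)
  c_time <- c_time[ord]; c_delta <- c_delta[ord]
  n_chg <- length(c_time)
  if (n_chg > 1L) {
    for (i in 2:n_chg) {
      if (c_time[i] <= c_time[i - 1L]) c_time[i] <- c_time[i - 1L] + epsilon
    }
  }
  # keep event times inside the window (death/censoring stays last)
  if (n_chg && any(c_time >= t_end)) {
    k <- which(c_time >= t_end)
    c_time[k] <- t_end - epsilon * (rev(seq_along(k)) - 0.5)
    ord <- order(c_time)
    c_time <- c_time[ord]; c_delta <- c_delta[ord]
  }

  count <- start_ltc
  times <- 0
  states <- count_to_state(count)
  if (n_chg) {
    run_count <- count + cumsum(c_delta)
    if (any(run_count < 0L)) {
      stop("resolution without an active condition for patient ",
           patient$patient_id)
    }
    st_seq <- count_to_state(run_count)
    prev <- c(states, st_seq[-n_chg])
    changed <- st_seq != prev
    times <- c(0, c_time[changed])
    states <- c(states, st_seq[changed])
    count <- run_count[n_chg]
  }
  if (died) {
    if (times[length(times)] >= t_end) stop("event at or after death time")
    times <- c(times, t_end)
    states <- c(states, DEATH_STATE)
  }
  state_history(patient$patient_id, times, states, t_end,
                start_ltc = start_ltc, end_ltc = count,
                n_acquired = sum(c_delta > 0),
                n_resolved = sum(c_delta < 0))
}

#' Classify a patient's trajectory as Stable, Progressed or Remitted
#'
#' End-of-follow-up classification on uncapped condition counts: anyone who
#' died, or ended with more conditions than they started with, Progressed;
#' fewer conditions, Remitted; the same number, Stable. Uncapped counts mean
#' a patient moving from 4 to 3 active conditions is Remitted even though
#' both map to the 3+ state.
#'
#' @param start_count,end_count Non-negative integer condition counts at the
#'   start and end of follow-up (vectorised).
#' @param died Logical (vectorised).
#' @return Character vector with levels `"Stable"`, `"Progressed"`,
#'   `"Remitted"`.
#' @export
#' @examples
#' classify_patient(2, 2, FALSE)  # "Stable"
#' classify_patient(0, 0, TRUE)   # "Progressed" (death counts as progression)
#' classify_patient(3, 1, FALSE)  # "Remitted"
classify_patient <- function(start_count, end_count, died) {
  n <- max(length(start_count), length(end_count), length(died))
  start_count <- rep_len(as.integer(start_count), n)
  end_count <- rep_len(as.integer(end_count), n)
  died <- rep_len(as.logical(died), n)
  if (anyNA(start_count) || anyNA(end_count) ||
      any(start_count < 0L) || any(end_count < 0L)) {
    stop("condition counts must be non-negative integers")
  }
  ifelse(died | end_count > start_count, "Progressed",
         ifelse(end_count < start_count, "Remitted", "Stable"))
}

#' Classify every history in a cohort
#'
#' @param histories List of [state_history()] objects (built with uncapped
#'   counts, as [build_state_history()] does).
#' @return data.frame with `patient_id`, `start_ltc`, `end_ltc`, `died`,
#'   `class`.
#' @export
classify_cohort <- function(histories) {
  data.frame(
    patient_id = vapply(histories, `[[`, "", "patient_id"),
    start_ltc = vapply(histories, `[[`, 0L, "start_ltc"),
    end_ltc = vapply(histories, `[[`, 0L, "end_ltc"),
    died = !vapply(histories, `[[`, TRUE, "censored"),
    class = vapply(histories, function(h) {
      classify_patient(h$start_ltc, h$end_ltc, !h$censored)
    }, ""),
    stringsAsFactors = FALSE
  )
}
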