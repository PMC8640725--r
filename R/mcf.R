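#' Mean cumulative function of condition acquisition
#'
#' Nonparametric recurrent-event (Nelson-Aalen-type) estimator of the
#' expected cumulative number of conditions acquired per subject by time t
#' since follow-up start. At each distinct event time u the curve increments
#' by (number of onsets at u) / (number of subjects still under follow-up at
#' u); subjects leave the risk set at the end of follow-up or death (death
#' is censoring, not an event), and resolutions never decrement the curve.
#' Onsets dated before follow-up start are baseline conditions, not
#' accumulation, and are excluded. Ties between an event and a risk-set
#' exit at the same time process the event first (the subject with
#' follow-up ending at u is still at risk at u).
#'
#' @param patients data.frame with `patient_id`, `follow_up_start`,
#'   `follow_up_end`.
#' @param events data.frame with `patient_id`, `condition`, `onset_date`.
#' @param group Optional vector (length `nrow(patients)`) of group labels;
#'   one curve per level. `NULL` gives a single curve labelled `"all"`.
#' @return List of `mcf_curve` objects (one per non-empty group), each a
#'   list with `group_label`, `steps` (data.frame `time`, `mcf`, `n_risk`),
#'   `n_subjects`. Empty groups are dropped with a warning.
#' @export
#' @examples
#' p <- data.frame(patient_id = c("a", "b", "c"),
#'                 follow_up_start = as.Date("2010-01-01"),
#'                 follow_up_end = as.Date("2020-01-01"))
#' ev <- data.frame(patient_id = c("a", "b"), condition = c("asthma", "ckd"),
#'                  onset_date = as.Date(c("2011-01-01", "2012-01-01")))
#' cv <- estimate_mcf(p, ev)[[1]]
#' mcf_at(cv, 2.01)  # 1/3 + 1/3
estimate_mcf <- function(patients, events, group = NULL) {
  if (is.null(group)) group <- rep("all", nrow(patients))
  if (length(group) != nrow(patients)) {
    stop("group must have one entry per patient")
  }
  start <- as.Date(patients$follow_up_start)
  end <- as.Date(patients$follow_up_end)
  dur <- as.numeric(end - start) / 365.25

  idx <- match(as.character(events$patient_id),
               as.character(patients$patient_id))
  if (anyNA(idx)) stop("event for unknown patient_id")
  etime <- as.numeric(as.Date(events$onset_date) - start[idx]) / 365.25
  late <- etime > dur[idx]
  if (any(late)) {
    warning(sum(late), " onset(s) outside the follow-up window excluded")
  }
  keep <- etime > 0 & !late

  out <- list()
  for (g in unique(as.character(group))) {
    in_g <- as.character(group) == g
    if (!any(in_g)) next
    d <- dur[in_g]
    ut <- sort(unique(etime[keep & in_g[idx]]))
    if (length(ut)) {
      n_event <- as.numeric(table(factor(etime[keep & in_g[idx]],
                                         levels = ut)))
      # risk set: still under follow-up at u (exit ties count as at risk)
      n_risk <- vapply(ut, function(u) sum(d >= u), 0)
      steps <- data.frame(time = ut,
                          mcf = cumsum(n_event / n_risk),
                          n_risk = n_risk)
    } else {
      steps <- data.frame(time = numeric(), mcf = numeric(),
                          n_risk = numeric())
    }
    out[[g]] <- structure(
      list(group_label = g, steps = steps, n_subjects = sum(in_g)),
      class = "mcf_curve"
    )
  }
  if (!length(out)) warning("no non-empty groups; no curves estimated")
  out
}

#' Evaluate an MCF curve at given times
#'
#' Right-continuous step-function evaluation: at a jump time the post-jump
#' value is returned; before the first jump the value is 0.
#'
#' @param curve An `mcf_curve` from [estimate_mcf()].
#' @param t Numeric vector of non-negative times (years).
#' @return Numeric vector of MCF values.
#' @export
mcf_at <- function(curve, t) {
  stopifnot(inherits(curve, "mcf_curve"))
  if (any(t < 0)) stop("t must be non-negative")
  if (!nrow(curve$steps)) return(rep(0, length(t)))
  i <- findInterval(t, curve$steps$time)
  c(0, curve$steps$mcf)[i + 1L]
}

#' @export
print.mcf_curve <- function(x, ...) {
  cat("MCF curve '", x$group_label, "': ", x$n_subjects, " subjects, ",
      nrow(x$steps), " steps", sep = "")
  if (nrow(x$steps)) {
    cat(", final MCF ", round(x$steps$mcf[nrow(x$steps)], 3), " at t=",
        round(x$steps$time[nrow(x$steps)], 2), "y", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
plot.mcf_curve <- function(x, add = FALSE, xlab = "Years since start of follow-up",
                           ylab = "Mean cumulative number of LTCs", ...) {
  s <- x$steps
  if (!add) {
    plot(NA, xlim = c(0, max(s$time, 1)), ylim = c(0, max(s$mcf, 0.1)),
         xlab = xlab, ylab = ylab, ...)
  }
  if (nrow(s)) {
    graphics::lines(stats::stepfun(s$time, c(0, s$mcf)), do.points = FALSE, ...)
  }
  invisible(x)
}

## Grouping vectors for the supported stratifiers.
mcf_group_vector <- function(stratifier, patients, events, catalogue) {
  start <- as.Date(patients$follow_up_start)
  idx <- match(as.character(events$patient_id),
               as.character(patients$patient_id))
  if (stratifier == "baseline_ltc") {
    onset <- as.Date(events$onset_date)
    resolve <- as.Date(events$resolve_date)
    base <- onset <= start[idx] &
      (is.na(resolve) | resolve > start[idx])
    cnt <- integer(nrow(patients))
    if (any(base)) {
      tb <- table(factor(events$patient_id[base],
                         levels = patients$patient_id))
      cnt <- as.integer(tb)
    }
    return(c("0", "1", "2", "3+")[count_to_state(cnt)])
  }
  if (stratifier == "first_condition_cluster") {
    ord <- order(idx, as.Date(events$onset_date), events$condition)
    first <- !duplicated(idx[ord])
    lab <- rep(NA_character_, nrow(patients))
    lab[idx[ord][first]] <-
      catalogue$cluster[match(events$condition[ord][first], catalogue$code)]
    lab[is.na(lab)] <- "none"
    return(lab)
  }
  col <- if (stratifier %in% names(patients)) stratifier
         else paste0("rf_", stratifier)
  if (!col %in% names(patients)) stop("unknown stratifier: ", stratifier)
  as.character(patients[[col]])
}

#' Panel of MCF curves by subgroup
#'
#' One set of curves per stratifier, emulating a multi-panel accumulation
#' figure: supported stratifiers are `"baseline_ltc"` (0/1/2/3+ conditions
#' at entry), `"age_group"`, `"sex"`, `"ethnicity"`, `"imd_quintile"`, any
#' risk-factor name (never/ever/resolved levels) and
#' `"first_condition_cluster"` (cluster A-F of the earliest recorded
#' onset).
#'
#' @param patients,events As [estimate_mcf()].
#' @param stratifiers Character vector of stratifier names.
#' @param catalogue Condition catalogue (for the cluster stratifier).
#' @return Named list: one entry per stratifier, each a list of
#'   `mcf_curve` objects keyed by level.
#' @export
mcf_panel <- function(patients, events,
                      stratifiers = c("baseline_ltc", "age_group", "sex"),
                      catalogue = default_catalogue()) {
  out <- lapply(stratifiers, function(s) {
    estimate_mcf(patients, events,
                 mcf_group_vector(s, patients, events, catalogue))
  })
  names(out) <- stratifiers
  out
}
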