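#' Descriptive cohort summary stratified by trajectory class
#'
#' Produces the standard baseline table for a trajectory cohort: patient
#' counts per class (Stable / Progressed / Remitted), per-category counts
#' and row percentages for each covariate, median (IQR) follow-up years per
#' class, and cross-tabulations of the number of conditions acquired and
#' resolved during follow-up (0 / 1 / 2+) by class. The patient data model
#' carries age as a category (age group at entry), so age is summarised as
#' a categorical covariate.
#'
#' Small-cell suppression: when `suppress_below` is set (e.g. 10), any
#' rendered cell count less than or equal to the threshold is shown as
#' `"<=10"`; the numeric tables in the returned object are left untouched so
#' that downstream computation is unaffected.
#'
#' @param patients data.frame of patient records (`patient_id`, covariate
#'   columns, `follow_up_start`, `follow_up_end`, `died`).
#' @param histories List of [state_history()] objects aligned with
#'   `patients` (same order or matchable by `patient_id`).
#' @param classes Optional character vector / data.frame from
#'   [classify_cohort()]; computed from `histories` when omitted.
#' @param covariates Covariate columns to tabulate; defaults to every
#'   categorical covariate present.
#' @param suppress_below Optional integer threshold for low-number
#'   suppression in the rendered table (default off).
#' @return Object of class `cohort_summary`: list with `n`, `class_counts`,
#'   `followup` (median/IQR by class), `covariate_tables` (named list of
#'   count matrices with row-percentage attributes), `acquired`, `resolved`
#'   (count matrices by class), and `rendered` (character matrix honouring
#'   suppression).
#' @export
summarize_cohort <- function(patients, histories, classes = NULL,
                             covariates = NULL, suppress_below = NULL) {
  if (length(histories) != nrow(patients)) {
    stop("patients and histories must have the same length")
  }
  ids <- vapply(histories, `[[`, "", "patient_id")
  if (!identical(ids, as.character(patients$patient_id))) {
    m <- match(as.character(patients$patient_id), ids)
    if (anyNA(m)) stop("histories do not match patients")
    histories <- histories[m]
  }
  if (is.null(classes)) classes <- classify_cohort(histories)$class
  if (is.data.frame(classes)) classes <- classes$class
  if (length(classes) != nrow(patients)) {
    stop("classes must align with patients")
  }
  lv <- c("Stable", "Progressed", "Remitted")
  cls <- factor(classes, levels = lv)

  if (is.null(covariates)) {
    covariates <- intersect(
      c("sex", "age_group", "ethnicity", "imd_quintile",
        grep("^rf_", names(patients), value = TRUE)),
      names(patients)
    )
  }

  fup <- as.numeric(as.Date(patients$follow_up_end) -
                      as.Date(patients$follow_up_start)) / 365.25
  fu_stats <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    c(median = q[2], q1 = q[1], q3 = q[3])
  }
  followup <- rbind(
    Overall = fu_stats(fup),
    t(vapply(lv, function(l) {
      if (!any(cls == l, na.rm = TRUE)) c(median = NA_real_, q1 = NA_real_, q3 = NA_real_)
      else fu_stats(fup[cls == l])
    }, c(median = 0, q1 = 0, q3 = 0)))
  )

  cov_tab <- lapply(covariates, function(v) {
    tab <- table(factor(patients[[v]]), cls)
    pct <- prop.table(tab + 0, 1) * 100
    pct[is.nan(pct)] <- NA_real_
    attr(tab, "row_pct") <- pct
    tab
  })
  names(cov_tab) <- covariates

  band <- function(n) cut(n, c(-0.5, 0.5, 1.5, Inf), labels = c("0", "1", "2+"))
  acq <- table(band(vapply(histories, `[[`, 0L, "n_acquired")), cls)
  res <- table(band(vapply(histories, `[[`, 0L, "n_resolved")), cls)

  render_cell <- function(x) {
    if (!is.null(suppress_below) && x <= suppress_below && x > 0) {
      paste0("<=", suppress_below)
    } else {
      format(x)
    }
  }
  rendered <- rbind(
    `Patients (n)` = vapply(c(sum(table(cls)), table(cls)), render_cell, ""),
    do.call(rbind, lapply(names(cov_tab), function(v) {
      tab <- cov_tab[[v]]
      out <- t(apply(cbind(rowSums(tab), tab), 1, function(r) {
        vapply(r, render_cell, "")
      }))
      rownames(out) <- paste0(v, ": ", rownames(tab))
      out
    }))
  )
  colnames(rendered) <- c("Overall", lv)

  structure(
    list(n = nrow(patients),
         class_counts = table(cls),
         followup = followup,
         covariate_tables = cov_tab,
         acquired = acq, resolved = res,
         suppress_below = suppress_below,
         rendered = rendered),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (", x$n, " patients)\n", sep = "")
  cat("Trajectory classes:\n")
  print(x$class_counts)
  cat("\nFollow-up years, median [IQR]:\n")
  fu <- x$followup
  for (i in seq_len(nrow(fu))) {
    cat(sprintf("  %-10s %.1f [%.1f, %.1f]\n", rownames(fu)[i],
                fu[i, "median"], fu[i, "q1"], fu[i, "q3"]))
  }
  cat("\nConditions acquired during follow-up (by class):\n")
  print(x$acquired)
  cat("\nConditions resolved during follow-up (by class):\n")
  print(x$resolved)
  cat("\nCovariates:\n")
  print(x$rendered, quote = FALSE)
  invisible(x)
}
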