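#' Build per-patient condition-acquisition sequences
#'
#' Orders each patient's first onsets by date (same-day ties broken
#' alphabetically by condition code, so the result is invariant to input
#' row order), ignores resolutions, keeps only the first onset of a
#' condition that was resolved and re-acquired, and appends a `"Death"`
#' token for deceased patients.
#'
#' @param patients data.frame with `patient_id`, `follow_up_start`,
#'   `follow_up_end`, `died`.
#' @param events data.frame with `patient_id`, `condition`, `onset_date`.
#' @param include_prior Include onsets dated before follow-up start
#'   (default `TRUE`; their dates are recorded and they order naturally).
#' @return Named list (by patient id) of character vectors; patients with
#'   no acquisitions and no death yield empty sequences.
#' @export
build_sequences <- function(patients, events, include_prior = TRUE) {
  idx <- match(as.character(events$patient_id),
               as.character(patients$patient_id))
  if (anyNA(idx)) stop("event for unknown patient_id")
  onset <- as.Date(events$onset_date)
  keep <- rep(TRUE, nrow(events))
  if (!include_prior) {
    keep <- onset > as.Date(patients$follow_up_start)[idx]
  }
  ord <- order(idx, onset, as.character(events$condition))
  ord <- ord[keep[ord]]
  pid <- idx[ord]
  cond <- as.character(events$condition)[ord]
  # first onsets only: a condition cannot succeed itself
  first <- !duplicated(paste0(pid, "\r", cond))
  pid <- pid[first]; cond <- cond[first]
  seqs <- split(cond, factor(pid, levels = seq_len(nrow(patients))))
  names(seqs) <- as.character(patients$patient_id)
  died <- as.logical(patients$died)
  for (i in which(died)) seqs[[i]] <- c(seqs[[i]], "Death")
  lapply(seqs, as.character)
}

#' Estimate the first-order Markov chain over disease sequences
#'
#' Pools adjacent pairs over all patients: `counts[A, B]` is the number of
#' times condition B was acquired immediately after condition A ("one time
#' step" = the next acquisition event); `probs` row-normalises the counts
#' (the maximum-likelihood estimator of a first-order chain). Rows with no
#' observed successor are all-zero and flagged. Death is an absorbing
#' consequent-only token; the diagonal is structurally zero because
#' sequences contain first onsets only.
#'
#' @param sequences List from [build_sequences()].
#' @param catalogue Condition catalogue fixing the label set.
#' @return Object of class `sequence_chain`: `labels` (32 conditions +
#'   `"Death"`), `counts`, `probs` (row-stochastic or zero), `empty_rows`
#'   (logical).
#' @export
#' @examples
#' seqs <- list(p1 = c("a", "b"), p2 = c("a", "c"), p3 = c("a", "b"))
#' cat3 <- data.frame(code = c("a", "b", "c"), name = c("A", "B", "C"),
#'                    resolvable = FALSE, cluster = "A")
#' estimate_chain(seqs, cat3)$probs["a", "b"]  # 2/3
estimate_chain <- function(sequences, catalogue = default_catalogue()) {
  labels <- c(catalogue$code, "Death")
  m <- length(labels)
  counts <- matrix(0, m, m, dimnames = list(labels, labels))
  for (s in sequences) {
    n <- length(s)
    if (n < 2L) next
    bad <- setdiff(s, labels)
    if (length(bad)) stop("unknown condition code in sequence: ",
                          paste(bad, collapse = ", "))
    from <- s[-n]; to <- s[-1L]
    if (any(from == "Death")) stop("no item may follow Death")
    for (j in seq_along(from)) {
      counts[from[j], to[j]] <- counts[from[j], to[j]] + 1
    }
  }
  if (any(diag(counts) != 0)) stop("self-succession found (diagonal must be zero)")
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs > 0, rs, 1)
  structure(
    list(labels = labels, counts = counts, probs = probs,
         empty_rows = rs == 0),
    class = "sequence_chain"
  )
}

#' @export
print.sequence_chain <- function(x, ...) {
  cat("First-order Markov chain over ", length(x$labels) - 1L,
      " conditions + Death: ", sum(x$counts), " observed successions, ",
      sum(!x$empty_rows), " non-empty rows\n", sep = "")
  invisible(x)
}

## Top-k entries of one probability vector, ties at the k-th value kept,
## zeros dropped.
top_k_probs <- function(p, k) {
  p <- p[p > 0]
  if (!length(p)) return(data.frame(condition = character(),
                                    prob = numeric()))
  p <- sort(p, decreasing = TRUE)
  if (length(p) > k) {
    cut <- p[k]
    p <- p[p >= cut]
  }
  data.frame(condition = names(p), prob = as.numeric(p),
             stringsAsFactors = FALSE)
}

#' Top-k antecedents and consequents per condition
#'
#' For each condition, the k highest-probability consequents (its row of
#' the transition matrix: what tends to be acquired next) and antecedents
#' (its column: what it tends to follow). Lists exceed k when
#' probabilities tie at the k-th value and are shorter when probabilities
#' are zero; Death appears only as a consequent.
#'
#' @param chain A `sequence_chain` from [estimate_chain()].
#' @param k Number of entries to select (default 3; must be >= 1).
#' @return Object of class `topk_selection`: named list per label with
#'   `consequents` and `antecedents` data.frames (`condition`, `prob`).
#' @export
select_top <- function(chain, k = 3) {
  stopifnot(inherits(chain, "sequence_chain"))
  if (!is.numeric(k) || k < 1) stop("k must be >= 1")
  out <- lapply(chain$labels, function(lab) {
    list(consequents = top_k_probs(chain$probs[lab, ], k),
         antecedents = top_k_probs(chain$probs[, lab], k))
  })
  names(out) <- chain$labels
  structure(out, class = "topk_selection", k = k)
}

#' Prevalence of each condition in a cohort
#'
#' Fraction of patients with any recorded onset of the condition.
#'
#' @param patients,events Cohort tables.
#' @param catalogue Condition catalogue.
#' @return Named numeric vector over condition codes.
#' @export
condition_prevalence <- function(patients, events,
                                 catalogue = default_catalogue()) {
  u <- unique(events[, c("patient_id", "condition")])
  tab <- table(factor(u$condition, levels = catalogue$code))
  stats::setNames(as.numeric(tab) / nrow(patients), catalogue$code)
}

#' Tabular report of top-k disease successions
#'
#' One row per condition (and Death): cluster label, cohort prevalence, and
#' the top-k antecedent and consequent conditions with probabilities,
#' rendered as `code (prob)` strings.
#'
#' @param selection A `topk_selection` from [select_top()].
#' @param catalogue Condition catalogue.
#' @param prevalence Optional named prevalence vector from
#'   [condition_prevalence()].
#' @return data.frame with `condition`, `cluster`, `prevalence`,
#'   `antecedents`, `consequents`.
#' @export
chain_report <- function(selection, catalogue = default_catalogue(),
                         prevalence = NULL) {
  stopifnot(inherits(selection, "topk_selection"))
  fmt <- function(df) {
    if (!nrow(df)) return("")
    paste(sprintf("%s (%.3f)", df$condition, df$prob), collapse = "; ")
  }
  labs <- names(selection)
  bad <- setdiff(setdiff(labs, "Death"), catalogue$code)
  if (length(bad)) stop("unknown condition code: ", paste(bad, collapse = ", "))
  data.frame(
    condition = labs,
    cluster = c(catalogue$cluster, "")[match(labs, c(catalogue$code, "Death"))],
    prevalence = if (is.null(prevalence)) NA_real_
                 else as.numeric(c(prevalence, NA)[match(labs, c(names(prevalence), "Death"))]),
    antecedents = vapply(selection, function(s) fmt(s$antecedents), ""),
    consequents = vapply(selection, function(s) fmt(s$consequents), ""),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' End-to-end disease-chain analysis, optionally stratified
#'
#' Convenience wrapper: build sequences, estimate the chain, select top-k,
#' and produce the report -- overall or per level of a stratifying patient
#' column (e.g. sex, ethnicity, imd_quintile).
#'
#' @param patients,events Cohort tables.
#' @param catalogue Condition catalogue.
#' @param by Optional patient column to stratify by.
#' @param k Top-k size (default 3).
#' @param include_prior Passed to [build_sequences()].
#' @return For `by = NULL`, a list with `chain`, `selection`, `report`;
#'   otherwise a named list of such lists per stratum level.
#' @export
chain_analysis <- function(patients, events, catalogue = default_catalogue(),
                           by = NULL, k = 3, include_prior = TRUE) {
  run1 <- function(p, e) {
    seqs <- build_sequences(p, e, include_prior = include_prior)
    ch <- estimate_chain(seqs, catalogue)
    sel <- select_top(ch, k)
    list(chain = ch, selection = sel,
         report = chain_report(sel, catalogue,
                               condition_prevalence(p, e, catalogue)))
  }
  if (is.null(by)) return(run1(patients, events))
  if (!by %in% names(patients)) stop("unknown stratifier: ", by)
  lv <- unique(as.character(patients[[by]]))
  out <- lapply(lv, function(l) {
    p <- patients[patients[[by]] == l, , drop = FALSE]
    e <- events[as.character(events$patient_id) %in% p$patient_id, ,
                drop = FALSE]
    run1(p, e)
  })
  names(out) <- lv
  out
}
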