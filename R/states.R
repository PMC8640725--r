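#' Five-state multimorbidity state space
#'
#' The analysis collapses a patient's number of active long-term conditions
#' (LTCs) into four living states -- 0, 1, 2 and 3-or-more active conditions
#' -- plus an absorbing death state. Allowed instantaneous moves are a single
#' step up (acquire one condition), a single step down (resolve one
#' condition), or death from any living state.
#'
#' @return Character vector of the five state labels, in order.
#' @export
ltc_states <- function() c("S0", "S1", "S2", "S3plus", "Death")

#' Allowed transitions of the five-state model
#'
#' Returns the ten allowed transitions: three progressing (S0->S1, S1->S2,
#' S2->S3plus), three resolving/remitting (S1->S0, S2->S1, S3plus->S2) and
#' four death transitions (each living state to Death). Death is absorbing.
#'
#' @return A data.frame with columns `from`, `to` (integer state indices,
#'   1 = S0 ... 5 = Death), `label` (e.g. `"S0->S1"`) and `type`
#'   (`"progressing"`, `"resolving"` or `"death"`).
#' @export
ltc_transitions <- function() {
  tr <- data.frame(
    from = c(1L, 2L, 3L, 2L, 3L, 4L, 1L, 2L, 3L, 4L),
    to   = c(2L, 3L, 4L, 1L, 2L, 3L, 5L, 5L, 5L, 5L),
    type = rep(c("progressing", "resolving", "death"), c(3L, 3L, 4L)),
    stringsAsFactors = FALSE
  )
  st <- ltc_states()
  tr$label <- paste0(st[tr$from], "->", st[tr$to])
  tr[, c("from", "to", "label", "type")]
}

#' Map a number of active conditions to the capped state index
#'
#' @param n non-negative integer count(s) of active conditions.
#' @return Integer state index in 1..4 (`min(n, 3) + 1`).
#' @keywords internal
count_to_state <- function(n) {
  stopifnot(all(n >= 0L))
  pmin(as.integer(n), 3L) + 1L
}

N_LIVING <- 4L
DEATH_STATE <- 5L
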