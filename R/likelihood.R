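#' Exact-times log-likelihood of one state history
#'
#' Log-likelihood of a fully observed continuous-time path: each sojourn of
#' length d in living state r contributes its survival term
#' \eqn{q_{rr} d = -(\mathrm{total\ exit\ rate}) \cdot d}; each observed
#' transition r -> s contributes \eqn{\log q_{rs}} (death transitions
#' included); a censored final sojourn contributes only its survival term.
#' An observed transition whose intensity is zero yields `-Inf`.
#'
#' @param history A [state_history()].
#' @param Q Valid 5x5 intensity matrix.
#' @return Log-likelihood (scalar; `-Inf` when the path is impossible
#'   under Q).
#' @export
#' @examples
#' h <- state_history("p", 0, 1, t_end = 2)          # censored 2y in S0
#' Q <- make_intensity_matrix(intensity_model(c("S0->S1" = 0.3)))
#' exact_path_loglik(h, Q)                            # -0.3 * 2
exact_path_loglik <- function(history, Q) {
  stopifnot(inherits(history, "state_history"))
  validate_rate_matrix(Q)
  ss <- history_suffstats(history)
  tr <- ltc_transitions()
  rates <- Q[cbind(tr$from, tr$to)]
  exit <- -diag(Q)[seq_len(N_LIVING)]
  ll <- -sum(exit * ss$time_in_state)
  obs <- ss$counts > 0
  if (any(obs & rates == 0)) return(-Inf)
  ll + sum(ss$counts[obs] * log(rates[obs]))
}

#' Sufficient statistics of a state history
#'
#' Under the exact-times likelihood with time-constant covariates the data
#' enter only through (a) the total time spent in each living state and
#' (b) the number of observed jumps of each allowed transition.
#'
#' @param history A [state_history()].
#' @return List with `time_in_state` (length 4) and `counts` (length 10,
#'   named by transition label).
#' @keywords internal
history_suffstats <- function(history) {
  tms <- c(history$times, if (history$censored) history$t_end)
  st <- history$states
  n <- length(st)
  tis <- numeric(N_LIVING)
  durs <- diff(tms)
  for (j in seq_along(durs)) {
    tis[st[j]] <- tis[st[j]] + durs[j]
  }
  tr <- ltc_transitions()
  counts <- stats::setNames(numeric(nrow(tr)), tr$label)
  if (n > 1L) {
    key <- paste0(st[-n], ".", st[-1L])
    tk <- paste0(tr$from, ".", tr$to)
    tab <- table(key)
    counts[match(names(tab), tk)] <- as.numeric(tab)
  }
  list(time_in_state = tis, counts = counts)
}

#' Panel-data log-likelihood of sparsely observed states
#'
#' Likelihood of observing state `s[i+1]` at time `t[i+1]` given state
#' `s[i]` at `t[i]` under a time-homogeneous chain:
#' \eqn{\sum_i \log [\exp((t_{i+1}-t_i) Q)]_{s_i, s_{i+1}}}. When
#' `death_exact = TRUE` (the usual convention for dated deaths) a final
#' transition into Death at time t is treated as exactly timed: its
#' contribution is \eqn{\log \sum_r P_{s,r}(\Delta t)\, q_{r,\mathrm{Death}}}
#' summed over living states r.
#'
#' @param times Increasing numeric observation times (years).
#' @param states Integer state indices (1..5) or labels at those times.
#' @param Q Valid 5x5 intensity matrix.
#' @param death_exact Treat death times as exact (default `TRUE`).
#' @param .cache Internal: environment memoising P(dt) across calls with a
#'   shared Q.
#' @return Log-likelihood (scalar; `-Inf` for an impossible observation
#'   pair).
#' @export
panel_loglik <- function(times, states, Q, death_exact = TRUE,
                         .cache = NULL) {
  validate_rate_matrix(Q)
  if (is.character(states) || is.factor(states)) {
    states <- match(as.character(states), ltc_states())
  }
  states <- as.integer(states)
  if (length(times) != length(states)) stop("times/states length mismatch")
  if (length(times) < 2L) return(0)
  dt <- diff(times)
  if (any(dt < 0)) stop("observation times must be non-decreasing")
  if (any(dt == 0 & diff(states) != 0L)) {
    stop("two different states cannot be observed at the same time")
  }
  ll <- 0
  cache <- if (is.null(.cache)) new.env(parent = emptyenv()) else .cache
  for (i in seq_along(dt)) {
    if (dt[i] == 0) next
    key <- format(dt[i], digits = 17)
    P <- get0(key, envir = cache)
    if (is.null(P)) {
      P <- expm_dense(Q * dt[i])
      P[P < 0] <- 0
      assign(key, P, envir = cache)
    }
    from <- states[i]; to <- states[i + 1L]
    p <- if (to == DEATH_STATE && death_exact) {
      sum(P[from, seq_len(N_LIVING)] * Q[seq_len(N_LIVING), DEATH_STATE])
    } else {
      P[from, to]
    }
    if (p <= 0) return(-Inf)
    ll <- ll + log(p)
  }
  ll
}

#' Cohort exact-times log-likelihood
#'
#' Sum of [exact_path_loglik()] over independent patients, each evaluated at
#' the intensity matrix for that patient's covariate pattern.
#'
#' @param histories List of [state_history()].
#' @param model An [intensity_model()].
#' @param X Optional numeric design matrix (one row per patient, columns
#'   named as `model$covariates`).
#' @return Scalar log-likelihood.
#' @export
cohort_loglik <- function(histories, model, X = NULL) {
  if (is.null(X)) {
    Q <- make_intensity_matrix(model)
    return(sum(vapply(histories, exact_path_loglik, 0, Q = Q)))
  }
  X <- as.matrix(X)
  if (nrow(X) != length(histories)) stop("X rows must match histories")
  pat <- apply(X, 1, paste, collapse = "\r")
  ll <- 0
  for (p in unique(pat)) {
    idx <- which(pat == p)
    Q <- make_intensity_matrix(model, X[idx[1L], ])
    ll <- ll + sum(vapply(histories[idx], exact_path_loglik, 0, Q = Q))
  }
  ll
}
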