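#' Construct a transition intensity model
#'
#' The model places a log-linear predictor on every allowed transition
#' intensity: \eqn{q_{rs}(x) = \exp(\log q^0_{rs} + \beta_{rs}' x)}, where
#' \eqn{x} is a vector of covariate-category dummies (reference categories
#' coded all-zero). The baseline rates are the intensities of the reference
#' pattern; `exp(beta)` are hazard ratios.
#'
#' @param baseline Named numeric vector of baseline intensities (per year,
#'   natural scale, all > 0), named by transition label (see
#'   [ltc_transitions()]). Unnamed vectors of length 10 are taken in
#'   transition order.
#' @param coefficients Optional numeric matrix of log hazard ratios with one
#'   row per transition (rownames = transition labels, or 10 unnamed rows in
#'   order) and one column per covariate dummy (colnames required).
#' @return An object of class `intensity_model` with elements `transitions`,
#'   `log_baseline` (named), `coefficients` (10 x p matrix, possibly
#'   0-column) and `covariates` (character vector of dummy names).
#' @export
#' @examples
#' m <- intensity_model(c("S0->S1" = 0.2, "S0->Death" = 0.01))
#' make_intensity_matrix(m)[1, 2]
intensity_model <- function(baseline, coefficients = NULL) {
  tr <- ltc_transitions()
  lab <- tr$label
  full <- stats::setNames(rep(0, nrow(tr)), lab)
  if (is.null(names(baseline))) {
    if (length(baseline) != nrow(tr)) {
      stop("unnamed baseline must have length ", nrow(tr))
    }
    full[] <- baseline
  } else {
    bad <- setdiff(names(baseline), lab)
    if (length(bad)) stop("unknown transition label(s): ",
                          paste(bad, collapse = ", "))
    full[names(baseline)] <- baseline
  }
  if (any(full < 0) || any(!is.finite(full))) {
    stop("baseline intensities must be finite and non-negative")
  }
  if (is.null(coefficients)) {
    coefficients <- matrix(0, nrow(tr), 0, dimnames = list(lab, NULL))
  } else {
    coefficients <- as.matrix(coefficients)
    if (is.null(colnames(coefficients))) {
      stop("coefficient columns must be named by covariate dummy")
    }
    if (is.null(rownames(coefficients))) {
      if (nrow(coefficients) != nrow(tr)) {
        stop("unnamed coefficient rows must number ", nrow(tr))
      }
      rownames(coefficients) <- lab
    } else {
      bad <- setdiff(rownames(coefficients), lab)
      if (length(bad)) stop("unknown transition label(s): ",
                            paste(bad, collapse = ", "))
      cf <- matrix(0, nrow(tr), ncol(coefficients),
                   dimnames = list(lab, colnames(coefficients)))
      cf[rownames(coefficients), ] <- coefficients
      coefficients <- cf
    }
  }
  structure(
    list(transitions = tr,
         log_baseline = log(full),
         coefficients = coefficients,
         covariates = colnames(coefficients)),
    class = "intensity_model"
  )
}

#' @export
print.intensity_model <- function(x, ...) {
  cat("Transition intensity model (5-state LTC chain)\n")
  cat("Baseline intensities (per year):\n")
  print(round(exp(x$log_baseline), 5))
  if (length(x$covariates)) {
    cat("Hazard ratios:\n")
    print(round(exp(x$coefficients), 3))
  } else {
    cat("No covariate effects.\n")
  }
  invisible(x)
}

#' Build the 5x5 intensity matrix Q(x) for one covariate pattern
#'
#' Off-diagonal entries of allowed transitions carry the log-linear
#' intensity; all other off-diagonals are zero; the diagonal makes each row
#' sum to zero; the Death row is identically zero (absorbing).
#'
#' @param model An [intensity_model()].
#' @param x Named numeric vector of covariate dummies (subset of
#'   `model$covariates`; missing names are taken as 0), or `NULL` for the
#'   reference pattern.
#' @return 5x5 numeric matrix with dimnames [ltc_states()].
#' @export
make_intensity_matrix <- function(model, x = NULL) {
  stopifnot(inherits(model, "intensity_model"))
  eta <- model$log_baseline
  if (length(model$covariates)) {
    xv <- stats::setNames(numeric(length(model$covariates)), model$covariates)
    if (!is.null(x) && length(x)) {
      bad <- setdiff(names(x), model$covariates)
      if (length(bad)) stop("unknown covariate dummy: ",
                            paste(bad, collapse = ", "))
      xv[names(x)] <- x
    }
    eta <- eta + drop(model$coefficients %*% xv)
  }
  tr <- model$transitions
  st <- ltc_states()
  Q <- matrix(0, 5, 5, dimnames = list(st, st))
  Q[cbind(tr$from, tr$to)] <- exp(eta)
  diag(Q) <- -rowSums(Q)
  Q
}

## Generic rate-matrix validity check (rows sum to 0, non-negative
## off-diagonals, absorbing rows all-zero allowed).
validate_rate_matrix <- function(Q, tol = 1e-8) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stop("Q must be square")
  off <- Q; diag(off) <- 0
  if (any(off < -tol)) stop("Q has negative off-diagonal entries")
  if (any(abs(rowSums(Q)) > tol * pmax(1, abs(diag(Q))) + tol)) {
    stop("rows of an intensity matrix must sum to 0")
  }
  invisible(TRUE)
}

## Dense matrix exponential: degree-13 Pade approximant with scaling and
## squaring (Higham 2005). Stable without assuming diagonalisability; for
## the 5x5 intensity matrices used here it is essentially exact and cheap
## enough for the inner loop of panel-likelihood optimisation.
expm_dense <- function(A) {
  b <- c(64764752532480000, 32382376266240000, 7771770303897600,
         1187353796428800, 129060195264000, 10559470521600, 670442572800,
         33522128640, 1323241920, 40840800, 960960, 16380, 182, 1)
  n <- nrow(A)
  I <- diag(n)
  nA <- max(colSums(abs(A)))
  s <- if (nA > 5.371920351148152) ceiling(log2(nA / 5.371920351148152)) else 0
  if (s > 0) A <- A / 2^s
  A2 <- A %*% A
  A4 <- A2 %*% A2
  A6 <- A2 %*% A4
  U <- A %*% (A6 %*% (b[14] * A6 + b[12] * A4 + b[10] * A2) +
                b[8] * A6 + b[6] * A4 + b[4] * A2 + b[2] * I)
  V <- A6 %*% (b[13] * A6 + b[11] * A4 + b[9] * A2) +
    b[7] * A6 + b[5] * A4 + b[3] * A2 + b[1] * I
  P <- solve(V - U, V + U)
  for (i in seq_len(s)) P <- P %*% P
  P
}

#' Transition probability matrix over an interval
#'
#' Computes \eqn{P(t) = \exp(tQ)} by degree-13 Pade approximation with
#' scaling and squaring, the standard numerically stable route that does
#' not assume Q is diagonalisable.
#'
#' @param Q Valid intensity matrix (rows sum to zero, non-negative
#'   off-diagonals); typically from [make_intensity_matrix()].
#' @param t Non-negative interval length (years).
#' @return Square probability matrix; rows sum to 1 within 1e-8 (a larger
#'   deviation raises an error rather than being silently renormalised).
#' @export
#' @examples
#' Q <- matrix(c(-0.5, 0, 0.5, 0), 2, 2)
#' transition_probability(Q, 1)[1, 2]  # 1 - exp(-0.5)
transition_probability <- function(Q, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("t must be a single non-negative number")
  }
  validate_rate_matrix(Q)
  if (t == 0) {
    P <- diag(nrow(Q))
    dimnames(P) <- dimnames(Q)
    return(P)
  }
  P <- expm_dense(Q * t)
  dimnames(P) <- dimnames(Q)
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-8)) {
    stop("matrix exponential row sums deviate from 1 beyond tolerance: max |err| = ",
         format(max(abs(rs - 1))))
  }
  # remove harmless round-off only (within the checked tolerance)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Mean sojourn times of the living states
#'
#' For a time-homogeneous chain the time spent in state r per visit is
#' exponential with mean \eqn{-1/q_{rr}}; a living state with no exit rate
#' has infinite mean sojourn.
#'
#' @param Q Valid 5x5 intensity matrix.
#' @return Named numeric vector of mean sojourn times (years) for the four
#'   living states; `Inf` where the total exit rate is zero.
#' @export
sojourn_times <- function(Q) {
  validate_rate_matrix(Q)
  d <- diag(Q)[seq_len(N_LIVING)]
  out <- ifelse(d < 0, -1 / d, Inf)
  names(out) <- ltc_states()[seq_len(N_LIVING)]
  out
}
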