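#' Build a dummy-coded design matrix for intensity regression
#'
#' Encodes age group at entry (reference 18-39) plus at most one exposure
#' variable, mirroring the modelling strategy of fitting separate
#' age-adjusted models per exposure. Reference categories are Male (sex),
#' White (ethnicity), quintile 5 = least deprived (IMD) and "never" (risk
#' factors); `"any_risk"` is the derived binary exposure "at least one risk
#' factor ever or resolved".
#'
#' @param patients data.frame with `age_group` and the exposure column
#'   (`sex`, `ethnicity`, `imd_quintile`, or a `rf_*` risk-factor column
#'   with levels never/ever/resolved).
#' @param exposure `NULL` (age adjustment only), `"sex"`, `"ethnicity"`,
#'   `"imd"`, `"any_risk"`, or a risk-factor name such as `"smoking"`
#'   (column `rf_smoking`).
#' @param adjust_age Include age-group dummies (default `TRUE`).
#' @return Numeric matrix, one row per patient, named dummy columns.
#' @export
covariate_design <- function(patients, exposure = NULL, adjust_age = TRUE) {
  n <- nrow(patients)
  cols <- list()
  dummy <- function(values, levels, prefix, ref) {
    f <- factor(as.character(values), levels = levels)
    if (anyNA(f)) stop("unexpected level in ", prefix, ": ",
                       paste(unique(setdiff(as.character(values), levels)),
                             collapse = ", "))
    for (lv in setdiff(levels, ref)) {
      clean <- gsub("_$", "", gsub("[^A-Za-z0-9]+", "_", sub("\\+$", "plus", lv)))
      nm <- paste0(prefix, "_", clean)
      cols[[nm]] <<- as.numeric(f == lv)
    }
  }
  if (adjust_age) {
    dummy(patients$age_group, c("18-39", "40-59", "60-79", "80+"),
          "age", "18-39")
  }
  if (!is.null(exposure)) {
    if (exposure == "sex") {
      dummy(patients$sex, c("Male", "Female"), "sex", "Male")
    } else if (exposure == "ethnicity") {
      dummy(patients$ethnicity,
            c("White", "Black", "Asian", "Mixed", "Other", "Missing"),
            "eth", "White")
    } else if (exposure == "imd") {
      dummy(patients$imd_quintile, c("1", "2", "3", "4", "5", "Missing"),
            "imd", "5")
    } else if (exposure == "any_risk") {
      rf <- grep("^rf_", names(patients), value = TRUE)
      if (!length(rf)) stop("no rf_* columns to derive any_risk from")
      any_rf <- Reduce(`|`, lapply(rf, function(v) {
        patients[[v]] %in% c("ever", "resolved")
      }))
      cols[["any_risk"]] <- as.numeric(any_rf)
    } else {
      col <- paste0("rf_", exposure)
      if (!col %in% names(patients)) stop("unknown exposure: ", exposure)
      dummy(patients[[col]], c("never", "ever", "resolved"), exposure, "never")
    }
  }
  if (!length(cols)) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  do.call(cbind, cols)
}

## Fit one transition's log-linear intensity by quasi-Newton (BFGS) on the
## exact-times likelihood kernel: nll = sum_i T_i exp(eta_i) - y_i eta_i,
## eta = Z theta. Data arrive aggregated by covariate pattern.
fit_one_transition <- function(y, T_at_risk, Z, control = list()) {
  keep <- T_at_risk > 0 | y > 0
  y <- y[keep]; T_at_risk <- T_at_risk[keep]
  Z <- Z[keep, , drop = FALSE]
  p <- ncol(Z)
  nll <- function(th) {
    eta <- drop(Z %*% th)
    sum(T_at_risk * exp(eta)) - sum(y * eta)
  }
  grd <- function(th) {
    eta <- drop(Z %*% th)
    drop(crossprod(Z, T_at_risk * exp(eta) - y))
  }
  init <- c(log(sum(y) / sum(T_at_risk)), rep(0, p - 1L))
  opt <- stats::optim(init, nll, grd, method = "BFGS",
                      control = utils::modifyList(
                        list(maxit = 500, reltol = 1e-12), control))
  # Newton polish with step-halving: quadratic near the optimum and robust
  # to the flat likelihoods of near-separated categories
  th <- opt$par
  f_cur <- nll(th)
  for (it in seq_len(50L)) {
    g <- grd(th)
    if (max(abs(g)) < 1e-8 * (1 + abs(f_cur))) break
    w <- T_at_risk * exp(drop(Z %*% th))
    H <- crossprod(Z, Z * w)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      f_new <- nll(th - lam * step)
      if (is.finite(f_new) && f_new <= f_cur) break
      lam <- lam / 2
      if (lam < 1e-10) break
    }
    if (lam < 1e-10) break
    th <- th - lam * step
    f_cur <- f_new
  }
  g <- grd(th)
  w <- T_at_risk * exp(drop(Z %*% th))
  H <- crossprod(Z, Z * w)          # observed information (analytic)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
  list(par = th, vcov = V, loglik = -f_cur,
       converged = max(abs(g)) < 1e-5 * (1 + abs(f_cur)))
}

#' Fit the five-state multistate Markov model by maximum likelihood
#'
#' Estimates baseline log-intensities and log hazard-ratio coefficients for
#' every allowed transition. In `"exact"` mode transition times are treated
#' as exactly observed; the likelihood then factorises over transitions
#' into independent kernels (event counts and time at risk in the origin
#' state), each maximised by quasi-Newton from the crude-rate initialiser
#' (events / person-years at risk), with the covariance from the analytic
#' observed information. In `"panel"` mode states are treated as seen only
#' at the recorded times and the interval-censored likelihood (matrix
#' exponentials, death exactly timed) is maximised jointly by BFGS with a
#' finite-difference Hessian.
#'
#' Transitions with zero observed events are inestimable and reported `NA`
#' (their fitted intensity is zero); a covariate category with no events on
#' some transition likewise gets an `NA` coefficient there, and in exact
#' mode that category's exposure time is excluded from that transition's
#' kernel so the remaining estimates are unbiased.
#'
#' @param histories List of [state_history()] objects.
#' @param X Optional design matrix from [covariate_design()] (one row per
#'   history; columns are covariate dummies).
#' @param mode `"exact"` (default) or `"panel"`.
#' @param panel_grid_dt Panel mode only: optional spacing (years) of extra
#'   observation times inserted between change-points (state carried
#'   forward). As the grid becomes dense the panel likelihood approaches
#'   the exact-times likelihood; the default `NULL` uses only the recorded
#'   times.
#' @param control Passed to [stats::optim()] control.
#' @return Object of class `msm_fit`: `model` (fitted [intensity_model()]),
#'   `par_table` (data.frame of per-parameter estimates, SEs and
#'   estimability), `covariance` (block matrix over free parameters),
#'   `loglik`, `converged`, `n_transitions_observed`, `mode`, `n`.
#' @export
msm_fit <- function(histories, X = NULL, mode = c("exact", "panel"),
                    panel_grid_dt = NULL, control = list()) {
  mode <- match.arg(mode)
  n <- length(histories)
  if (!n) stop("no histories supplied")
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != n) stop("X must have one row per history")
    if (is.null(colnames(X))) stop("X columns must be named")
  }
  p <- if (is.null(X)) 0L else ncol(X)
  tr <- ltc_transitions()
  K <- nrow(tr)

  ss <- lapply(histories, history_suffstats)
  counts <- do.call(rbind, lapply(ss, `[[`, "counts"))       # n x K
  tis <- do.call(rbind, lapply(ss, `[[`, "time_in_state"))   # n x 4
  n_obs <- colSums(counts)
  names(n_obs) <- tr$label

  # aggregate by covariate pattern (exact-mode kernels only need sums)
  if (p) {
    pat_key <- apply(X, 1, paste, collapse = "\r")
    pat_idx <- match(pat_key, unique(pat_key))
    m <- max(pat_idx)
    Xa <- X[match(seq_len(m), pat_idx), , drop = FALSE]
    agg <- function(M) {
      out <- matrix(0, m, ncol(M))
      for (j in seq_len(ncol(M))) {
        out[, j] <- as.numeric(rowsum(M[, j], pat_idx))
      }
      out
    }
    counts_a <- agg(counts); tis_a <- agg(tis)
  } else {
    m <- 1L
    Xa <- matrix(numeric(0), 1, 0)
    counts_a <- matrix(colSums(counts), 1)
    tis_a <- matrix(colSums(tis), 1)
  }

  est <- matrix(NA_real_, K, p + 1L)   # [ ,1] = log baseline, rest = beta
  ses <- matrix(NA_real_, K, p + 1L)
  term_names <- c("(baseline)", colnames(X))
  dimnames(est) <- dimnames(ses) <- list(tr$label, term_names)
  conv <- rep(NA, K)
  ll <- 0
  vcov_blocks <- vector("list", K)

  if (mode == "exact") {
    for (k in seq_len(K)) {
      y <- counts_a[, k]
      T_at <- tis_a[, tr$from[k]]
      if (sum(y) == 0) next                      # inestimable transition
      keep_col <- rep(TRUE, p)
      keep_row <- rep(TRUE, m)
      if (p) {
        for (j in seq_len(p)) {
          e1 <- sum(y[keep_row & Xa[, j] > 0])
          e0 <- sum(y[keep_row & Xa[, j] == 0])
          if (e1 == 0 || e0 == 0) {
            keep_col[j] <- FALSE
            # drop the sparse category's exposure so other estimates stay clean
            if (e1 == 0) keep_row <- keep_row & Xa[, j] == 0
          }
        }
      }
      Z <- cbind(1, if (p) Xa[keep_row, keep_col, drop = FALSE])
      f1 <- fit_one_transition(y[keep_row], T_at[keep_row], Z, control)
      idx <- c(1L, if (p) 1L + which(keep_col))
      est[k, idx] <- f1$par
      ses[k, idx] <- sqrt(pmax(diag(f1$vcov), 0))
      conv[k] <- f1$converged
      ll <- ll + f1$loglik
      vb <- matrix(NA_real_, p + 1L, p + 1L)
      vb[idx, idx] <- f1$vcov
      vcov_blocks[[k]] <- vb
    }
  } else {
    # panel mode: joint optimisation over all estimable parameters
    free <- matrix(FALSE, K, p + 1L)
    for (k in seq_len(K)) {
      if (n_obs[k] == 0) next
      free[k, 1L] <- TRUE
      if (p) for (j in seq_len(p)) {
        e1 <- sum(counts_a[Xa[, j] > 0, k])
        e0 <- sum(counts_a[Xa[, j] == 0, k])
        free[k, j + 1L] <- e1 > 0 && e0 > 0
      }
    }
    if (!any(free)) stop("no estimable parameters (no observed transitions)")
    crude <- log(pmax(colSums(counts_a), 0.5) /
                   pmax(colSums(tis_a)[tr$from], 1e-8))
    Minit <- cbind(crude, matrix(0, K, p))
    init <- Minit[free]                 # column-major, matching M[free] <- th
    unpack <- function(th) {
      M <- matrix(0, K, p + 1L)
      M[free] <- th
      M[!free[, 1L], 1L] <- -Inf        # inestimable transition: rate 0
      M
    }
    # panel observation sequences per patient (censor row repeats the state;
    # an optional grid densifies observations toward the exact likelihood)
    obs_list <- lapply(histories, function(h) {
      tt <- h$times; st <- h$states
      if (!is.null(panel_grid_dt)) {
        allt <- sort(unique(c(tt, seq(0, h$t_end, by = panel_grid_dt),
                              h$t_end)))
        st <- st[findInterval(allt, tt)]
        tt <- allt
      } else if (h$censored && h$t_end > tt[length(tt)]) {
        tt <- c(tt, h$t_end); st <- c(st, st[length(st)])
      }
      list(t = tt, s = st)
    })
    pat_of <- if (p) pat_idx else rep(1L, n)
    nll <- function(th) {
      M <- unpack(th)
      val <- 0
      for (g in seq_len(m)) {
        x <- if (p) Xa[g, ] else NULL
        eta <- M[, 1L] + if (p) drop(M[, -1L, drop = FALSE] %*% x) else 0
        Q <- matrix(0, 5, 5, dimnames = list(ltc_states(), ltc_states()))
        Q[cbind(tr$from, tr$to)] <- exp(eta)
        diag(Q) <- -rowSums(Q)
        cache <- new.env(parent = emptyenv())
        for (i in which(pat_of == g)) {
          li <- panel_loglik(obs_list[[i]]$t, obs_list[[i]]$s, Q,
                             .cache = cache)
          if (!is.finite(li)) return(1e10)
          val <- val - li
        }
      }
      val
    }
    opt <- stats::optim(init, nll, method = "BFGS", hessian = TRUE,
                        control = utils::modifyList(
                          list(maxit = 500, reltol = 1e-10), control))
    M <- matrix(NA_real_, K, p + 1L)
    M[free] <- opt$par
    est[] <- M
    V <- tryCatch(solve(opt$hessian),
                  error = function(e) matrix(NA_real_, length(opt$par),
                                             length(opt$par)))
    SE <- matrix(NA_real_, K, p + 1L)
    SE[free] <- sqrt(pmax(diag(V), 0))
    ses[] <- SE
    conv <- ifelse(n_obs > 0, opt$convergence == 0L, NA)
    ll <- -opt$value
    nm_mat <- matrix(paste(rep(tr$label, p + 1L),
                           rep(term_names, each = K), sep = " : "),
                     K, p + 1L)
    full_names <- nm_mat[free]
    dimnames(V) <- list(full_names, full_names)
    vcov_blocks <- V
  }

  baseline <- exp(est[, 1L])
  baseline[is.na(baseline)] <- 0          # inestimable => intensity 0
  coefs <- NULL
  if (p) {
    coefs <- est[, -1L, drop = FALSE]
    coefs[is.na(coefs)] <- 0
  }
  model <- intensity_model(stats::setNames(baseline, tr$label), coefs)

  if (mode == "exact") {
    nm <- paste(rep(tr$label, each = p + 1L), rep(term_names, K), sep = " : ")
    covariance <- matrix(NA_real_, K * (p + 1L), K * (p + 1L),
                         dimnames = list(nm, nm))
    for (k in seq_len(K)) {
      if (!is.null(vcov_blocks[[k]])) {
        idx <- (k - 1L) * (p + 1L) + seq_len(p + 1L)
        covariance[idx, idx] <- vcov_blocks[[k]]
      }
    }
  } else {
    covariance <- vcov_blocks
  }

  par_table <- data.frame(
    transition = rep(tr$label, each = p + 1L),
    term = rep(term_names, K),
    estimate = as.vector(t(est)),
    se = as.vector(t(ses)),
    stringsAsFactors = FALSE
  )
  par_table$estimable <- !is.na(par_table$estimate)

  structure(
    list(model = model, par_table = par_table, covariance = covariance,
         loglik = ll, converged = all(conv[!is.na(conv)]),
         n_transitions_observed = n_obs, mode = mode, n = n,
         covariates = colnames(X)),
    class = "msm_fit"
  )
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("Multistate model fit (", x$mode, " likelihood), ", x$n,
      " patients\n", sep = "")
  cat("log-likelihood: ", format(x$loglik), ", converged: ",
      x$converged, "\n", sep = "")
  cat("Observed transitions:\n")
  print(x$n_transitions_observed)
  cat("\nBaseline intensities (per year):\n")
  print(round(exp(x$model$log_baseline), 5))
  if (length(x$covariates)) {
    cat("\nHazard ratios:\n")
    print(hazard_ratios(x), digits = 3)
  }
  invisible(x)
}

#' Hazard-ratio table from a fitted multistate model
#'
#' One row per (allowed transition x non-reference covariate category):
#' HR = exp(beta) with the Wald 95% interval exp(beta +- 1.96 se) on the log
#' scale. Inestimable cells (no events in the category on that transition)
#' are `NA`.
#'
#' @param fit An [msm_fit()].
#' @param conf_level Confidence level (default 0.95).
#' @return data.frame with `transition`, `term`, `hr`, `lo`, `hi`,
#'   `se_log`, `n_events`.
#' @export
hazard_ratios <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "msm_fit"))
  pt <- fit$par_table[fit$par_table$term != "(baseline)", , drop = FALSE]
  if (!nrow(pt)) return(data.frame(transition = character(),
                                   term = character(), hr = numeric(),
                                   lo = numeric(), hi = numeric(),
                                   se_log = numeric(), n_events = numeric()))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(
    transition = pt$transition,
    term = pt$term,
    hr = exp(pt$estimate),
    lo = exp(pt$estimate - z * pt$se),
    hi = exp(pt$estimate + z * pt$se),
    se_log = pt$se,
    n_events = as.numeric(
      fit$n_transitions_observed[pt$transition]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Render an annual probability as "1 in N"
#'
#' @param p Probability in \[0, 1\].
#' @return `"1 in N"` with `N = round(1/p)`; `"1"` when the rounded odds
#'   reach 1; `"-"` for zero or undefined probabilities.
#' @export
one_in_n <- function(p) {
  vapply(p, function(pi) {
    if (!is.finite(pi) || pi <= 0) return("-")
    N <- round(1 / pi)
    if (N <= 1) "1" else paste("1 in", N)
  }, "")
}

#' One-year transition report for a covariate pattern
#'
#' For a covariate pattern (default: age 40-59, reference categories
#' otherwise) emits the one-year 5x5 transition probability matrix, the
#' headline annual summaries -- probability of moving to higher morbidity
#' or death from the healthy state, P(S0->S1) + P(S0->Death), and from the
#' multimorbid two-condition state, P(S2->S3plus) + P(S2->Death) -- their
#' "1 in N" renderings, and the mean sojourn times.
#'
#' @param fit An [msm_fit()] or an [intensity_model()].
#' @param x Named covariate dummy vector (default `c(age_40_59 = 1)` when
#'   the model has that dummy, else the reference pattern).
#' @param horizon Probability horizon in years (default 1).
#' @return Object of class `one_year_report` with elements `P`,
#'   `p_up_from_healthy`, `p_up_from_multimorbid`, their renderings,
#'   `sojourn`, `x`, `horizon`.
#' @export
one_year_report <- function(fit, x = NULL, horizon = 1) {
  model <- if (inherits(fit, "msm_fit")) fit$model else fit
  stopifnot(inherits(model, "intensity_model"))
  if (is.null(x)) {
    x <- if ("age_40_59" %in% model$covariates) c(age_40_59 = 1) else NULL
  }
  Q <- make_intensity_matrix(model, x)
  P <- transition_probability(Q, horizon)
  p0 <- P["S0", "S1"] + P["S0", "Death"]
  p2 <- P["S2", "S3plus"] + P["S2", "Death"]
  structure(
    list(P = P,
         p_up_from_healthy = p0,
         p_up_from_multimorbid = p2,
         rendered_healthy = one_in_n(p0),
         rendered_multimorbid = one_in_n(p2),
         sojourn = sojourn_times(Q),
         x = x, horizon = horizon),
    class = "one_year_report"
  )
}

#' @export
print.one_year_report <- function(x, ...) {
  cat("Transition probabilities over", x$horizon, "year(s)")
  if (length(x$x)) {
    cat(" at ", paste(names(x$x), "=", x$x, collapse = ", "), sep = "")
  }
  cat(":\n")
  print(round(x$P, 4))
  cat(sprintf("\nAnnual P(higher morbidity or death | no LTC):    %.3f (%s)\n",
              x$p_up_from_healthy, x$rendered_healthy))
  cat(sprintf("Annual P(higher morbidity or death | 2 LTCs):    %.3f (%s)\n",
              x$p_up_from_multimorbid, x$rendered_multimorbid))
  cat("\nMean sojourn times (years):\n")
  print(round(x$sojourn, 2))
  invisible(x)
}
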