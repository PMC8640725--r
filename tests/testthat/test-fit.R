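test_that("exact-mode estimates coincide with the Poisson-kernel oracle", {
  # the exact-times likelihood factorises per transition into a Poisson
  # kernel with log-time offset; glm(poisson) is an independent fitter
  cfg <- recovery_config(400, seed = 51)
  co <- simulate_cohort(cfg)
  h <- build_cohort_histories(co$patients, co$events)
  X <- build_dummies(co$patients, "grp")
  f <- msm_fit(h, X)
  ss <- lapply(h, ltctraj:::history_suffstats)
  for (lab in c("S0->S1", "S1->S2", "S3plus->Death")) {
    k <- match(lab, ltc_transitions()$label)
    y <- vapply(ss, function(s) s$counts[k], 0)
    Tt <- vapply(ss, function(s) s$time_in_state[ltc_transitions()$from[k]], 0)
    d <- data.frame(y = y, T = Tt, g = X[, "grp"])[Tt > 0, ]
    gfit <- stats::glm(y ~ g + offset(log(T)), poisson, d)
    ours <- f$par_table[f$par_table$transition == lab, "estimate"]
    expect_equal(ours, unname(stats::coef(gfit)), tolerance = 1e-6)
  }
})

test_that("baseline rates are recovered from a known truth without covariates", {
  m <- recovery_truth()
  truth0 <- intensity_model(exp(m$log_baseline))  # drop the covariate
  cfg <- cohort_config(2000, seed = 61, truth = truth0,
                       initial_state_probs = c(0.4, 0.3, 0.2, 0.1))
  co <- simulate_cohort(cfg)
  h <- build_cohort_histories(co$patients, co$events)
  f <- msm_fit(h)
  expect_true(f$converged)
  # each baseline within 3 estimated SEs of truth
  pt <- f$par_table[f$par_table$term == "(baseline)", ]
  for (k in seq_len(nrow(pt))) {
    expect_lt(abs(pt$estimate[k] - m$log_baseline[pt$transition[k]]),
              3.5 * pt$se[k])
  }
})

test_that("degenerate inputs flag inestimable transitions instead of diverging", {
  h <- state_history("solo", 0, 1, t_end = 3)   # one censored sojourn in S0
  f <- msm_fit(list(h))
  expect_true(all(is.na(f$par_table$estimate)))
  expect_true(all(!f$par_table$estimable))
  expect_equal(unname(f$n_transitions_observed), rep(0, 10))
  # fitted intensities are zero, so the model is still usable
  expect_true(all(exp(f$model$log_baseline) == 0))
})

test_that("a covariate category with no events is reported NA, others unaffected", {
  # females never progress in this tiny constructed cohort
  hs <- list(
    state_history("m1", c(0, 1), c(1, 2), t_end = 4),
    state_history("m2", c(0, 2), c(1, 2), t_end = 5),
    state_history("f1", 0, 1, t_end = 6),
    state_history("f2", 0, 1, t_end = 3)
  )
  X <- matrix(c(0, 0, 1, 1), 4, 1, dimnames = list(NULL, "sex_Female"))
  f <- msm_fit(hs, X)
  pt <- f$par_table
  row_b <- pt$transition == "S0->S1" & pt$term == "(baseline)"
  row_f <- pt$transition == "S0->S1" & pt$term == "sex_Female"
  expect_true(is.na(pt$estimate[row_f]))
  # baseline from male exposure only: 2 events / 3 male S0-years
  expect_equal(exp(pt$estimate[row_b]), 2 / 3, tolerance = 1e-6)
})

test_that("hazard ratio table is Table-2 shaped with delta-method intervals", {
  cfg <- recovery_config(800, seed = 71)
  co <- simulate_cohort(cfg)
  h <- build_cohort_histories(co$patients, co$events)
  f <- msm_fit(h, build_dummies(co$patients, "grp"))
  hr <- hazard_ratios(f)
  expect_equal(nrow(hr), 10L)       # 10 transitions x 1 dummy
  expect_setequal(hr$transition, ltc_transitions()$label)
  ok <- !is.na(hr$hr)
  expect_true(all(hr$lo[ok] <= hr$hr[ok] & hr$hr[ok] <= hr$hi[ok]))
  # the Wald interval is exp(beta +/- 1.96 se)
  i <- which(hr$transition == "S1->S2")
  beta <- log(hr$hr[i]); se <- hr$se_log[i]
  expect_equal(hr$lo[i], exp(beta - stats::qnorm(0.975) * se))
  expect_equal(hr$hi[i], exp(beta + stats::qnorm(0.975) * se))
  # beta = 0 renders HR 1 (construction check via a null model)
  m0 <- intensity_model(c("S0->S1" = 0.2),
                        matrix(0, 1, 1, dimnames = list("S0->S1", "z")))
  expect_equal(exp(m0$coefficients["S0->S1", "z"]), 1)
})

test_that("exact and dense-grid panel fits agree", {
  cfg <- recovery_config(60, seed = 81)
  co <- simulate_cohort(cfg)
  h <- build_cohort_histories(co$patients, co$events)
  fe <- msm_fit(h)
  fp <- msm_fit(h, mode = "panel", panel_grid_dt = 0.1)
  be <- exp(fe$model$log_baseline)
  bp <- exp(fp$model$log_baseline)
  est <- be > 0 & bp > 0
  expect_true(sum(est) >= 5)
  expect_lt(max(abs(bp[est] / be[est] - 1)), 0.10)
})

test_that("one-year report sums the right cells and renders 1-in-N odds", {
  m <- default_truth_model()
  rep1 <- one_year_report(m, x = c(age_40_59 = 1))
  expect_equal(rep1$p_up_from_healthy,
               rep1$P["S0", "S1"] + rep1$P["S0", "Death"])
  expect_equal(rep1$p_up_from_multimorbid,
               rep1$P["S2", "S3plus"] + rep1$P["S2", "Death"])
  expect_true(all(abs(rowSums(rep1$P) - 1) < 1e-8))
  expect_equal(one_in_n(0.06), "1 in 17")
  expect_equal(one_in_n(0.85), "1")
  expect_equal(one_in_n(0), "-")
  # identity matrix: degenerate rendering
  zero <- intensity_model(stats::setNames(rep(0, 10),
                                          ltc_transitions()$label))
  rep0 <- one_year_report(zero, x = NULL)
  expect_equal(rep0$p_up_from_healthy, 0)
  expect_equal(rep0$rendered_healthy, "-")
})
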