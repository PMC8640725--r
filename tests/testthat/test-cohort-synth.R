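test_that("an all-zero truth model freezes every patient in place", {
  zero <- intensity_model(stats::setNames(rep(0, 10), ltc_transitions()$label))
  cfg <- cohort_config(50, seed = 3, truth = zero)
  co <- simulate_cohort(cfg)
  expect_false(any(co$patients$died))
  # all events are prior onsets setting the initial state; none in follow-up
  if (nrow(co$events)) {
    expect_true(all(co$events$onset_date <=
                      co$patients$follow_up_start[
                        match(co$events$patient_id, co$patients$patient_id)]))
    expect_true(all(is.na(co$events$resolve_date)))
  }
  h <- build_cohort_histories(co$patients, co$events)
  expect_true(all(vapply(h, function(x) length(x$states) == 1L, TRUE)))
})

test_that("simulation is byte-identical for a repeated seed", {
  cfg <- cohort_config(10, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c <- simulate_cohort(cohort_config(10, seed = 8))
  expect_false(identical(a$patients, c$patients))
})

test_that("simulate_path validates inputs and honours zero rates", {
  m <- default_truth_model()
  expect_error(simulate_path(m, t_max = 5, initial_state = "Death"),
               "living state")
  expect_error(simulate_path(m, t_max = 0), "positive")
  # zero death intensities: Death never appears
  nodeath <- intensity_model(c("S0->S1" = 0.5, "S1->S2" = 0.5,
                               "S1->S0" = 0.3, "S2->S1" = 0.3,
                               "S2->S3plus" = 0.4, "S3plus->S2" = 0.4))
  set.seed(5)
  for (i in 1:100) {
    p <- simulate_path(nodeath, t_max = 20, initial_state = 1)
    expect_false(any(p$states == 5L))
    # consecutive states differ by one allowed move
    if (length(p$states) > 1) {
      expect_true(all(abs(diff(p$states)) == 1L))
    }
    expect_equal(p$times[1], 0)
  }
})

test_that("two-state absorption fraction matches exponential survival", {
  # only S0->Death at rate 0.5: P(absorbed by t=1) = 1 - exp(-0.5)
  m <- intensity_model(c("S0->Death" = 0.5))
  set.seed(123)
  n <- 50000
  absorbed <- 0L
  for (i in seq_len(n)) {
    p <- simulate_path(m, t_max = 1, initial_state = 1)
    absorbed <- absorbed + (p$states[length(p$states)] == 5L)
  }
  p_true <- 1 - exp(-0.5)
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(absorbed / n - p_true), 3 * se)
})

test_that("empirical sojourn times match -1/q_rr within 3 standard errors", {
  # keep only the exits out of S0 from the default truth so each simulated
  # path ends after its first move; the S0 sojourn distribution is untouched
  full <- exp(default_truth_model()$log_baseline)
  m <- intensity_model(full[c("S0->S1", "S0->Death")])
  Q <- make_intensity_matrix(m)
  lam <- -Q["S0", "S0"]
  set.seed(99)
  n <- 50000
  soj <- numeric(n)
  for (i in seq_len(n)) {
    p <- simulate_path(m, t_max = Inf, initial_state = 1)
    soj[i] <- p$times[2]
  }
  expect_equal(1 / lam, sojourn_times(Q)[["S0"]])
  expect_lt(abs(mean(soj) - 1 / lam), 3 * stats::sd(soj) / sqrt(n))
})

test_that("rendered events reproduce the latent path exactly (round trip)", {
  m <- recovery_truth()
  cat32 <- default_catalogue()
  set.seed(21)
  for (i in 1:1000) {
    init <- sample(1:4, 1)
    p <- simulate_path(m, c(grp = as.numeric(i %% 2 == 0)),
                       t_max = stats::runif(1, 1, 12), initial_state = init)
    ev <- render_events(p, cat32)
    # move/event bijection (a S3plus->Death move is not an acquisition)
    from <- p$states[-length(p$states)]; to <- p$states[-1]
    ups <- sum(to == from + 1L & to <= 4L)
    downs <- sum(to == from - 1L)
    expect_equal(sum(ev$onset_time > 0), ups)
    expect_equal(sum(!is.na(ev$resolve_time)), downs)
    expect_equal(sum(ev$onset_time <= 0), init - 1L)
    # resolutions always name a resolvable condition
    if (downs > 0) {
      res <- ev$condition[!is.na(ev$resolve_time)]
      expect_true(all(cat32$resolvable[match(res, cat32$code)]))
    }
    # rebuild the capped state sequence from the events
    t_end <- max(p$times, 1e-9) + 1e-9
    died <- p$states[length(p$states)] == 5L
    cnt_at <- function(t) {
      sum(ev$onset_time <= t &
            (is.na(ev$resolve_time) | ev$resolve_time > t))
    }
    probe <- c(0, p$times[-1] + 1e-12)
    rebuilt <- vapply(probe, function(t) count_to_state(cnt_at(t)), 1L)
    want <- p$states
    if (died) rebuilt[length(rebuilt)] <- 5L
    expect_equal(rebuilt, want)
  }
})

test_that("a path with explicit moves renders one event per move", {
  path <- list(times = c(0, 2.0, 3.5), states = c(2L, 3L, 2L))
  set.seed(4)
  ev <- render_events(path, default_catalogue())
  expect_equal(nrow(ev), 2L)          # 1 prior onset + 1 in-window onset
  expect_equal(sum(ev$onset_time == 2.0), 1L)
  expect_equal(sum(!is.na(ev$resolve_time)), 1L)
  expect_equal(ev$resolve_time[!is.na(ev$resolve_time)], 3.5)
  # no-move path: only the prior onsets
  ev0 <- render_events(list(times = 0, states = 3L), default_catalogue())
  expect_equal(nrow(ev0), 2L)
  expect_true(all(ev0$onset_time < 0))
})

test_that("without resolution or death intensities nobody remits", {
  m <- intensity_model(c("S0->S1" = 0.3, "S1->S2" = 0.3, "S2->S3plus" = 0.3))
  cfg <- cohort_config(300, seed = 17, truth = m)
  co <- simulate_cohort(cfg)
  h <- build_cohort_histories(co$patients, co$events)
  cl <- classify_cohort(h)
  expect_true(all(cl$class %in% c("Stable", "Progressed")))
  expect_false(any(co$patients$died))
})

test_that("median follow-up lands within 10 percent of the configured target", {
  cfg <- cohort_config(4000, seed = 31)
  co <- simulate_cohort(cfg)
  fup <- as.numeric(co$patients$follow_up_end -
                      co$patients$follow_up_start) / 365.25
  expect_lt(abs(stats::median(fup) - 4.2) / 4.2, 0.10)
  # initial-state distribution tracks the configured probabilities
  h <- build_cohort_histories(co$patients, co$events)
  start_state <- vapply(h, function(x) count_to_state(x$start_ltc), 1L)
  frac <- as.numeric(table(factor(start_state, levels = 1:4))) / 4000
  expect_lt(max(abs(frac - c(0.76, 0.15, 0.05, 0.04))), 0.03)
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(0), "positive")
  expect_error(cohort_config(10, initial_state_probs = c(0.5, 0.5, 0.1, 0)),
               "sum to 1")
  cv <- default_covariate_prevalences()
  cv$sex <- c(Male = 0.6, Female = 0.5)
  expect_error(cohort_config(10, covariates = cv), "sum to 1")
})
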