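mk_chain_cohort <- function() {
  patients <- data.frame(
    patient_id = c("p1", "p2", "p3"),
    follow_up_start = as.Date("2010-01-01"),
    follow_up_end = as.Date("2016-01-01"),
    died = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  events <- data.frame(
    patient_id = c("p1", "p1", "p2", "p3", "p3"),
    condition = c("diabetes_t2", "hypertension", "asthma",
                  "anxiety", "depression"),
    onset_date = as.Date(c("2010-06-01", "2012-07-01", "2011-01-01",
                           "2013-03-03", "2013-03-03")),
    resolve_date = as.Date(NA),
    stringsAsFactors = FALSE
  )
  list(patients = patients, events = events)
}

test_that("sequences order onsets by date, break ties alphabetically, append Death", {
  co <- mk_chain_cohort()
  seqs <- build_sequences(co$patients, co$events)
  expect_equal(seqs$p1, c("diabetes_t2", "hypertension", "Death"))
  expect_equal(seqs$p2, "asthma")        # single onset, censored
  expect_equal(seqs$p3, c("anxiety", "depression"))  # same-day tie: a < d
  # permutation invariance to event row order
  shuf <- co$events[c(4, 2, 5, 1, 3), , drop = FALSE]
  expect_equal(build_sequences(co$patients, shuf), seqs)
})

test_that("re-acquired conditions keep only their first onset", {
  p <- data.frame(patient_id = "p", follow_up_start = as.Date("2010-01-01"),
                  follow_up_end = as.Date("2016-01-01"), died = FALSE)
  e <- data.frame(patient_id = "p",
                  condition = c("asthma", "ckd", "asthma"),
                  onset_date = as.Date(c("2011-01-01", "2012-01-01",
                                         "2013-01-01")),
                  resolve_date = as.Date(c("2011-06-01", NA, NA)))
  seqs <- build_sequences(p, e)
  expect_equal(seqs$p, c("asthma", "ckd"))
  ch <- estimate_chain(seqs)
  expect_true(all(diag(ch$counts) == 0))
})

test_that("chain probabilities equal brute-force pair counts", {
  seqs <- list(p1 = c("aaa", "bbb"), p2 = c("aaa", "ccc"),
               p3 = c("aaa", "bbb"))
  ch <- estimate_chain(seqs, toy_catalogue())
  expect_equal(ch$probs["aaa", "bbb"], 2 / 3)
  expect_equal(ch$probs["aaa", "ccc"], 1 / 3)
  expect_equal(ch$counts["aaa", "bbb"], 2)
  # count conservation: sum = sum over patients of (length - 1)
  expect_equal(sum(ch$counts), sum(vapply(seqs, length, 0) - 1))
  # single sequence into death
  chd <- estimate_chain(list(p = c("aaa", "Death")), toy_catalogue())
  expect_equal(chd$probs["aaa", "Death"], 1)
  expect_true(all(chd$probs["Death", ] == 0))
  # every non-empty row is a probability vector
  rs <- rowSums(ch$probs)
  expect_true(all(abs(rs[!ch$empty_rows] - 1) < 1e-12))
  expect_true(all(rs[ch$empty_rows] == 0))
})

test_that("top-k selection honours ties at k and drops zeros", {
  cat5 <- data.frame(code = c("b", "c", "d", "e", "f"),
                     name = LETTERS[2:6], resolvable = FALSE, cluster = "A")
  ch <- structure(list(
    labels = c(cat5$code, "Death"),
    counts = matrix(0, 6, 6, dimnames = list(c(cat5$code, "Death"),
                                             c(cat5$code, "Death"))),
    probs = matrix(0, 6, 6, dimnames = list(c(cat5$code, "Death"),
                                            c(cat5$code, "Death"))),
    empty_rows = rep(FALSE, 6)), class = "sequence_chain")
  # tie at the 3rd value: four entries returned
  ch$probs["b", c("c", "d", "e", "f")] <- c(0.5, 0.3, 0.1, 0.1)
  # zeros shorten the list
  ch$probs["c", "d"] <- 0.4
  sel <- select_top(ch, 3)
  expect_equal(sel$b$consequents$condition, c("c", "d", "e", "f"))
  expect_equal(sel$c$consequents$condition, "d")
  expect_equal(nrow(sel$d$consequents), 0L)     # all-zero row
  expect_error(select_top(ch, 0), "k must be")
  # all-distinct probabilities return exactly k
  ch$probs["e", c("b", "c", "d", "f")] <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(nrow(select_top(ch, 3)$e$consequents), 3L)
})

test_that("the report carries cluster labels and prevalence and is order-invariant", {
  co <- mk_chain_cohort()
  res <- chain_analysis(co$patients, co$events)
  rp <- res$report
  expect_equal(nrow(rp), 33L)   # 32 conditions + Death
  expect_equal(rp$cluster[rp$condition == "anxiety"], "A")
  expect_equal(rp$prevalence[rp$condition == "asthma"], 1 / 3)
  expect_equal(rp$consequents[rp$condition == "diabetes_t2"],
               "hypertension (1.000)")
  shuf <- co$events[sample(nrow(co$events)), , drop = FALSE]
  expect_equal(chain_analysis(co$patients, shuf)$report, rp)
  # empty cohort gives an empty-but-shaped report
  res0 <- chain_analysis(co$patients[0, , drop = FALSE],
                         co$events[0, , drop = FALSE])
  expect_equal(nrow(res0$report), 33L)
  expect_true(all(res0$report$antecedents == ""))
})

test_that("cluster-weighted simulation recovers same-cluster succession", {
  # moderate cohort: the top consequent of most conditions shares their
  # cluster (the full-scale check lives in the acceptance suite)
  cfg <- cohort_config(3000, seed = 23)
  co <- simulate_cohort(cfg)
  res <- chain_analysis(co$patients, co$events)
  cat32 <- default_catalogue()
  cl <- stats::setNames(cat32$cluster, cat32$code)
  hits <- 0; tot <- 0
  for (code in cat32$code) {
    cons <- res$selection[[code]]$consequents
    cons <- cons[cons$condition != "Death", , drop = FALSE]
    if (!nrow(cons)) next
    tot <- tot + 1
    hits <- hits + (cl[cons$condition[1]] == cl[code])
  }
  expect_gt(hits / tot, 0.6)
})

test_that("stratified chain analysis runs per level", {
  cfg <- cohort_config(400, seed = 29)
  co <- simulate_cohort(cfg)
  res <- chain_analysis(co$patients, co$events, by = "sex")
  expect_setequal(names(res), c("Male", "Female"))
  for (r in res) expect_s3_class(r$chain, "sequence_chain")
})
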