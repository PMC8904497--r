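# a bet table with 5 no-brainers per setting for threshold tests
qc_bet_table <- function() {
  base <- mini_bet_table()
  extra <- purrr::map_dfr(1:4, function(j) {
    nb <- dplyr::filter(base, is_no_brainer)
    nb$couple_index <- nb$couple_index + 10L * j
    nb
  })
  dplyr::arrange(dplyr::bind_rows(base, extra), setting, couple_index)
}

respondent_with <- function(id, bets, n_correct_add, n_correct_mult,
                            group = "control") {
  s <- all_safer_spec(id, group, bets)
  nb <- dplyr::filter(bets, is_no_brainer)
  for (setting in c("additive", "multiplicative")) {
    idx <- as.character(nb$couple_index[nb$setting == setting])
    k <- if (setting == "additive") n_correct_add else n_correct_mult
    s$nb_correct[idx] <- c(rep(TRUE, k), rep(FALSE, length(idx) - k))
  }
  s
}

test_that("the 3-of-5 threshold is inclusive and applies per setting", {
  bets <- qc_bet_table()
  resp <- build_responses(bets, list(
    respondent_with("A", bets, 3, 3), # boundary pass
    respondent_with("B", bets, 5, 2), # fails one setting
    respondent_with("C", bets, 2, 5), # fails the other
    respondent_with("D", bets, 5, 5) # clean pass
  ))
  qc <- apply_filter(resp)
  expect_equal(sort(unique(qc$retained$respondent_id)), c("A", "D"))
  expect_equal(qc$report$n_initial, 4)
  expect_equal(qc$report$n_retained, 2)
  expect_equal(qc$report$frac_correct_all, (6 + 7 + 7 + 10) / 40)
  expect_equal(qc$report$frac_correct_retained, (6 + 10) / 20)
})

test_that("the filter is idempotent and monotone in correctness", {
  bets <- qc_bet_table()
  resp <- build_responses(bets, list(
    respondent_with("A", bets, 3, 4),
    respondent_with("B", bets, 2, 2),
    respondent_with("C", bets, 4, 5)
  ))
  qc1 <- apply_filter(resp)
  qc2 <- apply_filter(qc1$retained)
  expect_identical(qc1$retained, qc2$retained)

  # raising any respondent's correct count never flips retained -> excluded
  base_retained <- unique(qc1$retained$respondent_id)
  resp_up <- build_responses(bets, list(
    respondent_with("A", bets, 4, 4), # A improved
    respondent_with("B", bets, 2, 2),
    respondent_with("C", bets, 4, 5)
  ))
  up_retained <- unique(apply_filter(resp_up)$retained$respondent_id)
  expect_true(all(base_retained %in% up_retained))
})

test_that("cohort retention matches the exact binomial tail probability", {
  # with per-answer correctness 0.78, retention is P(Bin(5, .78) >= 3)^2
  p_pass <- sum(dbinom(3:5, 5, 0.78))
  target <- p_pass^2
  bets <- generate_bet_table(seed = 42)
  retained <- 0
  n_total <- 0
  for (s in 1:8) {
    cfg <- experiment_config(n_respondents = 50, seed = 100 + s)
    qc <- apply_filter(simulate_responses(bets, cfg))
    retained <- retained + qc$report$n_retained
    n_total <- n_total + qc$report$n_initial
  }
  se <- sqrt(target * (1 - target) / n_total)
  expect_lt(abs(retained / n_total - target), 3 * se)
})

test_that("cumulative time summaries reproduce a hand computation", {
  bets <- mini_bet_table()
  resp <- build_responses(bets, list(
    all_safer_spec("T1", "timed", bets, time = 2), # 6 couples x 2 s = 12 s
    all_safer_spec("T2", "timed", bets, time = 4), # 24 s
    all_safer_spec("T3", "timed", bets, time = 6), # 36 s
    all_safer_spec("C1", "control", bets, time = 5) # 30 s
  ))
  st <- summarize_times(resp)
  expect_equal(sort(st$totals$total_s), c(12, 24, 30, 36))
  by_group <- st$by_group
  expect_equal(by_group$median_s[by_group$group == "timed"], 24)
  # single respondent: the median is that respondent's total
  expect_equal(by_group$median_s[by_group$group == "control"], 30)
})

test_that("missing no-brainer answers error in strict mode", {
  bets <- mini_bet_table()
  resp <- build_responses(bets, list(all_safer_spec("A", "timed", bets)))
  # drop A's additive no-brainer rows entirely
  resp <- dplyr::filter(
    resp, !(is.na(chose_safer) & setting == "additive")
  )
  expect_error(apply_filter(resp), "missing no-brainer")
  qc <- apply_filter(resp, strict = FALSE)
  expect_equal(qc$report$n_retained, 0)
})
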