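test_that("two-stage updating collapses to the conjugate closed form", {
  set.seed(5)
  fit <- fit_couple(30, 40)
  expect_equal(fit$alpha, 30.5)
  expect_equal(fit$beta, 10.5)
  expect_equal(fit$mean, 30.5 / 41)
  expect_equal(fit$sd, sqrt(30.5 * 10.5 / (41^2 * 42)))

  # split and ordering are irrelevant: spot-check a (k, n) grid
  for (n in c(1, 2, 7, 40, 81)) {
    for (k in unique(c(0, 1, n %/% 2, n))) {
      f <- fit_couple(k, n, split_fraction = runif(1, 0.1, 0.9))
      expect_identical(unname(c(f$alpha, f$beta)), c(0.5 + k, 0.5 + n - k))
    }
  }
  expect_warning(f0 <- fit_couple(0, 0), "Jeffreys")
  expect_equal(f0$mean, 0.5)
})

test_that("per-couple estimates count safer choices per group and setting", {
  bets <- mini_bet_table()
  resp <- build_responses(bets, list(
    all_safer_spec("T1", "timed", bets),
    all_safer_spec("T2", "timed", bets),
    all_safer_spec("C1", "control", bets)
  ))
  # flip one of T2's choices to riskier
  resp$chose_safer[resp$respondent_id == "T2" & resp$couple_index == 1] <- 0L
  est <- estimate_couples(resp)
  expect_equal(nrow(est), 4 * 2) # 4 scored couples x 2 groups
  row <- dplyr::filter(est, group == "timed", couple_index == 1)
  expect_equal(row$k, 1)
  expect_equal(row$n, 2)
  expect_equal(row$alpha, 1.5)
  # no-brainers never enter estimation
  expect_false(any(est$couple_index %in% c(3, 6)))
})

test_that("aggregation averages means and propagates sds under independence", {
  est <- tibble::tibble(
    group = "timed", setting = "multiplicative",
    couple_index = 1:4, k = 1, n = 2,
    alpha = 1, beta = 1,
    mean = c(0.4, 0.5, 0.6, 0.7), sd = c(0.1, 0.1, 0.2, 0.2)
  )
  agg <- aggregate_settings(est)
  expect_equal(agg$p_s, 0.55)
  expect_equal(agg$sd_s, sqrt(sum(c(0.01, 0.01, 0.04, 0.04))) / 4)
  # single couple: the aggregate is that couple
  agg1 <- aggregate_settings(est[1, ])
  expect_equal(agg1$p_s, 0.4)
  expect_equal(agg1$sd_s, 0.1)
  # m identical couples: the classic sigma/sqrt(m) scaling
  est_same <- dplyr::mutate(est, mean = 0.5, sd = 0.3)
  expect_equal(aggregate_settings(est_same)$sd_s, 0.3 / sqrt(4))
  # p_s always within the range of the per-couple means
  expect_true(agg$p_s >= min(est$mean) && agg$p_s <= max(est$mean))
})

test_that("aggregation reproduces Monte-Carlo sampling of the posteriors", {
  set.seed(23)
  est <- tibble::tibble(
    group = "timed", setting = "additive", couple_index = 1:6,
    k = 0, n = 0, alpha = c(10, 20, 5, 8, 30, 12.5),
    beta = c(10, 10, 15, 8, 5, 12.5)
  )
  est$mean <- est$alpha / (est$alpha + est$beta)
  est$sd <- sqrt(est$alpha * est$beta /
    ((est$alpha + est$beta)^2 * (est$alpha + est$beta + 1)))
  agg <- aggregate_settings(est)
  draws <- replicate(20000, {
    mean(rbeta(6, est$alpha, est$beta))
  })
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - agg$p_s), 3 * se)
  expect_lt(abs(sd(draws) - agg$sd_s) / agg$sd_s, 0.05)
})

test_that("the one-sided z-test matches the normal-CDF oracle", {
  est <- tibble::tibble(
    group = rep(c("timed", "control"), each = 1),
    setting = "multiplicative", couple_index = 1,
    k = 1, n = 2, alpha = 1, beta = 1,
    mean = c(0.60, 0.56), sd = c(0.01, 0.01)
  )
  cmp <- compare_groups(est)
  expect_equal(cmp$z, 4 / sqrt(2), tolerance = 1e-12)
  expect_equal(cmp$p_one_sided, pnorm(4 / sqrt(2), lower.tail = FALSE))
  expect_equal(cmp$p_one_sided, 0.00234, tolerance = 1e-2)

  # identical estimates: z = 0, p = 0.5
  est_same <- dplyr::mutate(est, mean = 0.5, sd = 0.02)
  cmp0 <- compare_groups(est_same)
  expect_equal(cmp0$z, 0)
  expect_equal(cmp0$p_one_sided, 0.5)

  # flipped alternative negates z
  cmp_flip <- compare_groups(est, alternative = "control_greater")
  expect_equal(cmp_flip$z, -cmp$z)

  est_degenerate <- dplyr::mutate(est, sd = 0)
  expect_error(compare_groups(est_degenerate), "degenerate")
})

test_that("posterior normality checks behave as the beta shapes dictate", {
  # a moderate-count posterior is only mildly skewed: at 100 draws the
  # Shapiro-Wilk test typically retains normality, while the U-shaped
  # Jeffreys prior is rejected decisively at every seed
  near_p <- sapply(1:20, function(s) {
    check_normality(30.5, 10.5, n_draws = 100, seed = s)$shapiro_p
  })
  expect_gt(median(near_p), 0.05)
  u_p <- sapply(1:20, function(s) {
    check_normality(0.5, 0.5, n_draws = 100, seed = s)$shapiro_p
  })
  expect_lt(max(u_p), 1e-4)
  u_shaped <- check_normality(0.5, 0.5, n_draws = 500, seed = 1)
  expect_lt(u_shaped$jarque_bera_p, 0.01)
  expect_identical(
    check_normality(30.5, 10.5, seed = 7),
    check_normality(30.5, 10.5, seed = 7)
  )
})

test_that("Jarque-Bera matches the moment formula on a fixed sample", {
  set.seed(9)
  x <- rnorm(200)
  jb <- ergochoice:::jarque_bera(x)
  n <- length(x)
  s <- mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5
  k <- mean((x - mean(x))^4) / mean((x - mean(x))^2)^2
  expect_equal(jb$statistic, n / 6 * (s^2 + (k - 3)^2 / 4))
  expect_gt(jb$p.value, 0.05)
})

test_that("Mann-Whitney agrees with exhaustive permutation enumeration", {
  # closed textbook case: complete separation of {1,2,3} and {4,5,6}
  res <- response_time_test(
    timed_totals = c(1, 2, 3), control_totals = c(4, 5, 6)
  )
  expect_equal(unname(res$u), 0)
  expect_equal(res$p_value, 0.1) # 2/20 arrangements as extreme

  # random small samples vs brute force over all group assignments
  set.seed(41)
  for (rep in 1:10) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    x <- sample(seq_len(50), n1 + n2) # distinct values: no ties
    obs_u <- sum(outer(x[1:n1], x[(n1 + 1):(n1 + n2)], ">"))
    combos <- utils::combn(n1 + n2, n1)
    us <- apply(combos, 2, function(idx) {
      sum(outer(x[idx], x[-idx], ">"))
    })
    mu <- n1 * n2 / 2
    p_exact <- mean(abs(us - mu) >= abs(obs_u - mu))
    res <- response_time_test(
      timed_totals = x[1:n1], control_totals = x[(n1 + 1):(n1 + n2)]
    )
    expect_equal(unname(res$u), obs_u)
    expect_equal(res$p_value, p_exact)
  }
})

test_that("standardized ranking replays shared coin flips deterministically", {
  bets <- mini_bet_table()
  resp <- build_responses(bets, list(
    all_safer_spec("A", "timed", bets),
    all_safer_spec("B", "control", bets)
  ))
  rk <- standardized_ranking(resp, bets, seed = 6)
  # identical choices tie at identical capital
  expect_equal(rk$final_capital[1], rk$final_capital[2])
  expect_equal(rk$rank, c(1L, 1L))

  # hand computation on a two-couple table with forced flips
  two <- bets[c(1, 4), ] # one scored couple per setting
  one <- build_responses(two, list(list(
    id = "Z", group = "timed",
    chose_safer = c(`1` = 1L, `4` = 0L),
    nb_correct = list()
  )))
  set.seed(12)
  flips <- runif(2) < 0.5 # the flips standardized_ranking(seed = 12) will draw
  rk1 <- standardized_ranking(one, two, seed = 12)
  a_draw <- if (flips[1]) two$safer_lo[1] else two$safer_hi[1]
  m_draw <- if (flips[2]) two$riskier_lo[2] else two$riskier_hi[2]
  expect_equal(rk1$final_capital, (1000 + a_draw) * m_draw)

  # permuting respondent order never changes anyone's capital
  resp_perm <- dplyr::arrange(resp, dplyr::desc(respondent_id))
  rk2 <- standardized_ranking(resp_perm, bets, seed = 6)
  expect_equal(
    dplyr::arrange(rk, respondent_id)$final_capital,
    dplyr::arrange(rk2, respondent_id)$final_capital
  )

  expect_error(
    standardized_ranking(resp[-1, ], bets, seed = 6),
    "every couple"
  )
})

test_that("posterior credible intervals recover known choice probabilities", {
  set.seed(61)
  n_per_group <- 50
  covered <- 0
  total <- 0
  for (rep in 1:10) {
    p_true <- runif(70, 0.2, 0.8)
    k <- rbinom(70, n_per_group, p_true)
    for (i in 1:70) {
      f <- fit_couple(k[i], n_per_group)
      lo <- qbeta(0.025, f$alpha, f$beta)
      hi <- qbeta(0.975, f$alpha, f$beta)
      covered <- covered + (p_true[i] >= lo && p_true[i] <= hi)
      total <- total + 1
    }
  }
  se <- sqrt(0.95 * 0.05 / total)
  expect_gt(covered / total, 0.95 - 3 * se)
})
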