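#' Two-stage Jeffreys-prior posterior for one bet couple
#'
#' Estimates the probability `p_i` of taking the safer bet in couple `i`
#' from `k` safer choices in `n` answers. Updating is naive-Bayes in two
#' stages: a randomly chosen `split_fraction` of the Bernoulli observations
#' updates the Jeffreys prior Beta(1/2, 1/2) in one conjugate step, forming
#' an informed prior; the remaining observations are then added one at a
#' time. By conjugacy the final posterior is Beta(1/2 + k, 1/2 + n - k)
#' whatever the split or ordering — the procedure is retained because it is
#' the estimation protocol being modelled, and the invariance is checkable.
#'
#' @param k number of safer (risk-averse) choices.
#' @param n number of answers; `n = 0` returns the bare Jeffreys prior with
#'   a warning.
#' @param split_fraction fraction of observations used in the first stage.
#' @return A one-row tibble with `alpha`, `beta`, `mean`, `sd`, `k`, `n`.
#' @examples
#' fit_couple(30, 40) # Beta(30.5, 10.5), mean about 0.744
#' @export
fit_couple <- function(k, n, split_fraction = 0.8) {
  stopifnot(length(k) == 1, length(n) == 1, k >= 0, n >= 0, k <= n,
    split_fraction > 0, split_fraction < 1
  )
  if (n == 0) {
    rlang::warn("no observations: returning the Jeffreys prior")
    return(posterior_row(0.5, 0.5, 0L, 0L))
  }
  obs <- sample(c(rep(1L, k), rep(0L, n - k))) # random 80/20 partition
  n1 <- floor(split_fraction * n)
  stage1 <- obs[seq_len(n1)]
  alpha <- 0.5 + sum(stage1)
  beta <- 0.5 + n1 - sum(stage1)
  for (x in obs[setdiff(seq_len(n), seq_len(n1))]) {
    alpha <- alpha + x # iterative one-observation updates
    beta <- beta + 1L - x
  }
  posterior_row(alpha, beta, as.integer(k), as.integer(n))
}

posterior_row <- function(alpha, beta, k, n) {
  # new_tibble keeps this cheap: fit_couple is called tens of thousands of
  # times in grid sweeps
  tibble::new_tibble(
    list(
      alpha = alpha, beta = beta,
      mean = alpha / (alpha + beta),
      sd = sqrt(alpha * beta / ((alpha + beta)^2 * (alpha + beta + 1))),
      k = k, n = n
    ),
    nrow = 1L
  )
}

#' Per-couple posterior estimates for a response table
#'
#' Counts safer choices per couple within each group and setting (scored
#' couples only; no-brainers never enter estimation) and fits the
#' two-stage Jeffreys posterior to each count.
#'
#' @param responses a (typically QC-filtered) response tibble.
#' @param split_fraction passed to [fit_couple()].
#' @return A tibble of class `couple_estimates`: one row per
#'   group x setting x couple with the posterior parameters and moments.
#' @export
estimate_couples <- function(responses, split_fraction = 0.8) {
  check_responses(responses)
  scored <- dplyr::filter(responses, !is.na(.data$chose_safer))
  if (nrow(scored) == 0) {
    rlang::abort("no scored responses to estimate from")
  }
  counts <- scored |>
    dplyr::group_by(.data$group, .data$setting, .data$couple_index) |>
    dplyr::summarise(
      k = sum(.data$chose_safer), n = dplyr::n(),
      .groups = "drop"
    )
  fits <- purrr::map2_dfr(
    counts$k, counts$n,
    ~ fit_couple(.x, .y, split_fraction = split_fraction)[c(
      "alpha", "beta", "mean", "sd"
    )]
  )
  out <- dplyr::bind_cols(counts, fits)
  class(out) <- c("couple_estimates", class(out))
  out
}

#' Aggregate per-couple posteriors into a setting-level estimate
#'
#' The setting-level probability of taking the safer bet is the unweighted
#' mean of the per-couple posterior means; its uncertainty propagates the
#' per-couple posterior standard deviations assuming independence across
#' couples: `sd_s = sqrt(sum(sd_i^2)) / m`.
#'
#' @param estimates a `couple_estimates` tibble (any subset; rows must not
#'   mix settings within a group).
#' @return A tibble with one row per group x setting: `p_s`, `sd_s`,
#'   `m_couples`.
#' @export
aggregate_settings <- function(estimates) {
  stopifnot(all(c("group", "setting", "mean", "sd") %in% names(estimates)))
  estimates |>
    dplyr::group_by(.data$group, .data$setting) |>
    dplyr::summarise(
      p_s = mean(.data$mean),
      sd_s = sqrt(sum(.data$sd^2)) / dplyr::n(),
      m_couples = dplyr::n(),
      .groups = "drop"
    )
}

#' One-sided z-test comparing timed against control respondents
#'
#' For each setting, tests H0: `p_timed <= p_control` against the
#' alternative that timed respondents are more risk-averse, using the
#' aggregated setting-level estimates:
#' `z = (p_timed - p_control) / sqrt(sd_timed^2 + sd_control^2)` with an
#' upper-tail standard-normal p-value (no small-sample correction). The
#' direction of the alternative can be flipped.
#'
#' @param estimates a `couple_estimates` tibble covering both groups.
#' @param alternative `"timed_greater"` (default) or `"control_greater"`.
#' @return A tibble of class `group_comparison`: one row per setting with
#'   the two aggregated estimates, `z` and `p_one_sided`.
#' @export
compare_groups <- function(estimates, alternative = c(
                             "timed_greater", "control_greater"
                           )) {
  alternative <- match.arg(alternative)
  agg <- aggregate_settings(estimates)
  wide <- tidyr::pivot_wider(agg,
    names_from = "group",
    values_from = c("p_s", "sd_s", "m_couples")
  )
  if (!all(c("p_s_timed", "p_s_control") %in% names(wide))) {
    rlang::abort("both a timed and a control group are required")
  }
  pooled_sd <- sqrt(wide$sd_s_timed^2 + wide$sd_s_control^2)
  if (any(pooled_sd == 0)) {
    rlang::abort("degenerate comparison: pooled posterior sd is zero")
  }
  z <- (wide$p_s_timed - wide$p_s_control) / pooled_sd
  if (alternative == "control_greater") z <- -z
  out <- dplyr::mutate(wide,
    z = z,
    p_one_sided = stats::pnorm(z, lower.tail = FALSE),
    alternative = alternative
  )
  class(out) <- c("group_comparison", class(out))
  out
}

#' Normality checks on a beta posterior
#'
#' Draws samples from the Beta(alpha, beta) posterior and applies the
#' Shapiro-Wilk and Jarque-Bera tests. Posteriors with moderate counts are
#' approximately normal; the bare Jeffreys prior (U-shaped) is not.
#'
#' @param alpha,beta beta parameters of the posterior.
#' @param n_draws number of posterior draws (at least 20).
#' @param seed optional seed for the draws.
#' @return A one-row tibble with both statistics and p-values.
#' @export
check_normality <- function(alpha, beta, n_draws = 500, seed = NULL) {
  stopifnot(alpha > 0, beta > 0, n_draws >= 20)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rbeta(n_draws, alpha, beta)
  sw <- stats::shapiro.test(x)
  jb <- jarque_bera(x)
  tibble::tibble(
    shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
    jarque_bera_stat = jb$statistic, jarque_bera_p = jb$p.value
  )
}

# Jarque-Bera statistic n/6 (S^2 + (K - 3)^2 / 4) with a chi-squared(2)
# reference distribution.
jarque_bera <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  skew <- mean((x - m)^3) / s2^1.5
  kurt <- mean((x - m)^4) / s2^2
  stat <- n / 6 * (skew^2 + (kurt - 3)^2 / 4)
  list(statistic = stat, p.value = stats::pchisq(stat, df = 2, lower.tail = FALSE))
}

#' Mann-Whitney comparison of cumulative response times
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of the per-respondent
#' cumulative response times of the timed against the control group, with
#' R's standard exact/normal-approximation switch (exact for small
#' tie-free samples, otherwise the normal approximation with tie
#' correction). Group medians are reported alongside.
#'
#' @param responses a response tibble; alternatively supply `timed_totals`
#'   and `control_totals` directly.
#' @param timed_totals,control_totals optional numeric vectors of
#'   cumulative seconds, overriding `responses`.
#' @return A one-row tibble with `u`, `p_value`, `median_timed`,
#'   `median_control`, `n_timed`, `n_control`.
#' @export
response_time_test <- function(responses = NULL, timed_totals = NULL,
                               control_totals = NULL) {
  if (is.null(timed_totals) || is.null(control_totals)) {
    totals <- summarize_times(responses)$totals
    timed_totals <- totals$total_s[totals$group == "timed"]
    control_totals <- totals$total_s[totals$group == "control"]
  }
  stopifnot(length(timed_totals) >= 2, length(control_totals) >= 2)
  wt <- stats::wilcox.test(timed_totals, control_totals,
    alternative = "two.sided"
  )
  tibble::tibble(
    u = unname(wt$statistic),
    p_value = wt$p.value,
    median_timed = stats::median(timed_totals),
    median_control = stats::median(control_totals),
    n_timed = length(timed_totals),
    n_control = length(control_totals)
  )
}

#' Standardized final-capital ranking
#'
#' Replays every respondent's 80 stated choices against one shared set of
#' coin flips (one 50/50 draw per couple) in a standardized couple order:
#' the additive block is applied first (chosen outcomes added to the 1000
#' starting capital), then the multiplicative block (chosen factors
#' multiplied in). Because flips and order are shared, final capital
#' differences reflect choices alone.
#'
#' @param responses a response tibble with a choice for every couple of
#'   `bet_table` for every respondent (no-brainer rows use the
#'   `nobrainer_correct` flag: correct means the dominant bet was picked).
#' @param bet_table the bet table that was answered.
#' @param start_capital common starting capital.
#' @param seed seed for the shared coin flips.
#' @return A tibble with `respondent_id`, `group`, `final_capital` and
#'   dense `rank` (1 = highest capital), sorted by rank.
#' @export
standardized_ranking <- function(responses, bet_table,
                                 start_capital = 1000, seed = NULL) {
  check_responses(responses)
  check_bet_table(bet_table)
  if (!is.null(seed)) set.seed(seed)

  # one shared flip per couple: TRUE = the `lo` outcome comes up
  flips <- tibble::tibble(
    couple_index = bet_table$couple_index,
    flip_lo = stats::runif(nrow(bet_table)) < 0.5
  )

  tab <- dplyr::inner_join(responses, bet_table, by = c(
    "couple_index", "setting"
  )) |>
    dplyr::inner_join(flips, by = "couple_index")
  expected <- nrow(bet_table) * dplyr::n_distinct(responses$respondent_id)
  if (nrow(tab) != expected) {
    rlang::abort("every respondent must have a choice for every couple")
  }

  chose_safer <- ifelse(
    is.na(tab$chose_safer), as.integer(tab$nobrainer_correct), tab$chose_safer
  )
  tab$outcome <- ifelse(
    chose_safer == 1L,
    ifelse(tab$flip_lo, tab$safer_lo, tab$safer_hi),
    ifelse(tab$flip_lo, tab$riskier_lo, tab$riskier_hi)
  )

  # standardized order: additive block first, couples by index
  capitals <- tab |>
    dplyr::arrange(
      .data$respondent_id,
      .data$setting != "additive", .data$couple_index
    ) |>
    dplyr::group_by(.data$respondent_id, .data$group) |>
    dplyr::summarise(
      final_capital = {
        add <- sum(.data$outcome[.data$setting == "additive"])
        mult <- prod(.data$outcome[.data$setting == "multiplicative"])
        (start_capital + add) * mult
      },
      .groups = "drop"
    )
  capitals |>
    dplyr::arrange(dplyr::desc(.data$final_capital)) |>
    dplyr::mutate(rank = dplyr::dense_rank(dplyr::desc(.data$final_capital)))
}
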