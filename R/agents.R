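#' Specify a synthetic respondent's decision model
#'
#' A synthetic respondent scores each bet of a couple with a decision value
#' and chooses by a logistic (softmax) rule over the two values. Available
#' models:
#'
#' * `ev_indifferent` — scores by expected value; equal-expected-value
#'   couples therefore get identical scores and choices are coin flips at
#'   any temperature.
#' * `time_average_optimizer` — scores by time-average growth, so in the
#'   multiplicative setting the safer bet gets a strictly higher score
#'   while additive couples remain ties.
#' * `isoelastic` — expected isoelastic utility
#'   `u(x) = (x^(1 - eta) - 1)/(1 - eta)` (`ln x` at `eta = 1`) of
#'   end-of-round wealth, evaluated at a fixed reference wealth
#'   (the 1000 starting capital; respondents receive no capital updates,
#'   so there is no within-experiment wealth dynamic to track).
#'
#' No-brainer couples are not scored: the agent answers them correctly with
#' probability `1 - nobrainer_error_rate`.
#'
#' @param model one of `"ev_indifferent"`, `"time_average_optimizer"`,
#'   `"isoelastic"`.
#' @param eta relative risk aversion, used only by the isoelastic model.
#' @param temperature positive softmax noise scale, in the units of the
#'   decision values (currency for additive expected values, log growth
#'   per round for multiplicative time averages).
#' @param nobrainer_error_rate probability in `[0, 0.5)` of answering a
#'   no-brainer incorrectly.
#' @param reference_wealth wealth at which isoelastic utilities are
#'   evaluated.
#' @return A list of class `agent_spec`.
#' @export
agent_spec <- function(model = c(
                         "ev_indifferent", "time_average_optimizer",
                         "isoelastic"
                       ),
                       eta = 1, temperature = 0.05,
                       nobrainer_error_rate = 0.22,
                       reference_wealth = 1000) {
  model <- match.arg(model)
  stopifnot(
    temperature > 0,
    nobrainer_error_rate >= 0, nobrainer_error_rate < 0.5,
    reference_wealth > 0
  )
  structure(
    list(
      model = model, eta = eta, temperature = temperature,
      nobrainer_error_rate = nobrainer_error_rate,
      reference_wealth = reference_wealth
    ),
    class = "agent_spec"
  )
}

isoelastic_u <- function(x, eta) {
  if (any(x <= 0)) {
    rlang::abort("isoelastic utility needs strictly positive wealth")
  }
  if (abs(eta - 1) < 1e-12) log(x) else (x^(1 - eta) - 1) / (1 - eta)
}

#' Score a bet under an agent's decision model
#'
#' @param agent an [agent_spec()].
#' @param lo,hi the bet's outcomes (vectorised).
#' @param setting `"additive"` or `"multiplicative"`.
#' @return Numeric vector of decision values; only differences between the
#'   two bets of a couple matter for choice.
#' @export
decision_value <- function(agent, lo, hi, setting) {
  stopifnot(inherits(agent, "agent_spec"))
  setting <- check_dynamic(setting)
  switch(agent$model,
    ev_indifferent = ensemble_ev(lo, hi, setting),
    time_average_optimizer = time_avg_growth(lo, hi, setting),
    isoelastic = {
      w <- agent$reference_wealth
      w_lo <- if (setting == "additive") w + lo else w * lo
      w_hi <- if (setting == "additive") w + hi else w * hi
      (isoelastic_u(w_lo, agent$eta) + isoelastic_u(w_hi, agent$eta)) / 2
    }
  )
}

#' Closed-form probability that an agent picks the safer bet
#'
#' Logistic choice over the two decision values:
#' `plogis((v_safer - v_riskier) / temperature)`. Returned per couple;
#' no-brainer rows get `NA` (they are answered by the correctness rule, not
#' by the softmax).
#'
#' @param bet_table a bet table (see [generate_bet_table()]).
#' @param agent an [agent_spec()].
#' @return The table with an added `p_safer` column.
#' @export
choice_prob <- function(bet_table, agent) {
  check_bet_table(bet_table)
  v_s <- numeric(nrow(bet_table))
  v_r <- numeric(nrow(bet_table))
  for (setting in c("additive", "multiplicative")) {
    idx <- bet_table$setting == setting
    if (!any(idx)) next
    v_s[idx] <- decision_value(
      agent, bet_table$safer_lo[idx], bet_table$safer_hi[idx], setting
    )
    v_r[idx] <- decision_value(
      agent, bet_table$riskier_lo[idx], bet_table$riskier_hi[idx], setting
    )
  }
  p <- stats::plogis((v_s - v_r) / agent$temperature)
  p[bet_table$is_no_brainer] <- NA_real_
  dplyr::mutate(bet_table, p_safer = p)
}

#' Configure a synthetic experiment
#'
#' Defaults mirror the study's protocol: 100 respondents split evenly
#' between a timed and a control group, each answering all couples of an
#' 80-couple bet table in two independently shuffled setting blocks, with
#' cumulative response-time medians of 579 s (timed) and 694 s (control)
#' and the timed group less dispersed. The default behavioural scenario
#' encodes the hypothesis that perceived time pressure elicits intuitive,
#' time-average-optimising choices: timed respondents are
#' `time_average_optimizer` agents and control respondents
#' `ev_indifferent` agents.
#'
#' @param n_respondents total respondents.
#' @param p_timed probability of assignment to the timed group.
#' @param timed_agent,control_agent [agent_spec()]s per group.
#' @param median_time_s named vector of target cumulative response-time
#'   medians (seconds) for `timed` and `control`.
#' @param time_sdlog named vector of log-normal shape parameters for the
#'   per-respondent cumulative times.
#' @param seed integer seed driving all randomisation.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_respondents = 100, p_timed = 0.5,
                              timed_agent = agent_spec("time_average_optimizer"),
                              control_agent = agent_spec("ev_indifferent"),
                              median_time_s = c(timed = 579, control = 694),
                              time_sdlog = c(timed = 0.25, control = 0.45),
                              seed = 1L) {
  stopifnot(
    n_respondents >= 4, p_timed > 0, p_timed < 1,
    all(c("timed", "control") %in% names(median_time_s)),
    all(median_time_s > 0), all(time_sdlog > 0),
    inherits(timed_agent, "agent_spec"),
    inherits(control_agent, "agent_spec")
  )
  structure(
    list(
      n_respondents = n_respondents, p_timed = p_timed,
      timed_agent = timed_agent, control_agent = control_agent,
      median_time_s = median_time_s, time_sdlog = time_sdlog,
      seed = as.integer(seed)
    ),
    class = "experiment_config"
  )
}

#' Simulate a cohort of synthetic respondents
#'
#' Generates one response row per respondent and couple. Group membership,
#' block order, couple order within blocks, within-couple presentation
#' order, choices and response times all derive from `config$seed`, so a
#' fixed seed reproduces the table exactly. Scored couples are answered by
#' the group's softmax agent; no-brainers are answered correctly with
#' probability `1 - nobrainer_error_rate`. Each respondent's cumulative
#' response time is drawn log-normally with the group's target median and
#' shape, then split across couples by normalised gamma weights, so group
#' sample medians of cumulative time converge to the configured targets.
#'
#' @param bet_table a bet table (see [generate_bet_table()]).
#' @param config an [experiment_config()].
#' @return A response tibble (see [read_responses()] for the schema).
#' @examples
#' bets <- generate_bet_table(seed = 42)
#' resp <- simulate_responses(bets, experiment_config(n_respondents = 10))
#' dplyr::count(resp, group)
#' @export
simulate_responses <- function(bet_table, config = experiment_config()) {
  check_bet_table(bet_table)
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)

  n <- config$n_respondents
  ids <- sprintf("R%03d", seq_len(n))
  groups <- ifelse(stats::runif(n) < config$p_timed, "timed", "control")
  n_couples <- nrow(bet_table)

  p_by_group <- list(
    timed = choice_prob(bet_table, config$timed_agent),
    control = choice_prob(bet_table, config$control_agent)
  )

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    grp <- groups[i]
    agent <- if (grp == "timed") config$timed_agent else config$control_agent
    tab <- p_by_group[[grp]]

    # two independently played blocks, random starting setting
    settings <- sample(c("additive", "multiplicative"))
    order_idx <- unlist(lapply(settings, function(s) {
      sample(which(tab$setting == s))
    }))
    tab_i <- tab[order_idx, ]

    nb <- tab_i$is_no_brainer
    chose_safer <- rep(NA_integer_, n_couples)
    nb_correct <- rep(NA, n_couples)
    chose_safer[!nb] <- stats::rbinom(sum(!nb), 1, tab_i$p_safer[!nb])
    nb_correct[nb] <- stats::rbinom(sum(nb), 1, 1 - agent$nobrainer_error_rate) == 1

    total_time <- stats::rlnorm(
      1,
      meanlog = log(config$median_time_s[[grp]]),
      sdlog = config$time_sdlog[[grp]]
    )
    w <- stats::rgamma(n_couples, shape = 2)
    times <- total_time * w / sum(w)

    rows[[i]] <- tibble::tibble(
      respondent_id = ids[i],
      group = grp,
      setting = tab_i$setting,
      couple_index = tab_i$couple_index,
      chose_safer = chose_safer,
      nobrainer_correct = nb_correct,
      response_time_s = times,
      presentation_order = sample(
        c("safer_first", "riskier_first"), n_couples,
        replace = TRUE
      )
    )
  }
  out <- dplyr::bind_rows(rows)
  check_responses(out)
  out
}
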