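#' Apply the no-brainer quality filter
#'
#' Respondents must correctly answer at least 3 of the 5 no-brainer
#' (state-wise dominated) couples in each setting to be retained for
#' analysis; the threshold is inclusive and applies to both settings
#' jointly. The filter is idempotent and monotone in correctness.
#'
#' @param responses a response tibble (see [read_responses()]).
#' @param min_correct minimum correct no-brainers per setting (default 3).
#' @param strict if `TRUE` (default), a respondent with no no-brainer
#'   answers in some setting is an error; if `FALSE` such respondents are
#'   excluded silently.
#' @return A list of class `qc_result` with elements `retained` (the
#'   filtered response tibble), `report` (a one-row tibble: `n_initial`,
#'   `n_retained`, `frac_correct_all` and `frac_correct_retained`, the
#'   overall fraction of correct no-brainer answers among all and among
#'   retained respondents) and `per_respondent` (correct counts per
#'   respondent and setting plus the retention flag).
#' @examples
#' bets <- generate_bet_table(seed = 42)
#' resp <- simulate_responses(bets, experiment_config(n_respondents = 20))
#' qc <- apply_filter(resp)
#' qc$report
#' @export
apply_filter <- function(responses, min_correct = 3, strict = TRUE) {
  check_responses(responses)
  nb <- dplyr::filter(responses, !is.na(.data$nobrainer_correct))
  if (nrow(nb) == 0) {
    rlang::abort("no no-brainer answers found; cannot apply the filter")
  }

  per_resp <- nb |>
    dplyr::group_by(.data$respondent_id, .data$group, .data$setting) |>
    dplyr::summarise(
      n_answered = dplyr::n(),
      n_correct = sum(.data$nobrainer_correct),
      .groups = "drop"
    ) |>
    tidyr::complete(
      tidyr::nesting(respondent_id, group),
      setting = c("additive", "multiplicative"),
      fill = list(n_answered = 0L, n_correct = 0L)
    )

  missing <- per_resp$respondent_id[per_resp$n_answered == 0]
  if (length(missing) && strict) {
    rlang::abort(paste0(
      "respondent(s) with missing no-brainer answers: ",
      paste(unique(missing), collapse = ", ")
    ))
  }

  verdict <- per_resp |>
    dplyr::group_by(.data$respondent_id, .data$group) |>
    dplyr::summarise(
      retained = all(.data$n_correct >= min_correct) &&
        all(.data$n_answered > 0),
      .groups = "drop"
    )
  keep <- verdict$respondent_id[verdict$retained]

  report <- tibble::tibble(
    n_initial = dplyr::n_distinct(responses$respondent_id),
    n_retained = length(keep),
    frac_correct_all = mean(nb$nobrainer_correct),
    frac_correct_retained = mean(
      nb$nobrainer_correct[nb$respondent_id %in% keep]
    )
  )

  structure(
    list(
      retained = dplyr::filter(responses, .data$respondent_id %in% keep),
      report = report,
      per_respondent = dplyr::left_join(
        per_resp, verdict,
        by = c("respondent_id", "group")
      )
    ),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf(
    "No-brainer QC: %d of %d respondents retained (%.0f%% of no-brainer answers correct)\n",
    x$report$n_retained, x$report$n_initial,
    100 * x$report$frac_correct_all
  ))
  invisible(x)
}

#' Cumulative response-time summaries per group
#'
#' Sums each respondent's per-couple response times into a cumulative time
#' and summarises these by group (median and quartiles).
#'
#' @param responses a response tibble.
#' @return A list with `totals` (per-respondent cumulative seconds) and
#'   `by_group` (group-level `n`, `median_s`, `q1_s`, `q3_s`).
#' @export
summarize_times <- function(responses) {
  check_responses(responses)
  totals <- responses |>
    dplyr::group_by(.data$respondent_id, .data$group) |>
    dplyr::summarise(total_s = sum(.data$response_time_s), .groups = "drop")
  by_group <- totals |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_s = stats::median(.data$total_s),
      q1_s = stats::quantile(.data$total_s, 0.25)[[1]],
      q3_s = stats::quantile(.data$total_s, 0.75)[[1]],
      .groups = "drop"
    )
  list(totals = totals, by_group = by_group)
}
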