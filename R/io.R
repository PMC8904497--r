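#' Read and write bet tables and response tables
#'
#' Canonical on-disk schemas (comma-separated, UTF-8, headered, `.`-decimal):
#'
#' * bet table: `couple_index, setting, bet1_lo, bet1_hi, bet2_lo, bet2_hi,
#'   safer_bet, is_no_brainer`, where `safer_bet` (1 or 2) names the
#'   lower-variance bet — for no-brainers, the dominant bet. In memory the
#'   package uses the equivalent `riskier_* / safer_*` layout.
#' * response table: `respondent_id, group, setting, couple_index,
#'   chose_safer, nobrainer_correct, response_time_s, presentation_order`.
#'
#' Reading validates the schema strictly and names the offending column;
#' writing then reading a table reproduces it exactly.
#'
#' @param path file path.
#' @param bet_table,responses tibbles in the in-memory layouts above.
#' @name ergochoice-io
NULL

check_bet_table <- function(bet_table) {
  needed <- c(
    "couple_index", "setting", "riskier_lo", "riskier_hi",
    "safer_lo", "safer_hi", "is_no_brainer"
  )
  missing <- setdiff(needed, names(bet_table))
  if (length(missing)) {
    rlang::abort(paste0(
      "bet table is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  if (nrow(bet_table) == 0) {
    rlang::abort("bet table is empty")
  }
  bad <- !bet_table$setting %in% c("additive", "multiplicative")
  if (any(bad)) {
    rlang::abort(paste0(
      "invalid `setting` in bet table row(s) ",
      paste(which(bad), collapse = ", ")
    ))
  }
  invisible(bet_table)
}

check_responses <- function(responses) {
  needed <- c(
    "respondent_id", "group", "setting", "couple_index",
    "chose_safer", "nobrainer_correct", "response_time_s"
  )
  missing <- setdiff(needed, names(responses))
  if (length(missing)) {
    rlang::abort(paste0(
      "response table is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  if (any(!responses$group %in% c("timed", "control"))) {
    rlang::abort('`group` must be "timed" or "control"')
  }
  if (any(responses$response_time_s <= 0, na.rm = TRUE)) {
    rlang::abort("response times must be positive")
  }
  both <- !is.na(responses$chose_safer) & !is.na(responses$nobrainer_correct)
  neither <- is.na(responses$chose_safer) & is.na(responses$nobrainer_correct)
  if (any(both | neither)) {
    rlang::abort(paste0(
      "each response must have exactly one of `chose_safer` / ",
      "`nobrainer_correct`; bad row(s): ",
      paste(utils::head(which(both | neither), 5), collapse = ", ")
    ))
  }
  invisible(responses)
}

#' @describeIn ergochoice-io Write a bet table to CSV.
#' @export
write_bet_table <- function(bet_table, path) {
  check_bet_table(bet_table)
  out <- tibble::tibble(
    couple_index = bet_table$couple_index,
    setting = bet_table$setting,
    bet1_lo = bet_table$riskier_lo,
    bet1_hi = bet_table$riskier_hi,
    bet2_lo = bet_table$safer_lo,
    bet2_hi = bet_table$safer_hi,
    safer_bet = 2L,
    is_no_brainer = bet_table$is_no_brainer
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @describeIn ergochoice-io Read a bet table from CSV, with strict schema
#'   validation and a warning for multiplicative outcomes outside the
#'   design's [0.7, 1.4] feasibility band.
#' @export
read_bet_table <- function(path) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(
      couple_index = readr::col_integer(),
      setting = readr::col_character(),
      bet1_lo = readr::col_double(),
      bet1_hi = readr::col_double(),
      bet2_lo = readr::col_double(),
      bet2_hi = readr::col_double(),
      safer_bet = readr::col_integer(),
      is_no_brainer = readr::col_logical()
    )
  )
  if (nrow(raw) == 0) {
    rlang::abort(paste0("bet table file is empty: ", path))
  }
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    rlang::abort(sprintf(
      "malformed bet table %s: row %d, column %s",
      path, probs$row[1], probs$col[1]
    ))
  }
  if (any(!raw$safer_bet %in% c(1L, 2L))) {
    rlang::abort("`safer_bet` must be 1 or 2")
  }
  s2 <- raw$safer_bet == 2L
  out <- tibble::tibble(
    couple_index = raw$couple_index,
    setting = raw$setting,
    riskier_lo = ifelse(s2, raw$bet1_lo, raw$bet2_lo),
    riskier_hi = ifelse(s2, raw$bet1_hi, raw$bet2_hi),
    safer_lo = ifelse(s2, raw$bet2_lo, raw$bet1_lo),
    safer_hi = ifelse(s2, raw$bet2_hi, raw$bet1_hi),
    is_no_brainer = raw$is_no_brainer
  )
  check_bet_table(out)
  mult <- out$setting == "multiplicative"
  off <- mult & (
    out$riskier_lo < 0.7 | out$riskier_hi > 1.4 |
      out$safer_lo < 0.7 | out$safer_hi > 1.4
  )
  if (any(off)) {
    rlang::warn(paste0(
      "multiplicative outcomes outside the [0.7, 1.4] design band in ",
      "couple(s): ", paste(out$couple_index[off], collapse = ", ")
    ))
  }
  out
}

#' @describeIn ergochoice-io Write a response table to CSV.
#' @export
write_responses <- function(responses, path) {
  check_responses(responses)
  readr::write_csv(responses, path)
  invisible(path)
}

#' @describeIn ergochoice-io Read a response table from CSV with schema
#'   validation.
#' @export
read_responses <- function(path) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(
      respondent_id = readr::col_character(),
      group = readr::col_character(),
      setting = readr::col_character(),
      couple_index = readr::col_integer(),
      chose_safer = readr::col_integer(),
      nobrainer_correct = readr::col_logical(),
      response_time_s = readr::col_double(),
      presentation_order = readr::col_character()
    )
  )
  if (nrow(raw) == 0) {
    rlang::abort(paste0("response table file is empty: ", path))
  }
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    rlang::abort(sprintf(
      "malformed response table %s: row %d, column %s",
      path, probs$row[1], probs$col[1]
    ))
  }
  check_responses(raw)
  raw
}
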