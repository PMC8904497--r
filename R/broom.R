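#' Broom-style accessors for fitted objects
#'
#' `tidy()` returns one row per estimated component; `glance()` returns a
#' one-row model-level summary.
#'
#' @param x a `couple_estimates`, `group_comparison`, `qc_result` or
#'   `ergodicity_experiment` object.
#' @param ... ignored.
#' @name ergochoice-broom
NULL

#' @importFrom generics tidy glance
NULL

#' @rdname ergochoice-broom
#' @method tidy couple_estimates
#' @export
tidy.couple_estimates <- function(x, ...) {
  tibble::as_tibble(x)[c(
    "group", "setting", "couple_index", "k", "n",
    "alpha", "beta", "mean", "sd"
  )]
}

#' @rdname ergochoice-broom
#' @method glance couple_estimates
#' @export
glance.couple_estimates <- function(x, ...) {
  aggregate_settings(x)
}

#' @rdname ergochoice-broom
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::as_tibble(x)[c(
    "setting", "p_s_timed", "sd_s_timed", "p_s_control", "sd_s_control",
    "z", "p_one_sided", "alternative"
  )]
}

#' @rdname ergochoice-broom
#' @method tidy qc_result
#' @export
tidy.qc_result <- function(x, ...) {
  x$per_respondent
}

#' @rdname ergochoice-broom
#' @method glance qc_result
#' @export
glance.qc_result <- function(x, ...) {
  x$report
}

#' @rdname ergochoice-broom
#' @method tidy ergodicity_experiment
#' @export
tidy.ergodicity_experiment <- function(x, ...) {
  tidy.group_comparison(x$comparison)
}

#' @rdname ergochoice-broom
#' @method glance ergodicity_experiment
#' @export
glance.ergodicity_experiment <- function(x, ...) {
  dplyr::bind_cols(
    x$qc$report,
    tibble::tibble(
      mw_p_value = x$time_test$p_value,
      median_timed_s = x$time_test$median_timed,
      median_control_s = x$time_test$median_control
    )
  )
}
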