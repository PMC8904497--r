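#' Two-outcome bet arithmetic
#'
#' A bet is a 50/50 (by default) two-outcome gamble. In the additive dynamic
#' the outcomes are currency increments added to capital; in the
#' multiplicative dynamic they are growth factors multiplying capital and
#' must be strictly positive. All functions here are vectorised over
#' `lo` and `hi`.
#'
#' @param lo,hi numeric vectors, the two outcomes. `lo` must not exceed `hi`.
#' @param dynamic `"additive"` or `"multiplicative"`.
#' @param p_lo probability of the `lo` outcome, in (0, 1). The experiment
#'   uses 0.5 throughout.
#' @name bet-math
NULL

check_dynamic <- function(dynamic) {
  match.arg(dynamic, c("additive", "multiplicative"))
}

check_bet <- function(lo, hi, dynamic, p_lo = 0.5) {
  dynamic <- check_dynamic(dynamic)
  if (any(!is.finite(lo)) || any(!is.finite(hi))) {
    rlang::abort("bet outcomes must be finite")
  }
  if (any(lo > hi)) {
    rlang::abort("`lo` must not exceed `hi` for any bet")
  }
  if (any(p_lo <= 0 | p_lo >= 1)) {
    rlang::abort("`p_lo` must lie strictly inside (0, 1)")
  }
  if (dynamic == "multiplicative" && any(lo <= 0)) {
    rlang::abort("multiplicative bets need strictly positive growth factors")
  }
  dynamic
}

#' @describeIn bet-math Ensemble (expected-value) average of a bet: the
#'   expected per-round increment (additive) or expected growth factor
#'   (multiplicative), i.e. the average over infinitely many individuals
#'   playing once.
#' @return A numeric vector.
#' @examples
#' ensemble_ev(0.6, 1.5, "multiplicative") # 1.05: a 5% expected gain
#' time_avg_growth(0.6, 1.5, "multiplicative") # log(0.9)/2: about -5% per round
#' @export
ensemble_ev <- function(lo, hi, dynamic, p_lo = 0.5) {
  check_bet(lo, hi, dynamic, p_lo)
  p_lo * lo + (1 - p_lo) * hi
}

#' @describeIn bet-math Time-average growth: the per-round growth a single
#'   individual experiences as rounds go to infinity. Equals `ensemble_ev()`
#'   in the additive dynamic (the process is ergodic) and the expected log
#'   growth factor in the multiplicative one (where ergodicity breaks).
#' @export
time_avg_growth <- function(lo, hi, dynamic, p_lo = 0.5) {
  dynamic <- check_bet(lo, hi, dynamic, p_lo)
  if (dynamic == "additive") {
    p_lo * lo + (1 - p_lo) * hi
  } else {
    p_lo * log(lo) + (1 - p_lo) * log(hi)
  }
}

#' @describeIn bet-math The ergodic transformation: the mapping under which
#'   per-round increments become ergodic. Identity for additive dynamics,
#'   natural log for multiplicative ones.
#' @param value numeric vector of increments (additive) or factors
#'   (multiplicative; must be positive).
#' @export
ergodic_transform <- function(value, dynamic) {
  dynamic <- check_dynamic(dynamic)
  if (dynamic == "additive") {
    return(value)
  }
  if (any(value <= 0)) {
    rlang::abort("the log transform needs strictly positive values")
  }
  log(value)
}

#' @describeIn bet-math Population variance of the two-point outcome
#'   distribution: `p_lo * (1 - p_lo) * (hi - lo)^2`. Within a couple the
#'   bet with larger variance is the riskier one.
#' @export
bet_variance <- function(lo, hi, p_lo = 0.5) {
  if (any(lo > hi)) {
    rlang::abort("`lo` must not exceed `hi` for any bet")
  }
  p_lo * (1 - p_lo) * (hi - lo)^2
}
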