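#' Parameter space for bet-couple generation
#'
#' Bounds on the feasible region from which the riskier (seed) bet of each
#' couple is drawn. In the additive setting no outcome may win or lose more
#' than 300 and the expected gain or loss may not exceed 100 in magnitude.
#' In the multiplicative setting outcomes (growth factors) must lie in
#' [0.7, 1.4] and the bet's per-round average growth factor
#' `sqrt(lo * hi)` in [0.945, 1.05]. A minimum outcome spread keeps the
#' seed bet away from the zero-variance diagonal so that a strictly safer
#' partner always exists; the safer partner itself is constrained by the
#' outcome bounds only.
#'
#' Outcomes are quantized: integers in the additive setting, two decimals
#' in the multiplicative one. `quantum` is the grid step.
#'
#' @param setting `"additive"` or `"multiplicative"`.
#' @return A list of bounds with class `bet_space`.
#' @export
bet_space <- function(setting) {
  setting <- check_dynamic(setting)
  sp <- if (setting == "additive") {
    list(
      setting = setting,
      outcome_min = -300, outcome_max = 300,
      ev_min = -100, ev_max = 100,
      growth_min = -Inf, growth_max = Inf,
      min_spread = 20, quantum = 1
    )
  } else {
    list(
      setting = setting,
      outcome_min = 0.7, outcome_max = 1.4,
      ev_min = -Inf, ev_max = Inf,
      growth_min = 0.945, growth_max = 1.05,
      min_spread = 0.1, quantum = 0.01
    )
  }
  structure(sp, class = "bet_space")
}

# integer grid units for exact quantized arithmetic; converting back
# divides by the inverse step so grid values are the cleanest doubles
# (139 / 100 rather than 139 * 0.01)
to_units <- function(x, quantum) as.integer(round(x / quantum))
from_units <- function(u, quantum) u / round(1 / quantum)

space_ok <- function(lo, hi, space) {
  ev <- (lo + hi) / 2
  ok <- lo >= space$outcome_min & hi <= space$outcome_max &
    ev >= space$ev_min & ev <= space$ev_max
  if (is.finite(space$growth_min)) {
    g <- sqrt(lo * hi)
    ok <- ok & g >= space$growth_min & g <= space$growth_max
  }
  ok
}

sample_riskier <- function(space) {
  repeat {
    o <- sort(stats::runif(2, space$outcome_min, space$outcome_max))
    lo <- o[1]
    hi <- o[2]
    if (hi - lo < space$min_spread) next
    if (!space_ok(lo, hi, space)) next
    q <- space$quantum
    lo <- from_units(to_units(lo, q), q)
    hi <- from_units(to_units(hi, q), q)
    if (hi - lo < space$min_spread) next
    if (!space_ok(lo, hi, space)) next
    return(c(lo, hi))
  }
}

sample_safer <- function(riskier, space) {
  q <- space$quantum
  r_units <- to_units(riskier, q)
  sum_units <- sum(r_units) # twice the EV, exact on the grid
  spread_r <- diff(r_units)
  for (i in 1:1000) {
    spread <- stats::runif(1, 0, spread_r * q)
    s_lo <- to_units(mean(riskier) - spread / 2, q)
    s_hi <- sum_units - s_lo
    if (s_hi <= s_lo) next # zero/negative spread: no safer/riskier distinction
    if (s_hi - s_lo >= spread_r) next # must be strictly less dispersed
    lo <- from_units(s_lo, q)
    hi <- from_units(s_hi, q)
    if (lo < space$outcome_min || hi > space$outcome_max) next
    return(c(lo, hi))
  }
  NULL
}

#' Draw one equal-expected-value bet couple
#'
#' Samples the riskier bet uniformly over the feasible region of `space`,
#' then places the safer bet on the equal-expected-value locus with a
#' strictly smaller outcome spread. Outcomes are quantized to the space's
#' grid with expected-value equality restored exactly on the grid (the two
#' outcome sums are identical integers in grid units). Couples whose
#' quantized spreads coincide are rejected and resampled.
#'
#' @param space a [bet_space()].
#' @return A one-row tibble with columns `riskier_lo`, `riskier_hi`,
#'   `safer_lo`, `safer_hi`.
#' @export
sample_couple <- function(space) {
  stopifnot(inherits(space, "bet_space"))
  repeat {
    r <- sample_riskier(space)
    s <- sample_safer(r, space)
    if (is.null(s)) next
    return(tibble::tibble(
      riskier_lo = r[1], riskier_hi = r[2],
      safer_lo = s[1], safer_hi = s[2]
    ))
  }
}

#' Draw one dominated "no-brainer" couple
#'
#' A no-brainer couple has an objectively correct answer: one bet
#' state-wise dominates the other (each outcome at least as good, at least
#' one strictly better). The dominant bet is sampled from the feasible
#' region and the dominated partner is obtained by shifting each outcome
#' down by a non-negative grid amount, at least one strictly, while
#' respecting the outcome bounds.
#'
#' @param space a [bet_space()].
#' @return A one-row tibble with columns `dominant_lo`, `dominant_hi`,
#'   `dominated_lo`, `dominated_hi`.
#' @export
make_no_brainer <- function(space) {
  stopifnot(inherits(space, "bet_space"))
  q <- space$quantum
  max_shift <- if (space$setting == "additive") 100L else 25L
  repeat {
    d <- sample_riskier(space)
    room_lo <- to_units(d[1] - space$outcome_min, q)
    room_hi <- to_units(d[2] - space$outcome_min, q)
    shift <- c(
      sample(0:min(max_shift, room_lo), 1),
      sample(0:min(max_shift, room_hi), 1)
    )
    if (all(shift == 0)) next
    du <- to_units(d, q)
    lo <- from_units(du[1] - shift[1], q)
    hi <- from_units(du[2] - shift[2], q)
    if (hi < lo) { # keep the dominated pair ordered
      tmp <- lo
      lo <- hi
      hi <- tmp
    }
    if (lo < space$outcome_min) next
    return(tibble::tibble(
      dominant_lo = d[1], dominant_hi = d[2],
      dominated_lo = lo, dominated_hi = hi
    ))
  }
}

#' Generate the full experimental bet table
#'
#' Builds the 80-couple design: per setting, `n_scored` equal-expected-value
#' couples followed by `n_no_brainer` dominated attention-check couples.
#' Additive couples take indices `1:(n_scored + n_no_brainer)` and
#' multiplicative couples continue from there, so with the defaults the
#' no-brainers sit at indices 36-40 and 76-80. For no-brainer rows the
#' `safer_*` columns hold the dominant (objectively correct) bet.
#'
#' @param n_scored scored couples per setting (default 35).
#' @param n_no_brainer attention-check couples per setting (default 5).
#' @param seed integer seed for the generator; `NULL` uses the current RNG.
#' @return A tibble with columns `couple_index`, `setting`, `riskier_lo`,
#'   `riskier_hi`, `safer_lo`, `safer_hi`, `is_no_brainer`.
#' @examples
#' bets <- generate_bet_table(seed = 42)
#' dplyr::count(bets, setting, is_no_brainer)
#' @export
generate_bet_table <- function(n_scored = 35, n_no_brainer = 5, seed = NULL) {
  stopifnot(n_scored >= 1, n_no_brainer >= 0)
  if (!is.null(seed)) set.seed(seed)
  per_setting <- n_scored + n_no_brainer
  out <- purrr::map_dfr(c("additive", "multiplicative"), function(setting) {
    space <- bet_space(setting)
    offset <- if (setting == "additive") 0L else per_setting
    scored <- purrr::map_dfr(seq_len(n_scored), ~ sample_couple(space))
    scored <- dplyr::mutate(scored,
      couple_index = offset + dplyr::row_number(),
      setting = setting, is_no_brainer = FALSE, .before = 1
    )
    if (n_no_brainer == 0) {
      return(scored)
    }
    nb <- purrr::map_dfr(seq_len(n_no_brainer), ~ make_no_brainer(space))
    nb <- tibble::tibble(
      couple_index = offset + n_scored + seq_len(n_no_brainer),
      setting = setting,
      is_no_brainer = TRUE,
      riskier_lo = nb$dominated_lo, riskier_hi = nb$dominated_hi,
      safer_lo = nb$dominant_lo, safer_hi = nb$dominant_hi
    )
    dplyr::bind_rows(scored, nb)
  })
  dplyr::relocate(
    out, "couple_index", "setting",
    "riskier_lo", "riskier_hi", "safer_lo", "safer_hi", "is_no_brainer"
  )
}

#' Audit a bet table against its design constraints
#'
#' Checks, per couple: exact expected-value equality on the quantized grid,
#' strict variance ordering (scored couples), feasible-region membership of
#' the riskier bet, state-wise dominance (no-brainers), and the
#' time-average relations — identical time averages within additive couples,
#' strictly higher time-average growth for the safer bet in multiplicative
#' couples.
#'
#' @param bet_table a tibble from [generate_bet_table()] or
#'   [read_bet_table()].
#' @return The table with logical audit columns `ev_equal`, `var_ordered`,
#'   `in_space`, `dominance_ok`, `time_avg_ok` and `ok` (all checks that
#'   apply to the row).
#' @export
audit_bet_table <- function(bet_table) {
  check_bet_table(bet_table)
  q <- ifelse(bet_table$setting == "additive", 1, 0.01)
  r_sum <- round((bet_table$riskier_lo + bet_table$riskier_hi) / q)
  s_sum <- round((bet_table$safer_lo + bet_table$safer_hi) / q)
  var_r <- bet_variance(bet_table$riskier_lo, bet_table$riskier_hi)
  var_s <- bet_variance(bet_table$safer_lo, bet_table$safer_hi)

  in_space <- purrr::map_lgl(seq_len(nrow(bet_table)), function(i) {
    space <- bet_space(bet_table$setting[i])
    bet <- if (bet_table$is_no_brainer[i]) {
      c(bet_table$safer_lo[i], bet_table$safer_hi[i]) # the dominant seed bet
    } else {
      c(bet_table$riskier_lo[i], bet_table$riskier_hi[i])
    }
    isTRUE(space_ok(bet[1], bet[2], space))
  })

  dominance_ok <- !bet_table$is_no_brainer |
    (bet_table$safer_lo >= bet_table$riskier_lo &
      bet_table$safer_hi >= bet_table$riskier_hi &
      (bet_table$safer_lo > bet_table$riskier_lo |
        bet_table$safer_hi > bet_table$riskier_hi))

  tag_r <- time_avg_growth(
    bet_table$riskier_lo, bet_table$riskier_hi, "additive"
  )
  tag_s <- time_avg_growth(bet_table$safer_lo, bet_table$safer_hi, "additive")
  mult <- bet_table$setting == "multiplicative"
  tag_r[mult] <- time_avg_growth(
    bet_table$riskier_lo[mult], bet_table$riskier_hi[mult], "multiplicative"
  )
  tag_s[mult] <- time_avg_growth(
    bet_table$safer_lo[mult], bet_table$safer_hi[mult], "multiplicative"
  )
  time_avg_ok <- dplyr::if_else(
    bet_table$is_no_brainer, TRUE,
    dplyr::if_else(mult, tag_s > tag_r, tag_s == tag_r)
  )

  dplyr::mutate(bet_table,
    ev_equal = is_no_brainer | r_sum == s_sum,
    var_ordered = is_no_brainer | var_r > var_s,
    in_space = in_space,
    dominance_ok = dominance_ok,
    time_avg_ok = time_avg_ok,
    ok = ev_equal & var_ordered & in_space & dominance_ok & time_avg_ok
  )
}

#' Code a stated choice as risk-averse or risk-taking
#'
#' Within an equal-expected-value couple, picking the higher-variance
#' (riskier) bet is a risk-taking decision (coded 0) and picking the
#' lower-variance (safer) bet a risk-averse one (coded 1). No-brainer
#' couples carry an objectively correct answer instead of a risk reading,
#' so they cannot be classified and raise an error.
#'
#' @param bet_table the bet table rows being answered (recycled against
#'   `chosen`).
#' @param chosen character vector, `"safer"` or `"riskier"`, the bet picked.
#' @return Integer vector: 1 = risk-averse, 0 = risk-taking.
#' @export
classify_choice <- function(bet_table, chosen) {
  check_bet_table(bet_table)
  if (any(bet_table$is_no_brainer)) {
    rlang::abort(
      "no-brainer couples have a correct answer, not a risk classification"
    )
  }
  if (!all(chosen %in% c("safer", "riskier"))) {
    rlang::abort('`chosen` must be "safer" or "riskier"')
  }
  as.integer(chosen == "safer")
}

#' Expected-utility comparison within an equal-expected-value couple
#'
#' For a couple with outcomes `a < b < c < d` (riskier bet `{a, d}`, safer
#' bet `{b, c}`, all 50/50) and a monotone utility with a constant
#' curvature sign, Jensen's inequality forces every concave utility to
#' weakly prefer the safer bet and every convex one the riskier bet;
#' a linear utility is exactly indifferent. This evaluates whether the
#' safer bet's expected utility is at least the riskier bet's.
#'
#' @param couple a one-row tibble with `riskier_lo`, `riskier_hi`,
#'   `safer_lo`, `safer_hi` (equal expected values; not a no-brainer).
#' @param utility a vectorised monotone utility function defined on
#'   `[riskier_lo, riskier_hi]`.
#' @return `TRUE` if the safer bet is weakly preferred under `utility`.
#' @examples
#' cpl <- tibble::tibble(
#'   riskier_lo = 0.8, riskier_hi = 1.3, safer_lo = 1.0, safer_hi = 1.1
#' )
#' safer_preferred(cpl, log) # concave: TRUE
#' safer_preferred(cpl, exp) # convex: FALSE
#' @export
safer_preferred <- function(couple, utility) {
  stopifnot(nrow(couple) == 1, is.function(utility))
  u <- utility(c(
    couple$riskier_lo, couple$riskier_hi,
    couple$safer_lo, couple$safer_hi
  ))
  if (any(!is.finite(u))) {
    rlang::abort("`utility` is not finite on the couple's outcome range")
  }
  eu_riskier <- (u[1] + u[2]) / 2
  eu_safer <- (u[3] + u[4]) / 2
  scale <- max(abs(u), 1)
  eu_safer >= eu_riskier - 1e-10 * scale
}
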