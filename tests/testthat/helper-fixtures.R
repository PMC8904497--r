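# Hand-written miniature bet table: two scored couples and one no-brainer
# per setting. Values chosen so every audit check holds by inspection.
mini_bet_table <- function() {
  tibble::tibble(
    couple_index = c(1L, 2L, 3L, 4L, 5L, 6L),
    setting = rep(c("additive", "multiplicative"), each = 3),
    riskier_lo = c(-100, -200, -10, 0.80, 0.70, 0.90),
    riskier_hi = c(100, 150, 5, 1.30, 1.35, 1.20),
    safer_lo = c(-20, -50, 10, 1.00, 0.95, 1.00),
    safer_hi = c(20, 0, 20, 1.10, 1.10, 1.25),
    is_no_brainer = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE)
  )
}

# Build a response table from per-respondent specifications.
# spec: list of lists with id, group, chose_safer (named by couple index,
# scored couples), nb_correct (named by couple index), times (optional).
build_responses <- function(bet_table, spec) {
  purrr::map_dfr(spec, function(s) {
    rows <- purrr::map_dfr(seq_len(nrow(bet_table)), function(i) {
      idx <- as.character(bet_table$couple_index[i])
      nb <- bet_table$is_no_brainer[i]
      tibble::tibble(
        respondent_id = s$id,
        group = s$group,
        setting = bet_table$setting[i],
        couple_index = bet_table$couple_index[i],
        chose_safer = if (nb) NA_integer_ else as.integer(s$chose_safer[[idx]]),
        nobrainer_correct = if (nb) isTRUE(s$nb_correct[[idx]]) else NA,
        response_time_s = if (is.null(s$time)) 10 else s$time,
        presentation_order = "safer_first"
      )
    })
    rows
  })
}

# Monotone piecewise-linear utility: positive segment slopes between knots.
# Decreasing slopes give a concave function, increasing slopes a convex one.
make_piecewise_linear <- function(knots, slopes) {
  stopifnot(length(slopes) == length(knots) + 1, all(slopes > 0))
  force(knots)
  force(slopes)
  function(x) {
    brk <- c(-Inf, knots, Inf)
    vapply(x, function(xi) {
      # signed integral of the slope step function between 0 and xi
      a <- min(0, xi)
      b <- max(0, xi)
      len <- pmax(0, pmin(brk[-1], b) - pmax(brk[-length(brk)], a))
      sign(xi) * sum(slopes * len)
    }, numeric(1))
  }
}

# all-purpose respondent: safer everywhere, no-brainers right
all_safer_spec <- function(id, group, bet_table, time = 10,
                           nb_correct = TRUE) {
  scored <- bet_table$couple_index[!bet_table$is_no_brainer]
  nbs <- bet_table$couple_index[bet_table$is_no_brainer]
  list(
    id = id, group = group,
    chose_safer = stats::setNames(rep(1L, length(scored)), scored),
    nb_correct = stats::setNames(rep(nb_correct, length(nbs)), nbs),
    time = time
  )
}
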