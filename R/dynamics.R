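#' Simulate an ensemble of wealth trajectories under a repeated bet
#'
#' Every individual independently plays the same two-outcome bet each round:
#' additive outcomes are added to capital, multiplicative outcomes multiply
#' it. The contrast between the ensemble mean (which tracks
#' `ensemble_ev()`) and the typical individual trajectory (whose growth is
#' `time_avg_growth()`) is the ergodicity-breaking signature of
#' multiplicative dynamics: a bet can have a positive expected gain per
#' round yet ruin almost every individual who plays it repeatedly.
#'
#' Random draws are consumed round-major (all individuals' coin flips for
#' round 1, then round 2, ...), so the trajectory matrix is reproducible
#' from `seed` alone. Additive capital may go negative; no clamp is applied.
#'
#' @param lo,hi the bet's two outcomes (each drawn with probability `p_lo`
#'   and `1 - p_lo`).
#' @param dynamic `"additive"` or `"multiplicative"`.
#' @param n_individuals number of independent players (rows).
#' @param n_rounds number of repetitions of the bet.
#' @param start_capital common starting capital (default 1000).
#' @param seed integer seed; if `NULL` the current RNG stream is used.
#' @param p_lo probability of the `lo` outcome.
#'
#' @return A tibble in long format with columns `individual`, `round`
#'   (0 = starting capital) and `capital`, of class `trajectory_ensemble`.
#'   The bet, dynamic, seed and start capital are attached as attributes.
#' @examples
#' traj <- simulate_trajectories(0.6, 1.5, "multiplicative",
#'   n_individuals = 20, n_rounds = 100, seed = 1
#' )
#' dplyr::filter(traj, round == 100)
#' @export
simulate_trajectories <- function(lo, hi, dynamic,
                                  n_individuals, n_rounds,
                                  start_capital = 1000,
                                  seed = NULL, p_lo = 0.5) {
  dynamic <- check_bet(lo, hi, dynamic, p_lo)
  stopifnot(n_individuals >= 1, n_rounds >= 0, start_capital > 0)
  if (!is.null(seed)) set.seed(seed)

  capital <- matrix(start_capital, nrow = n_individuals, ncol = n_rounds + 1)
  if (n_rounds > 0) {
    for (t in seq_len(n_rounds)) {
      draw <- ifelse(stats::runif(n_individuals) < p_lo, lo, hi)
      capital[, t + 1] <- if (dynamic == "additive") {
        capital[, t] + draw
      } else {
        capital[, t] * draw
      }
    }
  }

  out <- tibble::tibble(
    individual = rep(seq_len(n_individuals), times = n_rounds + 1),
    round = rep(0:n_rounds, each = n_individuals),
    capital = as.vector(capital)
  )
  structure(out,
    class = c("trajectory_ensemble", class(out)),
    bet = c(lo = lo, hi = hi), dynamic = dynamic,
    start_capital = start_capital, seed = seed, p_lo = p_lo
  )
}

#' Per-round growth diagnostics of a simulated ensemble
#'
#' Summarises a `trajectory_ensemble` by the empirical mean per-round
#' increment of the ergodically transformed capital (the quantity that
#' converges to `time_avg_growth()`) together with the ensemble mean and
#' median capital at the final round.
#'
#' @param traj a `trajectory_ensemble` from [simulate_trajectories()].
#' @return A one-row tibble with columns `mean_increment`, `se_increment`
#'   (standard error of the per-step transformed increments),
#'   `final_ensemble_mean` and `final_median`.
#' @export
trajectory_growth <- function(traj) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  dynamic <- attr(traj, "dynamic")
  wide <- tidyr::pivot_wider(tibble::as_tibble(traj),
    names_from = "round", values_from = "capital"
  )
  m <- as.matrix(wide[, -1])
  g <- ergodic_transform(m, dynamic)
  inc <- g[, -1, drop = FALSE] - g[, -ncol(g), drop = FALSE]
  tibble::tibble(
    mean_increment = mean(inc),
    se_increment = stats::sd(inc) / sqrt(length(inc)),
    final_ensemble_mean = mean(m[, ncol(m)]),
    final_median = stats::median(m[, ncol(m)])
  )
}

#' Exact ensemble mean by exhaustive path enumeration
#'
#' Enumerates all `2^n_rounds` equally weighted outcome paths of a 50/50
#' bet and returns the exact expected capital after `n_rounds`. Usable only
#' for small horizons; serves as a brute-force check that the simulated
#' ensemble mean tracks `start_capital + t * ensemble_ev` (additive) or
#' `start_capital * ensemble_ev^t` (multiplicative).
#'
#' @inheritParams simulate_trajectories
#' @return The exact ensemble-mean capital after `n_rounds`.
#' @export
enumerate_ensemble_mean <- function(lo, hi, dynamic, n_rounds,
                                    start_capital = 1000) {
  dynamic <- check_bet(lo, hi, dynamic)
  stopifnot(n_rounds >= 0, n_rounds <= 20)
  if (n_rounds == 0) {
    return(start_capital)
  }
  # paths indexed by number of `lo` draws k, weight choose(n, k) / 2^n
  k <- 0:n_rounds
  w <- choose(n_rounds, k) / 2^n_rounds
  terminal <- if (dynamic == "additive") {
    start_capital + k * lo + (n_rounds - k) * hi
  } else {
    start_capital * lo^k * hi^(n_rounds - k)
  }
  sum(w * terminal)
}

#' Plot a trajectory ensemble with its expected-value overlay
#'
#' Spaghetti plot of individual capital trajectories with the ensemble
#' expectation (`start * ev^t` or `start + t * ev`) as a black line,
#' and a log y scale for multiplicative dynamics.
#'
#' @param object a `trajectory_ensemble`.
#' @param max_individuals cap on the number of trajectories drawn.
#' @param ... ignored.
#' @return A ggplot object.
#' @method autoplot trajectory_ensemble
#' @export
autoplot.trajectory_ensemble <- function(object, max_individuals = 200, ...) {
  dynamic <- attr(object, "dynamic")
  bet <- attr(object, "bet")
  start <- attr(object, "start_capital")
  ev <- ensemble_ev(bet[["lo"]], bet[["hi"]], dynamic, attr(object, "p_lo"))
  keep <- unique(object$individual)
  keep <- keep[seq_len(min(length(keep), max_individuals))]
  rounds <- 0:max(object$round)
  expected <- tibble::tibble(
    round = rounds,
    capital = if (dynamic == "additive") start + rounds * ev else start * ev^rounds
  )
  p <- ggplot2::ggplot(
    dplyr::filter(object, .data$individual %in% keep),
    ggplot2::aes(.data$round, .data$capital, group = .data$individual)
  ) +
    ggplot2::geom_line(alpha = 0.25, colour = "grey40") +
    ggplot2::geom_line(
      data = expected, ggplot2::aes(group = NULL),
      colour = "black", linewidth = 0.9
    ) +
    ggplot2::labs(
      x = "round", y = "capital",
      title = sprintf("%s dynamic: bet (%g, %g)", dynamic, bet[["lo"]], bet[["hi"]])
    )
  if (dynamic == "multiplicative") p <- p + ggplot2::scale_y_log10()
  p
}
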