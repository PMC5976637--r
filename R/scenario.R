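#' Configure an invasion / disturbance experiment
#'
#' A scenario designates one resident species (rank `invader_rank`) as the
#' "invader" and moves it off the tradeoff surface: a sustained or pulsed
#' external propagule supply `h_a` emulates cultivation, a mortality
#' reduction emulates enemy release, and an optional community-wide
#' mortality replacement emulates elevated disturbance (trampling, mowing,
#' fire, ...), applied to every species including the invader.
#'
#' @param invader_rank Competitive rank `a` of the manipulated species.
#' @param h Sustained external propagule level `h_a >= 0`. Mutually
#'   exclusive with `pulse`.
#' @param pulse Temporary propagule supply: a list/vector with elements
#'   `onset`, `duration`, `level`; `h_a(t) = level` for
#'   `onset <= t < onset + duration`, 0 otherwise.
#' @param mortality_delta Amount subtracted from the invader's mortality
#'   (enemy release), `>= 0` and leaving `m_a > 0`.
#' @param disturbance_mortality Replacement mortality applied to all species
#'   (including the invader), or `NULL` for unchanged.
#' @param horizon Total integration time `T` (model time units).
#' @param output_times Reporting grid on `[0, T]`; default 64 log-spaced
#'   points plus 0.
#' @param extinction_threshold Fraction of a species' own baseline
#'   equilibrium below which it counts as extinct (strictly below; default
#'   1e-4, i.e. 0.01%).
#' @return A `scenario_config` list.
#' @examples
#' scenario_config(invader_rank = 10, h = 0.05)
#' @export
scenario_config <- function(invader_rank, h = 0, pulse = NULL,
                            mortality_delta = 0, disturbance_mortality = NULL,
                            horizon = 5000, output_times = NULL,
                            extinction_threshold = 1e-4) {
  invader_rank <- as.integer(invader_rank)
  stopifnot(length(invader_rank) == 1L, invader_rank >= 1L)
  if (h < 0) abort("`h` must be >= 0.")
  if (mortality_delta < 0) abort("`mortality_delta` must be >= 0.")
  if (!(extinction_threshold > 0 && extinction_threshold < 1)) {
    abort("`extinction_threshold` must lie in (0, 1).")
  }
  if (horizon <= 0) abort("`horizon` must be > 0.")
  if (!is.null(pulse)) {
    pulse <- as.list(pulse)
    need <- c("onset", "duration", "level")
    if (!all(need %in% names(pulse))) {
      abort("`pulse` needs elements `onset`, `duration`, `level`.")
    }
    pulse <- lapply(pulse[need], as.numeric)
    if (h > 0) abort("give either sustained `h` or a `pulse`, not both.")
    if (pulse$onset < 0 || pulse$duration <= 0 || pulse$level < 0 ||
        pulse$onset + pulse$duration > horizon) {
      abort("`pulse` window must satisfy 0 <= onset < onset + duration <= horizon, level >= 0.")
    }
  }
  if (!is.null(disturbance_mortality)) {
    stopifnot(is.numeric(disturbance_mortality), disturbance_mortality > 0)
  }
  if (is.null(output_times)) {
    output_times <- c(0, exp(seq(log(horizon / 1e4), log(horizon), length.out = 64)))
    output_times[length(output_times)] <- horizon  # guard rounding past the horizon
  } else {
    output_times <- sort(unique(as.numeric(output_times)))
    if (min(output_times) < 0 || max(output_times) > horizon) {
      abort("`output_times` must lie in [0, horizon].")
    }
  }
  structure(
    list(invader_rank = invader_rank, h = h, pulse = pulse,
         mortality_delta = mortality_delta,
         disturbance_mortality = disturbance_mortality,
         horizon = horizon, output_times = output_times,
         extinction_threshold = extinction_threshold),
    class = "scenario_config"
  )
}

#' Apply a scenario to a baseline metacommunity
#'
#' Pure mapping from a baseline community and a [scenario_config()] to a
#' time-dependent parameterisation: only the invader's `h` and `m` (and,
#' under disturbance, every species' `m`) differ from baseline, and `h_a`
#' is piecewise-constant in time (one epoch for sustained supply, three for
#' a pulse). The baseline object is not modified.
#'
#' @param mc A baseline feasible [metacommunity()].
#' @param cfg A [scenario_config()] valid for `mc`.
#' @return A `scenario_params` list: `baseline`, `manipulated` (sustained /
#'   post-pulse parameters, used for the analytic end state), `schedule`
#'   (tibble of epochs `t0`, `t1`, `h_a`), and `cfg`.
#' @export
apply_scenario <- function(mc, cfg) {
  stopifnot(inherits(mc, "metacommunity"), inherits(cfg, "scenario_config"))
  n <- nrow(mc)
  a <- cfg$invader_rank
  if (a > n) abort(sprintf("`invader_rank` = %d out of range for %d species.", a, n))
  m2 <- if (is.null(cfg$disturbance_mortality)) mc$m else rep(cfg$disturbance_mortality, n)
  m2[a] <- m2[a] - cfg$mortality_delta
  if (m2[a] <= 0) {
    abort(sprintf("mortality delta %g leaves invader mortality %g <= 0.",
                  cfg$mortality_delta, m2[a]))
  }
  h2 <- mc$h
  h2[a] <- cfg$h   # sustained level; pulses live in the schedule
  manipulated <- metacommunity(
    c = mc$c, m = m2, h = h2,
    community_id = attr(mc, "community_id"),
    seed_provenance = attr(mc, "seed_provenance"),
    invader_rank = a, check_tradeoff = FALSE
  )
  if (is.null(cfg$pulse)) {
    schedule <- tibble::tibble(t0 = 0, t1 = cfg$horizon, h_a = cfg$h)
  } else {
    p <- cfg$pulse
    schedule <- tibble::tibble(
      t0 = c(0, p$onset, p$onset + p$duration),
      t1 = c(p$onset, p$onset + p$duration, cfg$horizon),
      h_a = c(0, p$level, 0)
    )
    schedule <- schedule[schedule$t1 > schedule$t0, , drop = FALSE]
  }
  structure(list(baseline = mc, manipulated = manipulated,
                 schedule = schedule, cfg = cfg),
            class = "scenario_params")
}

#' @export
print.scenario_params <- function(x, ...) {
  cat(sprintf("<scenario_params> invader rank %d, %d epoch(s), horizon %g\n",
              x$cfg$invader_rank, nrow(x$schedule), x$cfg$horizon))
  invisible(x)
}
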