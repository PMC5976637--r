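#' Run one invasion experiment end to end
#'
#' Composes [apply_scenario()], [integrate_occupancy()] and
#' [detect_extinctions()] for a single community, and additionally solves
#' the analytic end state of the manipulated parameterisation (the
#' "eventual" outcome, free of horizon artefacts). The extinction timeline
#' reports, at every output time, the proportion of the `N - 1` native
#' species extinct so far; the invader is never counted.
#'
#' @param mc A baseline feasible [metacommunity()].
#' @param cfg A [scenario_config()].
#' @param ... Passed on to [integrate_occupancy()].
#' @return An `invasion_run` object with components `trajectory`,
#'   `extinctions`, `timeline`, `eventual`, plus `cfg` and the
#'   `community_id`. Use [tidy()] for per-species records, [glance()] for a
#'   one-row summary, and [autoplot()] for a relative-abundance plot.
#' @examples
#' ens <- make_fixture_ensemble(n_species = 3, count = 1, seed = 5)
#' run <- run_invasion(ens[[1]], scenario_config(invader_rank = 2, h = 0.05))
#' glance(run)
#' @export
run_invasion <- function(mc, cfg, ...) {
  stopifnot(inherits(mc, "metacommunity"), inherits(cfg, "scenario_config"))
  eqb <- solve_equilibrium_vec(mc$c, mc$m, mc$h)
  if (!eqb$feasible) abort("`mc` must be a feasible baseline community.")
  sp <- apply_scenario(mc, cfg)
  traj <- integrate_occupancy(sp, ...)
  ext <- detect_extinctions(traj)
  natives <- ext$rank != cfg$invader_rank
  crossing <- ext$first_crossing_time
  timeline <- tibble::tibble(
    time = cfg$output_times,
    prop_extinct = vapply(cfg$output_times, function(t) {
      mean(!is.na(crossing[natives]) & crossing[natives] <= t)
    }, numeric(1))
  )
  man <- sp$manipulated
  pe <- solve_equilibrium_vec(man$c, man$m, man$h)
  eventual <- tibble::tibble(
    rank = mc$rank, native = mc$rank != cfg$invader_rank,
    p_star = pe$p, ratio_to_baseline = pe$p / eqb$p,
    extinct = pe$p / eqb$p < cfg$extinction_threshold
  )
  structure(list(trajectory = traj, extinctions = ext, timeline = timeline,
                 eventual = eventual, cfg = cfg,
                 community_id = attr(mc, "community_id")),
            class = "invasion_run")
}

#' @export
print.invasion_run <- function(x, ...) {
  cat(sprintf(
    "<invasion_run> invader rank %d: %d native extinction(s) by t = %g, %d eventual\n",
    x$cfg$invader_rank,
    sum(x$extinctions$extinct & x$extinctions$native),
    x$cfg$horizon,
    sum(x$eventual$extinct & x$eventual$native)))
  invisible(x)
}

#' @rdname run_invasion
#' @param x An `invasion_run`.
#' @export
tidy.invasion_run <- function(x, ...) {
  dplyr::left_join(
    x$extinctions,
    dplyr::select(x$eventual, "rank",
                  eventual_ratio = "ratio_to_baseline",
                  eventual_extinct = "extinct"),
    by = "rank"
  )
}

#' @rdname run_invasion
#' @export
glance.invasion_run <- function(x, ...) {
  nat <- x$extinctions$native
  tibble::tibble(
    community_id = x$community_id,
    invader_rank = x$cfg$invader_rank,
    h = x$cfg$h,
    mortality_delta = x$cfg$mortality_delta,
    disturbance = x$cfg$disturbance_mortality %||% NA_real_,
    pulsed = !is.null(x$cfg$pulse),
    horizon = x$cfg$horizon,
    n_extinct = sum(x$extinctions$extinct & nat),
    n_extinct_eventual = sum(x$eventual$extinct & x$eventual$native),
    prop_extinct = sum(x$extinctions$extinct & nat) / sum(nat)
  )
}

# analytic eventual extinction count for a sustained manipulation; fast path
# used by sweeps (no integration)
eventual_count <- function(mc, invader_rank, h = 0, mortality_delta = 0,
                           disturbance = NULL, threshold = 1e-4) {
  n <- nrow(mc)
  pb <- solve_equilibrium_vec(mc$c, mc$m, mc$h)$p
  m2 <- if (is.null(disturbance) || is.na(disturbance)) mc$m else rep(disturbance, n)
  m2[invader_rank] <- m2[invader_rank] - mortality_delta
  if (m2[invader_rank] <= 0) abort("mortality delta leaves invader mortality <= 0.")
  h2 <- mc$h
  h2[invader_rank] <- h
  pe <- solve_equilibrium_vec(mc$c, m2, h2)$p
  sum((pe / pb < threshold)[-invader_rank])
}
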