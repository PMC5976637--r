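#' Build a grid of scenario conditions
#'
#' Full crossing of invader ranks with propagule levels, enemy-release
#' mortality reductions and community-wide disturbance levels. Defaults
#' follow the study design: four invader ranks spanning the hierarchy, 21
#' propagule levels on `[0, 0.1]`, no mortality reduction, no disturbance.
#'
#' @param invader_ranks Integer ranks of the manipulated species.
#' @param h_values Sustained external propagule levels.
#' @param mortality_deltas Invader mortality reductions.
#' @param disturbance_levels Community-wide mortality replacements; `NA`
#'   means unchanged.
#' @return A tibble with columns `invader_rank`, `h`, `mortality_delta`,
#'   `disturbance`, one row per grid point.
#' @export
sweep_grid <- function(invader_ranks = c(1, 7, 13, 19),
                       h_values = seq(0, 0.1, length.out = 21),
                       mortality_deltas = 0,
                       disturbance_levels = NA_real_) {
  stopifnot(all(invader_ranks >= 1), all(h_values >= 0),
            all(mortality_deltas >= 0))
  tidyr::expand_grid(
    invader_rank = as.integer(invader_ranks),
    h = as.numeric(h_values),
    mortality_delta = as.numeric(mortality_deltas),
    disturbance = as.numeric(disturbance_levels)
  )
}

#' Mean and quantile envelope of ensemble measurements
#'
#' Arithmetic mean plus a pointwise quantile envelope of per-community
#' values, using the linear-interpolation quantile convention
#' (`stats::quantile()` type 7). With `coverage = 0.95` the envelope runs
#' from the 2.5th to the 97.5th percentile; `coverage = 1` gives the range.
#'
#' @param values Numeric vector of per-community measurements (nonempty).
#' @param coverage Envelope coverage in `[0, 1]`.
#' @return A one-row tibble with columns `lower`, `mean`, `upper`.
#' @examples
#' envelope(c(0, 0, 0, 1))
#' @export
envelope <- function(values, coverage = 0.95) {
  values <- as.numeric(values)
  if (length(values) == 0L) abort("`values` must be nonempty.")
  stopifnot(coverage >= 0, coverage <= 1)
  alpha <- (1 - coverage) / 2
  q <- unname(quantile(values, probs = c(alpha, 1 - alpha), type = 7))
  tibble::tibble(lower = q[1], mean = mean(values), upper = q[2])
}

#' Run a scenario grid across an ensemble
#'
#' Evaluates, for every (community, grid point) pair, the eventual native
#' extinction proportion under the analytic end state of the manipulated
#' equilibrium (horizon-free, matching the plateau reading: where curves
#' plateau, all inferior competitors are extinct), and aggregates across
#' communities into a mean and quantile envelope. Deterministic given the
#' ensemble and grid; communities enter every grid point, so aggregation is
#' permutation-invariant.
#'
#' @param ensemble An `mc_ensemble` (or plain list of [metacommunity()]).
#' @param grid A [sweep_grid()] tibble.
#' @param extinction_threshold Fraction of baseline equilibrium below which
#'   a species counts as extinct.
#' @param coverage Envelope coverage (default 0.95).
#' @return An `ensemble_summary` tibble: grid columns plus `mean_extinct`,
#'   `lo95`, `hi95`, `n_communities`. Per-community counts are retained in
#'   `attr(, "counts")` for audit; any per-community failure is recorded in
#'   `attr(, "failures")` and raised as a warning.
#' @export
run_sweep <- function(ensemble, grid, extinction_threshold = 1e-4,
                      coverage = 0.95) {
  communities <- as_community_list(ensemble)
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  n_sp <- nrow(communities[[1]])
  if (any(grid$invader_rank > n_sp)) {
    abort(sprintf("grid invader ranks exceed the %d-species communities.", n_sp))
  }
  per_comm <- purrr::imap(communities, function(mc, k) {
    id <- attr(mc, "community_id") %||% as.character(k)
    tryCatch({
      cnt <- purrr::pmap_dbl(
        grid[c("invader_rank", "h", "mortality_delta", "disturbance")],
        function(invader_rank, h, mortality_delta, disturbance) {
          eventual_count(mc, invader_rank, h = h,
                         mortality_delta = mortality_delta,
                         disturbance = disturbance,
                         threshold = extinction_threshold)
        })
      dplyr::bind_cols(grid, tibble::tibble(
        community_id = id, n_extinct = cnt,
        prop_extinct = cnt / (n_sp - 1)))
    }, error = function(e) {
      tibble::tibble(community_id = id, error = conditionMessage(e))
    })
  })
  failed <- vapply(per_comm, function(x) "error" %in% names(x), logical(1))
  failures <- if (any(failed)) dplyr::bind_rows(per_comm[failed]) else NULL
  if (any(failed)) {
    warn(sprintf("%d community(ies) failed and were excluded from the sweep.",
                 sum(failed)))
  }
  if (all(failed)) {
    abort("every community failed under this grid; see the error messages above.")
  }
  counts <- dplyr::bind_rows(per_comm[!failed])
  summary <- counts |>
    dplyr::group_by(.data$invader_rank, .data$h, .data$mortality_delta,
                    .data$disturbance) |>
    dplyr::summarise(
      mean_extinct = mean(.data$prop_extinct),
      lo95 = quantile(.data$prop_extinct, (1 - coverage) / 2, type = 7,
                      names = FALSE),
      hi95 = quantile(.data$prop_extinct, 1 - (1 - coverage) / 2, type = 7,
                      names = FALSE),
      n_communities = dplyr::n(),
      .groups = "drop"
    )
  structure(summary,
            class = c("ensemble_summary", class(summary)),
            counts = counts, failures = failures, coverage = coverage,
            extinction_threshold = extinction_threshold)
}

as_community_list <- function(ensemble) {
  communities <- if (inherits(ensemble, "mc_ensemble")) ensemble$communities
                 else if (inherits(ensemble, "metacommunity")) list(ensemble)
                 else ensemble
  if (length(communities) == 0L) abort("`ensemble` must contain at least one community.")
  stopifnot(all(vapply(communities, inherits, logical(1), "metacommunity")))
  communities
}

#' Ensemble timeline of native extinctions
#'
#' Runs the same scenario on every community in an ensemble and aggregates
#' the per-time proportion of natives extinct so far into a mean and
#' quantile envelope. Per-community timelines are non-decreasing in time
#' because extinction is absorbing in the accounting.
#'
#' @inheritParams run_sweep
#' @param cfg A [scenario_config()] applied to every community.
#' @param ... Passed on to [run_invasion()].
#' @return A `timeline_summary` tibble: `time`, `mean_extinct`, `lo95`,
#'   `hi95`, `n_communities`, with per-community timelines in
#'   `attr(, "timelines")`.
#' @export
extinction_timeline_summary <- function(ensemble, cfg, coverage = 0.95, ...) {
  communities <- as_community_list(ensemble)
  stopifnot(inherits(cfg, "scenario_config"))
  timelines <- purrr::imap_dfr(communities, function(mc, k) {
    id <- attr(mc, "community_id") %||% as.character(k)
    run <- run_invasion(mc, cfg, ...)
    dplyr::bind_cols(community_id = id, run$timeline)
  })
  summary <- timelines |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(
      mean_extinct = mean(.data$prop_extinct),
      lo95 = quantile(.data$prop_extinct, (1 - coverage) / 2, type = 7,
                      names = FALSE),
      hi95 = quantile(.data$prop_extinct, 1 - (1 - coverage) / 2, type = 7,
                      names = FALSE),
      n_communities = dplyr::n(),
      .groups = "drop"
    )
  structure(summary,
            class = c("timeline_summary", class(summary)),
            timelines = timelines, cfg = cfg, coverage = coverage)
}
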