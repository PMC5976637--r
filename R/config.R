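#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration describing an ensemble search plus
#' optional scenario and sweep definitions, fills defaults (the study
#' conditions: 20 species, c ~ U(0, 5), m = 0.05, 250 communities), and
#' validates every field before any computation starts. Unknown keys are
#' rejected, naming the offending field, to guard against typos.
#'
#' Recognised sections and keys:
#' \describe{
#'   \item{ensemble}{arguments of [ensemble_spec()]}
#'   \item{scenario}{arguments of [scenario_config()]}
#'   \item{sweep}{arguments of [sweep_grid()]}
#'   \item{seed}{master seed overriding `ensemble$seed`}
#'   \item{output_dir}{where run artefacts should be written}
#' }
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `invasim_config` list with elements `ensemble`
#'   (an [ensemble_spec()]), `scenario` (a [scenario_config()] or `NULL`),
#'   `sweep` (a [sweep_grid()] tibble or `NULL`), and `output_dir`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  raw <- raw %||% list()
  check_keys(raw, c("ensemble", "scenario", "sweep", "seed", "output_dir"),
             "top level")
  ens_args <- raw$ensemble %||% list()
  check_keys(ens_args, names(formals(ensemble_spec)), "ensemble")
  if (!is.null(raw$seed)) ens_args$seed <- raw$seed
  spec <- do.call(ensemble_spec, ens_args)
  scenario <- NULL
  if (!is.null(raw$scenario)) {
    sc_args <- raw$scenario
    check_keys(sc_args, names(formals(scenario_config)), "scenario")
    scenario <- do.call(scenario_config, sc_args)
    if (scenario$invader_rank > spec$n_species) {
      abort(sprintf(
        "scenario$invader_rank = %d exceeds ensemble$n_species = %d.",
        scenario$invader_rank, spec$n_species))
    }
  }
  sweep <- NULL
  if (!is.null(raw$sweep)) {
    sw_args <- raw$sweep
    check_keys(sw_args, names(formals(sweep_grid)), "sweep")
    sweep <- do.call(sweep_grid, sw_args)
    if (any(sweep$invader_rank > spec$n_species)) {
      abort(sprintf("sweep invader ranks exceed ensemble$n_species = %d.",
                    spec$n_species))
    }
  }
  structure(list(ensemble = spec, scenario = scenario, sweep = sweep,
                 output_dir = raw$output_dir %||% "."),
            class = "invasim_config")
}

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    abort(sprintf("unknown %s key(s): %s", where, paste(bad, collapse = ", ")))
  }
}

#' Serialise a configuration back to YAML
#'
#' Inverse of [load_config()] up to default filling: dumping and re-loading
#' yields an equivalent configuration.
#'
#' @param config An `invasim_config`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "invasim_config"))
  out <- list(ensemble = unclass(config$ensemble))
  if (!is.null(config$scenario)) {
    sc <- config$scenario
    out$scenario <- list(
      invader_rank = sc$invader_rank, h = sc$h, pulse = sc$pulse,
      mortality_delta = sc$mortality_delta,
      disturbance_mortality = sc$disturbance_mortality,
      horizon = sc$horizon, output_times = sc$output_times,
      extinction_threshold = sc$extinction_threshold
    )
    out$scenario <- out$scenario[!vapply(out$scenario, is.null, logical(1))]
  }
  if (!is.null(config$sweep)) {
    out$sweep <- list(
      invader_ranks = unique(config$sweep$invader_rank),
      h_values = unique(config$sweep$h),
      mortality_deltas = unique(config$sweep$mortality_delta),
      disturbance_levels = unique(config$sweep$disturbance)
    )
  }
  out$output_dir <- config$output_dir
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Small feasible ensemble for tests and examples
#'
#' Fast seeded generation of small coexisting communities (feasibility is
#' common at low species counts, so plain rejection sampling suffices in
#' well under a second). Communities follow the same generative
#' distribution as the full search, at reduced `n_species`.
#'
#' @param n_species Species count, 2..6.
#' @param count Number of communities.
#' @param seed Seed for the draws.
#' @param c_low,c_high,m Generative parameters, as in [ensemble_spec()].
#' @return An `mc_ensemble`.
#' @export
make_fixture_ensemble <- function(n_species = 3, count = 20, seed = 42,
                                  c_low = 0, c_high = 5, m = 0.05) {
  stopifnot(n_species >= 2, n_species <= 6, count >= 1)
  set.seed(seed)
  communities <- vector("list", count)
  found <- 0L
  draws <- 0L
  while (found < count) {
    draws <- draws + 1L
    cvals <- sort(runif(n_species, c_low, c_high))
    if (solve_equilibrium_vec(cvals, rep(m, n_species), rep(0, n_species))$feasible) {
      found <- found + 1L
      communities[[found]] <- metacommunity(
        c = cvals, m = m, h = 0,
        community_id = sprintf("fix_s%d_n%d_%d", seed, n_species, found),
        seed_provenance = list(seed = seed, draw_index = draws,
                               generator = "make_fixture_ensemble")
      )
    }
  }
  spec <- ensemble_spec(n_species = n_species, c_low = c_low, c_high = c_high,
                        m = m, target_count = count, max_draws = draws,
                        seed = seed)
  report <- tibble::tibble(draws_used = draws, accepted = count,
                           acceptance_rate = count / draws, blocks = NA_integer_,
                           seed = as.integer(seed), status = "complete")
  structure(list(communities = communities, spec = spec, report = report),
            class = "mc_ensemble")
}
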