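test_that("envelope follows the linear-interpolation quantile convention", {
  # all equal values collapse the band
  expect_equal(envelope(rep(0.3, 7)), tibble::tibble(lower = 0.3, mean = 0.3, upper = 0.3))
  # frozen worked example, checked against the hand-written quantile oracle
  e <- envelope(c(0, 0, 0, 1))
  expect_equal(e$mean, 0.25)
  expect_equal(e$lower, oracle_quantile(c(0, 0, 0, 1), 0.025))
  expect_equal(e$upper, oracle_quantile(c(0, 0, 0, 1), 0.975))
  expect_equal(e$lower, 0)
  expect_equal(e$upper, 0.925)
  # full coverage gives the range
  x <- c(0.2, 0.9, 0.4, 0.1)
  expect_equal(envelope(x, coverage = 1),
               tibble::tibble(lower = 0.1, mean = mean(x), upper = 0.9))
  # random draws against the oracle
  set.seed(42)
  for (n in c(2, 5, 40)) {
    v <- runif(n)
    e <- envelope(v)
    expect_equal(e$lower, oracle_quantile(v, 0.025))
    expect_equal(e$upper, oracle_quantile(v, 0.975))
  }
  expect_error(envelope(numeric(0)), "nonempty")
})

test_that("baseline grid points have zero extinction and zero-width envelopes", {
  ens <- small_ensemble(5, 10, seed = 17)
  sw <- run_sweep(ens, sweep_grid(invader_ranks = c(1, 3),
                                  h_values = c(0, 0.05)))
  at0 <- dplyr::filter(sw, .data$h == 0)
  expect_true(all(at0$mean_extinct == 0))
  expect_true(all(at0$lo95 == 0 & at0$hi95 == 0))
  expect_identical(unique(sw$n_communities), 10L)
})

test_that("extinction proportions are capped by the number of inferior competitors", {
  ens <- small_ensemble(5, 10, seed = 17)
  n <- 5
  grid <- sweep_grid(invader_ranks = c(2, 4), h_values = seq(0, 0.2, by = 0.02))
  sw <- run_sweep(ens, grid)
  counts <- attr(sw, "counts")
  for (a in c(2, 4)) {
    cc <- dplyr::filter(counts, .data$invader_rank == a)
    expect_true(all(cc$prop_extinct <= (n - a) / (n - 1) + 1e-12))
    expect_true(all(cc$n_extinct[cc$h == 0] == 0))
  }
  # strong pressure displaces more than none: the mean curve ends above its start
  means <- dplyr::filter(sw, .data$invader_rank == 2)
  expect_gt(means$mean_extinct[which.max(means$h)], means$mean_extinct[means$h == 0])
})

test_that("the invader itself always gains from propagule supply or enemy release", {
  ens <- small_ensemble(5, 10, seed = 17)
  for (k in 1:10) {
    mc <- ens[[k]]
    pb <- solve_equilibrium(mc)$p_star
    inv_h <- sapply(seq(0, 0.2, by = 0.02), function(hv) {
      h2 <- replace(mc$h, 2, hv)
      invasim:::solve_equilibrium_vec(mc$c, mc$m, h2)$p[2] / pb[2]
    })
    expect_true(all(diff(inv_h) >= -1e-12))
    inv_d <- sapply(seq(0, 0.045, by = 0.005), function(dv) {
      m2 <- replace(mc$m, 2, mc$m[2] - dv)
      invasim:::solve_equilibrium_vec(mc$c, m2, mc$h)$p[2] / pb[2]
    })
    expect_true(all(diff(inv_d) >= -1e-12))
  }
})

test_that("count drops along an h sweep are competitive release, not noise", {
  # displacing rank a+1 can free microsites that rescue a lower-ranked
  # species at higher h; wherever a community's count drops, the rescued
  # species must be an inferior competitor and its equilibrium must have
  # genuinely recovered
  ens <- small_ensemble(5, 10, seed = 17)
  hgrid <- seq(0, 0.2, by = 0.02)
  a <- 2
  n_drops <- 0
  for (k in 1:10) {
    mc <- ens[[k]]
    pb <- solve_equilibrium(mc)$p_star
    ext_sets <- lapply(hgrid, function(hv) {
      pe <- invasim:::solve_equilibrium_vec(mc$c, mc$m, replace(mc$h, a, hv))$p
      which(pe / pb < 1e-4)
    })
    for (i in seq_along(hgrid)[-1]) {
      rescued <- setdiff(ext_sets[[i - 1]], ext_sets[[i]])
      if (length(rescued)) {
        n_drops <- n_drops + 1
        expect_true(all(rescued > a))
        # something else must have been displaced to free the space
        expect_true(length(setdiff(ext_sets[[i]], ext_sets[[i - 1]])) > 0 ||
                      length(ext_sets[[i]]) < length(ext_sets[[i - 1]]))
      }
    }
  }
  expect_gt(n_drops, 0)  # the fixture does exhibit the mechanism
})

test_that("sweeps are deterministic and permutation-invariant over communities", {
  ens <- small_ensemble(4, 8, seed = 3)
  grid <- sweep_grid(invader_ranks = 2, h_values = c(0, 0.03, 0.09))
  s1 <- run_sweep(ens, grid)
  s2 <- run_sweep(ens, grid)
  strip <- function(x) as.data.frame(lapply(x, identity))
  expect_identical(strip(s1), strip(s2))
  shuffled <- structure(
    list(communities = rev(ens$communities), spec = ens$spec, report = ens$report),
    class = "mc_ensemble")
  s3 <- run_sweep(shuffled, grid)
  expect_equal(strip(s1), strip(s3))
})

test_that("sweep validation and failure accounting work", {
  ens <- small_ensemble(4, 4, seed = 3)
  expect_error(run_sweep(ens, sweep_grid(invader_ranks = 9, h_values = 0.1)),
               "exceed")
  # a community whose invader cannot sustain the mortality reduction is
  # excluded with a warning; the rest are analysed
  frail <- metacommunity(ens[[2]]$c, m = replace(ens[[2]]$m, 2, 0.03),
                         community_id = "frail", check_tradeoff = FALSE)
  mixed <- list(ens[[1]], frail)
  grid <- sweep_grid(invader_ranks = 2, h_values = 0, mortality_deltas = 0.045)
  expect_warning(sw <- run_sweep(mixed, grid), "excluded")
  expect_identical(nrow(attr(sw, "failures")), 1L)
  expect_identical(attr(sw, "failures")$community_id, "frail")
  expect_identical(unique(sw$n_communities), 1L)
  # if no community survives the grid, that is an error, not empty output
  expect_error(suppressWarnings(
    run_sweep(ens, sweep_grid(invader_ranks = 2, h_values = 0,
                              mortality_deltas = 0.05))),
    "every community")
})

test_that("ensemble timelines start at zero and never decrease", {
  ens <- small_ensemble(5, 6, seed = 17)
  tl <- extinction_timeline_summary(ens, scenario_config(2, h = 0.08,
                                                         horizon = 20000))
  percomm <- attr(tl, "timelines")
  expect_true(all(percomm$prop_extinct[percomm$time == 0] == 0))
  for (id in unique(percomm$community_id)) {
    pc <- dplyr::arrange(dplyr::filter(percomm, .data$community_id == id),
                         .data$time)
    expect_true(all(diff(pc$prop_extinct) >= 0))
  }
  expect_true(all(tl$lo95 <= tl$mean_extinct & tl$mean_extinct <= tl$hi95))
})

test_that("sustained timelines reach the analytic eventual count", {
  ens <- small_ensemble(5, 10, seed = 17)
  cfg <- scenario_config(2, h = 0.07, horizon = 50000)
  tl <- extinction_timeline_summary(ens, cfg)
  percomm <- attr(tl, "timelines")
  final <- dplyr::filter(percomm, .data$time == max(.data$time))
  eventual <- purrr::map_dbl(ens$communities, function(mc) {
    run <- run_invasion(mc, cfg)
    sum(run$eventual$extinct & run$eventual$native) / (nrow(mc) - 1)
  })
  expect_gte(mean(abs(final$prop_extinct - eventual) < 1e-12), 0.95)
})
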