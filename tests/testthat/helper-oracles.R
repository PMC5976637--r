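# Independent reference implementations used as oracles. Deliberately
# written as naive loops, sharing no code with the package internals.

`%or%` <- function(a, b) if (is.null(a)) b else a

# direct transcription of the occupancy equations, one species at a time
oracle_rhs <- function(p, cv, m, h) {
  n <- length(p)
  dp <- numeric(n)
  for (i in seq_len(n)) {
    gain <- (cv[i] * p[i] + h[i]) * (1 - sum(p[seq_len(i)]))
    loss <- m[i] * p[i]
    if (i > 1) {
      for (j in seq_len(i - 1)) loss <- loss + (cv[j] * p[j] + h[j]) * p[i]
    }
    dp[i] <- gain - loss
  }
  dp
}

# long-horizon integration built directly on the oracle RHS
oracle_integrate_end <- function(cv, m, h, p0, t_end, rtol = 1e-10, atol = 1e-14) {
  sol <- deSolve::lsoda(
    y = p0, times = c(0, t_end),
    func = function(t, y, parms) list(oracle_rhs(pmax(y, 0), cv, m, h)),
    rtol = rtol, atol = atol
  )
  pmax(sol[nrow(sol), -1], 0)
}

# type-7 (linear interpolation) quantile, written out by hand
oracle_quantile <- function(x, prob) {
  x <- sort(x)
  n <- length(x)
  pos <- (n - 1) * prob + 1
  lo <- floor(pos)
  hi <- ceiling(pos)
  x[lo] + (pos - lo) * (x[hi] - x[lo])
}

# plain-loop rejection sampler following the published draw-stream contract:
# draw d consumes N uniforms in order; accepted iff the sequential
# equilibrium is feasible (solved here with its own small recursion)
oracle_feasible_draw <- function(cv, m0, tol = 1e-12) {
  n <- length(cv)
  S <- 0
  A <- m0
  for (i in seq_len(n)) {
    pi <- (1 - S) - A / cv[i]
    if (pi <= tol) return(FALSE)
    S <- S + pi
    A <- A + cv[i] * pi
  }
  TRUE
}

oracle_loop_search <- function(n_draws, n_species, c_low, c_high, m0, seed_val) {
  set.seed(seed_val)
  accepted <- list()
  idx <- integer(0)
  for (d in seq_len(n_draws)) {
    cv <- sort(runif(n_species, c_low, c_high))
    if (oracle_feasible_draw(cv, m0)) {
      accepted <- c(accepted, list(cv))
      idx <- c(idx, d)
    }
  }
  list(accepted = accepted, draw_index = idx)
}

# shared small fixtures (built once per test run)
fixture_cache <- new.env(parent = emptyenv())

small_ensemble <- function(n_species = 4, count = 10, seed = 21) {
  key <- sprintf("ens_%d_%d_%d", n_species, count, seed)
  if (is.null(fixture_cache[[key]])) {
    fixture_cache[[key]] <- make_fixture_ensemble(n_species, count, seed = seed)
  }
  fixture_cache[[key]]
}
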