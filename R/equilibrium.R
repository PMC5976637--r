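#' Right-hand side of the patch-occupancy dynamics
#'
#' Computes the time derivative of the proportion of microsites occupied by
#' each species under hierarchical competition-colonisation dynamics:
#'
#' \deqn{dp_i/dt = (c_i p_i + h_i)\,(1 - \sum_{j \le i} p_j)
#'   - (m_i + \sum_{j < i} (c_j p_j + h_j))\, p_i}
#'
#' Species `i` gains sites it colonises among those not held by itself or a
#' superior competitor, and loses sites to mortality and to displacement by
#' superior competitors' propagules (natural, `c_j p_j`, plus external,
#' `h_j`). The derivative for species `i` depends only on species `j <= i`.
#'
#' @param mc A [metacommunity()].
#' @param p Numeric vector of occupancies, one per rank; all `p_i >= 0` and
#'   `sum(p) <= 1`.
#' @return A tibble with columns `rank`, `p`, `dp_dt`.
#' @examples
#' occupancy_rhs(metacommunity(1), p = 0.5)
#' @export
occupancy_rhs <- function(mc, p) {
  stopifnot(inherits(mc, "metacommunity"))
  p <- as.numeric(p)
  if (length(p) != nrow(mc)) {
    abort(sprintf("`p` must have length %d (one occupancy per species).", nrow(mc)))
  }
  if (any(!is.finite(p)) || any(p < 0)) abort("occupancies `p` must be finite and >= 0.")
  if (sum(p) > 1 + 1e-9) abort("occupancies must satisfy sum(p) <= 1.")
  tibble::tibble(rank = mc$rank, p = p,
                 dp_dt = rhs_vec(p, mc$c, mc$m, mc$h))
}

#' Sequential equilibrium of a metacommunity
#'
#' Solves for the steady state of the occupancy dynamics one species at a
#' time, from the best competitor down: each species' equilibrium only
#' depends on the species ranked above it. Writing
#' \eqn{S_i = \sum_{j<i} p_j^*} and
#' \eqn{D_i = m_i + \sum_{j<i} (c_j p_j^* + h_j)},
#' the steady state with `h_i = 0` is
#' \eqn{p_i^* = (1 - S_i) - D_i / c_i}, and with `h_i > 0` it is the unique
#' nonnegative root of
#' \eqn{-c_i p^2 + p\,(c_i (1 - S_i) - h_i - D_i) + h_i (1 - S_i) = 0}
#' (the product of roots is \eqn{-h_i(1-S_i)/c_i \le 0}, so exactly one root
#' is nonnegative whenever space remains). A species whose solved occupancy
#' is at or below `tol` is set to exactly 0 (extinct at equilibrium) before
#' the recursion continues, so extinct species exert no competitive pressure.
#'
#' @param mc A [metacommunity()].
#' @param tol Feasibility tolerance: occupancies must exceed `tol` to count
#'   as strictly positive. Default `1e-12`, guarding against numerically-zero
#'   coexistence.
#' @return A tibble with columns `rank`, `c`, `m`, `h`, `p_star`, `p_raw`
#'   (the pre-clamping solution) and attribute `feasible`: `TRUE` iff all
#'   species have `p_star > tol`. Query it with [is_feasible()].
#' @examples
#' solve_equilibrium(metacommunity(c(0.0625, 0.15625)))  # p* = (0.2, 0.4)
#' @export
solve_equilibrium <- function(mc, tol = 1e-12) {
  stopifnot(inherits(mc, "metacommunity"))
  sol <- solve_equilibrium_vec(mc$c, mc$m, mc$h, tol = tol)
  out <- tibble::tibble(rank = mc$rank, c = mc$c, m = mc$m, h = mc$h,
                        p_star = sol$p, p_raw = sol$raw)
  structure(out, feasible = sol$feasible,
            class = c("mc_equilibrium", class(out)),
            community_id = attr(mc, "community_id"), tol = tol)
}

# numeric core of the sequential solver; returns list(p, raw, feasible)
solve_equilibrium_vec <- function(cvec, m, h, tol = 1e-12) {
  n <- length(cvec)
  p <- raw <- numeric(n)
  S <- 0     # occupied space above rank i
  A <- 0     # superior propagule pressure: sum_{j<i} (c_j p_j + h_j)
  for (i in seq_len(n)) {
    D <- m[i] + A
    space <- 1 - S
    if (h[i] <= 0) {
      pi <- if (cvec[i] > 0) space - D / cvec[i] else 0
    } else if (space <= 0) {
      pi <- 0
    } else if (cvec[i] <= 0) {
      # degenerate linear case: p (h + D) = h (1 - S)
      pi <- h[i] * space / (h[i] + D)
    } else {
      B <- cvec[i] * space - h[i] - D
      pi <- (B + sqrt(B * B + 4 * cvec[i] * h[i] * space)) / (2 * cvec[i])
    }
    raw[i] <- pi
    if (pi <= tol) pi <- 0
    p[i] <- pi
    S <- S + pi
    A <- A + cvec[i] * pi + h[i]
  }
  list(p = p, raw = raw, feasible = all(p > tol))
}

#' Is a metacommunity (or solved equilibrium) feasible?
#'
#' Feasibility means every species has strictly positive occupancy at the
#' sequentially solved equilibrium — the acceptance rule for ensemble
#' membership.
#'
#' @param x A [metacommunity()] or the result of [solve_equilibrium()].
#' @param tol Feasibility tolerance (see [solve_equilibrium()]).
#' @return Logical scalar.
#' @export
is_feasible <- function(x, tol = 1e-12) {
  if (inherits(x, "mc_equilibrium")) return(isTRUE(attr(x, "feasible")))
  stopifnot(inherits(x, "metacommunity"))
  solve_equilibrium_vec(x$c, x$m, x$h, tol = tol)$feasible
}
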