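#' Construct a metacommunity parameter set
#'
#' A metacommunity is a set of `N` species competing for microsites under a
#' strict competitive hierarchy: rank 1 is the best competitor and displaces
#' all lower ranks from occupied sites. Coexistence is possible because
#' competitive rank trades off against colonisation ability: in a baseline
#' (tradeoff-conforming) community the colonisation rate `c` is strictly
#' increasing in rank, so the best competitor is the worst coloniser.
#'
#' The returned object is a tibble with one row per species, ordered by
#' competitive rank, and columns:
#' \describe{
#'   \item{rank}{competitive rank `i = 1..N` (1 = best competitor)}
#'   \item{c}{per-capita colonisation rate, per unit time (> 0)}
#'   \item{m}{per-capita mortality rate, per unit time (> 0)}
#'   \item{h}{external propagule rate: the fraction of all microsites that
#'     anthropogenic propagules could colonise per unit time in an empty
#'     landscape (>= 0)}
#' }
#'
#' @param c Numeric vector of colonisation rates, indexed by competitive rank.
#' @param m Mortality rate(s); a scalar is recycled to all species.
#' @param h External propagule rate(s); a scalar is recycled. Default 0.
#' @param community_id Optional opaque identifier (character scalar).
#' @param seed_provenance Optional list recording the random draws that
#'   produced the community (master seed, block, draw index).
#' @param invader_rank Rank of the single species allowed to sit off the
#'   tradeoff surface (manipulated `h`/`m`), or `NA` for a baseline community.
#' @param check_tradeoff If `TRUE` (default), require `c` strictly increasing
#'   in rank for all species except a flagged invader.
#'
#' @return A `metacommunity` tibble (see Details).
#' @examples
#' mc <- metacommunity(c = c(0.0625, 0.15625))
#' solve_equilibrium(mc)
#' @export
metacommunity <- function(c, m = 0.05, h = 0, community_id = NULL,
                          seed_provenance = NULL, invader_rank = NA_integer_,
                          check_tradeoff = TRUE) {
  c <- as.numeric(c)
  n <- length(c)
  if (n < 1L) abort("`c` must contain at least one colonisation rate.")
  m <- vctrs_recycle(as.numeric(m), n, "m")
  h <- vctrs_recycle(as.numeric(h), n, "h")
  if (any(!is.finite(c)) || any(c <= 0)) abort("all colonisation rates `c` must be finite and > 0.")
  if (any(!is.finite(m)) || any(m <= 0)) abort("all mortality rates `m` must be finite and > 0.")
  if (any(!is.finite(h)) || any(h < 0)) abort("all propagule rates `h` must be finite and >= 0.")
  invader_rank <- if (is.null(invader_rank) || is.na(invader_rank)) NA_integer_ else as.integer(invader_rank)
  if (!is.na(invader_rank) && (invader_rank < 1L || invader_rank > n)) {
    abort(sprintf("`invader_rank` must be in 1..%d.", n))
  }
  if (isTRUE(check_tradeoff)) {
    keep <- if (is.na(invader_rank)) seq_len(n) else setdiff(seq_len(n), invader_rank)
    cc <- c[keep]
    if (n > 1L && any(diff(cc) <= 0)) {
      abort(paste0(
        "colonisation rates must be strictly increasing in competitive rank ",
        "(tradeoff surface); flag a manipulated species via `invader_rank` ",
        "or set `check_tradeoff = FALSE`."
      ))
    }
    if (!is.na(invader_rank)) {
      hk <- h[keep]
      if (any(hk > 0)) abort("only the flagged invader may have h > 0 on a tradeoff-conforming community.")
    }
  }
  out <- tibble::tibble(rank = seq_len(n), c = c, m = m, h = h)
  structure(
    out,
    class = c("metacommunity", class(out)),
    community_id = community_id %||% NA_character_,
    seed_provenance = seed_provenance,
    invader_rank = invader_rank
  )
}

vctrs_recycle <- function(x, n, name) {
  if (length(x) == 1L) rep(x, n)
  else if (length(x) == n) x
  else abort(sprintf("`%s` must have length 1 or %d, not %d.", name, n, length(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of species in a metacommunity
#' @param mc A [metacommunity()].
#' @return Integer species count.
#' @export
n_species <- function(mc) {
  stopifnot(inherits(mc, "metacommunity"))
  nrow(mc)
}

#' @export
print.metacommunity <- function(x, ...) {
  id <- attr(x, "community_id")
  inv <- attr(x, "invader_rank")
  cat(sprintf(
    "<metacommunity> %d species%s%s\n", nrow(x),
    if (!is.na(id)) paste0(", id = ", id) else "",
    if (!is.na(inv)) paste0(", invader rank = ", inv) else ""
  ))
  NextMethod()
}

as_mc_list <- function(mc) {
  list(
    community_id = attr(mc, "community_id"),
    N = nrow(mc),
    c = mc$c, m = mc$m, h = mc$h,
    seed_provenance = attr(mc, "seed_provenance"),
    invader_rank = attr(mc, "invader_rank")
  )
}

mc_from_list <- function(x, check_tradeoff = TRUE) {
  inv <- x$invader_rank %||% NA_integer_
  if (length(inv) == 0L || identical(inv, "NA")) inv <- NA_integer_
  metacommunity(
    c = as.numeric(x$c), m = as.numeric(x$m), h = as.numeric(x$h),
    community_id = if (is.null(x$community_id) || is.na(x$community_id)) NULL else as.character(x$community_id),
    seed_provenance = x$seed_provenance,
    invader_rank = inv,
    check_tradeoff = check_tradeoff
  )
}

#' Write / read a single metacommunity as JSON
#'
#' Serialises `{community_id, N, c, m, h, seed_provenance}` with full numeric
#' precision so that the round trip is deterministic: reading the file back
#' reproduces the parameter values bit for bit.
#'
#' @param mc A [metacommunity()].
#' @param path File path.
#' @return `write_metacommunity_json()` returns `path` invisibly;
#'   `read_metacommunity_json()` returns a [metacommunity()].
#' @export
write_metacommunity_json <- function(mc, path) {
  stopifnot(inherits(mc, "metacommunity"))
  jsonlite::write_json(as_mc_list(mc), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_metacommunity_json
#' @param check_tradeoff Passed on to [metacommunity()].
#' @export
read_metacommunity_json <- function(path, check_tradeoff = TRUE) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mc_from_list(x, check_tradeoff = check_tradeoff)
}
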