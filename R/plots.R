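#' Plot the competition-colonisation tradeoff surface
#'
#' Colonisation rate against competitive rank for a community; the
#' manipulated invader (if flagged) is highlighted.
#'
#' @param mc A [metacommunity()].
#' @return A ggplot object.
#' @export
plot_tradeoff_surface <- function(mc) {
  stopifnot(inherits(mc, "metacommunity"))
  inv <- attr(mc, "invader_rank")
  df <- tibble::as_tibble(mc)
  df$invader <- !is.na(inv) & df$rank == inv
  ggplot2::ggplot(df, ggplot2::aes(x = .data$c, y = .data$rank)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$invader), size = 2,
                        show.legend = !is.na(inv)) +
    ggplot2::scale_y_reverse(breaks = df$rank) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "colonisation rate c", y = "competitive rank (1 = best)",
                  colour = "invader")
}

#' @describeIn run_invasion Relative abundance of every species over time
#'   (log scale); the invader drawn in red, extinct natives in grey.
#' @param object An `invasion_run`.
#' @export
autoplot.invasion_run <- function(object, ...) {
  tr <- object$trajectory
  ext <- object$extinctions
  df <- dplyr::left_join(tibble::as_tibble(tr),
                         ext[, c("rank", "extinct")], by = "rank")
  a <- object$cfg$invader_rank
  df$role <- dplyr::case_when(
    df$rank == a ~ "invader",
    df$extinct ~ "native (extinct)",
    TRUE ~ "native"
  )
  df <- df[df$time > 0 & df$ratio_to_baseline > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$ratio_to_baseline,
                                   group = .data$rank, colour = .data$role)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(
      invader = "firebrick", native = "steelblue",
      `native (extinct)` = "grey55")) +
    ggplot2::labs(x = "time", y = "abundance relative to baseline equilibrium",
                  colour = NULL)
}

#' @describeIn run_sweep Extinction proportion against the varying grid
#'   axis, one line per invader rank, ribbon = quantile envelope.
#' @param object An `ensemble_summary`.
#' @param x_var Grid column for the x axis; by default whichever of `h`,
#'   `mortality_delta`, `disturbance` varies.
#' @param ... Unused.
#' @export
autoplot.ensemble_summary <- function(object, x_var = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (is.null(x_var)) {
    cand <- c("h", "mortality_delta", "disturbance")
    vary <- cand[vapply(cand, function(v) length(unique(df[[v]])) > 1, logical(1))]
    x_var <- if (length(vary)) vary[1] else "h"
  }
  df$invader <- factor(df$invader_rank)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[x_var]],
                                        y = .data$mean_extinct,
                                        colour = .data$invader,
                                        fill = .data$invader)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = x_var, y = "proportion of natives extinct",
                  colour = "invader rank", fill = "invader rank")
  if (length(unique(df$disturbance)) > 1 && x_var != "disturbance") {
    p <- p + ggplot2::facet_wrap(~disturbance, labeller = ggplot2::label_both)
  }
  p
}

#' @describeIn extinction_timeline_summary Mean extinction timeline with
#'   quantile-envelope ribbon.
#' @param object A `timeline_summary`.
#' @export
autoplot.timeline_summary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mean_extinct)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "proportion of natives extinct")
}
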