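#' Plot prevalence trajectories under contrasting horizontal-transmission
#' rates
#'
#' One panel per scenario, prevalence against generation, line type and
#' colour distinguishing the horizontal-transmission rate (no transmission
#' drawn in blue, transmission in orange, dashed for the lower rate).
#'
#' @param panels Named list of scenario results, each a named list of
#'   `wolb_trajectory` objects as returned by [scenario_trajectories()].
#' @return A ggplot object.
#' @examples
#' p <- plot_scenario_panels(list(neutral = scenario_trajectories("A", 200)))
#' @export
plot_scenario_panels <- function(panels) {
  if (!length(panels)) stop("no trajectories to plot", call. = FALSE)
  if (inherits(panels, "wolb_trajectory")) panels <- list(list(panels))
  if (all(vapply(panels, inherits, logical(1), "wolb_trajectory")))
    panels <- list(panels)
  if (is.null(names(panels))) names(panels) <- seq_along(panels)
  df <- do.call(rbind, lapply(names(panels), function(pn) {
    trs <- panels[[pn]]
    if (is.null(names(trs))) names(trs) <- seq_along(trs)
    do.call(rbind, lapply(names(trs), function(wn) {
      d <- as.data.frame(trs[[wn]])
      d$panel <- pn
      d$w <- wn
      d
    }))
  }))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$generation, y = .data$prevalence,
    colour = .data$w, linetype = .data$w)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Generation", y = "Prevalence of infection",
                  colour = "horizontal\ntransmission",
                  linetype = "horizontal\ntransmission") +
    ggplot2::theme_bw()
}

#' Plot a bifurcation-style equilibrium sweep
#'
#' Fixed-point prevalence against the horizontal-transmission rate, with
#' stability shown by point shape.
#'
#' @param sweep Output of [equilibrium_sweep()].
#' @return A ggplot object.
#' @export
plot_equilibrium_sweep <- function(sweep) {
  stopifnot(is.data.frame(sweep), nrow(sweep) > 0)
  ggplot2::ggplot(sweep, ggplot2::aes(
    x = .data$w, y = .data$p_star, shape = .data$stability,
    colour = .data$stability)) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Horizontal transmission rate w",
                  y = "Equilibrium prevalence") +
    ggplot2::theme_bw()
}
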