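#' Plot species populations versus delay
#'
#' @param object A `population_trajectory` from [solve_populations()].
#' @param ... Unused.
#' @return A ggplot object (pseudo-log delay axis).
#' @export
autoplot.population_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"time",
                              names_to = "species", values_to = "population")
  long$species <- factor(long$species, levels = c("N1", "N2", "N3", "N4", "N0"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$population,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(trans = "pseudo_log") +
    ggplot2::labs(x = "delay (ps)", y = "population (per excitation)",
                  colour = NULL)
}

#' Plot transient-absorption traces
#'
#' @param object A `transient_traces` tibble ([simulate_traces()],
#'   [read_traces()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transient_traces <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$delay_ps, y = .data$dA)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$dA - .data$sigma,
                                        ymax = .data$dA + .data$sigma),
                           colour = "grey60", width = 0) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~ .data$probe_energy, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::scale_x_continuous(trans = "pseudo_log") +
    ggplot2::labs(x = "delay (ps)", y = expression(Delta * A))
}
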