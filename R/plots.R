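# ggplot2 views of the main result types.

#' Bar chart of regulatory-element class proportions
#'
#' @param elements Classified element tibble ([classify_elements()]).
#' @return A ggplot object.
#' @export
plot_class_proportions <- function(elements) {
  props <- class_proportions(elements)
  ggplot2::ggplot(props, ggplot2::aes(x = .data$state, y = .data$fraction,
                                      fill = .data$state)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "fraction of elements",
                  title = "Regulatory element classes") +
    ggplot2::theme_minimal()
}

#' Eigenvector track plot
#'
#' Per-bin leading-eigenvector values coloured by compartment call, the
#' usual A/B compartment view.
#'
#' @param object An `eigen_track` tibble (after [call_compartments()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eigen_track <- function(object, ...) {
  df <- as_tibble(object)
  if (!"compartment" %in% names(df)) {
    df$compartment <- ifelse(df$value > 0, "A", "B")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start / 1e6, y = .data$value,
                                   fill = .data$compartment)) +
    ggplot2::geom_col(width = (df$end[1] - df$start[1]) / 1e6) +
    ggplot2::scale_fill_manual(values = c(A = "#d73027", B = "#4575b4"),
                               na.value = "grey70") +
    ggplot2::labs(x = "position (Mb)", y = "eigenvector",
                  title = paste0("A/B compartments: ", df$chrom[1])) +
    ggplot2::theme_minimal()
}

#' Rose plot of division angles
#'
#' @param object A `rose_histogram` tibble ([rose_histogram()]).
#' @param ... Unused.
#' @return A ggplot object on polar coordinates over the 0-90 degree
#'   quadrant.
#' @export
autoplot.rose_histogram <- function(object, ...) {
  df <- as_tibble(object)
  df$mid <- (df$bin_start + df$bin_end) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = df$bin_end[1] - df$bin_start[1],
                      fill = "#74add1", colour = "white") +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 90, by = 30)) +
    ggplot2::labs(x = "division angle (degrees from pial surface)", y = "count",
                  title = "Axis of division") +
    ggplot2::theme_minimal()
}

#' Domain-level contact change against signal change
#'
#' Scatter of per-domain log2 contact-frequency change against log2 mean
#' signal fold-change, split by domain class.
#'
#' @param domain_changes Tibble with `contact_log2fc`, `signal_log2fc` and
#'   `domain_class` (see the pipeline's `domain_changes.tsv`).
#' @return A ggplot object.
#' @export
plot_domain_changes <- function(domain_changes) {
  df <- filter(domain_changes, !is.na(.data$signal_log2fc),
               !is.na(.data$contact_log2fc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$signal_log2fc,
                                   y = .data$contact_log2fc)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(~domain_class) +
    ggplot2::labs(x = "domain signal log2 fold-change",
                  y = "intradomain contact log2 fold-change") +
    ggplot2::theme_minimal()
}
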