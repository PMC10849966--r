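#' Plot a terminal damage profile
#'
#' The classic aDNA deamination plot: C->T frequency against distance
#' from each read end, with Wilson 95% ribbons. The 3' panel's axis is
#' reversed so both panels read "into the fragment".
#'
#' @param object A [damage_profile()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.damage_profile <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::mutate(end = factor(.data$end, levels = c("5p", "3p"),
                               labels = c("5' end", "3' end")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$frequency)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "firebrick", alpha = 0.2) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_point(colour = "firebrick", size = 1) +
    ggplot2::facet_wrap(~end, scales = "free_x") +
    ggplot2::labs(x = "position from read end",
                  y = "C→T frequency (read orientation)") +
    ggplot2::theme_minimal()
}

#' Plot per-site consensus coverage and call status
#'
#' @param object A [call_consensus()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.consensus_genome <- function(object, ...) {
  d <- object$sites
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$coverage_masked,
                                  colour = .data$called)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "grey30",
                                            `FALSE` = "firebrick")) +
    ggplot2::labs(x = "reference position", y = "masked coverage",
                  colour = "called",
                  title = sprintf("%s (%s)", object$name, object$mode_used)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a pairwise difference matrix
#'
#' @param object A [difference_matrix()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.difference_matrix <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$id_a, y = .data$id_b,
                                  fill = .data$n_diff)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_diff), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "differences") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
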