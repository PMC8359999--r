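#' Mercator plot of six-membered-ring puckering states
#'
#' Projects puckering states on the (phi2, theta) Mercator chart used for
#' pyranose conformational analysis, with the 38 canonical conformers drawn
#' as labelled reference points.
#'
#' @param data A tibble with columns `phi2` and `theta` (e.g. from
#'   [pucker_report()]), or a `conformer_batch` of a six-membered ring.
#' @param show_catalog Draw the canonical-conformer grid? Default `TRUE`.
#' @return A ggplot object.
#' @export
plot_mercator <- function(data, show_catalog = TRUE) {
  if (inherits(data, "conformer_batch")) {
    states <- purrr::map(data$molecules, function(m) {
      cp_pucker(m$coords[seq_len(data$spec$template$n_atoms), , drop = FALSE])
    })
    data <- purrr::map_dfr(states, tidy)
  }
  stopifnot(all(c("phi2", "theta") %in% names(data)))
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$phi2, y = .data$theta)) +
    ggplot2::geom_point(alpha = 0.6, colour = "steelblue") +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 360, 60)) +
    ggplot2::scale_y_reverse(limits = c(180, 0), breaks = seq(0, 180, 30)) +
    ggplot2::labs(x = expression(phi[2] ~ "(deg)"),
                  y = expression(theta ~ "(deg)"),
                  title = "Puckering sphere (Mercator projection)") +
    ggplot2::theme_minimal()
  if (show_catalog) {
    cat6 <- enumerate_catalog(6)
    p <- p +
      ggplot2::geom_point(data = cat6, shape = 3, colour = "grey40") +
      ggplot2::geom_text(
        data = cat6, ggplot2::aes(label = .data$name),
        size = 2.5, vjust = -0.8, colour = "grey30"
      )
  }
  p
}

#' Autoplot a conformer batch
#'
#' Bar chart of how often each canonical ring conformation was sampled,
#' clashes highlighted.
#'
#' @param object A `conformer_batch`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conformer_batch <- function(object, ...) {
  man <- object$manifest |>
    dplyr::count(.data$label, .data$clash)
  ggplot2::ggplot(man, ggplot2::aes(x = .data$label, y = .data$n,
                                    fill = .data$clash)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue",
                                          `TRUE` = "firebrick"),
                               name = "clash") +
    ggplot2::labs(x = "ring conformation", y = "conformers",
                  title = sprintf("%d sampled conformers (seed %d)",
                                  nrow(object$manifest), object$seed)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
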