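#' Plot a patch grid
#'
#' Patch centroids sized by total reef area, coloured by abundance when
#' available; sampled sites are labelled.
#'
#' @param grid A `patch_grid`.
#' @return A ggplot object.
#' @export
plot_reefscape <- function(grid) {
  ps <- patch_summary(grid)
  p <- ggplot2::ggplot(ps, ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$area_ha,
                                     colour = .data$N)) +
    ggplot2::scale_size_area(name = "reef area (ha)") +
    ggplot2::scale_colour_viridis_c(name = "abundance N") +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
  lab <- ps %>% dplyr::filter(!is.na(.data$sampled_site_code))
  if (nrow(lab) > 0) {
    p <- p + ggplot2::geom_text(data = lab,
                                ggplot2::aes(label = .data$sampled_site_code),
                                vjust = -1, size = 3)
  }
  p
}

#' Heatmap of a dispersal or distance matrix
#'
#' @param m Square matrix with id dimnames.
#' @param log10 Show log10 of positive entries (useful for kernels).
#' @return A ggplot object.
#' @export
plot_matrix <- function(m, log10 = FALSE) {
  tb <- as_tibble(as.matrix(m), rownames = "from") %>%
    tidyr::pivot_longer(-"from", names_to = "to", values_to = "value")
  if (log10) tb$value <- log10(pmax(tb$value, 1e-300))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = if (log10) "log10" else "value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6),
                   axis.text.y = ggplot2::element_text(size = 6)) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.kernel_scan <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$a, y = .data$r_median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$r_q05, ymax = .data$r_q95),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "best_a"),
                        linetype = "dashed") +
    ggplot2::labs(x = "kernel base a", y = "Mantel r (median, 5-95%)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sensitivity_result <- function(object, ...) {
  tb <- tidy(object) %>%
    dplyr::mutate(fragmentation = factor(100 * .data$fragmentation),
                  composition = factor(.data$composition,
                                       levels = c("L3", "L2", "L1")))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$fragmentation,
                                   y = .data$r_median,
                                   fill = .data$composition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$r_q05,
                                        ymax = .data$r_q95),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.2) +
    ggplot2::labs(x = "habitat fragmentation (%)",
                  y = "Mantel r (median, 5-95% quantiles)") +
    ggplot2::theme_minimal()
}
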