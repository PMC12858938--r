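#' Plot a cell reconstruction as a 2-D projection
#'
#' Draws the node tree projected onto a coordinate plane, with line width
#' proportional to radius and colour by SWC type code.
#'
#' @param cell A `swc_cell`.
#' @param plane `"xy"` (default), `"xz"` or `"yz"`.
#' @return A ggplot object.
#' @export
plot_cell <- function(cell, plane = c("xy", "xz", "yz")) {
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1]]
  idx <- stats::setNames(seq_len(nrow(cell)), cell$id)
  pr <- ifelse(is.na(cell$parent), NA_integer_, idx[as.character(cell$parent)])
  edges <- tibble::tibble(
    a1 = cell[[ax[1]]], a2 = cell[[ax[2]]],
    b1 = cell[[ax[1]]][pr], b2 = cell[[ax[2]]][pr],
    radius = cell$radius, type = factor(cell$type)
  ) |> dplyr::filter(!is.na(b1))
  ggplot2::ggplot(edges) +
    ggplot2::geom_segment(
      ggplot2::aes(x = b1, y = b2, xend = a1, yend = a2,
        linewidth = radius, colour = type)
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 2), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = paste0(ax[1], " (µm)"), y = paste0(ax[2], " (µm)"),
      colour = "type"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_cell
#' @param object A `swc_cell`.
#' @param ... Passed to [plot_cell()].
#' @method autoplot swc_cell
#' @export
autoplot.swc_cell <- function(object, ...) plot_cell(object, ...)

#' Plot a persistence barcode
#'
#' Bars span birth to death path length, ordered by death.
#'
#' @param bars A `persistence_barcode`.
#' @return A ggplot object.
#' @export
plot_barcode <- function(bars) {
  b <- dplyr::arrange(tibble::as_tibble(bars), death) |>
    dplyr::mutate(row = dplyr::row_number())
  ggplot2::ggplot(b) +
    ggplot2::geom_segment(
      ggplot2::aes(x = birth, xend = death, y = row, yend = row,
        colour = factor(projection))
    ) +
    ggplot2::labs(x = "path length from soma (µm)", y = NULL,
      colour = "projection") +
    ggplot2::theme_minimal()
}

#' @rdname plot_barcode
#' @param object A `persistence_barcode`.
#' @param ... Unused.
#' @method autoplot persistence_barcode
#' @export
autoplot.persistence_barcode <- function(object, ...) plot_barcode(object)

#' Plot a persistence image
#'
#' @param img A `persistence_image`.
#' @return A ggplot object.
#' @export
plot_persistence_image <- function(img) {
  df <- tibble::tibble(
    birth = rep(img$x, times = length(img$y)),
    death = rep(img$y, each = length(img$x)),
    value = as.vector(img$z)
  )
  ggplot2::ggplot(df, ggplot2::aes(birth, death, fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "birth (µm)", y = "death (µm)", fill = "density") +
    ggplot2::theme_minimal()
}

#' @rdname plot_persistence_image
#' @param object A `persistence_image`.
#' @param ... Unused.
#' @method autoplot persistence_image
#' @export
autoplot.persistence_image <- function(object, ...) plot_persistence_image(object)

#' Plot residence/exchange times against membrane permeability
#'
#' @param sweep Output of [permeability_sweep()].
#' @return A ggplot object.
#' @export
plot_permeability_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(sweep, c(tau_i_ms, tau_ex_ms),
    names_to = "quantity", values_to = "time_ms")
  ggplot2::ggplot(long, ggplot2::aes(kappa_perm, time_ms,
    colour = quantity, group = interaction(quantity, sv))) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "membrane permeability (µm/s)", y = "time (ms)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
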