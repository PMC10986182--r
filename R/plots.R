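#' Plot an LGE intensity map
#'
#' Tile map of the normalized LGE intensity on a sheet (thin-3D slabs
#' show the mid-slice).
#'
#' @param mesh An `fs_mesh`.
#' @param lge LGE tibble.
#' @return A ggplot object.
#' @export
plot_lge <- function(mesh, lge) {
  df <- dplyr::left_join(mesh$elements, lge, by = "element")
  df <- df[df$iz == ceiling(mesh$dims[3] / 2), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "LGE") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Plot an activation-time map
#'
#' First-activation times per element after a chosen time origin;
#' elements that never activate are shown as missing.
#'
#' @param mesh An `fs_mesh`.
#' @param record Activation tibble.
#' @param from_ms Ignore activations before this time (default 0).
#' @return A ggplot object.
#' @export
plot_activation_map <- function(mesh, record, from_ms = 0) {
  first <- record[record$time_ms >= from_ms, ] |>
    dplyr::group_by(.data$element) |>
    dplyr::summarise(t1 = min(.data$time_ms), .groups = "drop")
  df <- dplyr::left_join(mesh$elements, first, by = "element")
  df <- df[df$iz == ceiling(mesh$dims[3] / 2), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                   fill = .data$t1)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "plasma",
                                  name = "activation (ms)",
                                  na.value = "grey20") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Plot initiation sites over the LGE map
#'
#' @param mesh,lge As in [plot_lge()].
#' @param sites Initiation-site tibble (needs `x_mm`, `y_mm`; a
#'   `morphology` column, when present, colors the markers).
#' @return A ggplot object.
#' @export
plot_initiation_sites <- function(mesh, lge, sites) {
  p <- plot_lge(mesh, lge)
  if (nrow(sites) == 0) return(p)
  if ("morphology" %in% names(sites)) {
    p + ggplot2::geom_point(
      data = sites,
      ggplot2::aes(.data$x_mm, .data$y_mm, shape = .data$morphology),
      inherit.aes = FALSE, color = "red", size = 3, stroke = 1.2)
  } else {
    p + ggplot2::geom_point(data = sites,
                            ggplot2::aes(.data$x_mm, .data$y_mm),
                            inherit.aes = FALSE, color = "red", size = 3,
                            shape = 4, stroke = 1.2)
  }
}

#' Autoplot a single-cell pacing result
#'
#' Final-beat action potential with the APD90 interval annotated.
#'
#' @param object An `fs_pacing` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fs_pacing <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$time_ms, .data$v_mv)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "time (ms)", y = "V (mV)",
                  subtitle = sprintf("APD90 = %.1f ms", object$apd90)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
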