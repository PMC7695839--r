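#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a sampled spectrum against the theory
#'
#' Eigenvalues of a realized stability matrix in the complex plane, with the
#' predicted bulk boundary and outlier positions overlaid.
#'
#' @param spec A [spectrum_result][compute_spectrum()].
#' @param boundary Optional [bulk_boundary()] at the same `q`.
#' @param outliers Optional [outlier_eigenvalues()] at the same `q`.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spec, boundary = NULL, outliers = NULL) {
  df <- tidy(spec)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$re, y = .data$im)) +
    ggplot2::geom_point(shape = 4, alpha = 0.5, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = expression(Re(omega)), y = expression(Im(omega)),
                  title = sprintf("Eigenvalue spectrum at q = %g", spec$q)) +
    ggplot2::theme_minimal()
  if (!is.null(boundary) && nrow(boundary$curve)) {
    bc <- dplyr::bind_rows(
      boundary$curve,
      dplyr::mutate(boundary$curve[rev(seq_len(nrow(boundary$curve))), ],
                    omega_y = -.data$omega_y))
    gg <- gg + ggplot2::geom_path(
      data = bc, ggplot2::aes(x = .data$omega_x, y = .data$omega_y,
                              group = .data$component),
      colour = "firebrick", inherit.aes = FALSE)
  }
  if (!is.null(outliers) && nrow(outliers$values)) {
    ot <- tibble::tibble(re = Re(outliers$values$omega),
                         im = Im(outliers$values$omega),
                         admissible = outliers$values$admissible)
    gg <- gg + ggplot2::geom_point(
      data = ot[ot$admissible, ], ggplot2::aes(x = .data$re, y = .data$im),
      shape = 1, size = 4, colour = "firebrick", inherit.aes = FALSE)
  }
  gg
}

#' @export
autoplot.bulk_boundary <- function(object, ...) {
  bc <- dplyr::bind_rows(
    object$curve,
    dplyr::mutate(object$curve[rev(seq_len(nrow(object$curve))), ],
                  omega_y = -.data$omega_y))
  ggplot2::ggplot(bc, ggplot2::aes(x = .data$omega_x, y = .data$omega_y,
                                   group = .data$component)) +
    ggplot2::geom_path(colour = "firebrick") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = expression(Re(omega)), y = expression(Im(omega)),
                  title = sprintf("Bulk boundary at q = %g", object$q)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dispersion_relation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$q, y = .data$re_max,
                                       colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "wavenumber q", y = expression(Re(omega[max])),
                  title = "Dispersion relation") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.phase_diagram <- function(object, ...) {
  gg <- ggplot2::ggplot(object$cells,
                        ggplot2::aes(x = .data$axis1, y = .data$axis2,
                                     fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(
      stable = "#4477AA", dispersal_induced_unstable = "#DDCC77",
      nonspatial_unstable = "#CC6677"), na.value = "grey70") +
    ggplot2::labs(x = object$axis1$param, y = object$axis2$param,
                  fill = "stability") +
    ggplot2::theme_minimal()
  if (nrow(object$thresholds)) {
    gg <- gg + ggplot2::geom_line(
      data = object$thresholds,
      ggplot2::aes(x = .data$axis1, y = .data$axis2,
                   group = .data$transition),
      colour = "black", inherit.aes = FALSE)
  }
  gg
}

#' @export
autoplot.ls_trajectory <- function(object, ...) {
  final_t <- max(object$profiles$t)
  prof <- object$profiles[object$profiles$t == final_t, ]
  long <- tidyr::pivot_longer(prof, c("prey", "predator"),
                              names_to = "group", values_to = "abundance")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$abundance,
                                     colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(prey = "steelblue",
                                            predator = "firebrick")) +
    ggplot2::labs(x = "x", y = "summed abundance",
                  title = sprintf("Spatial profile at t = %g", final_t)) +
    ggplot2::theme_minimal()
}
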