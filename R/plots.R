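#' Plot a dispersal kernel
#'
#' Draws the radial density of dispersal distance \eqn{2\pi r P(r)} (the
#' distribution actually sampled by a seed), optionally marking the
#' long-distance threshold.
#'
#' @param object A [dispersal_kernel()].
#' @param r_max Right edge of the distance axis (m).
#' @param ldd_threshold Threshold to mark (set `NULL` to omit).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dispersal_kernel <- function(object, r_max = 100,
                                      ldd_threshold = 50, ...) {
  r <- seq(0.01, r_max, length.out = 400)
  df <- tibble::tibble(r = r, density = 2 * pi * r *
                         kernel_density(object, r))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from source (m)",
                  y = "radial density (1/m)",
                  title = object$family) +
    ggplot2::theme_minimal()
  if (!is.null(ldd_threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = ldd_threshold,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Trade-off scatter plot
#'
#' Cross-species scatter of colonization ability (1/t) against competitive
#' ability (SOR at high crowding) at one diameter, with 95% bootstrap CIs as
#' segments on both axes — the standard display for a
#' competition-colonization trade-off test.
#'
#' @param analysis A [tradeoff_analysis()] result.
#' @param dbh Which evaluation diameter to show.
#' @param log_axes Use log10 axes (abilities span orders of magnitude).
#' @return A ggplot.
#' @export
plot_tradeoff <- function(analysis, dbh = 5, log_axes = TRUE) {
  stopifnot(inherits(analysis, "tradeoff_analysis"))
  inv_q <- paste0("inv_t_dbh", dbh)
  sor_q <- paste0("sor_dbh", dbh)
  ab <- purrr::map_dfr(analysis$trap_boots, function(b) {
    ci <- boot_ci(b)
    dplyr::mutate(ci[ci$quantity == inv_q, ], species = b$species)
  })
  cp <- purrr::map_dfr(analysis$quadrat_boots, function(b) {
    ci <- boot_ci(b)
    dplyr::mutate(ci[ci$quantity == sor_q, ], species = b$species)
  })
  df <- dplyr::inner_join(ab, cp, by = "species",
                          suffix = c("_col", "_comp"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_col,
                                        y = .data$mean_comp)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lower_col,
                                       xend = .data$upper_col,
                                       yend = .data$mean_comp),
                          colour = "grey70") +
    ggplot2::geom_segment(ggplot2::aes(y = .data$lower_comp,
                                       yend = .data$upper_comp,
                                       xend = .data$mean_col),
                          colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::labs(x = bquote("colonization ability 1/t (" * yr^-1 * ")"),
                  y = "competitive ability (SOR at high crowding)",
                  title = paste0("DBH = ", dbh, " cm")) +
    ggplot2::theme_minimal()
  if (log_axes) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

#' Scree / loading plot for the trait PCA
#'
#' @param object A [trait_pca()].
#' @param ... Unused.
#' @return A ggplot of loadings for the retained components, with variance
#'   fractions in the panel labels.
#' @export
autoplot.trait_pca <- function(object, ...) {
  df <- tidy.trait_pca(object) |>
    dplyr::filter(.data$component %in%
                    colnames(object$loadings)[seq_len(object$n_components)]) |>
    dplyr::mutate(panel = paste0(.data$component, " (",
                                 round(100 * .data$variance_fraction, 1),
                                 "%)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$loading, y = .data$trait)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "loading", y = NULL) +
    ggplot2::theme_minimal()
}
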