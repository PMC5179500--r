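#' Induction-ratio scatterplot for a dependence partition
#'
#' Reproduces the two-background induction scatter: reference log2 induction
#' on x, comparison on y, one panel per read class, dependent genes
#' highlighted and the fitted attenuated relation drawn through the origin.
#'
#' @param object A `dependence_partition` from [iterate_partition()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dependence_partition <- function(object, ...) {
  calls <- object$calls
  long <- bind_rows(
    tibble(read_class = "total", x = calls$x_total, y = calls$y_total,
           label = calls$label),
    tibble(read_class = "intronic", x = calls$x_intronic,
           y = calls$y_intronic, label = calls$label)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$label)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_abline(slope = object$fit$beta, intercept = 0,
                         colour = "black") +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::facet_wrap(~read_class) +
    ggplot2::scale_colour_manual(values = c(dependent = "#E69F00",
                                            independent = "grey50",
                                            rescued = "#D55E00",
                                            refractory = "grey50")) +
    ggplot2::labs(
      x = "log2 induction, reference background",
      y = "log2 induction, comparison background",
      colour = NULL,
      subtitle = sprintf("slope %.2f, Spearman r %.2f",
                         object$fit$beta, object$fit$spearman_r)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Contact-map heat map
#'
#' @param map A [contact_map()].
#' @param log_scale Plot log10(count + 1) (default TRUE).
#' @return A ggplot object.
#' @export
plot_contact_map <- function(map, log_scale = TRUE) {
  df <- bind_rows(
    as_tibble(map),
    as_tibble(map) |> rename(bin_i = "bin_j", bin_j = "bin_i")
  ) |>
    mutate(value = if (log_scale) log10(.data$count + 1) else .data$count)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_i, y = .data$bin_j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(
      name = if (log_scale) "log10(count + 1)" else "count") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "bin", y = "bin") +
    ggplot2::theme_minimal()
}

#' Compartment score track
#'
#' Bar track of scaled PC1 scores with A bins (score above the threshold)
#' red and B bins blue, the usual compartment display.
#'
#' @param track Output of [compartment_pca()].
#' @param threshold Assignment threshold drawn on the plot (default 100).
#' @return A ggplot object.
#' @export
plot_compartment_track <- function(track, threshold = 100) {
  ggplot2::ggplot(filter(track, !is.na(.data$score)),
                  ggplot2::aes(x = .data$bin, y = .data$score,
                               fill = .data$label)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dotted") +
    ggplot2::scale_fill_manual(values = c(A = "#C0392B", B = "#2E6DA4",
                                          unassigned = "grey70")) +
    ggplot2::labs(x = "bin", y = "PCA score", fill = NULL) +
    ggplot2::theme_minimal()
}
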