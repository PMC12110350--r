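#' Plot a simulated trajectory
#'
#' Draws the node-by-time excitatory activity as a raster with the summed
#' glutamate series beneath it, the standard at-a-glance view of a run.
#'
#' @param object An `epi_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epi_trajectory <- function(object, ...) {
  d <- tidy.epi_trajectory(object)
  gs <- tibble::tibble(time = object$times,
                       glu = glutamate_series(object))
  d$panel <- "excitatory activity"
  top <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$node,
                                         fill = .data$Ex)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = "node", fill = "Ex")
  bottom <- ggplot2::ggplot(gs, ggplot2::aes(x = .data$time, y = .data$glu)) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::labs(x = "time (nominal ms)", y = "summed [Glu]")
  if (requireNamespace("patchwork", quietly = TRUE)) {
    top / bottom + patchwork::plot_layout(heights = c(3, 1))
  } else {
    top
  }
}

#' Plot a synchronisation report
#'
#' Heatmap of the pairwise PLV matrix over active nodes.
#'
#' @param object An `epi_sync_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epi_sync_report <- function(object, ...) {
  d <- tidy.epi_sync_report(object)
  both <- dplyr::bind_rows(d,
    dplyr::rename(d, node_i = "node_j", node_j = "node_i"))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$node_i, y = .data$node_j,
                                     fill = .data$plv)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "node", y = "node", fill = "PLV",
                  title = sprintf("network PLV = %.3f", object$network_plv))
}

#' Plot a stimulation sweep
#'
#' Mean network PLV (with a ribbon of +/- one standard deviation across
#' replicates) against the swept variable, one curve per waveform kind.
#'
#' @param object An `epi_sweep` tibble from [run_stimulation_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epi_sweep <- function(object, ...) {
  d <- dplyr::summarise(
    dplyr::group_by(object, .data$kind, .data$grid_value),
    mean_plv = mean(.data$network_plv),
    sd_plv = stats::sd(.data$network_plv), .groups = "drop")
  xlab <- if (object$axis[1] == "n_targets") "stimulated high-degree nodes"
          else "stimulation intensity z"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$grid_value, y = .data$mean_plv,
                                  colour = .data$kind, fill = .data$kind)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_plv - .data$sd_plv,
                                      ymax = .data$mean_plv + .data$sd_plv),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = xlab, y = "network PLV", colour = "waveform",
                  fill = "waveform")
}

#' Plot a resection comparison
#'
#' Glutamate peak, network PLV and CV by plan across replicates.
#'
#' @param object An `epi_resection` tibble from
#'   [run_resection_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epi_resection <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::select(object, "plan", "glu_peak", "network_plv", "cv"),
    -"plan", names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$plan), y = .data$value)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "resection plan", y = NULL)
}
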