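#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Genome-wide gain/loss frequency plot
#'
#' Fraction of samples gained (up, red) and lost (down, blue) at each
#' probe, faceted by chromosome — the classic aCGH cohort summary.
#'
#' @param object A `cna_calls` object.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot cna_calls
#' @export
autoplot.cna_calls <- function(object, ...) {
  pm <- object$probe_map
  df <- tibble::tibble(
    chrom = pm$chrom, pos = probe_midpoints(pm) / 1e6,
    gain = colMeans(object$states == "GAIN" | object$states == "AMP"),
    loss = -colMeans(object$states == "LOSS" | object$states == "HD")
  )
  df <- tidyr::pivot_longer(df, c("gain", "loss"), names_to = "direction",
                            values_to = "freq")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$freq,
                                   fill = .data$direction)) +
    ggplot2::geom_col(width = 0.11) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_manual(values = c(gain = "#c0392b", loss = "#2b63c0")) +
    ggplot2::labs(x = "position (Mb)", y = "fraction of samples",
                  title = "Copy-number gain/loss frequencies") +
    ggplot2::theme_minimal()
}

#' Support-count plot for recurrent-region discovery
#'
#' Per-probe support counts for one region kind with the detected core
#' (dark) and extended (light) intervals overlaid.
#'
#' @param recurrence A `recurrent_alterations` object.
#' @param kind `"FGA"`, `"HD"`, or `"MRD"`.
#' @return A ggplot.
#' @export
plot_region_support <- function(recurrence, kind = "FGA") {
  sup <- recurrence$support[recurrence$support$kind == kind, ]
  sup$idx <- seq_len(nrow(sup))
  reg <- recurrence$regions[recurrence$regions$kind == kind, ]
  p <- ggplot2::ggplot(sup, ggplot2::aes(x = .data$idx, y = .data$support)) +
    ggplot2::geom_step(color = "grey30") +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "probe index", y = "supporting samples",
                  title = paste("Recurrent", kind, "support")) +
    ggplot2::theme_minimal()
  if (nrow(reg) > 0) {
    p <- p +
      ggplot2::geom_rect(data = reg, inherit.aes = FALSE,
                         ggplot2::aes(xmin = .data$ext_from, xmax = .data$ext_to,
                                      ymin = 0, ymax = .data$max_support),
                         fill = "orange", alpha = 0.25) +
      ggplot2::geom_rect(data = reg, inherit.aes = FALSE,
                         ggplot2::aes(xmin = .data$core_from, xmax = .data$core_to,
                                      ymin = 0, ymax = .data$max_support),
                         fill = "orange", alpha = 0.5)
  }
  p
}

#' @method autoplot alteration_matrix
#' @export
autoplot.alteration_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$sample_id,
                                   fill = factor(.data$carrier))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey92", `1` = "grey15"),
                               name = "carrier") +
    ggplot2::labs(x = NULL, y = NULL, title = "Alteration matrix") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1),
                   axis.text.y = ggplot2::element_blank())
}

#' @method autoplot hca_fit
#' @export
autoplot.hca_fit <- function(object, ...) {
  df <- dplyr::count(object$assignments, .data$hc, .data$ms)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hc, y = .data$n, fill = .data$ms)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "HC cluster", y = "samples", fill = "MS class",
                  title = "Expression cluster sizes") +
    ggplot2::theme_minimal()
}

#' @method autoplot mds_fit
#' @export
autoplot.mds_fit <- function(object, ...) {
  ggplot2::ggplot(object$coordinates,
                  ggplot2::aes(x = .data$dim1, y = .data$dim2,
                               label = .data$feature)) +
    ggplot2::geom_point(color = "#c0392b") +
    ggplot2::geom_text(vjust = -0.7, size = 3) +
    ggplot2::labs(x = "MDS 1", y = "MDS 2",
                  title = "Jaccard-distance MDS of alterations") +
    ggplot2::theme_minimal()
}

#' @method autoplot assoc_network
#' @export
autoplot.assoc_network <- function(object, ...) {
  if (nrow(object$edges) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "No significant associations"))
  }
  lay <- igraph::layout_in_circle(object$graph)
  nodes <- tibble::tibble(feature = igraph::V(object$graph)$name,
                          x = lay[, 1], y = lay[, 2])
  ed <- object$edges
  ed$x <- nodes$x[match(ed$feature_a, nodes$feature)]
  ed$y <- nodes$y[match(ed$feature_a, nodes$feature)]
  ed$xend <- nodes$x[match(ed$feature_b, nodes$feature)]
  ed$yend <- nodes$y[match(ed$feature_b, nodes$feature)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       color = .data$direction)) +
    ggplot2::scale_color_manual(values = c(positive = "#1e8449",
                                           negative = "#c0392b")) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(x = .data$x, y = .data$y),
                        size = 2) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$feature),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(title = "Alteration co-occurrence network",
                  color = "association") +
    ggplot2::theme_void()
}

#' @method autoplot km_fit
#' @export
autoplot.km_fit <- function(object, ...) {
  df <- tidy(object)
  start <- df |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, survival = 1)
  df <- dplyr::bind_rows(start, df[c("group", "time", "survival")]) |>
    dplyr::arrange(.data$group, .data$time)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "disease-specific survival",
                  title = "Kaplan-Meier estimate") +
    ggplot2::theme_minimal()
}
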