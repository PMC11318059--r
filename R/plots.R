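#' Plot a binary subtree dataset
#'
#' Genes-by-points raster of Boolean states with cell boundaries, the
#' standard way to eyeball a lineage-laid-out Boolean dataset.
#'
#' @param object A [subtree_dataset].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.subtree_dataset <- function(object, ...) {
  df <- tidy(object)
  df$state <- factor(df$state, levels = c(0, 1), labels = c("0", "1"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$point, y = .data$gene,
                                   fill = .data$state)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey92", `1` = "grey20"),
                               na.value = "tomato", name = "state") +
    ggplot2::labs(x = "lineage-indexed interpolation point", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot MCMC parameter traces
#'
#' Log-posterior and continuous-parameter traces per chain; the standard
#' plateau check for convergence of the discrete sampler.
#'
#' @param object A `bn_mcmc` from [run_mcmc()].
#' @param params Traces to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bn_mcmc <- function(object, params = c("lp", "alpha", "beta",
                                                "lambda", "kappa"), ...) {
  df <- mcmc_traces(object, params = params)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value,
                                   colour = factor(.data$chain))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(colour = "chain") +
    ggplot2::theme_minimal()
}

#' Plot a regulatory network
#'
#' Node-and-arrow view of a [grn]: solid edges activate, dashed edges
#' repress, edge colour encodes the time delay.
#'
#' @param object A [grn].
#' @param layout_seed Seed for the deterministic layout.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grn <- function(object, layout_seed = 1L, ...) {
  edges <- as_edges(object)
  g <- igraph::graph_from_data_frame(
    edges[, c("regulator", "target")], directed = TRUE,
    vertices = tibble(name = rownames(object$A)))
  set.seed(layout_seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(name = rownames(object$A), x = xy[, 1], y = xy[, 2])
  seg <- edges |>
    left_join(rename(nodes, x0 = "x", y0 = "y"),
              by = c(regulator = "name")) |>
    left_join(rename(nodes, x1 = "x", y1 = "y"),
              by = c(target = "name")) |>
    mutate(kind = ifelse(.data$sign > 0, "activation", "repression"))
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(seg) > 0) {
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linetype = .data$kind,
                   colour = factor(.data$delay_units)),
      arrow = grid::arrow(length = grid::unit(6, "pt")),
      inherit.aes = FALSE)
  }
  p + ggplot2::geom_point(size = 8, colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$name), size = 2.8) +
    ggplot2::scale_colour_viridis_d(name = "delay", drop = FALSE) +
    ggplot2::scale_linetype_manual(
      values = c(activation = "solid", repression = "dashed"),
      name = NULL) +
    ggplot2::theme_void()
}

#' Plot a simulation-study report
#'
#' Per-replicate metric values with their means, mirroring the columns of
#' a recovery-metrics summary table.
#'
#' @param object An `eval_report` from [replicate_study()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eval_report <- function(object, ...) {
  metric_cols <- intersect(c("PR", "FNR", "TPR", "PPR", "TNR", "PNR", "ACC"),
                           names(object$replicates))
  df <- tidyr::pivot_longer(object$replicates,
                            dplyr::all_of(metric_cols),
                            names_to = "metric", values_to = "value")
  df$metric <- factor(df$metric, levels = metric_cols)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.5, size = 1) +
    ggplot2::stat_summary(fun = function(v) mean(v, na.rm = TRUE),
                          geom = "point", shape = 95, size = 10,
                          colour = "firebrick") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "value") +
    ggplot2::theme_minimal()
}
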