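#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a free-energy surface
#'
#' 1D surfaces become free-energy profiles with jackknife error bars (when
#' available); 2D surfaces become filled landscapes with empty bins masked.
#'
#' @param object A `bs_fes`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bs_fes
#' @export
autoplot.bs_fes <- function(object, ...) {
  b <- object$bins[object$bins$occupied, , drop = FALSE]
  if (length(object$axes) == 1) {
    ax <- object$axes[1]
    p <- ggplot2::ggplot(b, ggplot2::aes(x = .data[[ax]], y = .data$F)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 0.8)
    if (!all(is.na(b$err))) {
      p <- p + ggplot2::geom_errorbar(
        ggplot2::aes(ymin = .data$F - .data$err, ymax = .data$F + .data$err),
        width = 0)
    }
    p + ggplot2::labs(y = "free energy (kT)")
  } else {
    ggplot2::ggplot(b, ggplot2::aes(x = .data[[object$axes[1]]],
                                    y = .data[[object$axes[2]]],
                                    fill = .data$F)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(name = "F (kT)", direction = -1) +
      ggplot2::labs(fill = "F (kT)")
  }
}

#' Plot a probabilistic contact map
#'
#' @param object A `bs_contact_map`.
#' @param ... Unused.
#' @return A ggplot object (tile map of contact probabilities).
#' @method autoplot bs_contact_map
#' @export
autoplot.bs_contact_map <- function(object, ...) {
  long <- tidy(object)
  long$peptide_residue <- factor(long$peptide_residue,
                                 levels = rownames(object$prob))
  long$pocket_residue <- factor(long$pocket_residue,
                                levels = colnames(object$prob))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$peptide_residue,
                                     y = .data$pocket_residue,
                                     fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(title = paste0("contact probabilities (", object$state, ")"),
                  x = "peptide residue", y = "pocket residue") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot cluster sizes
#'
#' @param object A `bs_clusters`.
#' @param ... Unused.
#' @return A ggplot bar chart of cluster sizes (largest first).
#' @method autoplot bs_clusters
#' @export
autoplot.bs_clusters <- function(object, ...) {
  df <- tibble::tibble(cluster = factor(seq_along(object$sizes)),
                       size = object$sizes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$size)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cluster (by size)", y = "members",
                  title = paste0("complete-linkage clusters, cutoff ",
                                 object$cutoff, " \u00c5"))
}

#' Trace plot of a binding observable along a trajectory
#'
#' @param table Observable tibble.
#' @param observable Column to trace (default `delta`).
#' @param thresholds Optional named list with `delta_bound`/`delta_unbound`
#'   drawn as horizontal guides.
#' @return A ggplot object.
#' @export
plot_observable_trace <- function(table, observable = "delta",
                                  thresholds = NULL) {
  p <- ggplot2::ggplot(table, ggplot2::aes(x = .data$frame,
                                           y = .data[[observable]])) +
    ggplot2::geom_line(linewidth = 0.3)
  if (!is.null(thresholds) && observable == "delta") {
    p <- p +
      ggplot2::geom_hline(yintercept = thresholds$delta_bound,
                          linetype = "dashed") +
      ggplot2::geom_hline(yintercept = thresholds$delta_unbound,
                          linetype = "dotted")
  }
  p
}
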