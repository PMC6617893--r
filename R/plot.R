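#' Plot a compressed spacer graph
#'
#' ggplot2 rendering with the same conventions as the DOT export: leader on
#' the left, source blocks blue, sink blocks yellow, dominant-path edges
#' red, edge labels showing support. Blocks are placed on longest-path
#' layers so edges always point rightwards in an acyclic graph.
#'
#' @param object A `compressed_spacer_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.compressed_spacer_graph <- function(object, ...) {
  cg <- object
  nb <- length(cg$blocks)
  if (nb == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void())
  }

  # longest-path layering from the sources; cycles fall back to layer 0
  layer <- rep(0L, nb)
  if (nrow(cg$edges) > 0) {
    for (pass in seq_len(nb)) {
      changed <- FALSE
      for (e in seq_len(nrow(cg$edges))) {
        u <- cg$edges$from[[e]]; v <- cg$edges$to[[e]]
        if (u != v && layer[v] < layer[u] + 1L && pass <= nb) {
          layer[v] <- layer[u] + 1L
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  ys <- stats::ave(seq_len(nb), layer,
                   FUN = function(ix) seq_along(ix) - (length(ix) + 1) / 2)
  nodes <- tibble::tibble(
    block = seq_len(nb),
    x = layer, y = ys,
    label = vapply(cg$blocks, block_label, character(1)),
    role = dplyr::case_when(
      seq_len(nb) %in% cg$sinks ~ "sink",
      seq_len(nb) %in% cg$sources ~ "source",
      TRUE ~ "internal"
    )
  )

  p <- ggplot2::ggplot()
  if (nrow(cg$edges) > 0) {
    dom <- cg$dominant_path
    dom_pairs <- if (length(dom) >= 2) paste(dom[-length(dom)], dom[-1])
                 else character()
    edges <- cg$edges |>
      dplyr::mutate(
        x = nodes$x[.data$from], y = nodes$y[.data$from],
        xend = nodes$x[.data$to], yend = nodes$y[.data$to],
        dominant = paste(.data$from, .data$to) %in% dom_pairs
      )
    p <- p +
      ggplot2::geom_segment(
        data = edges,
        ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend, color = .data$dominant),
        arrow = ggplot2::arrow(length = ggplot2::unit(2.5, "mm")),
        linewidth = 0.6, show.legend = FALSE
      ) +
      ggplot2::geom_text(
        data = edges,
        ggplot2::aes(x = (.data$x + .data$xend) / 2,
                     y = (.data$y + .data$yend) / 2,
                     label = .data$support),
        size = 3, vjust = -0.6
      ) +
      ggplot2::scale_color_manual(values = c(`TRUE` = "red",
                                             `FALSE` = "grey40"))
  }
  p +
    ggplot2::geom_label(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label,
                   fill = .data$role)
    ) +
    ggplot2::scale_fill_manual(
      values = c(source = "lightblue", sink = "yellow", internal = "white"),
      name = NULL
    ) +
    ggplot2::labs(x = "leader → trailer", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' @export
plot.compressed_spacer_graph <- function(x, ...) {
  print(autoplot.compressed_spacer_graph(x, ...))
}

#' Plot cluster-size distribution of a spacer cluster map
#'
#' @param object A `spacer_cluster_map`.
#' @param ... Unused.
#' @return A ggplot bar chart of cluster sizes; the long right tail is what
#'   high spacer redundancy looks like.
#' @export
autoplot.spacer_cluster_map <- function(object, ...) {
  df <- dplyr::count(object$clusters, size = .data$n_members)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "spacers per cluster", y = "clusters") +
    ggplot2::theme_minimal()
}
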