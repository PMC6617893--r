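#' Export a compressed spacer graph as Graphviz DOT
#'
#' One node per block, labeled with its spacer-cluster labels (multi-label
#' blocks as `[b-c]`). Source blocks are filled blue (they tend to hold
#' newly gained leader spacers), sink blocks yellow (the conserved anchor
#' spacer); a block that is both source and sink takes the sink styling.
#' Edges along the dominant path are red; every edge is labeled with its
#' support count. The layout runs left to right, leader side on the left.
#'
#' @param cg A `compressed_spacer_graph`.
#' @param path Output file path.
#' @param highlight Apply source/sink fills and dominant-path coloring
#'   (default `TRUE`).
#' @return The path, invisibly.
#' @export
write_dot <- function(cg, path, highlight = TRUE) {
  stopifnot(inherits(cg, "compressed_spacer_graph"))
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(paste0("cannot write DOT file: ", path))
  })
  on.exit(close(con))

  lines <- c("digraph spacer_graph {",
             "  rankdir=LR;",
             "  node [shape=box, style=filled, fillcolor=white];")
  for (i in seq_along(cg$blocks)) {
    fill <- "white"
    if (isTRUE(highlight)) {
      if (i %in% cg$sources) fill <- "lightblue"
      if (i %in% cg$sinks) fill <- "yellow"   # sink style wins on lone blocks
    }
    lines <- c(lines, sprintf("  n%d [label=\"%s\", fillcolor=%s];",
                              i, block_label(cg$blocks[[i]]), fill))
  }
  dom <- cg$dominant_path
  dom_pairs <- if (length(dom) >= 2) {
    paste(dom[-length(dom)], dom[-1])
  } else character()
  if (nrow(cg$edges) > 0) {
    for (e in seq_len(nrow(cg$edges))) {
      u <- cg$edges$from[[e]]; v <- cg$edges$to[[e]]
      style <- if (isTRUE(highlight) && paste(u, v) %in% dom_pairs) {
        ", color=red, penwidth=2"
      } else ""
      lines <- c(lines, sprintf("  n%d -> n%d [label=\"%d\"%s];",
                                u, v, cg$edges$support[[e]], style))
    }
  }
  lines <- c(lines, "}")
  writeLines(lines, con)
  invisible(path)
}
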