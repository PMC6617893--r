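#' Build the spacer graph of a group of arrays
#'
#' Nodes are spacer-cluster labels; a directed edge u -> v carries a support
#' count equal to the number of times v immediately follows u across the
#' arrays of the group. An array of four consecutive spacers a,b,c,d thus
#' contributes four nodes and the three edges a->b, b->c, c->d.
#'
#' @param labeled A `labeled_arrays` tibble for a single group (all arrays
#'   expected to share spacers; nothing enforces it, the graph is simply
#'   disconnected otherwise).
#' @return An object of class `spacer_graph`: list with `nodes` (sorted
#'   integer labels), `edges` (tibble `from`, `to`, `support`), and the input
#'   `arrays` (kept for walk and dominant-path computation).
#' @export
build_spacer_graph <- function(labeled) {
  labeled <- tibble::as_tibble(labeled)
  if (nrow(labeled) > 0) {
    stopifnot(all(c("array_id", "labels") %in% names(labeled)))
  }
  if (!"left_complete" %in% names(labeled)) labeled$left_complete <- TRUE
  if (!"right_complete" %in% names(labeled)) labeled$right_complete <- TRUE

  if (nrow(labeled) == 0) {
    g <- list(nodes = integer(),
              edges = tibble::tibble(from = integer(), to = integer(),
                                     support = integer()),
              arrays = labeled)
    class(g) <- "spacer_graph"
    return(g)
  }

  pairs <- purrr::map_dfr(labeled$labels, function(l) {
    if (length(l) < 2) {
      return(tibble::tibble(from = integer(), to = integer()))
    }
    tibble::tibble(from = l[-length(l)], to = l[-1])
  })
  edges <- pairs |>
    dplyr::count(.data$from, .data$to, name = "support") |>
    dplyr::arrange(.data$from, .data$to)

  g <- list(nodes = sort(unique(unlist(labeled$labels))),
            edges = edges,
            arrays = labeled)
  class(g) <- "spacer_graph"
  g
}

# Labels occurring >= 2 times within any single array are pinned to
# singleton blocks: merging them would make per-array walks ambiguous.
unmergeable_labels <- function(arrays) {
  dup <- lapply(arrays$labels, function(l) unique(l[duplicated(l)]))
  sort(unique(unlist(dup)))
}

block_degrees <- function(edges, n_blocks) {
  indeg <- tabulate(edges$to, nbins = n_blocks)
  outdeg <- tabulate(edges$from, nbins = n_blocks)
  list(indeg = indeg, outdeg = outdeg)
}

#' Compress a spacer graph by collapsing non-branching chains
#'
#' Unitig-style edge contraction: an edge u -> v is contracted into a single
#' block whenever u has out-degree 1 and v has in-degree 1 (and no reverse
#' edge v -> u exists), repeated to a fixed point. The fixed point is
#' order-independent for this rule; edges are still processed in
#' deterministic label order. Labels duplicated within a single array are
#' kept as singleton blocks so that every array remains readable as one
#' contiguous walk. With `strict = TRUE` the contraction additionally
#' requires in-degree(u) <= 1 and out-degree(v) <= 1 — the literal
#' "both nodes have in- and out-degree at most one" reading, which differs
#' from the default only next to junctions.
#'
#' The result also stores, per array, its walk through the blocks (with entry
#' and exit offsets, since fragmented arrays may start or end mid-block), the
#' source and sink blocks, and the dominant path (see [dominant_path()]).
#'
#' @param graph A `spacer_graph` from [build_spacer_graph()].
#' @param strict Use the stricter contraction rule (default `FALSE`).
#' @return An object of class `compressed_spacer_graph`: list with `blocks`
#'   (list of integer label vectors), `edges` (tibble `from`, `to`,
#'   `support` over block indices), `sources`, `sinks` (block indices),
#'   `walks` (tibble `array_id`, `blocks` list-column, `start_offset`,
#'   `end_offset`), `dominant_path` (block index vector), `arrays`, `strict`.
#' @export
compress <- function(graph, strict = FALSE) {
  stopifnot(inherits(graph, "spacer_graph"))
  labels <- graph$nodes
  nb <- length(labels)
  blocks <- as.list(labels)
  alive <- rep(TRUE, nb)
  pinned <- labels %in% unmergeable_labels(graph$arrays)

  block_of <- stats::setNames(seq_len(nb), labels)
  edges <- graph$edges
  edges$from <- unname(block_of[as.character(edges$from)])
  edges$to <- unname(block_of[as.character(edges$to)])

  repeat {
    deg <- block_degrees(edges, nb)
    first_lab <- vapply(blocks, function(b) b[[1]], numeric(1))
    rev_key <- paste(edges$to, edges$from)
    cand <- which(
      edges$from != edges$to &
        deg$outdeg[edges$from] == 1 &
        deg$indeg[edges$to] == 1 &
        !pinned[edges$from] & !pinned[edges$to] &
        !(paste(edges$from, edges$to) %in% rev_key)
    )
    if (isTRUE(strict)) {
      cand <- cand[deg$indeg[edges$from[cand]] <= 1 &
                     deg$outdeg[edges$to[cand]] <= 1]
    }
    if (length(cand) == 0) break
    ord <- order(first_lab[edges$from[cand]], first_lab[edges$to[cand]])
    e <- cand[ord[[1]]]
    u <- edges$from[[e]]
    v <- edges$to[[e]]
    blocks[[u]] <- c(blocks[[u]], blocks[[v]])
    alive[v] <- FALSE
    edges <- edges[-e, , drop = FALSE]
    edges$from[edges$from == v] <- u
    edges$to[edges$to == v] <- u
  }

  # renumber surviving blocks by their first label so output is canonical
  keep <- which(alive)
  keep <- keep[order(vapply(blocks[keep], function(b) b[[1]], numeric(1)))]
  renum <- integer(nb)
  renum[keep] <- seq_along(keep)
  blocks <- blocks[keep]
  edges$from <- renum[edges$from]
  edges$to <- renum[edges$to]
  edges <- dplyr::arrange(edges, .data$from, .data$to)

  deg <- block_degrees(edges, length(blocks))
  cg <- list(
    blocks = lapply(blocks, as.integer),
    edges = edges,
    sources = which(deg$indeg == 0),
    sinks = which(deg$outdeg == 0),
    arrays = graph$arrays,
    strict = isTRUE(strict)
  )
  cg$walks <- compute_walks(cg)
  class(cg) <- "compressed_spacer_graph"
  cg$dominant_path <- dominant_path(cg)
  cg
}

# Per-array walk through the blocks. Verifies the path-preservation
# invariant: each maximal run inside one block must spell a contiguous slice
# of that block, mid-block entry/exit being legal only at walk ends.
compute_walks <- function(cg) {
  labels <- unlist(cg$blocks)
  block_of <- rep(seq_along(cg$blocks), lengths(cg$blocks))
  pos_in_block <- unlist(lapply(cg$blocks, seq_along))
  names(block_of) <- labels
  names(pos_in_block) <- labels

  arrays <- cg$arrays
  res <- purrr::map(seq_len(nrow(arrays)), function(i) {
    l <- arrays$labels[[i]]
    b <- unname(block_of[as.character(l)])
    p <- unname(pos_in_block[as.character(l)])
    r <- rle(b)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      pp <- p[starts[k]:ends[k]]
      if (any(diff(pp) != 1)) {
        abort(paste0("array '", arrays$array_id[[i]],
                     "': walk is not contiguous within a block"))
      }
      blen <- length(cg$blocks[[r$values[k]]])
      if (k > 1 && pp[[1]] != 1) {
        abort(paste0("array '", arrays$array_id[[i]],
                     "': mid-block entry inside a walk"))
      }
      if (k < length(r$values) && pp[[length(pp)]] != blen) {
        abort(paste0("array '", arrays$array_id[[i]],
                     "': mid-block exit inside a walk"))
      }
    }
    list(blocks = r$values,
         start_offset = p[[1]],
         end_offset = p[[length(p)]])
  })
  tibble::tibble(
    array_id = arrays$array_id,
    blocks = purrr::map(res, "blocks"),
    start_offset = purrr::map_int(res, ~ as.integer(.x$start_offset)),
    end_offset = purrr::map_int(res, ~ as.integer(.x$end_offset))
  )
}

#' Recover an array's label sequence from its stored walk
#'
#' Inverse of the walk mapping: concatenates the blocks along the array's
#' walk, honouring the entry offset in the first block and the exit offset in
#' the last. Used to assert that compression loses no array.
#'
#' @param cg A `compressed_spacer_graph`.
#' @param array_id Id of one array stored in the graph.
#' @return Integer vector of spacer-cluster labels.
#' @export
walk_labels <- function(cg, array_id) {
  stopifnot(inherits(cg, "compressed_spacer_graph"))
  i <- match(array_id, cg$walks$array_id)
  if (is.na(i)) abort(paste0("unknown array_id: ", array_id))
  w <- cg$walks$blocks[[i]]
  s <- cg$walks$start_offset[[i]]
  e <- cg$walks$end_offset[[i]]
  if (length(w) == 1) {
    return(cg$blocks[[w]][s:e])
  }
  first <- cg$blocks[[w[[1]]]]
  last <- cg$blocks[[w[[length(w)]]]]
  mid <- if (length(w) > 2) unlist(cg$blocks[w[-c(1, length(w))]]) else integer()
  as.integer(c(first[s:length(first)], mid, last[1:e]))
}

#' Dominant path of a compressed spacer graph
#'
#' The walk of the most frequently observed array organization in the group
#' — the "typical" array, drawn in red in rendered graphs. Organizations are
#' counted over arrays complete at both ends (fragments of the dominant form
#' would otherwise each count as their own organization); if the group has no
#' complete array, all arrays are counted. Ties go to the longer
#' organization, then to the lexicographically smallest label sequence.
#'
#' @param cg A `compressed_spacer_graph`.
#' @return Integer vector of block indices (empty if the group is empty).
#' @export
dominant_path <- function(cg) {
  stopifnot(inherits(cg, "compressed_spacer_graph"))
  arrays <- cg$arrays
  if (nrow(arrays) == 0) return(integer())
  use <- arrays$left_complete & arrays$right_complete
  if (!any(use)) use <- rep(TRUE, nrow(arrays))
  org <- vapply(arrays$labels, paste, character(1), collapse = ",")
  cnt <- table(org[use])
  best <- names(cnt)[cnt == max(cnt)]
  if (length(best) > 1) {
    len <- vapply(strsplit(best, ","), length, integer(1))
    best <- best[len == max(len)]
    best <- sort(best)[[1]]
  }
  i <- which(org == best & use)[[1]]
  w <- cg$walks$blocks[[match(arrays$array_id[[i]], cg$walks$array_id)]]
  as.integer(w)
}

#' Source and sink blocks
#'
#' Sources (no incoming edge) hold candidate newly gained spacers at the
#' leader side; the sink holds the conserved trailer-end ("anchor") spacer.
#'
#' @param cg A `compressed_spacer_graph`.
#' @return List with integer block indices `sources` and `sinks`.
#' @export
classify_terminals <- function(cg) {
  stopifnot(inherits(cg, "compressed_spacer_graph"))
  list(sources = cg$sources, sinks = cg$sinks)
}

block_label <- function(block) {
  if (length(block) == 1) as.character(block) else
    paste0("[", paste(block, collapse = "-"), "]")
}

#' @export
print.spacer_graph <- function(x, ...) {
  cat("# Spacer graph: ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges, ", nrow(x$arrays), " arrays\n", sep = "")
  invisible(x)
}

#' @export
print.compressed_spacer_graph <- function(x, ...) {
  cat("# Compressed spacer graph: ", length(x$blocks), " blocks, ",
      nrow(x$edges), " edges; ", length(x$sources), " source(s), ",
      length(x$sinks), " sink(s)\n", sep = "")
  cat("# blocks: ",
      paste(vapply(x$blocks, block_label, character(1)), collapse = " "),
      "\n", sep = "")
  invisible(x)
}
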