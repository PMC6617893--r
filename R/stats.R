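#' Spacer redundancy of a dataset
#'
#' Redundancy = number of predicted spacers / number of spacer clusters:
#' how many times, on average, each distinct spacer is observed. Long reads
#' of a microbiome give values far above 1 (each spacer seen many times),
#' whereas short-read assemblies collapse repeats and sit near 1 — the
#' property that makes array-dynamics analysis possible at all.
#'
#' @param n_spacers Total spacer count (>= `n_clusters`).
#' @param n_clusters Number of spacer clusters (>= 1).
#' @return A one-row tibble of class `redundancy_report`: `n_spacers`,
#'   `n_clusters`, `redundancy` (full precision; printing rounds to 2
#'   decimals).
#' @examples
#' redundancy(51416, 5685)   # ~9.04
#' @export
redundancy <- function(n_spacers, n_clusters) {
  if (!is.numeric(n_clusters) || length(n_clusters) != 1 || n_clusters < 1) {
    abort("n_clusters must be a single count >= 1")
  }
  if (!is.numeric(n_spacers) || length(n_spacers) != 1 ||
      n_spacers < n_clusters) {
    abort("n_spacers must be a single count >= n_clusters")
  }
  out <- tibble::tibble(
    n_spacers = as.integer(n_spacers),
    n_clusters = as.integer(n_clusters),
    redundancy = n_spacers / n_clusters
  )
  class(out) <- unique(c("redundancy_report", class(out)))
  out
}

#' @export
print.redundancy_report <- function(x, ...) {
  cat("# Spacer redundancy: ", x$n_spacers, " spacers / ", x$n_clusters,
      " clusters = ", sprintf("%.2f", x$redundancy), "\n", sep = "")
  invisible(x)
}

#' Per-group descriptive report
#'
#' One row per array group combining size, graph shape, anchor conservation
#' and the orientation call. Groups without a graph (e.g. below the reporting
#' threshold) keep their row with the graph-derived columns `NA` and trigger
#' a warning.
#'
#' @param groups A `crispr_array_groups` tibble.
#' @param graphs Named list of `compressed_spacer_graph`s, names =
#'   `group_id`.
#' @param trailer_reports Optional named list (or tibble with `group_id`) of
#'   [trailer_conservation()] rows.
#' @param orientations Optional named list (or tibble with `group_id`) of
#'   [infer_orientation()] rows.
#' @return A tibble: `group_id`, `size`, `n_labels`, `n_blocks`,
#'   `n_sources`, `n_sinks`, `anchor_conservation`, `orientation`.
#' @export
group_report <- function(groups, graphs, trailer_reports = NULL,
                         orientations = NULL) {
  as_by_group <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.data.frame(x)) return(x)
    dplyr::bind_rows(x)
  }
  tr <- as_by_group(trailer_reports)
  ori <- as_by_group(orientations)

  rows <- purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    gid <- groups$group_id[[i]]
    cg <- graphs[[as.character(gid)]]
    if (is.null(cg)) {
      warn(paste0("no graph for group ", gid, "; graph columns left empty"))
      gr <- tibble::tibble(n_labels = NA_integer_, n_blocks = NA_integer_,
                           n_sources = NA_integer_, n_sinks = NA_integer_)
    } else {
      gr <- tibble::tibble(
        n_labels = sum(lengths(cg$blocks)),
        n_blocks = length(cg$blocks),
        n_sources = length(cg$sources),
        n_sinks = length(cg$sinks)
      )
    }
    cons <- if (!is.null(tr) && gid %in% tr$group_id) {
      tr$conservation[[match(gid, tr$group_id)]]
    } else NA_real_
    orient <- if (!is.null(ori) && gid %in% ori$group_id) {
      ori$orientation[[match(gid, ori$group_id)]]
    } else NA_character_
    tibble::tibble(group_id = gid, size = groups$member_count[[i]], gr,
                   anchor_conservation = cons, orientation = orient)
  })
  rows
}
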