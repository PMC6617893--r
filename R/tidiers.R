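#' Tidy a spacer cluster map
#'
#' @param x A `spacer_cluster_map`.
#' @param ... Unused.
#' @return One row per spacer: `spacer_id`, `cluster_id`,
#'   `is_representative`.
#' @export
tidy.spacer_cluster_map <- function(x, ...) {
  x$assignment
}

#' @rdname tidy.spacer_cluster_map
#' @return For `glance()`: one row with `n_spacers`, `n_clusters`,
#'   `redundancy`, `identity_threshold`, `strand_mode`.
#' @export
glance.spacer_cluster_map <- function(x, ...) {
  tibble::tibble(
    n_spacers = nrow(x$assignment),
    n_clusters = nrow(x$clusters),
    redundancy = nrow(x$assignment) / nrow(x$clusters),
    identity_threshold = x$identity_threshold,
    strand_mode = x$strand_mode
  )
}

#' Tidy array groups
#'
#' @param x A `crispr_array_groups` tibble.
#' @param ... Unused.
#' @return Long membership table: `group_id`, `array_id`, `is_reference`.
#' @export
tidy.crispr_array_groups <- function(x, ...) {
  x |>
    tibble::as_tibble() |>
    dplyr::select("group_id", "reference_array_id", "member_array_ids") |>
    tidyr::unnest_longer("member_array_ids", values_to = "array_id") |>
    dplyr::transmute(.data$group_id, .data$array_id,
                     is_reference = .data$array_id == .data$reference_array_id)
}

#' @rdname tidy.crispr_array_groups
#' @param min_size Reporting threshold forwarded to [group_summary()].
#' @export
glance.crispr_array_groups <- function(x, min_size = 10, ...) {
  group_summary(x, min_size = min_size)
}

#' Tidy a compressed spacer graph
#'
#' @param x A `compressed_spacer_graph`.
#' @param ... Unused.
#' @return One row per block: `block`, `labels` (list-column), `n_labels`,
#'   `is_source`, `is_sink`, `on_dominant_path`.
#' @export
tidy.compressed_spacer_graph <- function(x, ...) {
  tibble::tibble(
    block = seq_along(x$blocks),
    labels = x$blocks,
    n_labels = lengths(x$blocks),
    is_source = seq_along(x$blocks) %in% x$sources,
    is_sink = seq_along(x$blocks) %in% x$sinks,
    on_dominant_path = seq_along(x$blocks) %in% x$dominant_path
  )
}

#' @rdname tidy.compressed_spacer_graph
#' @export
glance.compressed_spacer_graph <- function(x, ...) {
  tibble::tibble(
    n_blocks = length(x$blocks),
    n_labels = sum(lengths(x$blocks)),
    n_edges = nrow(x$edges),
    n_sources = length(x$sources),
    n_sinks = length(x$sinks),
    n_arrays = nrow(x$arrays),
    dominant_path_length = length(x$dominant_path)
  )
}
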