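#' CRISPR array records
#'
#' A CRISPR array captured on a single read is an ordered run of spacers
#' interleaved with near-identical repeats. Arrays are held one per row in a
#' tibble with list-columns for the per-unit sequences, so a whole dataset
#' pipes through dplyr verbs.
#'
#' @param array_id Character, unique per array.
#' @param read_id Character, the read each array was called on.
#' @param spacers List of character vectors: ordered spacer sequences
#'   (uppercase A/C/G/T/N), leader to trailer as the read was sequenced.
#' @param repeats List of character vectors: the repeat units flanking the
#'   spacers. A fully repeat-bounded array has `length(spacers) + 1` repeats;
#'   a fragmented end may drop its terminal repeat, so `length(spacers)`
#'   repeats is also valid.
#' @param left_complete,right_complete Logical: `TRUE` when the respective
#'   array end is intact rather than truncated by the read boundary. End-based
#'   statistics (trailer conservation, repeat degeneracy) only trust complete
#'   ends.
#'
#' @return A tibble of class `crispr_arrays` with one row per array.
#' @examples
#' crispr_arrays(
#'   array_id = "a1", read_id = "r1",
#'   spacers = list(c("ACGTACGT", "GGTTGGTT")),
#'   repeats = list(c("AAAATTTT", "AAAATTTT", "AAAATTTT"))
#' )
#' @export
crispr_arrays <- function(array_id, read_id, spacers, repeats,
                          left_complete = TRUE, right_complete = TRUE) {
  out <- tibble::tibble(
    array_id = as.character(array_id),
    read_id = as.character(read_id),
    left_complete = as.logical(left_complete),
    right_complete = as.logical(right_complete),
    spacers = as.list(spacers),
    repeats = as.list(repeats)
  )
  validate_arrays(out)
}

#' Validate a CRISPR array table
#'
#' Checks the structural invariants every downstream stage relies on:
#' unique array ids, non-empty uppercase DNA sequences, and a repeat count of
#' `n_spacers` or `n_spacers + 1`.
#'
#' @param arrays A `crispr_arrays` tibble (or anything coercible: a data frame
#'   with the same columns).
#' @return The validated tibble, classed `crispr_arrays`, invisibly usable in
#'   a pipe.
#' @export
validate_arrays <- function(arrays) {
  arrays <- tibble::as_tibble(arrays)
  needed <- c("array_id", "read_id", "left_complete", "right_complete",
              "spacers", "repeats")
  missing <- setdiff(needed, names(arrays))
  if (length(missing) > 0) {
    abort(paste0("array table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(arrays$array_id)) {
    dup <- unique(arrays$array_id[duplicated(arrays$array_id)])
    abort(paste0("duplicate array_id: ", paste(dup, collapse = ", ")))
  }
  for (i in seq_len(nrow(arrays))) {
    sp <- arrays$spacers[[i]]
    rp <- arrays$repeats[[i]]
    id <- arrays$array_id[[i]]
    if (length(sp) < 1) {
      abort(paste0("array '", id, "': spacer list is empty"))
    }
    if (!length(rp) %in% (length(sp) + 0:1)) {
      abort(paste0("array '", id, "': ", length(rp), " repeats for ",
                   length(sp), " spacers (need n or n+1)"))
    }
    seqs <- c(sp, rp)
    if (any(!nzchar(seqs))) {
      abort(paste0("array '", id, "': empty sequence"))
    }
    if (any(grepl("[^ACGTN]", seqs))) {
      abort(paste0("array '", id, "': non-DNA character (allowed: A/C/G/T/N)"))
    }
  }
  class(arrays) <- unique(c("crispr_arrays", class(arrays)))
  arrays
}

#' Extract spacer instances from an array table
#'
#' Flattens the per-array spacer list-column into one row per spacer
#' occurrence. The generated `spacer_id` (`"<array_id>|<position>"`) is stable
#' and unique, and is what the clustering stage assigns labels to.
#'
#' @param arrays A `crispr_arrays` tibble.
#' @return A tibble with columns `spacer_id`, `array_id`, `position`
#'   (1-based along the array) and `sequence`.
#' @export
extract_spacers <- function(arrays) {
  arrays <- validate_arrays(arrays)
  if (nrow(arrays) == 0) {
    return(tibble::tibble(spacer_id = character(), array_id = character(),
                          position = integer(), sequence = character()))
  }
  arrays |>
    dplyr::select("array_id", "spacers") |>
    dplyr::mutate(position = purrr::map(.data$spacers, seq_along)) |>
    tidyr::unnest(c("spacers", "position")) |>
    dplyr::transmute(
      spacer_id = paste0(.data$array_id, "|", .data$position),
      array_id = .data$array_id,
      position = as.integer(.data$position),
      sequence = .data$spacers
    )
}

#' Relabel arrays as sequences of spacer-cluster labels
#'
#' Replaces each spacer occurrence by the integer label of its spacer
#' cluster, so arrays sharing near-identical spacers share labels. This is the
#' representation every graph and grouping stage consumes.
#'
#' @param arrays A `crispr_arrays` tibble.
#' @param cluster_map A [spacer_cluster_map] whose assignment covers every
#'   spacer instance of `arrays` (as produced by [cluster_spacers()] on
#'   [extract_spacers()] output).
#' @return A tibble of class `labeled_arrays`: `array_id`, `labels`
#'   (list-column of integer vectors), `n_spacers`, `left_complete`,
#'   `right_complete`.
#' @export
label_arrays <- function(arrays, cluster_map) {
  arrays <- validate_arrays(arrays)
  stopifnot(inherits(cluster_map, "spacer_cluster_map"))
  inst <- extract_spacers(arrays)
  lab <- stats::setNames(cluster_map$assignment$cluster_id,
                         cluster_map$assignment$spacer_id)
  miss <- setdiff(inst$spacer_id, names(lab))
  if (length(miss) > 0) {
    abort(paste0("cluster map lacks labels for ", length(miss),
                 " spacer instance(s), e.g. ", miss[[1]]))
  }
  out <- arrays |>
    dplyr::transmute(
      .data$array_id,
      labels = purrr::map2(.data$array_id, .data$spacers, function(id, sp) {
        as.integer(unname(lab[paste0(id, "|", seq_along(sp))]))
      }),
      n_spacers = lengths(.data$spacers),
      .data$left_complete, .data$right_complete
    )
  class(out) <- unique(c("labeled_arrays", class(out)))
  out
}

#' @export
print.crispr_arrays <- function(x, ...) {
  cat("# CRISPR array table: ", nrow(x), " array(s), ",
      sum(lengths(x$spacers)), " spacer occurrence(s)\n", sep = "")
  NextMethod()
}
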