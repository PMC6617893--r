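#' Match spacers against same-sample reads (protospacer search)
#'
#' Deterministic in-package replacement for a blastn search of spacers
#' against the reads they came from. Exact k-mer seeds (default k = 12, both
#' strands) anchor candidate placements which are extended to a full-spacer
#' alignment; spacers shorter than the seed fall back to an exhaustive scan.
#' A hit needs `identity = matches / spacer length >= min_identity` and
#' `coverage = matched-span fraction of the spacer >= min_coverage`.
#'
#' Matches inside predicted CRISPR regions are the arrays themselves, not
#' protospacers: any hit overlapping a supplied interval by at least one base
#' is retained but flagged `excluded` with reason `in_crispr_region`, keeping
#' the filtering auditable. Self-targeting spacers are reported like any
#' other hit — deciding whether a match is a genuine invader is ad hoc by
#' nature and left to the analyst.
#'
#' @param spacers Data frame with an id column (`spacer_cluster_id` or
#'   `spacer_id` or `cluster_id`) and `sequence` — typically the cluster
#'   representatives (`$representatives` of a [cluster_spacers()] result).
#' @param reads Data frame with `read_id`, `sequence`.
#' @param crispr_intervals Optional data frame `read_id`, `start`, `end`
#'   (0-based half-open, e.g. from [read_bed3()]) of predicted CRISPR
#'   regions. Interval read ids absent from `reads` raise a warning.
#' @param min_identity,min_coverage Acceptance thresholds (defaults 0.90 and
#'   0.95).
#' @param k Seed length (default 12).
#' @return A tibble of class `protospacer_hits`, ordered by `read_id` then
#'   `start`: `spacer_cluster_id`, `read_id`, `start`, `end` (0-based
#'   half-open), `strand`, `identity`, `coverage`, `excluded`,
#'   `exclusion_reason`.
#' @export
find_protospacers <- function(spacers, reads, crispr_intervals = NULL,
                              min_identity = 0.90, min_coverage = 0.95,
                              k = 12) {
  spacers <- tibble::as_tibble(spacers)
  reads <- tibble::as_tibble(reads)
  id_col <- intersect(c("spacer_cluster_id", "spacer_id", "cluster_id"),
                      names(spacers))[1]
  if (is.na(id_col) || !"sequence" %in% names(spacers)) {
    abort("spacers need an id column and a 'sequence' column")
  }
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))

  empty <- tibble::tibble(
    spacer_cluster_id = character(), read_id = character(),
    start = integer(), end = integer(), strand = character(),
    identity = double(), coverage = double(),
    excluded = logical(), exclusion_reason = character()
  )
  if (nrow(spacers) == 0 || nrow(reads) == 0) {
    class(empty) <- unique(c("protospacer_hits", class(empty)))
    return(empty)
  }

  hits <- protospacer_scan_cpp(
    as.character(spacers[[id_col]]), toupper(spacers$sequence),
    as.character(reads$read_id), toupper(reads$sequence),
    as.integer(k), min_identity, min_coverage
  ) |>
    tibble::as_tibble()

  if (nrow(hits) > 0) {
    # one best, non-overlapping hit per (spacer, read, strand) locus
    hits <- hits |>
      dplyr::group_by(.data$spacer_cluster_id, .data$read_id, .data$strand) |>
      dplyr::arrange(dplyr::desc(.data$identity), .data$start,
                     .by_group = TRUE) |>
      dplyr::filter(!remove_overlapping(.data$start, .data$end)) |>
      dplyr::ungroup()
  }

  hits$excluded <- FALSE
  hits$exclusion_reason <- "none"
  if (!is.null(crispr_intervals) && nrow(hits) > 0) {
    iv <- tibble::as_tibble(crispr_intervals)
    stopifnot(all(c("read_id", "start", "end") %in% names(iv)))
    orphan <- setdiff(iv$read_id, reads$read_id)
    if (length(orphan) > 0) {
      warn(paste0("CRISPR interval read id(s) absent from reads: ",
                  paste(utils::head(orphan, 3), collapse = ", ")))
    }
    for (i in seq_len(nrow(hits))) {
      ov <- iv$read_id == hits$read_id[[i]] &
        iv$start < hits$end[[i]] & hits$start[[i]] < iv$end
      if (any(ov)) {
        hits$excluded[[i]] <- TRUE
        hits$exclusion_reason[[i]] <- "in_crispr_region"
      }
    }
  }

  out <- hits |>
    dplyr::arrange(.data$read_id, .data$start, .data$spacer_cluster_id,
                   .data$strand)
  class(out) <- unique(c("protospacer_hits", class(out)))
  out
}

# TRUE for entries overlapping an earlier-kept interval (input pre-sorted
# best-first within a group)
remove_overlapping <- function(start, end) {
  drop <- logical(length(start))
  kept_s <- integer(0); kept_e <- integer(0)
  for (i in seq_along(start)) {
    if (any(kept_s < end[[i]] & start[[i]] < kept_e)) {
      drop[[i]] <- TRUE
    } else {
      kept_s <- c(kept_s, start[[i]]); kept_e <- c(kept_e, end[[i]])
    }
  }
  drop
}

#' Reads carrying candidate protospacers
#'
#' The unique reads with at least one non-excluded hit — the putative
#' invader-derived reads a downstream assembler would consume.
#'
#' @param hits A `protospacer_hits` tibble from [find_protospacers()].
#' @return Sorted character vector of read ids.
#' @export
invader_read_set <- function(hits) {
  hits <- tibble::as_tibble(hits)
  if (nrow(hits) == 0) return(character())
  sort(unique(hits$read_id[!hits$excluded]))
}
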