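#' Cluster spacer sequences at an identity threshold
#'
#' Greedy longest-first clustering with cd-hit-est semantics: sequences are
#' visited in decreasing length (ties broken by id, ascending); each joins
#' the first existing cluster, in founding order, whose *representative* it
#' matches at or above the threshold, otherwise it founds a new cluster with
#' itself as representative. Near-identical spacers — sequencing errors or
#' real point mutations — thus receive the same integer label, and arrays can
#' be compared as label sequences.
#'
#' No k-mer prefilter is applied: with free internal gaps in the identity
#' score no filter is provably lossless, and the compiled alignment kernel
#' keeps the brute-force member-versus-representative scan fast at realistic
#' spacer counts.
#'
#' @param spacers A data frame with columns `spacer_id` (unique) and
#'   `sequence`, e.g. from [extract_spacers()] or [read_spacer_fasta()].
#' @param threshold Identity threshold in `(0, 1]`; the default 0.90 tolerates
#'   a small number of errors in a ~30 bp spacer.
#' @param strand_mode `"both"` (default, matches reverse complements) or
#'   `"forward"`; see [sequence_identity()].
#' @return An object of class `spacer_cluster_map`: a list with
#'   * `clusters` — tibble `cluster_id`, `representative_id`, `n_members`,
#'     `member_ids` (list-column), in founding order;
#'   * `assignment` — tibble `spacer_id`, `cluster_id`, `is_representative`;
#'   * `identity_threshold`, `strand_mode`.
#' @seealso [label_arrays()] to apply the labels, [redundancy()] for the
#'   dataset-level spacers-per-cluster summary.
#' @export
cluster_spacers <- function(spacers, threshold = 0.90,
                            strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  spacers <- tibble::as_tibble(spacers)
  stopifnot(all(c("spacer_id", "sequence") %in% names(spacers)))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    abort("threshold must be in (0, 1]")
  }
  if (anyDuplicated(spacers$spacer_id)) {
    abort("duplicate spacer_id in input")
  }
  if (any(is.na(spacers$sequence) | !nzchar(spacers$sequence))) {
    abort("empty spacer sequence in input")
  }

  spacers <- spacers |>
    dplyr::mutate(sequence = toupper(.data$sequence)) |>
    dplyr::arrange(dplyr::desc(nchar(.data$sequence)),
                   .data$spacer_id)

  ids <- spacers$spacer_id
  seqs <- spacers$sequence
  n <- length(seqs)

  rep_seq <- character(0)
  rep_len <- integer(0)
  rep_id <- character(0)
  assign_cluster <- integer(n)

  for (i in seq_len(n)) {
    q <- seqs[[i]]
    ql <- nchar(q)
    hit <- 0L
    if (length(rep_seq) > 0) {
      m <- match_counts_cpp(q, rep_seq)
      if (strand_mode == "both") {
        m <- pmax(m, match_counts_cpp(revcomp_cpp(q), rep_seq))
      }
      ident <- m / pmin(ql, rep_len)
      idx <- which(ident >= threshold)
      if (length(idx) > 0) hit <- idx[[1]]
    }
    if (hit == 0L) {
      rep_seq <- c(rep_seq, q)
      rep_len <- c(rep_len, ql)
      rep_id <- c(rep_id, ids[[i]])
      hit <- length(rep_seq)
    }
    assign_cluster[[i]] <- hit
  }

  assignment <- tibble::tibble(
    spacer_id = ids,
    cluster_id = assign_cluster,
    is_representative = ids %in% rep_id &
      assign_cluster == match(ids, rep_id)
  )
  clusters <- assignment |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(member_ids = list(.data$spacer_id),
                     n_members = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$cluster_id) |>
    dplyr::mutate(representative_id = rep_id[.data$cluster_id]) |>
    dplyr::select("cluster_id", "representative_id", "n_members", "member_ids")

  structure(
    list(clusters = clusters, assignment = assignment,
         representatives = tibble::tibble(cluster_id = seq_along(rep_id),
                                          spacer_id = rep_id,
                                          sequence = rep_seq),
         identity_threshold = threshold, strand_mode = strand_mode),
    class = "spacer_cluster_map"
  )
}

#' @export
print.spacer_cluster_map <- function(x, ...) {
  cat("# Spacer cluster map: ", nrow(x$assignment), " spacers in ",
      nrow(x$clusters), " clusters (identity >= ",
      format(x$identity_threshold), ", strand ", x$strand_mode, ")\n",
      sep = "")
  invisible(x)
}
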