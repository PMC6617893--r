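#' Run the full spacer-graph pipeline
#'
#' Chains every stage over one array table: spacer extraction, identity
#' clustering, array labeling, greedy array grouping, per-group compressed
#' spacer graphs with orientation and trailer-conservation calls, the
#' dataset redundancy figure, and (when reads are supplied) the protospacer
#' search. When `out_dir` is given, all intermediates are written as plain
#' text: `clusters.tsv`, `groups.tsv`, `summary.tsv`, one DOT file per
#' reported group, `hits.tsv`, and a `config.txt` provenance record.
#'
#' @param arrays A `crispr_arrays` tibble, or a path to an array TSV.
#' @param identity_threshold Spacer-clustering identity (default 0.90).
#' @param strand_mode Spacer-clustering strand handling (default `"both"`).
#' @param min_group_report Build graphs and reports for groups of at least
#'   this many arrays (default 10, the usual reporting threshold); graphs
#'   are still built for smaller groups when `graph_all_groups = TRUE`.
#' @param graph_all_groups Build a graph for every group regardless of size
#'   (default `FALSE`).
#' @param reads Optional reads tibble (`read_id`, `sequence`) or FASTA path
#'   for the protospacer stage.
#' @param crispr_intervals Optional interval tibble or BED path; see
#'   [find_protospacers()].
#' @param min_identity,min_coverage Protospacer thresholds.
#' @param out_dir Optional output directory (created if needed).
#' @return A list: `arrays`, `cluster_map`, `labeled`, `groups`,
#'   `group_summary`, `graphs` (named by group id), `orientations`,
#'   `trailer_reports`, `report`, `redundancy`, and `hits`/`invader_reads`
#'   when reads were supplied. Deterministic for fixed inputs.
#' @export
run_pipeline <- function(arrays,
                         identity_threshold = 0.90,
                         strand_mode = "both",
                         min_group_report = 10,
                         graph_all_groups = FALSE,
                         reads = NULL,
                         crispr_intervals = NULL,
                         min_identity = 0.90,
                         min_coverage = 0.95,
                         out_dir = NULL) {
  if (is.character(arrays) && length(arrays) == 1) {
    arrays <- read_arrays_tsv(arrays)
  }
  arrays <- validate_arrays(arrays)
  if (is.character(reads) && length(reads) == 1) {
    rf <- read_spacer_fasta(reads)
    reads <- tibble::tibble(read_id = rf$spacer_id, sequence = rf$sequence)
  }
  if (is.character(crispr_intervals) && length(crispr_intervals) == 1) {
    crispr_intervals <- read_bed3(crispr_intervals)
  }

  if (nrow(arrays) == 0) {
    warn("empty array table; producing empty outputs")
    res <- list(arrays = arrays, cluster_map = NULL,
                labeled = NULL,
                groups = cluster_arrays(tibble::tibble(array_id = character(),
                                                       labels = list())),
                group_summary = tibble::tibble(n_groups = 0L,
                                               n_singletons = 0L,
                                               n_at_least_min = 0L),
                graphs = list(), orientations = NULL, trailer_reports = NULL,
                report = NULL, redundancy = NULL)
    return(res)
  }

  inst <- extract_spacers(arrays)
  cluster_map <- cluster_spacers(inst, threshold = identity_threshold,
                                 strand_mode = strand_mode)
  labeled <- label_arrays(arrays, cluster_map)
  groups <- cluster_arrays(labeled)
  gs <- group_summary(groups, min_size = min_group_report)
  red <- redundancy(nrow(cluster_map$assignment), nrow(cluster_map$clusters))

  graphs <- list()
  orientations <- list()
  trailer_reports <- list()
  todo <- if (graph_all_groups) seq_len(nrow(groups)) else
    which(groups$member_count >= min_group_report)
  for (i in todo) {
    gid <- groups$group_id[[i]]
    members <- groups$member_array_ids[[i]]
    lab_g <- labeled[labeled$array_id %in% members, ]
    arr_g <- arrays[arrays$array_id %in% members, ]
    cg <- compress(build_spacer_graph(lab_g))
    ori <- infer_orientation(arr_g, cg, group_id = gid)
    orient_for_trailer <- if (ori$orientation == "reversed") "reversed"
                          else "as_given"
    tr <- trailer_conservation(lab_g, orient_for_trailer, group_id = gid)
    graphs[[as.character(gid)]] <- cg
    orientations[[as.character(gid)]] <- ori
    trailer_reports[[as.character(gid)]] <- tr
  }

  reported <- groups[groups$group_id %in% as.integer(names(graphs)), ]
  report <- if (nrow(reported) > 0) {
    group_report(reported, graphs, trailer_reports, orientations)
  } else NULL

  res <- list(arrays = arrays, cluster_map = cluster_map, labeled = labeled,
              groups = groups, group_summary = gs, graphs = graphs,
              orientations = orientations, trailer_reports = trailer_reports,
              report = report, redundancy = red)

  if (!is.null(reads)) {
    res$hits <- find_protospacers(
      cluster_map$representatives |>
        dplyr::transmute(spacer_cluster_id = as.character(.data$cluster_id),
                         sequence = .data$sequence),
      reads, crispr_intervals,
      min_identity = min_identity, min_coverage = min_coverage)
    res$invader_reads <- invader_read_set(res$hits)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_clusters_tsv(cluster_map, file.path(out_dir, "clusters.tsv"))
    write_groups_tsv(groups, file.path(out_dir, "groups.tsv"))
    if (!is.null(report)) {
      readr::write_tsv(report, file.path(out_dir, "summary.tsv"))
    }
    for (gid in names(graphs)) {
      write_dot(graphs[[gid]], file.path(out_dir, paste0("group", gid, ".dot")))
    }
    if (!is.null(res$hits)) {
      readr::write_tsv(res$hits, file.path(out_dir, "hits.tsv"))
    }
    cfg <- c(identity_threshold = identity_threshold,
             strand_mode = strand_mode,
             min_group_report = min_group_report,
             min_identity = min_identity, min_coverage = min_coverage)
    writeLines(paste(names(cfg), unname(cfg), sep = " = "),
               file.path(out_dir, "config.txt"))
  }
  res
}
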