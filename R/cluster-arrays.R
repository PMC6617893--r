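#' Group CRISPR arrays that share spacers
#'
#' Greedy grouping of arrays represented as spacer-label sequences. The
#' longest unclustered array (most spacers; ties by `array_id`, ascending)
#' founds a new group as its reference. Remaining arrays are then swept in
#' the same order and an array joins the first existing group, in founding
#' order, with which it shares at least `min_shared` labels; sweeps repeat
#' until none joins, so each group is closed under spacer sharing before the
#' next reference is chosen. Every array ends in exactly one group;
#' singletons are kept as groups of one.
#'
#' With `transitive = FALSE` sharing is assessed against the group's
#' reference array only instead of the union of all members' labels — a
#' stricter reading of reference-based recruitment, kept behind a flag.
#'
#' @param labeled A `labeled_arrays` tibble from [label_arrays()] (columns
#'   `array_id`, `labels`; `n_spacers` is recomputed if absent).
#' @param min_shared Minimum number of shared labels to join a group
#'   (default 1).
#' @param transitive Compare against all current members (`TRUE`, default)
#'   or only the reference array (`FALSE`).
#' @return A tibble of class `crispr_array_groups`, one row per group, in
#'   founding order: `group_id`, `reference_array_id`, `member_array_ids`
#'   (list-column), `member_count`.
#' @export
cluster_arrays <- function(labeled, min_shared = 1, transitive = TRUE) {
  labeled <- tibble::as_tibble(labeled)
  if (nrow(labeled) == 0) {
    out <- tibble::tibble(group_id = integer(),
                          reference_array_id = character(),
                          member_array_ids = list(),
                          member_count = integer())
    class(out) <- unique(c("crispr_array_groups", class(out)))
    return(out)
  }
  stopifnot(all(c("array_id", "labels") %in% names(labeled)))
  if (any(lengths(labeled$labels) == 0)) {
    abort("array with zero spacer labels cannot be grouped")
  }
  if (anyDuplicated(labeled$array_id)) abort("duplicate array_id")

  ord <- order(-lengths(labeled$labels), labeled$array_id)
  ids <- labeled$array_id[ord]
  labs <- lapply(labeled$labels[ord], unique)

  n <- length(ids)
  unclustered <- rep(TRUE, n)
  group_members <- list()   # indices into ids
  group_labels <- list()    # label union (or reference labels if !transitive)
  group_ref <- integer(0)

  while (any(unclustered)) {
    ref <- which(unclustered)[1]  # ids are in spacer-count-desc order
    g <- length(group_members) + 1L
    group_members[[g]] <- ref
    group_labels[[g]] <- labs[[ref]]
    group_ref[g] <- ref
    unclustered[ref] <- FALSE

    repeat {
      added <- FALSE
      for (i in which(unclustered)) {
        for (k in seq_along(group_members)) {
          if (sum(labs[[i]] %in% group_labels[[k]]) >= min_shared) {
            group_members[[k]] <- c(group_members[[k]], i)
            if (transitive) {
              group_labels[[k]] <- union(group_labels[[k]], labs[[i]])
            }
            unclustered[i] <- FALSE
            added <- TRUE
            break
          }
        }
      }
      if (!added) break
    }
  }

  out <- tibble::tibble(
    group_id = seq_along(group_members),
    reference_array_id = ids[group_ref],
    member_array_ids = lapply(group_members, function(ix) ids[ix]),
    member_count = lengths(group_members)
  )
  class(out) <- unique(c("crispr_array_groups", class(out)))
  out
}

#' Summarize group sizes
#'
#' Counts groups overall, singleton groups, and groups of at least
#' `min_size` members — the size classes used when reporting how much array
#' sharing a dataset contains (groups with 10 or more spacer-sharing arrays
#' are the ones worth a spacer graph).
#'
#' @param groups A `crispr_array_groups` tibble from [cluster_arrays()].
#' @param min_size Reporting threshold (default 10); must be >= 1.
#' @return A one-row tibble: `n_groups`, `n_singletons`, `n_at_least_min`.
#' @export
group_summary <- function(groups, min_size = 10) {
  if (!is.numeric(min_size) || length(min_size) != 1 || min_size < 1) {
    abort("min_size must be a single number >= 1")
  }
  sizes <- groups$member_count %||% integer(0)
  tibble::tibble(
    n_groups = length(sizes),
    n_singletons = sum(sizes == 1),
    n_at_least_min = sum(sizes >= min_size)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
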