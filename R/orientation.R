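#' Repeat degeneracy score of a group of arrays
#'
#' The trailer-proximal repeat of an active CRISPR array is typically
#' degenerate relative to the array's consensus repeat. The score is
#'
#'   mean mismatches(last repeat, consensus)  -
#'   mean mismatches(first repeat, consensus)
#'
#' where each mean runs over arrays whose respective end is complete, and
#' the consensus is the positionwise majority over all repeat units of the
#' modal repeat length. A positive score means the right end is the more
#' degenerate — i.e. the trailer, under the convention that the trailer
#' repeat decays. Mismatches between repeats of unequal length count the
#' length difference on top of the positionwise differences.
#'
#' @param arrays A `crispr_arrays` tibble (one group), with per-unit repeats.
#' @return Signed numeric score; `NA` with a warning when no array has a
#'   complete end on one side or the other (never silently 0).
#' @export
repeat_degeneracy_score <- function(arrays) {
  arrays <- validate_arrays(arrays)
  units <- unlist(arrays$repeats)
  if (length(units) == 0) {
    warn("no repeat units; degeneracy score undefined")
    return(NA_real_)
  }
  len <- nchar(units)
  modal_len <- as.integer(names(sort(table(len), decreasing = TRUE))[[1]])
  cons <- consensus_seq(units[len == modal_len], modal_len)

  # first repeat exists whenever a left repeat is present (n+1 repeats, or a
  # left-anchored n-repeat layout); end repeats are only trusted on complete ends
  first_mm <- c()
  last_mm <- c()
  for (i in seq_len(nrow(arrays))) {
    rp <- arrays$repeats[[i]]
    ns <- length(arrays$spacers[[i]])
    has_both <- length(rp) == ns + 1
    if (arrays$left_complete[[i]] && (has_both || length(rp) == ns)) {
      first_mm <- c(first_mm, mismatches(rp[[1]], cons))
    }
    if (arrays$right_complete[[i]] && has_both) {
      last_mm <- c(last_mm, mismatches(rp[[length(rp)]], cons))
    }
  }
  if (length(first_mm) == 0 || length(last_mm) == 0) {
    warn("no arrays with complete ends on both sides; degeneracy score undefined")
    return(NA_real_)
  }
  mean(last_mm) - mean(first_mm)
}

consensus_seq <- function(seqs, len) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  paste(apply(mat, 2, function(col) {
    names(sort(table(col), decreasing = TRUE))[[1]]
  }), collapse = "")
}

mismatches <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  n <- min(la, lb)
  av <- strsplit(substr(a, 1, n), "")[[1]]
  bv <- strsplit(substr(b, 1, n), "")[[1]]
  sum(av != bv) + abs(la - lb)
}

#' Infer the orientation of a group of CRISPR arrays
#'
#' Two independent signals are combined. The *degeneracy* signal is
#' [repeat_degeneracy_score()]: a degenerate right-end repeat puts the
#' trailer on the right, i.e. leader left, orientation `as_given`. The
#' *topology* signal compares the diversity of source blocks against sink
#' blocks in the compressed spacer graph: new spacers accrete at the leader,
#' so the leader side shows many alternative source blocks while the trailer
#' side funnels into a single conserved sink. Diversity is measured as the
#' number of distinct terminal blocks (each source block starts with a
#' distinct label, each sink ends with one), so the signal reduces to
#' `sign(n_sources - n_sinks)`; counting every label *inside* terminal
#' blocks would instead let a long conserved core that compresses into the
#' sink block swamp the signal. A single-block graph carries no topological
#' information.
#'
#' Agreeing signs give a high-confidence call; a single informative signal
#' gives a low-confidence call; conflicting signals (or none) yield
#' `undetermined` with both scores reported — conflicts are surfaced, never
#' silently resolved, since even dedicated orientation predictors disagree
#' on real arrays.
#'
#' @param arrays The group's `crispr_arrays` tibble (carries the repeats).
#' @param cg The group's `compressed_spacer_graph`.
#' @param group_id Optional identifier copied into the result.
#' @return A one-row tibble of class `orientation_call`: `group_id`,
#'   `orientation` (`"as_given"`, `"reversed"`, `"undetermined"`),
#'   `degeneracy_score`, `topology_score`, `confidence` (`"high"`/`"low"`).
#' @export
infer_orientation <- function(arrays, cg, group_id = NA_integer_) {
  stopifnot(inherits(cg, "compressed_spacer_graph"))
  deg <- withCallingHandlers(
    repeat_degeneracy_score(arrays),
    warning = function(w) invokeRestart("muffleWarning")
  )
  topo_raw <- length(cg$sources) - length(cg$sinks)
  # a lone block is both source and sink: no topological information
  if (length(cg$blocks) == 1) topo_raw <- 0
  topo <- sign(topo_raw)

  dsign <- if (is.na(deg)) 0 else sign(deg)
  combined <- dplyr::case_when(
    dsign != 0 & topo != 0 & dsign == topo ~ "agree",
    dsign != 0 & topo != 0 & dsign != topo ~ "conflict",
    dsign != 0 | topo != 0 ~ "single",
    TRUE ~ "none"
  )
  orientation <- switch(
    combined,
    agree = if (dsign > 0) "as_given" else "reversed",
    single = if ((dsign + topo) > 0) "as_given" else "reversed",
    "undetermined"
  )
  confidence <- if (combined == "agree") "high" else "low"

  out <- tibble::tibble(
    group_id = group_id,
    orientation = orientation,
    degeneracy_score = if (is.na(deg)) NA_real_ else as.numeric(deg),
    topology_score = as.numeric(topo),
    confidence = confidence
  )
  class(out) <- unique(c("orientation_call", class(out)))
  out
}

#' Trailer ("anchor") spacer conservation of a group
#'
#' The trailer-end spacer is strongly conserved across spacer-sharing array
#' variants; it is the anchor spacer and the sink of the compressed graph.
#' Only arrays whose trailer-side end is complete are eligible — a fragmented
#' end says nothing about the true terminal spacer. The anchor is the modal
#' trailer-end label among eligible arrays (ties: smallest label).
#'
#' @param labeled The group's `labeled_arrays` tibble.
#' @param orientation `"as_given"` (trailer is the right end, default) or
#'   `"reversed"` (trailer left), e.g. from [infer_orientation()].
#' @param group_id Optional identifier copied into the result.
#' @return A one-row tibble of class `trailer_report`: `group_id`,
#'   `anchor_label`, `n_supporting`, `n_eligible`, `conservation`
#'   (`n_supporting / n_eligible`; `NA` when nothing is eligible).
#' @export
trailer_conservation <- function(labeled, orientation = c("as_given", "reversed"),
                                 group_id = NA_integer_) {
  orientation <- match.arg(orientation)
  labeled <- tibble::as_tibble(labeled)
  trailer_right <- orientation == "as_given"
  eligible <- if (trailer_right) labeled$right_complete else labeled$left_complete
  end_label <- vapply(labeled$labels, function(l) {
    if (trailer_right) l[[length(l)]] else l[[1]]
  }, numeric(1))
  end_label <- end_label[eligible]

  if (length(end_label) == 0) {
    out <- tibble::tibble(group_id = group_id, anchor_label = NA_integer_,
                          n_supporting = 0L, n_eligible = 0L,
                          conservation = NA_real_)
  } else {
    cnt <- table(end_label)
    top <- cnt[cnt == max(cnt)]
    anchor <- min(as.integer(names(top)))
    out <- tibble::tibble(
      group_id = group_id,
      anchor_label = as.integer(anchor),
      n_supporting = as.integer(sum(end_label == anchor)),
      n_eligible = length(end_label),
      conservation = sum(end_label == anchor) / length(end_label)
    )
  }
  class(out) <- unique(c("trailer_report", class(out)))
  out
}
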