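# Label simulated arrays with their *true* labels (valid when
# mutation_rate = 0 and strands are not randomized: sequences then identify
# labels exactly, including after fragmentation).
truth_labeled <- function(sim, fragmented = FALSE) {
  dict <- c(
    stats::setNames(sim$truth$ancestor$labels, sim$truth$ancestor$spacers),
    stats::setNames(sim$truth$novel_spacers$label,
                    sim$truth$novel_spacers$sequence)
  )
  arrays <- sim$arrays
  labels <- lapply(arrays$spacers, function(sp) as.integer(dict[sp]))
  stopifnot(!anyNA(unlist(labels)))
  tibble::tibble(
    array_id = arrays$array_id,
    labels = labels,
    n_spacers = lengths(labels),
    left_complete = arrays$left_complete,
    right_complete = arrays$right_complete
  )
}

walk_path_labels <- function(cg, path, labels) {
  identical(as.integer(unlist(cg$blocks[path])), as.integer(labels))
}
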