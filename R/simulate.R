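#' Configuration for the CRISPR array evolution simulator
#'
#' The stated world the simulator emulates: a single ancestral array
#' diversifying in a population through leader-end spacer acquisition,
#' internal segmental loss, and point mutation, observed through reads that
#' may truncate array ends. Defaults follow typical CRISPR unit sizes
#' (~30 bp spacers and repeats) and the regime used for orientation
#' benchmarking (gain 0.3 and loss 0.1 events per lineage, 0.5% per-base
#' substitution, 3 degenerate positions planted in the trailer repeat).
#'
#' @param seed Integer seed; every stochastic draw flows through one RNG.
#' @param n_ancestral_spacers Spacers in the ancestor (default 20).
#' @param spacer_length,repeat_length Unit lengths in bp (default 30).
#' @param population_size Number of sampled arrays (default 50).
#' @param gain_rate Expected leader-end insertions per lineage (Poisson).
#' @param loss_rate Expected segmental deletions per lineage (Poisson).
#' @param loss_block_mean Mean deleted block length (geometric, default 3).
#' @param mutation_rate Per-base substitution probability.
#' @param trailer_repeat_degeneracy Mismatches planted once in the
#'   *ancestral* trailer-proximal repeat (a property of the locus, inherited
#'   by every descendant).
#' @param fragmentation_prob Probability each array end is truncated by the
#'   read boundary (applied by [fragment_reads()]; default 0 here).
#' @param protect_trailer Never delete the trailer spacer (default `TRUE`),
#'   mirroring the observed conservation of anchor spacers.
#' @param randomize_strand Emit each array on a random strand (default
#'   `FALSE`; graph building expects a consistent within-group orientation).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_ancestral_spacers = 20, spacer_length = 30,
                       repeat_length = 30, population_size = 50,
                       gain_rate = 0.3, loss_rate = 0.1, loss_block_mean = 3,
                       mutation_rate = 0.005, trailer_repeat_degeneracy = 3,
                       fragmentation_prob = 0, protect_trailer = TRUE,
                       randomize_strand = FALSE) {
  cfg <- list(seed = as.integer(seed),
              n_ancestral_spacers = as.integer(n_ancestral_spacers),
              spacer_length = as.integer(spacer_length),
              repeat_length = as.integer(repeat_length),
              population_size = as.integer(population_size),
              gain_rate = gain_rate, loss_rate = loss_rate,
              loss_block_mean = loss_block_mean,
              mutation_rate = mutation_rate,
              trailer_repeat_degeneracy = as.integer(trailer_repeat_degeneracy),
              fragmentation_prob = fragmentation_prob,
              protect_trailer = isTRUE(protect_trailer),
              randomize_strand = isTRUE(randomize_strand))
  with(cfg, {
    stopifnot(n_ancestral_spacers >= 1, spacer_length >= 1, repeat_length >= 1,
              population_size >= 1, gain_rate >= 0, loss_rate >= 0,
              loss_block_mean >= 1, mutation_rate >= 0, mutation_rate <= 1,
              trailer_repeat_degeneracy >= 0,
              trailer_repeat_degeneracy <= repeat_length,
              fragmentation_prob >= 0, fragmentation_prob <= 1)
  })
  class(cfg) <- "sim_config"
  cfg
}

# run code under a given seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

substitute_base <- function(base) {
  sample(setdiff(c("A", "C", "G", "T"), base), 1)
}

mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  k <- rbinom(1, n, rate)
  if (k == 0) {
    return(list(seq = seq, subs = tibble::tibble(pos = integer(),
                                                 from = character(),
                                                 to = character())))
  }
  pos <- sort(sample.int(n, k))
  chars <- strsplit(seq, "")[[1]]
  from <- chars[pos]
  to <- vapply(from, substitute_base, character(1), USE.NAMES = FALSE)
  chars[pos] <- to
  list(seq = paste(chars, collapse = ""),
       subs = tibble::tibble(pos = pos, from = from, to = to))
}

#' Simulate a population of spacer-sharing CRISPR arrays
#'
#' Forward simulation from a single random ancestor. Each sampled lineage
#' independently applies `Poisson(gain_rate)` insertions of novel random
#' spacers at the leader (left) end — newest outermost — then
#' `Poisson(loss_rate)` deletions of geometric-length internal blocks (a
#' deletion that would exceed the array, empty it, or hit a protected
#' trailer spacer is resampled), then per-base substitutions at
#' `mutation_rate` on every spacer and repeat unit. The ancestral
#' trailer-proximal repeat carries `trailer_repeat_degeneracy` planted
#' mismatches, inherited by all lineages. Arrays are emitted leader to
#' trailer, each optionally flipped to the reverse strand with probability
#' 0.5 when `randomize_strand` is on. Fully reproducible from `seed`.
#'
#' @param config A [sim_config()].
#' @return A list with
#'   * `arrays` — a `crispr_arrays` tibble, one row per sampled array;
#'   * `truth` — a `sim_truth` object: the ancestor (labels, spacer and
#'     repeat sequences), the per-array event history (gains, losses,
#'     substitutions, strand flip) and true label sequence, the novel-spacer
#'     table, `true_orientation` (`"as_given"`) and `true_anchor_label`.
#'     [replay_array()] rebuilds any emitted array from this record.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    n0 <- config$n_ancestral_spacers
    anc_spacers <- vapply(seq_len(n0), function(i)
      random_dna(config$spacer_length), character(1))
    cons_repeat <- random_dna(config$repeat_length)
    anc_repeats <- rep(cons_repeat, n0 + 1)
    if (config$trailer_repeat_degeneracy > 0) {
      pos <- sort(sample.int(config$repeat_length,
                             config$trailer_repeat_degeneracy))
      chars <- strsplit(cons_repeat, "")[[1]]
      chars[pos] <- vapply(chars[pos], substitute_base, character(1),
                           USE.NAMES = FALSE)
      anc_repeats[n0 + 1] <- paste(chars, collapse = "")
    }

    novel_label <- n0
    novel_tab <- tibble::tibble(label = integer(), sequence = character())
    events <- list()
    rows <- vector("list", config$population_size)

    for (i in seq_len(config$population_size)) {
      labels <- seq_len(n0)
      spacers <- anc_spacers
      repeats <- anc_repeats

      n_gain <- rpois(1, config$gain_rate)
      gains <- tibble::tibble(label = integer(), sequence = character())
      for (g in seq_len(n_gain)) {
        novel_label <- novel_label + 1L
        seq <- random_dna(config$spacer_length)
        labels <- c(novel_label, labels)
        spacers <- c(seq, spacers)
        repeats <- c(cons_repeat, repeats)
        gains <- dplyr::bind_rows(
          gains, tibble::tibble(label = novel_label, sequence = seq))
        novel_tab <- dplyr::bind_rows(
          novel_tab, tibble::tibble(label = novel_label, sequence = seq))
      }

      n_loss <- rpois(1, config$loss_rate)
      losses <- tibble::tibble(start = integer(), length = integer())
      for (l in seq_len(n_loss)) {
        for (try in 1:50) {
          len <- rgeom(1, 1 / config$loss_block_mean) + 1L
          ncur <- length(labels)
          max_start <- if (config$protect_trailer) ncur - len
                       else ncur - len + 1L
          if (ncur - len < 1 || max_start < 1) next
          start <- sample.int(max_start, 1)
          idx <- start:(start + len - 1L)
          labels <- labels[-idx]
          spacers <- spacers[-idx]
          repeats <- repeats[-idx]
          losses <- dplyr::bind_rows(
            losses, tibble::tibble(start = start, length = len))
          break
        }
      }

      subs <- tibble::tibble(unit = character(), index = integer(),
                             pos = integer(), from = character(),
                             to = character())
      if (config$mutation_rate > 0) {
        for (j in seq_along(spacers)) {
          m <- mutate_seq(spacers[[j]], config$mutation_rate)
          spacers[[j]] <- m$seq
          if (nrow(m$subs) > 0) {
            subs <- dplyr::bind_rows(
              subs, dplyr::mutate(m$subs, unit = "spacer", index = j,
                                  .before = 1))
          }
        }
        for (j in seq_along(repeats)) {
          m <- mutate_seq(repeats[[j]], config$mutation_rate)
          repeats[[j]] <- m$seq
          if (nrow(m$subs) > 0) {
            subs <- dplyr::bind_rows(
              subs, dplyr::mutate(m$subs, unit = "repeat", index = j,
                                  .before = 1))
          }
        }
      }

      flipped <- config$randomize_strand && runif(1) < 0.5
      out_spacers <- spacers
      out_repeats <- repeats
      if (flipped) {
        out_spacers <- rev(revcomp(spacers))
        out_repeats <- rev(revcomp(repeats))
      }

      aid <- sprintf("sim%04d", i)
      events[[aid]] <- list(gains = gains, losses = losses,
                            substitutions = subs, flipped = flipped,
                            labels = as.integer(labels))
      rows[[i]] <- tibble::tibble(
        array_id = aid, read_id = sprintf("read%04d", i),
        left_complete = TRUE, right_complete = TRUE,
        spacers = list(out_spacers), repeats = list(out_repeats)
      )
    }

    truth <- structure(
      list(config = config,
           ancestor = list(labels = seq_len(n0), spacers = anc_spacers,
                           repeats = anc_repeats,
                           consensus_repeat = cons_repeat),
           novel_spacers = novel_tab,
           arrays = events,
           true_orientation = "as_given",
           true_anchor_label = n0),
      class = "sim_truth")

    list(arrays = validate_arrays(dplyr::bind_rows(rows)), truth = truth)
  })
}

#' Replay a simulated array from its recorded event history
#'
#' Deterministically rebuilds one emitted array from the ancestor plus the
#' recorded gains, losses, substitutions and strand flip. Used to assert the
#' ground-truth invariant: replay reproduces every emitted array exactly.
#'
#' @param truth A `sim_truth` from [simulate_population()].
#' @param array_id One of the emitted array ids.
#' @return List with `spacers`, `repeats`, `labels`.
#' @export
replay_array <- function(truth, array_id) {
  stopifnot(inherits(truth, "sim_truth"))
  ev <- truth$arrays[[array_id]]
  if (is.null(ev)) abort(paste0("unknown array_id: ", array_id))
  labels <- truth$ancestor$labels
  spacers <- truth$ancestor$spacers
  repeats <- truth$ancestor$repeats
  cons <- truth$ancestor$consensus_repeat

  if (nrow(ev$gains) > 0) {
    for (g in seq_len(nrow(ev$gains))) {
      labels <- c(ev$gains$label[[g]], labels)
      spacers <- c(ev$gains$sequence[[g]], spacers)
      repeats <- c(cons, repeats)
    }
  }
  if (nrow(ev$losses) > 0) {
    for (l in seq_len(nrow(ev$losses))) {
      idx <- ev$losses$start[[l]]:(ev$losses$start[[l]] + ev$losses$length[[l]] - 1L)
      labels <- labels[-idx]
      spacers <- spacers[-idx]
      repeats <- repeats[-idx]
    }
  }
  if (nrow(ev$substitutions) > 0) {
    for (s in seq_len(nrow(ev$substitutions))) {
      row <- ev$substitutions[s, ]
      target <- if (row$unit == "spacer") spacers[[row$index]] else repeats[[row$index]]
      substr(target, row$pos, row$pos) <- row$to
      if (row$unit == "spacer") spacers[[row$index]] <- target
      else repeats[[row$index]] <- target
    }
  }
  if (isTRUE(ev$flipped)) {
    spacers <- rev(revcomp(spacers))
    repeats <- rev(revcomp(repeats))
    labels <- rev(labels)
  }
  list(spacers = spacers, repeats = repeats, labels = labels)
}

#' Truncate array ends to emulate read fragmentation
#'
#' Independently for each end of each array, with probability
#' `fragmentation_prob`, removes a uniform number (at least 1 when possible)
#' of terminal spacer-repeat units and clears that end's completeness flag.
#' An array is never emptied: a single-spacer array keeps its spacer but
#' still loses the flag. Truncated ends retain their boundary repeat, so the
#' `n + 1` repeat layout is preserved.
#'
#' @param arrays A `crispr_arrays` tibble.
#' @param fragmentation_prob Per-end truncation probability.
#' @param seed Integer seed.
#' @return The modified `crispr_arrays` tibble.
#' @export
fragment_reads <- function(arrays, fragmentation_prob, seed = 1L) {
  arrays <- validate_arrays(arrays)
  stopifnot(fragmentation_prob >= 0, fragmentation_prob <= 1)
  if (fragmentation_prob == 0 || nrow(arrays) == 0) return(arrays)
  with_local_seed(seed, {
    for (i in seq_len(nrow(arrays))) {
      sp <- arrays$spacers[[i]]
      rp <- arrays$repeats[[i]]
      has_extra <- length(rp) == length(sp) + 1
      if (runif(1) < fragmentation_prob) {         # left end
        n <- length(sp)
        if (n >= 2) {
          u <- sample.int(n - 1L, 1)
          sp <- sp[-(1:u)]
          rp <- rp[-(1:u)]
        }
        arrays$left_complete[[i]] <- FALSE
      }
      if (runif(1) < fragmentation_prob) {         # right end
        n <- length(sp)
        if (n >= 2) {
          u <- sample.int(n - 1L, 1)
          sp <- sp[seq_len(n - u)]
          rp <- rp[seq_len(length(rp) - u)]
        }
        arrays$right_complete[[i]] <- FALSE
      }
      arrays$spacers[[i]] <- sp
      arrays$repeats[[i]] <- rp
    }
    validate_arrays(arrays)
  })
}

#' Generate random background reads
#'
#' @param n Number of reads.
#' @param length Read length in bp.
#' @param seed Integer seed.
#' @param prefix Read id prefix.
#' @return Tibble `read_id`, `sequence`.
#' @export
random_reads <- function(n, length = 2000, seed = 1L, prefix = "read") {
  with_local_seed(seed, {
    tibble::tibble(
      read_id = sprintf("%s%04d", prefix, seq_len(n)),
      sequence = vapply(seq_len(n), function(i) random_dna(length),
                        character(1))
    )
  })
}

#' Plant spacer copies into background reads
#'
#' Inserts (overwrites in place) chosen spacer sequences at recorded
#' positions and strands, with optional per-base substitution errors, and
#' returns the modified reads together with the truth table that drives
#' protospacer-recovery tests. Plants never overlap each other on a read.
#'
#' @param reads Tibble `read_id`, `sequence` (e.g. [random_reads()]).
#' @param spacers Data frame with an id column and `sequence`.
#' @param n_plants Number of plants (0 returns the reads unchanged).
#' @param error_rate Per-base substitution probability within the plant.
#' @param seed Integer seed.
#' @return List with `reads` (modified tibble) and `truth` (tibble
#'   `read_id`, `spacer_id`, `start`, `end`, `strand`, `n_errors`; 0-based
#'   half-open coordinates).
#' @export
plant_protospacers <- function(reads, spacers, n_plants, error_rate = 0,
                               seed = 1L) {
  reads <- tibble::as_tibble(reads)
  spacers <- tibble::as_tibble(spacers)
  id_col <- intersect(c("spacer_cluster_id", "spacer_id", "cluster_id",
                        "label"), names(spacers))[1]
  stopifnot(!is.na(id_col), "sequence" %in% names(spacers))
  truth <- tibble::tibble(read_id = character(), spacer_id = character(),
                          start = integer(), end = integer(),
                          strand = character(), n_errors = integer())
  if (n_plants == 0) return(list(reads = reads, truth = truth))

  with_local_seed(seed, {
    occupied <- stats::setNames(vector("list", nrow(reads)), reads$read_id)
    for (p in seq_len(n_plants)) {
      for (try in 1:100) {
        si <- sample.int(nrow(spacers), 1)
        ri <- sample.int(nrow(reads), 1)
        seq <- toupper(spacers$sequence[[si]])
        len <- nchar(seq)
        rlen <- nchar(reads$sequence[[ri]])
        if (rlen < len) next
        start <- sample.int(rlen - len + 1L, 1) - 1L   # 0-based
        end <- start + len
        occ <- occupied[[reads$read_id[[ri]]]]
        clash <- any(vapply(occ, function(iv) iv[1] < end && start < iv[2],
                            logical(1)))
        if (clash) next
        strand <- sample(c("+", "-"), 1)
        planted <- if (strand == "+") seq else revcomp_cpp(seq)
        n_err <- 0L
        if (error_rate > 0) {
          m <- mutate_seq(planted, error_rate)
          planted <- m$seq
          n_err <- nrow(m$subs)
        }
        s <- reads$sequence[[ri]]
        substr(s, start + 1L, end) <- planted
        reads$sequence[[ri]] <- s
        occupied[[reads$read_id[[ri]]]] <- c(occ, list(c(start, end)))
        truth <- dplyr::bind_rows(truth, tibble::tibble(
          read_id = reads$read_id[[ri]],
          spacer_id = as.character(spacers[[id_col]][[si]]),
          start = start, end = end, strand = strand, n_errors = n_err))
        break
      }
    }
    list(reads = reads, truth = truth)
  })
}
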