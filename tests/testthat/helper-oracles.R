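# Independent oracles, deliberately naive, kept free of the package's
# implementation paths (pure R, recursive/tabular dynamic programming).

# max matched bases under match=+1, mismatch/gap=0, free end gaps:
# the longest common subsequence over exact A/C/G/T matches (N never matches)
lcs_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      hit <- av[i] == bv[j] && av[i] %in% c("A", "C", "G", "T")
      M[i + 1, j + 1] <- max(M[i, j] + as.integer(hit), M[i, j + 1], M[i + 1, j])
    }
  }
  M[n + 1, m + 1]
}

rc_oracle <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

identity_oracle <- function(a, b, strand_mode = "both") {
  m <- lcs_oracle(a, b)
  if (strand_mode == "both") m <- max(m, lcs_oracle(a, rc_oracle(b)))
  m / min(nchar(a), nchar(b))
}

# naive re-implementation of cd-hit-style greedy clustering from the full
# pairwise identity matrix
greedy_cluster_oracle <- function(ids, seqs, threshold, strand_mode = "both") {
  ord <- order(-nchar(seqs), ids)
  ids <- ids[ord]; seqs <- seqs[ord]
  reps <- integer(0)  # indices of representatives in sorted order
  assign <- integer(length(ids))
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (identity_oracle(seqs[i], seqs[reps[k]], strand_mode) >= threshold) {
        assign[i] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign[i] <- length(reps)
    }
  }
  stats::setNames(assign, ids)
}

# naive re-implementation of the greedy array grouping rule
greedy_groups_oracle <- function(ids, label_list, min_shared = 1) {
  ord <- order(-lengths(label_list), ids)
  ids <- ids[ord]; label_list <- lapply(label_list[ord], unique)
  group_of <- rep(NA_integer_, length(ids))
  glabels <- list()
  ng <- 0L
  while (anyNA(group_of)) {
    ref <- which(is.na(group_of))[1]
    ng <- ng + 1L
    group_of[ref] <- ng
    glabels[[ng]] <- label_list[[ref]]
    repeat {
      moved <- FALSE
      for (i in which(is.na(group_of))) {
        for (k in seq_len(ng)) {
          if (length(intersect(label_list[[i]], glabels[[k]])) >= min_shared) {
            group_of[i] <- k
            glabels[[k]] <- union(glabels[[k]], label_list[[i]])
            moved <- TRUE
            break
          }
        }
      }
      if (!moved) break
    }
  }
  stats::setNames(group_of, ids)
}

# connected components of the "shares >= 1 label" graph (union-find)
components_oracle <- function(ids, label_list) {
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && length(intersect(label_list[[i]], label_list[[j]])) > 0) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  stats::setNames(match(comp, unique(comp)), ids)
}

# partitions equal up to renaming of part ids
same_partition <- function(p, q) {
  stopifnot(identical(sort(names(p)), sort(names(q))))
  q <- q[names(p)]
  length(unique(paste(p, q))) == length(unique(p)) &&
    length(unique(p)) == length(unique(q))
}

random_dna_str <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_dna_str <- function(seq, n_subs) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(chars), n_subs)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

# quick labeled-array tibble builder
lab_tbl <- function(..., left = TRUE, right = TRUE) {
  labels <- list(...)
  tibble::tibble(
    array_id = sprintf("a%02d", seq_along(labels)),
    labels = lapply(labels, as.integer),
    n_spacers = lengths(labels),
    left_complete = rep_len(left, length(labels)),
    right_complete = rep_len(right, length(labels))
  )
}
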