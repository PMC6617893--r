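#' Read and write the array table
#'
#' The on-disk array table is a tab-separated file with header columns
#' `array_id`, `read_id`, `left_complete`, `right_complete`, `spacers`,
#' `repeats`; the two sequence columns are semicolon-delimited lists and the
#' flags are serialized as 0/1 (true/false also accepted on input).
#' Sequences are uppercased on read. Writing then reading is the identity on
#' valid records. Native outputs of upstream CRISPR detectors are *not*
#' parsed; converting them to this table is the documented extension point.
#'
#' @param path File path.
#' @return `read_arrays_tsv()`: a validated `crispr_arrays` tibble in file
#'   order. Malformed rows (wrong column count, empty sequence field,
#'   non-DNA character) raise a parse error naming the offending line;
#'   duplicate `array_id`s raise a validation error.
#' @export
read_arrays_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  needed <- c("array_id", "read_id", "left_complete", "right_complete",
              "spacers", "repeats")
  if (length(lines) == 0) abort("empty file: header row required")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!all(needed %in% header)) {
    abort(paste0("header must contain: ", paste(needed, collapse = ", ")))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(crispr_arrays(character(), character(), list(), list(),
                         logical(), logical()))
  }
  rows <- vector("list", length(body))
  for (i in seq_along(body)) {
    lineno <- i + 1L
    f <- strsplit(body[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(header)) {
      abort(paste0("line ", lineno, ": expected ", length(header),
                   " fields, got ", length(f)))
    }
    names(f) <- header
    sp <- toupper(strsplit(f[["spacers"]], ";", fixed = TRUE)[[1]])
    rp <- toupper(strsplit(f[["repeats"]], ";", fixed = TRUE)[[1]])
    if (length(sp) == 0 || any(!nzchar(sp))) {
      abort(paste0("line ", lineno, ": empty spacer field"))
    }
    if (length(rp) == 0 || any(!nzchar(rp))) {
      abort(paste0("line ", lineno, ": empty repeat field"))
    }
    if (any(grepl("[^ACGTN]", c(sp, rp)))) {
      abort(paste0("line ", lineno, ": non-DNA character"))
    }
    rows[[i]] <- tibble::tibble(
      array_id = f[["array_id"]], read_id = f[["read_id"]],
      left_complete = parse_flag(f[["left_complete"]], lineno),
      right_complete = parse_flag(f[["right_complete"]], lineno),
      spacers = list(sp), repeats = list(rp)
    )
  }
  validate_arrays(dplyr::bind_rows(rows))
}

parse_flag <- function(x, lineno) {
  v <- tolower(trimws(x))
  if (v %in% c("1", "true")) return(TRUE)
  if (v %in% c("0", "false")) return(FALSE)
  abort(paste0("line ", lineno, ": flag must be 0/1/true/false, got '", x, "'"))
}

#' @rdname read_arrays_tsv
#' @param arrays A `crispr_arrays` tibble.
#' @export
write_arrays_tsv <- function(arrays, path) {
  arrays <- validate_arrays(arrays)
  lines <- c(
    paste(c("array_id", "read_id", "left_complete", "right_complete",
            "spacers", "repeats"), collapse = "\t"),
    vapply(seq_len(nrow(arrays)), function(i) {
      paste(c(arrays$array_id[[i]], arrays$read_id[[i]],
              as.integer(arrays$left_complete[[i]]),
              as.integer(arrays$right_complete[[i]]),
              paste(arrays$spacers[[i]], collapse = ";"),
              paste(arrays$repeats[[i]], collapse = ";")),
            collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a spacer FASTA
#'
#' Multi-line records are supported (via Biostrings); sequences are
#' uppercased; duplicate ids are a validation error. Only the first
#' whitespace-delimited token of each header is kept as the id.
#'
#' @param path FASTA file path.
#' @return Tibble `spacer_id`, `sequence`.
#' @export
read_spacer_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA id: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  tibble::tibble(spacer_id = unname(ids),
                 sequence = unname(toupper(as.character(ss))))
}

#' Write sequences as FASTA
#'
#' @param seqs Data frame whose first character column is the id and which
#'   has a `sequence` column, or a named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    ids <- names(seqs); s <- unname(seqs)
  } else {
    seqs <- tibble::as_tibble(seqs)
    ids <- as.character(seqs[[1]]); s <- seqs$sequence
  }
  ss <- Biostrings::BStringSet(s)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Cluster and group table I/O
#'
#' Cluster tables have columns `spacer_id`, `cluster_id`,
#' `is_representative` (0/1); group tables have `group_id`, `array_id`,
#' `reference_flag` (0/1). Both round-trip.
#'
#' @param map A `spacer_cluster_map`.
#' @param path File path.
#' @export
write_clusters_tsv <- function(map, path) {
  stopifnot(inherits(map, "spacer_cluster_map"))
  df <- map$assignment |>
    dplyr::mutate(is_representative = as.integer(.data$is_representative))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_clusters_tsv
#' @export
read_clusters_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    spacer_id = readr::col_character(),
    cluster_id = readr::col_integer(),
    is_representative = readr::col_integer()
  )) |>
    dplyr::mutate(is_representative = .data$is_representative == 1L)
}

#' @rdname write_clusters_tsv
#' @param groups A `crispr_array_groups` tibble.
#' @export
write_groups_tsv <- function(groups, path) {
  df <- groups |>
    tibble::as_tibble() |>
    dplyr::select("group_id", "reference_array_id", "member_array_ids") |>
    tidyr::unnest_longer("member_array_ids", values_to = "array_id") |>
    dplyr::transmute(
      .data$group_id, .data$array_id,
      reference_flag = as.integer(.data$array_id == .data$reference_array_id))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_clusters_tsv
#' @export
read_groups_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    group_id = readr::col_integer(),
    array_id = readr::col_character(),
    reference_flag = readr::col_integer()
  )) |>
    dplyr::mutate(reference_flag = .data$reference_flag == 1L)
}

#' Read a 3-column BED of CRISPR intervals
#'
#' 0-based half-open intervals on reads; used to exclude protospacer hits
#' that fall inside predicted CRISPR regions.
#'
#' @param path BED file path.
#' @return Tibble `read_id`, `start`, `end`.
#' @export
read_bed3 <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  readr::read_tsv(path,
                  col_names = c("read_id", "start", "end"),
                  col_types = readr::cols(
                    read_id = readr::col_character(),
                    start = readr::col_integer(),
                    end = readr::col_integer()
                  ),
                  comment = "#")
}
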