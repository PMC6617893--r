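#' Reverse complement of DNA strings
#'
#' @param x Character vector of A/C/G/T/N sequences. Anything outside that
#'   alphabet complements to N.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(as.character(x), revcomp_cpp, character(1), USE.NAMES = FALSE)
}

#' Pairwise sequence identity, cd-hit style
#'
#' Identity between two spacers is the number of matched bases in an optimal
#' alignment divided by the length of the shorter sequence — the convention
#' of cd-hit, which the 90% spacer-clustering threshold was defined against.
#' The alignment scores match +1 with mismatches and gaps contributing
#' nothing and end gaps free, so the optimum equals the longest common
#' subsequence of exact base matches. `N` never matches anything, itself
#' included.
#'
#' @param a,b Non-empty DNA strings.
#' @param strand_mode `"both"` (default) also tries the reverse complement of
#'   `b` and keeps the better score, so spacers called from opposite-strand
#'   arrays still co-cluster; `"forward"` compares as given.
#' @return Identity fraction in `[0, 1]`; symmetric in its arguments.
#' @examples
#' sequence_identity("ACGTACGTAC", "ACGTACGTAC")      # 1
#' sequence_identity("ACGTACGTAC", "GTACGGCGTACGT")   # shorter-length denominator
#' @export
sequence_identity <- function(a, b, strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  a <- toupper(as.character(a))
  b <- toupper(as.character(b))
  if (length(a) != 1 || length(b) != 1 || is.na(a) || is.na(b) ||
      !nzchar(a) || !nzchar(b)) {
    abort("sequence_identity() needs two non-empty sequences")
  }
  m <- match_count_cpp(a, b)
  if (strand_mode == "both") {
    m <- max(m, match_count_cpp(a, revcomp_cpp(b)))
  }
  m / min(nchar(a), nchar(b))
}
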