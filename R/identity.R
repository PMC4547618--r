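#' Global-alignment identity between two nucleotide sequences
#'
#' Computes the fraction of identical positions over the alignment columns of
#' an optimal end-to-end (Needleman-Wunsch) alignment under a linear gap
#' penalty. This is the similarity measure used to match marker reference
#' sequences to genome 16S rRNA sequences when building the association
#' matrix.
#'
#' When several alignments share the optimal score, the reported alignment is
#' picked by a deterministic rule: maximize the score, then the number of
#' matches, then minimize the number of alignment columns. All three
#' objectives are per-column additive, so the choice is well defined and
#' reproducible.
#'
#' Input sequences are case-insensitive over the alphabet `A C G T U N`;
#' `U` is treated as `T`. The ambiguity code `N` scores as a mismatch against
#' every symbol (including another `N`), keeping the identity a lower bound.
#'
#' @param seq_a,seq_b Nonempty nucleotide strings.
#' @param match,mismatch,gap Per-column alignment scores (defaults +1, -1, -1).
#' @param detail If `TRUE`, return the score, match count and column count
#'   alongside the identity.
#' @return The identity fraction in `[0, 1]`, or a named numeric vector with
#'   elements `identity`, `score`, `matches`, `columns` when `detail = TRUE`.
#' @examples
#' pairwise_identity("ACGT", "ACGT")   # 1
#' pairwise_identity("ACGT", "ACGA")   # 0.75
#' @export
pairwise_identity <- function(seq_a, seq_b, match = 1, mismatch = -1,
                              gap = -1, detail = FALSE) {
  a <- encode_sequence(seq_a)
  b <- encode_sequence(seq_b)
  res <- nw_identity_cpp(a, b, match, mismatch, gap)
  if (detail) res else unname(res[["identity"]])
}

# Map a nucleotide string to integer codes 0..3 (A,C,G,T) and 4 (N).
encode_sequence <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    stop_ampliko("sequence must be a single nonempty string",
                 "ampliko_bad_sequence")
  }
  chars <- strsplit(chartr("uU", "tT", seq), "", fixed = TRUE)[[1]]
  codes <- match(toupper(chars), c("A", "C", "G", "T", "N")) - 1L
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    stop_ampliko(sprintf("sequence contains symbols outside {A,C,G,T,U,N}: %s",
                         paste(bad, collapse = " ")),
                 "ampliko_bad_sequence")
  }
  codes
}
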