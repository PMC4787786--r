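#' Pairwise alignment kernels
#'
#' Fixed-scoring dynamic-programming aligners used throughout the pipeline.
#' Global (Needleman-Wunsch) alignment scores match +1, mismatch -1, gap -2
#' (linear); local (Smith-Waterman) alignment scores match +2, mismatch -1,
#' gap -3. Traceback ties are always resolved diagonal > up > left so results
#' are deterministic. Wildcard characters ('N' in nucleotide mode, 'X' in
#' protein mode) mismatch every character including themselves.
#'
#' @name aligners
NULL

.wild_for <- function(alphabet) {
  switch(alphabet, dna = "N", protein = "X",
         stop("alphabet must be 'dna' or 'protein'"))
}

#' Global alignment identity between two sequences
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap -2) with
#' identity defined as identical aligned columns divided by the total number
#' of alignment columns, gap columns included in the denominator.
#'
#' @param seq_a,seq_b Non-empty character scalars (nucleotide by default).
#' @param alphabet `"dna"` or `"protein"`; controls the wildcard character.
#' @return Identity fraction in `[0, 1]`.
#' @export
#' @examples
#' global_identity("ACGTACGTAC", "ACGTACGTAA")  # 0.9
global_identity <- function(seq_a, seq_b, alphabet = "dna") {
  stopifnot(is.character(seq_a), is.character(seq_b),
            length(seq_a) == 1L, length(seq_b) == 1L)
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L)
    stop("global_identity() requires non-empty sequences")
  res <- cpp_align_global(toupper(seq_a), toupper(seq_b), 1L, -1L, -2L,
                          .wild_for(alphabet))
  res$identity
}

#' Global alignment with full result
#'
#' As [global_identity()] but returning score, match count and column count.
#'
#' @inheritParams global_identity
#' @return List with `score`, `matches`, `columns`, `identity`.
#' @export
nw_align <- function(seq_a, seq_b, alphabet = "dna") {
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L)
    stop("nw_align() requires non-empty sequences")
  cpp_align_global(toupper(seq_a), toupper(seq_b), 1L, -1L, -2L,
                   .wild_for(alphabet))
}

#' Semi-global alignment of a read against a reference
#'
#' The read is aligned end to end; gaps hanging off either end of the
#' reference are free (the standard "read fully aligned" mode used when
#' matching reads against 16S database sequences). Identity is counted over
#' the read-spanning alignment columns.
#'
#' @param read,ref Character scalars.
#' @inheritParams global_identity
#' @return List with `score`, `matches`, `columns`, `identity`, `ref_start`,
#'   `ref_end` (1-based reference span).
#' @export
overlap_align <- function(read, ref, alphabet = "dna") {
  if (nchar(read) == 0L || nchar(ref) == 0L)
    stop("overlap_align() requires non-empty sequences")
  cpp_align_overlap(toupper(read), toupper(ref), 1L, -1L, -2L,
                    .wild_for(alphabet))
}

#' Local (Smith-Waterman) alignment
#'
#' Match +2, mismatch -1, gap -3 (linear). Identity is identical residues over
#' aligned columns of the optimal local alignment; the spans on both sequences
#' are returned so callers can apply coverage rules.
#'
#' @param seq_a,seq_b Character scalars (protein by default).
#' @param alphabet `"protein"` or `"dna"`.
#' @return List with `score`, `matches`, `columns`, `identity`, `a_start`,
#'   `a_end`, `b_start`, `b_end` (1-based, 0 when the best alignment is empty).
#' @export
sw_align <- function(seq_a, seq_b, alphabet = "protein") {
  cpp_align_local(toupper(seq_a), toupper(seq_b), 2L, -1L, -3L,
                  .wild_for(alphabet))
}

#' All-against-all global identity matrix
#'
#' @param seqs Character vector of sequences (named or not).
#' @inheritParams global_identity
#' @return Symmetric numeric matrix of pairwise global identities.
#' @export
identity_matrix <- function(seqs, alphabet = "dna") {
  stopifnot(length(seqs) >= 1L, all(nchar(seqs) > 0L))
  m <- cpp_identity_matrix(toupper(seqs), 1L, -1L, -2L, .wild_for(alphabet))
  dimnames(m) <- list(names(seqs), names(seqs))
  m
}
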