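#' Quality truncation of a single read
#'
#' Truncates a read immediately before the first run of `run_len` consecutive
#' bases whose quality is below `q_min`; the full read is returned when no
#' such run exists. The low-quality run itself is always removed.
#'
#' @param seq Nucleotide string.
#' @param qual Integer Phred vector, same length as `seq`.
#' @param run_len Length of the triggering low-quality run (default 3).
#' @param q_min Quality threshold; bases with quality `< q_min` count towards
#'   a run (default 15).
#' @return List with truncated `seq` and `qual` (possibly empty).
#' @export
#' @examples
#' quality_truncate("ACGTAC", c(30, 30, 14, 14, 14, 30))$seq  # "AC"
quality_truncate <- function(seq, qual, run_len = 3L, q_min = 15L) {
  stopifnot(nchar(seq) == length(qual))
  if (length(qual) < run_len) return(list(seq = seq, qual = qual))
  low <- qual < q_min
  # rolling AND over windows of run_len via cumulative sums
  cs <- cumsum(c(0L, as.integer(low)))
  win <- cs[(run_len + 1L):length(cs)] - cs[seq_len(length(qual) - run_len + 1L)]
  hit <- which(win == run_len)
  if (length(hit) == 0L) return(list(seq = seq, qual = qual))
  keep <- hit[1L] - 1L
  list(seq = substr(seq, 1L, keep), qual = qual[seq_len(keep)])
}

#' Keep-or-drop filter for a truncated read pair
#'
#' A pair is dropped when either mate is shorter than `min_len` bases or has a
#' mean quality below `min_avg_q`; mates exactly at either threshold are kept.
#'
#' @param len1,len2 Mate lengths after truncation.
#' @param mean_q1,mean_q2 Mate mean qualities (NaN for empty mates drops).
#' @param min_len Minimum length (default 100).
#' @param min_avg_q Minimum mean quality (default 20).
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
filter_pair <- function(len1, len2, mean_q1, mean_q2,
                        min_len = 100L, min_avg_q = 20) {
  if (len1 < min_len || len2 < min_len) return(FALSE)
  if (is.nan(mean_q1) || is.nan(mean_q2)) return(FALSE)
  !(mean_q1 < min_avg_q || mean_q2 < min_avg_q)
}

#' Quality-filter a table of read pairs
#'
#' Applies [quality_truncate()] to both mates of every pair and then drops
#' pairs failing [filter_pair()].
#'
#' @param pairs Read-pair table (columns `pair_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`; qualities as Phred+33 strings).
#' @inheritParams quality_truncate
#' @inheritParams filter_pair
#' @return List with `pairs` (the kept, truncated table) and `summary`
#'   (list: `n_in`, `n_kept`).
#' @export
qc_pairs <- function(pairs, run_len = 3L, q_min = 15L,
                     min_len = 100L, min_avg_q = 20) {
  n <- nrow(pairs)
  keep <- logical(n)
  s1 <- character(n); q1 <- character(n)
  s2 <- character(n); q2 <- character(n)
  for (i in seq_len(n)) {
    t1 <- quality_truncate(pairs$seq1[i], phred_to_int(pairs$qual1[i]),
                           run_len, q_min)
    t2 <- quality_truncate(pairs$seq2[i], phred_to_int(pairs$qual2[i]),
                           run_len, q_min)
    keep[i] <- filter_pair(nchar(t1$seq), nchar(t2$seq),
                           mean(t1$qual), mean(t2$qual), min_len, min_avg_q)
    s1[i] <- t1$seq; q1[i] <- int_to_phred(t1$qual)
    s2[i] <- t2$seq; q2[i] <- int_to_phred(t2$qual)
  }
  out <- data.frame(pair_id = pairs$pair_id, seq1 = s1, qual1 = q1,
                    seq2 = s2, qual2 = q2, stringsAsFactors = FALSE)[keep, ]
  rownames(out) <- NULL
  list(pairs = out, summary = list(n_in = n, n_kept = sum(keep)))
}
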