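#' Six-frame ORFs of a read pair
#'
#' Translates both mates in all six frames under the standard genetic code
#' (ambiguous codons, e.g. those containing 'N', translate to 'X', which
#' mismatches everything downstream). An ORF is a maximal stop-free stretch of
#' a frame's translation; only stretches strictly longer than `min_len`
#' residues qualify. A pair is retained only when both mates contribute at
#' least one qualifying ORF.
#'
#' @param seq1,seq2 Mate nucleotide sequences.
#' @param min_len Minimum ORF length in residues, exclusive (default 45).
#' @return List with `orfs1`, `orfs2` (data frames `frame`, `aa_seq`; zero
#'   rows when none qualify) and `qualifies` (both mates have >= 1 ORF).
#' @export
six_frame_orfs <- function(seq1, seq2, min_len = 45L) {
  orfs <- .six_frame_batch(c(seq1, seq2), min_len)
  list(orfs1 = orfs[[1]], orfs2 = orfs[[2]],
       qualifies = nrow(orfs[[1]]) > 0L && nrow(orfs[[2]]) > 0L)
}

## Vectorized six-frame ORF extraction over many reads at once: one
## Biostrings::translate call per frame/strand instead of twelve per pair.
.six_frame_batch <- function(seqs, min_len) {
  seqs <- toupper(seqs)
  n <- length(seqs)
  per_seq <- rep(list(NULL), n)
  strands <- list(`+` = seqs, `-` = .revcomp(seqs))
  for (strand in names(strands)) {
    s <- strands[[strand]]
    L <- nchar(s)
    for (off in 0:2) {
      n_codon <- (L - off) %/% 3L
      ok <- which(n_codon >= 1L)
      if (length(ok) == 0L) next
      sub <- substr(s[ok], off + 1L, off + 3L * n_codon[ok])
      aa <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAStringSet(sub), if.fuzzy.codon = "X",
        no.init.codon = TRUE)))
      pieces <- strsplit(aa, "*", fixed = TRUE)
      for (k in seq_along(ok)) {
        keep <- pieces[[k]][nchar(pieces[[k]]) > min_len]
        if (length(keep)) {
          i <- ok[k]
          per_seq[[i]] <- rbind(per_seq[[i]], data.frame(
            frame = paste0(strand, off + 1L), aa_seq = keep,
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  empty <- data.frame(frame = character(0), aa_seq = character(0))
  lapply(per_seq, function(x) if (is.null(x)) empty else x)
}

#' Build an enzyme database object
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param reaction_ids Named list mapping each sequence id to a non-empty
#'   character vector of reaction ids.
#' @return `enzyme_db` list with `proteins` and `reaction_ids`.
#' @export
enzyme_db <- function(proteins, reaction_ids) {
  stopifnot(!is.null(names(proteins)),
            all(names(proteins) %in% names(reaction_ids)))
  reaction_ids <- reaction_ids[names(proteins)]
  if (any(lengths(reaction_ids) == 0L))
    stop("every enzyme must be linked to at least one reaction")
  if (any(nchar(proteins) == 0L)) stop("empty enzyme sequence")
  structure(list(proteins = proteins, reaction_ids = reaction_ids),
            class = "enzyme_db")
}

#' Build an enzyme database from a reference's reaction table
#'
#' @param reference A `rumenet_reference`, or any list with `proteins` and a
#'   reaction table carrying `enzymes` list-column.
#' @return An [enzyme_db()].
#' @export
enzyme_db_from_reference <- function(reference) {
  rx <- reference$reactions
  enz <- unlist(rx$enzymes, use.names = FALSE)
  rxid <- rep(rx$reaction_id, lengths(rx$enzymes))
  enzyme_db(reference$proteins[enz], split(rxid, factor(enz, levels = enz)))
}

.seed_positions <- function(aa, k) {
  L <- nchar(aa)
  if (L < k) return(character(0))
  substring(aa, 1:(L - k + 1L), k:L)
}

#' Dereplicate an enzyme database
#'
#' Greedy removal of near-duplicate sequences: records are visited in
#' descending length (ties broken by ascending id); a record is removed when
#' some already-retained record aligns to it locally with more than
#' `min_identity` identity over more than `min_coverage` of the shorter
#' sequence's length. Reaction annotations of removed records are merged into
#' the record that retained them, so no reaction id is ever lost.
#'
#' @param db An [enzyme_db()].
#' @param min_identity,min_coverage Thresholds, both exclusive (default 0.97).
#' @param seed_len,min_seeds Candidate prefilter: only pairs sharing at least
#'   `min_seeds` distinct `seed_len`-mers are aligned (defaults 7 and 2).
#' @return A dereplicated [enzyme_db()].
#' @export
dereplicate_db <- function(db, min_identity = 0.97, min_coverage = 0.97,
                           seed_len = 7L, min_seeds = 2L) {
  stopifnot(inherits(db, "enzyme_db"))
  ids <- names(db$proteins)
  ord <- ids[order(-nchar(db$proteins), ids)]
  retained <- character(0)
  reactions <- db$reaction_ids
  idx <- new.env(parent = emptyenv(), hash = TRUE)  # seed -> retained ids
  for (id in ord) {
    aa <- db$proteins[[id]]
    words <- unique(.seed_positions(aa, seed_len))
    tallies <- table(unlist(lapply(words, function(w) idx[[w]]),
                            use.names = FALSE))
    cand <- names(tallies)[tallies >= min_seeds]
    absorbed_by <- NA_character_
    for (r in cand) {
      other <- db$proteins[[r]]
      al <- sw_align(aa, other)
      short_len <- min(nchar(aa), nchar(other))
      span <- if (nchar(aa) <= nchar(other)) al$a_end - al$a_start + 1L
              else al$b_end - al$b_start + 1L
      if (al$columns > 0 && al$identity > min_identity &&
          span / short_len > min_coverage) {
        absorbed_by <- r
        break
      }
    }
    if (is.na(absorbed_by)) {
      retained <- c(retained, id)
      for (w in words) assign(w, c(idx[[w]], id), envir = idx)
    } else {
      reactions[[absorbed_by]] <- union(reactions[[absorbed_by]],
                                        reactions[[id]])
    }
  }
  enzyme_db(db$proteins[retained], reactions[retained])
}

#' Seed-and-extend search of one ORF against an enzyme database
#'
#' Candidate database sequences are those sharing at least `min_seeds`
#' distinct exact `seed_len`-residue words (distinct ORF start positions) with
#' the ORF. Each candidate is Smith-Waterman aligned; a hit is reported when
#' the local alignment shows at least `min_identity` amino-acid identity over
#' aligned columns and covers at least `min_coverage` of the ORF.
#'
#' @param orf Amino-acid string.
#' @param db An [enzyme_db()].
#' @param db_index Optional precomputed seed index over the database
#'   (built on the fly when NULL).
#' @param seed_len Seed word length (default 7).
#' @param min_seeds Distinct seeds required (default 2).
#' @param min_identity,min_coverage Acceptance thresholds, inclusive
#'   (default 0.8).
#' @return Data frame `seq_id`, `identity`, `orf_coverage`.
#' @export
seed_sw_search <- function(orf, db, db_index = NULL, seed_len = 7L,
                           min_seeds = 2L, min_identity = 0.8,
                           min_coverage = 0.8) {
  stopifnot(inherits(db, "enzyme_db"))
  if (is.null(db_index)) db_index <- .kmer_index(db$proteins, seed_len)
  words <- .seed_positions(orf, seed_len)  # one word per ORF start position
  ## count distinct ORF start positions with a word present in each candidate:
  ## a word occurring at several ORF starts contributes each start
  word_hits <- lapply(words, function(w) unique(db_index[[w]]))
  tallies <- table(unlist(word_hits, use.names = FALSE))
  cand <- as.integer(names(tallies)[tallies >= min_seeds])
  if (length(cand) == 0L)
    return(data.frame(seq_id = character(0), identity = numeric(0),
                      orf_coverage = numeric(0)))
  rows <- lapply(cand, function(j) {
    al <- sw_align(orf, db$proteins[[j]])
    cov <- (al$a_end - al$a_start + 1L) / nchar(orf)
    if (al$columns > 0 && al$identity >= min_identity && cov >= min_coverage)
      data.frame(seq_id = names(db$proteins)[j], identity = al$identity,
                 orf_coverage = cov, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L)
    return(data.frame(seq_id = character(0), identity = numeric(0),
                      orf_coverage = numeric(0)))
  do.call(rbind, rows)
}

#' Assign a read pair to reactions from its mates' enzyme hits
#'
#' Both mates must hit at least one common enzyme; otherwise the pair is
#' discarded (`discarded_mate_mismatch`), or `no_hit` when a mate has no hits
#' at all. Over the common enzymes, the pair is assigned the union of their
#' reaction sets when those sets are identical or nested (form a chain under
#' inclusion); if any two are disjoint — or otherwise incomparable — the pair
#' is discarded as ambiguous (`discarded_disjoint`).
#'
#' @param hits1,hits2 Character vectors of enzyme seq_ids hit by each mate.
#' @param db An [enzyme_db()] carrying the reaction annotations.
#' @return List with `status` and `reaction_ids` (non-empty iff assigned).
#' @export
assign_pair <- function(hits1, hits2, db) {
  stopifnot(inherits(db, "enzyme_db"))
  if (length(hits1) == 0L || length(hits2) == 0L)
    return(list(status = "no_hit", reaction_ids = character(0)))
  common <- intersect(hits1, hits2)
  if (length(common) == 0L)
    return(list(status = "discarded_mate_mismatch", reaction_ids = character(0)))
  sets <- db$reaction_ids[common]
  if (length(sets) > 1L) {
    for (i in seq_len(length(sets) - 1L)) {
      for (j in (i + 1L):length(sets)) {
        a <- sets[[i]]; b <- sets[[j]]
        nested <- all(a %in% b) || all(b %in% a)
        if (!nested)
          return(list(status = "discarded_disjoint",
                      reaction_ids = character(0)))
      }
    }
  }
  list(status = "assigned",
       reaction_ids = sort(unique(unlist(sets, use.names = FALSE))))
}

#' Map read pairs to reactions through the translated-read search
#'
#' Runs [six_frame_orfs()], [seed_sw_search()] (a mate's hit set is the union
#' over all of its qualifying ORFs) and [assign_pair()] over a read-pair
#' table.
#'
#' @param pairs QC-passed read-pair table.
#' @param db An [enzyme_db()] (dereplicate first if desired).
#' @param min_orf Minimum ORF length, exclusive (default 45).
#' @inheritParams seed_sw_search
#' @return Data frame `pair_id`, `status`, `reaction_ids`
#'   (semicolon-joined, empty unless assigned).
#' @export
map_enzyme_reads <- function(pairs, db, min_orf = 45L, seed_len = 7L,
                             min_seeds = 2L, min_identity = 0.8,
                             min_coverage = 0.8) {
  idx <- .kmer_index(db$proteins, seed_len)
  n <- nrow(pairs)
  status <- character(n); rxs <- character(n)
  orfs1 <- .six_frame_batch(pairs$seq1, min_orf)
  orfs2 <- .six_frame_batch(pairs$seq2, min_orf)
  mate_hits <- function(orfs) {
    if (nrow(orfs) == 0L) return(character(0))
    unique(unlist(lapply(orfs$aa_seq, function(aa)
      seed_sw_search(aa, db, idx, seed_len, min_seeds, min_identity,
                     min_coverage)$seq_id), use.names = FALSE))
  }
  for (i in seq_len(n)) {
    if (nrow(orfs1[[i]]) == 0L || nrow(orfs2[[i]]) == 0L) {
      status[i] <- "no_hit"; rxs[i] <- ""
      next
    }
    res <- assign_pair(mate_hits(orfs1[[i]]), mate_hits(orfs2[[i]]), db)
    status[i] <- res$status
    rxs[i] <- paste(res$reaction_ids, collapse = ";")
  }
  data.frame(pair_id = pairs$pair_id, status = status, reaction_ids = rxs,
             stringsAsFactors = FALSE)
}
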