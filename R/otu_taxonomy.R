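#' Prepare a 16S database
#'
#' Applies the standard database pre-filters: drop sequences shorter than
#' `min_len` bases or containing undetermined nucleotides ('N'), then purge
#' exact duplicates (the first sequence in id order is kept).
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param min_len Minimum sequence length (default 1450).
#' @param drop_n Drop sequences containing 'N' (default TRUE).
#' @return Named character vector of retained sequences.
#' @export
prepare_db <- function(seqs, min_len = 1450L, drop_n = TRUE) {
  stopifnot(!is.null(names(seqs)))
  keep <- nchar(seqs) >= min_len
  if (drop_n) keep <- keep & !grepl("N", seqs, fixed = TRUE)
  seqs <- seqs[keep]
  seqs <- seqs[order(names(seqs))]
  seqs[!duplicated(unname(seqs))]
}

#' Cluster a 16S database into OTUs
#'
#' Computes all pairwise global alignment identities, links sequences at or
#' above `threshold`, and defines OTUs as connected components of that
#' identity graph. OTU ids are deterministic: components are numbered by their
#' lexicographically smallest member id.
#'
#' @param seqs Named character vector of 16S sequences (>= 1).
#' @param threshold Identity threshold in `[0, 1]` (default 0.97).
#' @return An `otu_set`: list with `membership` (data frame `seq_id`,
#'   `otu_id`), `threshold`, and `otus` (named list of member ids).
#' @export
cluster_otus <- function(seqs, threshold = 0.97) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  ids <- names(seqs)
  adj <- identity_matrix(seqs) >= threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  min_id <- vapply(split(ids, comp), min, "")
  ord <- rank(min_id)  # component -> otu rank by smallest member id
  otu_id <- sprintf("OTU_%03d", ord[comp])
  membership <- data.frame(seq_id = ids, otu_id = otu_id,
                           stringsAsFactors = FALSE)
  structure(list(membership = membership, threshold = threshold,
                 otus = split(ids, otu_id)),
            class = "otu_set")
}

.kmer_index <- function(seqs, k) {
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    L <- nchar(s)
    if (L < k) next
    km <- unique(substring(s, 1:(L - k + 1L), k:L))
    for (w in km) assign(w, c(idx[[w]], i), envir = idx)
  }
  idx
}

#' Classify read pairs against an OTU-clustered 16S database
#'
#' Each mate is matched against the database by semi-global alignment (the
#' read fully aligned, free end-gaps on the database sequence, both strands
#' tried) at `threshold` identity over the read-spanning columns. A pair is
#' assigned only when both mates have at least one hit and all hits of both
#' mates fall in one and the same OTU; pairs whose hits span several OTUs get
#' status `multi_otu`, pairs with a hitless mate `no_hit`.
#'
#' An exact shared-word prefilter (`prefilter_k`-mers, per strand) selects
#' candidate database sequences before alignment: a strand of a read is
#' aligned against a database sequence only when they share at least
#' `prefilter_min_words` words at distinct read positions. At the default
#' word length (12) and identity threshold (0.97 over reads of 100 bp or
#' more) the filter is lossless: a matching read has a guaranteed clean
#' stretch long enough to contain two exact words. Set `prefilter_k = 0` to
#' align every strand against every sequence.
#'
#' @param pairs Read-pair table (QC-passed).
#' @param seqs Named character vector: the 16S database.
#' @param otus An `otu_set` over `seqs` from [cluster_otus()].
#' @param threshold Identity threshold (default 0.97).
#' @param prefilter_k Word length of the candidate prefilter (default 12).
#' @param prefilter_min_words Shared words required per candidate (default 2).
#' @return Data frame `pair_id`, `status` (`assigned`/`multi_otu`/`no_hit`),
#'   `otu_id` (NA unless assigned).
#' @export
classify_pairs <- function(pairs, seqs, otus, threshold = 0.97,
                           prefilter_k = 12L, prefilter_min_words = 2L) {
  stopifnot(inherits(otus, "otu_set"))
  otu_of <- setNames(otus$membership$otu_id, otus$membership$seq_id)
  stopifnot(all(names(seqs) %in% names(otu_of)))
  idx <- if (prefilter_k > 0) .kmer_index(seqs, prefilter_k) else NULL
  seq_list <- unname(seqs)

  strand_candidates <- function(s) {
    if (is.null(idx)) return(seq_along(seq_list))
    L <- nchar(s)
    if (L < prefilter_k) return(integer(0))
    words <- substring(s, 1:(L - prefilter_k + 1L), prefilter_k:L)
    tallies <- table(unlist(lapply(words, function(w) unique(idx[[w]])),
                            use.names = FALSE))
    as.integer(names(tallies)[tallies >= prefilter_min_words])
  }

  hit_otus <- function(read, rc) {
    hit <- integer(0)
    for (s in c(read, rc)) {
      for (j in setdiff(strand_candidates(s), hit)) {
        if (cpp_align_overlap(s, seq_list[[j]], 1L, -1L, -2L,
                              "N")$identity >= threshold)
          hit <- c(hit, j)
      }
    }
    unique(otu_of[names(seqs)[hit]])
  }

  n <- nrow(pairs)
  rc1 <- .revcomp(pairs$seq1); rc2 <- .revcomp(pairs$seq2)
  status <- character(n); otu_id <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    o1 <- hit_otus(pairs$seq1[i], rc1[i])
    o2 <- hit_otus(pairs$seq2[i], rc2[i])
    if (length(o1) == 0L || length(o2) == 0L) {
      status[i] <- "no_hit"
    } else {
      u <- union(o1, o2)
      if (length(u) == 1L) {
        status[i] <- "assigned"; otu_id[i] <- u
      } else status[i] <- "multi_otu"
    }
  }
  data.frame(pair_id = pairs$pair_id, status = status, otu_id = otu_id,
             stringsAsFactors = FALSE)
}

#' Per-OTU count profiles and the shared-read fraction
#'
#' Builds the OTU-by-sample count table from classified pairs and computes the
#' fraction of reads mapping to the same OTUs in both samples: each sample's
#' counts are normalized to sum to one and the shared fraction is the sum over
#' OTUs of the smaller of the two normalized counts (min-overlap).
#'
#' @param classified1,classified2 Classification tables from
#'   [classify_pairs()] for the two samples (`classified2` may be NULL for a
#'   single-sample profile).
#' @return List with `counts` (matrix OTU x sample) and `shared_fraction`
#'   (NA for single-sample input).
#' @export
otu_profile <- function(classified1, classified2 = NULL) {
  count_of <- function(cl) {
    a <- cl[cl$status == "assigned", , drop = FALSE]
    table(a$otu_id)
  }
  t1 <- count_of(classified1)
  if (is.null(classified2)) {
    counts <- matrix(as.integer(t1), ncol = 1,
                     dimnames = list(names(t1), "sample1"))
    return(list(counts = counts, shared_fraction = NA_real_))
  }
  t2 <- count_of(classified2)
  all_otus <- sort(union(names(t1), names(t2)))
  counts <- cbind(sample1 = as.integer(t1[all_otus]),
                  sample2 = as.integer(t2[all_otus]))
  counts[is.na(counts)] <- 0L
  rownames(counts) <- all_otus
  list(counts = counts,
       shared_fraction = min_overlap(counts[, 1], counts[, 2]))
}

#' Min-overlap of two count profiles
#'
#' Normalizes both count vectors to sum to one and returns the sum of
#' elementwise minima — 1 for identical profiles, 0 for disjoint support.
#'
#' @param c1,c2 Non-negative count vectors over the same categories.
#' @return Shared fraction in `[0, 1]`.
#' @export
min_overlap <- function(c1, c2) {
  stopifnot(length(c1) == length(c2))
  if (sum(c1) == 0 || sum(c2) == 0) return(0)
  sum(pmin(c1 / sum(c1), c2 / sum(c2)))
}
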