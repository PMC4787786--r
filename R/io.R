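#' File formats
#'
#' Read pairs are held in a plain data frame with columns `pair_id`, `seq1`,
#' `qual1`, `seq2`, `qual2`; qualities are Phred+33 ASCII strings the same
#' length as their sequence. Reaction tables are data frames with list-columns
#' for metabolite and enzyme sets.
#'
#' @name formats
NULL

#' Convert a Phred+33 quality string to integer scores (and back)
#'
#' @param qual Character scalar (ASCII-encoded qualities).
#' @return Integer vector of Phred scores.
#' @export
phred_to_int <- function(qual) {
  if (nchar(qual) == 0L) return(integer(0))
  as.integer(charToRaw(qual)) - 33L
}

#' @rdname phred_to_int
#' @param q Integer vector of Phred scores in `[0, 60]`.
#' @return Character scalar.
#' @export
int_to_phred <- function(q) {
  if (length(q) == 0L) return("")
  stopifnot(all(q >= 0L & q <= 60L))
  rawToChar(as.raw(q + 33L))
}

#' Read a pair of FASTQ files into a read-pair table
#'
#' Files must list mates in the same order (standard paired FASTQ convention);
#' ids are taken from the first file with any `/1`, `/2` or space suffix
#' stripped.
#'
#' @param file1,file2 Paths to the forward and reverse FASTQ (Phred+33).
#' @return Data frame with columns `pair_id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(file1, file2) {
  r1 <- Biostrings::readDNAStringSet(file1, format = "fastq", with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(file2, format = "fastq", with.qualities = TRUE)
  if (length(r1) != length(r2))
    stop("FASTQ mate files have different numbers of records")
  ids <- sub("[/ ].*$", "", names(r1))
  data.frame(
    pair_id = ids,
    seq1 = as.character(r1),
    qual1 = as.character(S4Vectors::mcols(r1)$qualities),
    seq2 = as.character(r2),
    qual2 = as.character(S4Vectors::mcols(r2)$qualities),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write a read-pair table to two FASTQ files
#'
#' @param pairs Read-pair table (see [read_fastq_pairs()]).
#' @param file1,file2 Output paths.
#' @return Invisibly, the input table.
#' @export
write_fastq_pairs <- function(pairs, file1, file2) {
  .write_one <- function(seqs, quals, ids, suffix, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- paste0(ids, suffix)
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  .write_one(pairs$seq1, pairs$qual1, pairs$pair_id, "/1", file1)
  .write_one(pairs$seq2, pairs$qual2, pairs$pair_id, "/2", file2)
  invisible(pairs)
}

#' Read or write a reaction table
#'
#' The on-disk format is TSV with three columns: reaction id, comma-separated
#' metabolite ids, comma-separated enzyme sequence ids (possibly empty for
#' host reactions). In memory the table is a data frame with list-columns
#' `metabolites` and `enzymes`.
#'
#' @param path File path.
#' @return Data frame with columns `reaction_id`, `metabolites` (list),
#'   `enzymes` (list).
#' @export
read_reactions <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  stopifnot(all(c("reaction_id", "metabolites", "enzymes") %in% names(raw)))
  split_csv <- function(x) {
    out <- strsplit(x, ",", fixed = TRUE)
    lapply(out, function(v) v[nzchar(v)])
  }
  data.frame(
    reaction_id = raw$reaction_id,
    metabolites = I(split_csv(raw$metabolites)),
    enzymes = I(split_csv(raw$enzymes)),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_reactions
#' @param reactions In-memory reaction table.
#' @export
write_reactions <- function(reactions, path) {
  join <- function(col) vapply(col, paste, "", collapse = ",")
  out <- data.frame(reaction_id = reactions$reaction_id,
                    metabolites = join(reactions$metabolites),
                    enzymes = join(reactions$enzymes))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(reactions)
}

#' Read a per-metabolite taxon-count table
#'
#' TSV with columns `metabolite_id` and `taxon_count`.
#'
#' @param path File path.
#' @return Data frame with those two columns.
#' @export
read_metabolite_taxa <- function(path) {
  x <- read.delim(path, header = TRUE, sep = "\t")
  stopifnot(all(c("metabolite_id", "taxon_count") %in% names(x)))
  x$taxon_count <- as.integer(x$taxon_count)
  x
}
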