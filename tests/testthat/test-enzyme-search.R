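codon_of <- local({
  tab <- Biostrings::getGeneticCode()
  tab <- tab[!names(tab) %in% c("TAA", "TAG", "TGA")]
  function(aa) names(tab)[match(aa, tab)]
})

encode_protein <- function(aa) {
  paste(vapply(strsplit(aa, "")[[1]], codon_of, ""), collapse = "")
}

test_that("six-frame translation finds the planted ORF on both strands", {
  set.seed(1)
  prot <- random_seq(50, AA20_CHARS)
  read <- encode_protein(prot)   # 150 bp, stop-free in frame +1
  o <- six_frame_orfs(read, read)
  expect_true(o$qualifies)
  expect_true(prot %in% o$orfs1$aa_seq)
  expect_true("+1" %in% o$orfs1$frame[o$orfs1$aa_seq == prot])

  # the reverse complement recovers the same peptide in a negative frame
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(read)))
  orc <- six_frame_orfs(rc, rc)
  hit <- orc$orfs1[orc$orfs1$aa_seq == prot, ]
  expect_equal(nrow(hit), 1L)
  expect_true(startsWith(hit$frame, "-"))
})

test_that("reads too short for a 46-residue ORF disqualify the pair", {
  set.seed(2)
  short <- random_seq(120)  # at most 40 codons in any frame
  long <- encode_protein(random_seq(50, AA20_CHARS))
  o <- six_frame_orfs(short, long)
  expect_false(o$qualifies)
  expect_equal(nrow(o$orfs1), 0L)
  expect_gt(nrow(o$orfs2), 0L)
})

test_that("stop codons split translations below the ORF threshold", {
  set.seed(3)
  left <- random_seq(20, AA20_CHARS)
  right <- random_seq(25, AA20_CHARS)
  read <- paste0(encode_protein(left), "TAA", encode_protein(right))  # 138 bp
  o <- six_frame_orfs(read, read, min_len = 19)
  expect_true(right %in% o$orfs1$aa_seq)   # 25 > 19 qualifies
  expect_true(left %in% o$orfs1$aa_seq)    # 20 > 19 qualifies
  o45 <- six_frame_orfs(read, read, min_len = 45)
  expect_false(any(c(left, right) %in% o45$orfs1$aa_seq))
})

test_that("dereplication follows the greedy rule and keeps reaction ids", {
  set.seed(4)
  A <- random_seq(100, AA20_CHARS)
  B <- mutate_seq(A, 2, AA20_CHARS)   # 98% to A
  C <- mutate_seq(B, 2, AA20_CHARS)   # 98% to B, ~96% to A
  stopifnot(sw_align(A, C)$identity < 0.97)
  db <- enzyme_db(c(dbA = A, dbB = B, dbC = C),
                  list(dbA = "R1", dbB = "R2", dbC = "R3"))
  red <- dereplicate_db(db)
  expect_identical(sort(names(red$proteins)), c("dbA", "dbC"))
  expect_identical(sort(red$reaction_ids$dbA), c("R1", "R2"))
  expect_identical(red$reaction_ids$dbC, "R3")
  # the reaction-id union is preserved
  expect_setequal(unlist(red$reaction_ids, use.names = FALSE),
                  unlist(db$reaction_ids, use.names = FALSE))

  # identical duplicates collapse; 96% neighbours both survive
  dup <- enzyme_db(c(x = A, y = A), list(x = "R1", y = c("R2", "R9")))
  red2 <- dereplicate_db(dup)
  expect_equal(length(red2$proteins), 1L)
  expect_setequal(red2$reaction_ids[[1]], c("R1", "R2", "R9"))
  far <- enzyme_db(c(x = A, y = C), list(x = "R1", y = "R2"))
  expect_equal(length(dereplicate_db(far)$proteins), 2L)
})

test_that("the double-seed rule gates candidate alignment", {
  set.seed(5)
  target <- random_seq(60, AA20_CHARS)
  db <- enzyme_db(setNames(c(target, replicate(5, random_seq(60, AA20_CHARS))),
                           paste0("e", 1:6)),
                  setNames(as.list(paste0("R", 1:6)), paste0("e", 1:6)))

  # an exact 50-mer of the target: many shared seeds, perfect hit
  orf <- substr(target, 6, 55)
  hits <- seed_sw_search(orf, db)
  expect_true("e1" %in% hits$seq_id)
  expect_equal(hits$identity[hits$seq_id == "e1"], 1.0)
  expect_equal(hits$orf_coverage[hits$seq_id == "e1"], 1.0)

  # exactly one shared 7-mer: never aligned, no hit
  one_seed <- paste0(substr(target, 1, 7),
                     random_seq(43, setdiff(AA20_CHARS, "W")))
  shared <- intersect(substring(one_seed, 1:44, 7:50),
                      substring(target, 1:54, 7:60))
  stopifnot(length(shared) == 1)
  expect_equal(nrow(seed_sw_search(one_seed, db)), 0L)
})

test_that("reported hits always satisfy the 80/80 rule (oracle re-check)", {
  set.seed(6)
  db_seqs <- setNames(replicate(8, random_seq(70, AA20_CHARS)), paste0("e", 1:8))
  db <- enzyme_db(db_seqs, setNames(as.list(paste0("R", 1:8)), names(db_seqs)))
  queries <- c(
    substr(db_seqs[[1]], 1, 50),                       # perfect
    mutate_seq(substr(db_seqs[[2]], 1, 50), 5, AA20_CHARS),   # 90%
    mutate_seq(substr(db_seqs[[3]], 1, 50), 15, AA20_CHARS),  # 70%: reject
    random_seq(50, AA20_CHARS))
  for (q in queries) {
    hits <- seed_sw_search(q, db)
    for (k in seq_len(nrow(hits))) {
      o <- oracle_sw(q, db_seqs[[hits$seq_id[k]]])
      expect_gte(o$identity, 0.8)
      expect_gte((o$a_end - o$a_start + 1) / nchar(q), 0.8)
    }
  }
  # the 70%-identity query must not be reported against its source
  hits70 <- seed_sw_search(queries[3], db)
  expect_false("e3" %in% hits70$seq_id)
})

test_that("error-free in-frame reads always rediscover their source enzyme", {
  ref <- small_reference(seed = 30)
  db <- enzyme_db_from_reference(ref)
  idx_hits <- function(orf) seed_sw_search(orf, db)$seq_id
  set.seed(7)
  for (i in 1:15) {
    enz <- sample(names(ref$genes), 1)
    gene <- ref$genes[[enz]]
    start <- 3 * sample.int((nchar(gene) - 150) / 3, 1) + 1
    read <- substr(gene, start, start + 149)
    o <- six_frame_orfs(read, read)
    expect_true(o$qualifies)
    expect_true(enz %in% unlist(lapply(o$orfs1$aa_seq, idx_hits)))
  }
})

test_that("pair assignment implements the union/subset/disjoint logic", {
  db <- enzyme_db(
    setNames(replicate(4, random_seq(50, AA20_CHARS)), c("E1", "E2", "E3", "E4")),
    list(E1 = c("R1", "R2"), E2 = "R1", E3 = "R9", E4 = c("R1", "R9")))

  # nested reaction sets: union assigned
  r <- assign_pair(c("E1", "E2"), c("E1", "E2"), db)
  expect_equal(r$status, "assigned")
  expect_equal(r$reaction_ids, c("R1", "R2"))

  # disjoint reaction sets: discarded
  r2 <- assign_pair(c("E2", "E3"), c("E2", "E3"), db)
  expect_equal(r2$status, "discarded_disjoint")

  # partially overlapping, non-nested sets are ambiguous too
  r3 <- assign_pair(c("E1", "E4"), c("E1", "E4"), db)
  expect_equal(r3$status, "discarded_disjoint")

  # mates hitting different enzymes only: mate mismatch
  r4 <- assign_pair("E1", "E2", db)
  expect_equal(r4$status, "discarded_mate_mismatch")
  expect_equal(assign_pair(character(0), "E1", db)$status, "no_hit")

  # symmetric in mate order
  expect_identical(assign_pair(c("E1", "E2"), "E1", db),
                   assign_pair("E1", c("E1", "E2"), db))
})

test_that("end-to-end mapping recovers planted reaction labels", {
  ref <- small_reference(seed = 31)
  com <- generate_community(community_spec(6, "power_law", 1, 300, seed = 1),
                            ref)
  rd <- generate_reads(com, ref, readsim_spec(
    n_pairs = 60, read_length = 150, insert_mean = 300, base_error_rate = 0,
    rrna_fraction = 0, seed = 2))
  res <- map_enzyme_reads(rd$pairs, enzyme_db_from_reference(ref))
  expect_true(all(res$status == "assigned"))
  truth_rx <- ref$enzyme_reactions$reaction_id[
    match(rd$truth$gene_id, ref$enzyme_reactions$enzyme)]
  expect_equal(res$reaction_ids, truth_rx)
})
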