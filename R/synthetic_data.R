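#' Specification of a synthetic community
#'
#' @param n_taxa Number of taxa (ranks) in the community.
#' @param abundance_model `"power_law"` (rank frequency proportional to
#'   `i^-alpha`) or `"geometric"` (`q (1-q)^(i-1)`), renormalized over ranks
#'   `1..n_taxa`.
#' @param abundance_param Power-law exponent `alpha >= 0` or geometric
#'   parameter `q` in `(0, 1)`.
#' @param n_individuals Total individuals to draw (multinomial).
#' @param seed Integer seed.
#' @param taxa Optional character vector naming which reference taxa occupy
#'   ranks 1..n_taxa (defaults to the first `n_taxa` reference taxa).
#' @return Validated `community_spec` list.
#' @export
community_spec <- function(n_taxa, abundance_model = c("power_law", "geometric"),
                           abundance_param, n_individuals, seed, taxa = NULL) {
  abundance_model <- match.arg(abundance_model)
  stopifnot(n_taxa >= 1, n_individuals >= 1)
  if (abundance_model == "power_law" && abundance_param < 0)
    stop("power-law exponent must be >= 0")
  if (abundance_model == "geometric" &&
      (abundance_param <= 0 || abundance_param >= 1))
    stop("geometric parameter must be in (0, 1)")
  structure(list(n_taxa = as.integer(n_taxa), abundance_model = abundance_model,
                 abundance_param = abundance_param,
                 n_individuals = as.integer(n_individuals),
                 seed = as.integer(seed), taxa = taxa),
            class = "community_spec")
}

#' Specification of a synthetic reference (reactions, enzymes, 16S, host)
#'
#' The microbial reaction set is built in tiers that plant the layer structure
#' by construction: every tier-0 reaction carries one interface metabolite,
#' and each tier-k reaction shares a private linker metabolite with a tier-k-1
#' reaction, so a node's metabolic distance from the host interface equals its
#' tier. Hub metabolites are placed into exactly `hub_degree` reactions each,
#' making them currency candidates at the usual thresholds.
#'
#' @param n_taxa Number of taxa carried by the reference.
#' @param n_reactions Microbial reactions (split evenly across tiers).
#' @param n_metabolites Size of the private (non-hub, non-linker) metabolite
#'   pool; must be at least `n_reactions`.
#' @param n_hub_metabolites,hub_degree Hub ("currency-like") metabolites and
#'   the exact number of reactions each appears in.
#' @param enzymes_per_reaction Enzyme sequences annotated to each reaction.
#' @param protein_length Enzyme length in amino acids.
#' @param n_tiers Number of planted layers (default 4).
#' @param rrna_length 16S gene length in bp (default 1500).
#' @param taxa_per_otu Taxa per planted 16S cluster (default 2).
#' @param rrna_divergence Per-member substitution fraction from the cluster
#'   centroid (default 0.01; must be <= 0.03 so within-cluster identity stays
#'   at or above the 97% threshold).
#' @param genes_per_taxon Enzyme genes carried by each taxon.
#' @param layer_decay Relative weight `layer_decay^tier` used when sampling a
#'   taxon's genes; values below 1 plant enzyme content preferentially near
#'   the host interface (default 1 = uniform).
#' @param n_host_reactions Human-annotated host reactions (two host tiers).
#' @param n_host_only Host reactions absent from the human reconstruction.
#' @param ortholog_fraction Fraction of human enzyme genes with a 1:1 host
#'   ortholog (default 0.9).
#' @param frac_single_taxon Fraction of metabolites planted with a taxon count
#'   of 1 (excluded from edge formation downstream; default 0).
#' @param seed Integer seed.
#' @return Validated `reference_spec` list.
#' @export
reference_spec <- function(n_taxa = 12L, n_reactions = 60L,
                           n_metabolites = 80L, n_hub_metabolites = 2L,
                           hub_degree = 30L, enzymes_per_reaction = 1L,
                           protein_length = 120L, n_tiers = 4L,
                           rrna_length = 1500L, taxa_per_otu = 2L,
                           rrna_divergence = 0.01, genes_per_taxon = 25L,
                           layer_decay = 1, n_host_reactions = 24L,
                           n_host_only = 4L, ortholog_fraction = 0.9,
                           frac_single_taxon = 0, seed = 1L) {
  stopifnot(n_taxa >= 1, n_reactions >= n_tiers, n_tiers >= 1,
            n_hub_metabolites >= 0, enzymes_per_reaction >= 1,
            protein_length >= 1, taxa_per_otu >= 1, rrna_length >= 60,
            genes_per_taxon >= 1, layer_decay > 0,
            frac_single_taxon >= 0, frac_single_taxon <= 1)
  if (n_metabolites < n_reactions)
    stop("n_metabolites must be >= n_reactions (one private metabolite each)")
  if (n_hub_metabolites > n_metabolites)
    stop("n_hub_metabolites must be <= n_metabolites")
  if (hub_degree > n_reactions)
    stop("impossible hub structure: hub_degree exceeds the number of reactions")
  if (rrna_divergence > 0.03)
    stop(paste("impossible identity structure: rrna_divergence > 0.03 cannot",
               "guarantee >= 97% within-cluster identity"))
  if (genes_per_taxon > n_reactions * enzymes_per_reaction)
    stop("genes_per_taxon exceeds the number of enzymes in the reference")
  structure(as.list(environment()), class = "reference_spec")
}

#' Specification of a paired-read simulation
#'
#' @param n_pairs Read pairs to emit.
#' @param read_length Read length in bp (default 150).
#' @param insert_mean Insert size in bp; inserts are fixed at this length
#'   (default 303).
#' @param base_error_rate Per-base substitution probability in `[0, 1)`.
#' @param quality_high,quality_low Phred scores used for the planted
#'   high/low-quality pattern (defaults 40 and 10).
#' @param low_quality_fraction Fraction of pairs given a low-quality tail over
#'   the final `tail_fraction` of both mates.
#' @param tail_fraction Fraction of the read occupied by the low-quality tail
#'   (default 0.4, long enough that default QC drops the pair).
#' @param rrna_fraction Fraction of pairs drawn from the source taxon's 16S
#'   gene rather than one of its enzyme genes (default 0.5).
#' @param seed Integer seed.
#' @return Validated `readsim_spec` list.
#' @export
readsim_spec <- function(n_pairs, read_length = 150L, insert_mean = 303,
                         base_error_rate = 0.005, quality_high = 40L,
                         quality_low = 10L, low_quality_fraction = 0,
                         tail_fraction = 0.4, rrna_fraction = 0.5, seed = 1L) {
  stopifnot(n_pairs >= 1, read_length >= 1, read_length <= insert_mean,
            base_error_rate >= 0, base_error_rate < 1,
            quality_high >= 0, quality_high <= 60,
            quality_low >= 0, quality_low <= 60,
            low_quality_fraction >= 0, low_quality_fraction <= 1,
            rrna_fraction >= 0, rrna_fraction <= 1)
  structure(as.list(environment()), class = "readsim_spec")
}

DNA_BASES <- c("A", "C", "G", "T")

.random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

.codons_sense <- local({
  all <- as.vector(outer(as.vector(outer(DNA_BASES, DNA_BASES, paste0)),
                         DNA_BASES, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## scalar fast path (avoids per-call XStringSet overhead in tight loops)
.revcomp_one <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

.mutate_positions <- function(seq, pos) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Generate a synthetic reference
#'
#' Builds the full ground-truth reference a pipeline run needs: the microbial
#' reaction table (with tiered layer structure and hub metabolites), enzyme
#' protein and nucleotide gene sequences, a 16S database with planted cluster
#' structure, per-taxon gene content, per-metabolite taxon counts, and the
#' host side (human reactions + ortholog map + host-only reactions).
#' Deterministic given `spec$seed`.
#'
#' @param spec A [reference_spec()].
#' @return A `rumenet_reference` list; see Details in the package vignette.
#' @export
generate_reference <- function(spec) {
  stopifnot(inherits(spec, "reference_spec"))
  set.seed(spec$seed)
  iface <- interface_metabolites("vfa_aa")

  ## --- microbial reactions, tiered ---
  tier_sizes <- diff(floor(seq(0, spec$n_reactions, length.out = spec$n_tiers + 1)))
  tiers <- rep(seq_len(spec$n_tiers) - 1L, tier_sizes)
  rx_id <- sprintf("R%03d", seq_len(spec$n_reactions))
  private <- sprintf("m%03d", seq_len(spec$n_reactions))
  mets <- vector("list", spec$n_reactions)
  idx_by_tier <- split(seq_len(spec$n_reactions), tiers)
  for (j in seq_along(idx_by_tier[["0"]])) {
    i <- idx_by_tier[["0"]][j]
    mets[[i]] <- c(iface[((j - 1L) %% length(iface)) + 1L], private[i])
  }
  if (spec$n_tiers > 1) {
    for (k in seq_len(spec$n_tiers - 1L)) {
      prev <- idx_by_tier[[as.character(k - 1L)]]
      cur <- idx_by_tier[[as.character(k)]]
      for (j in seq_along(cur)) {
        i <- cur[j]
        target <- prev[((j - 1L) %% length(prev)) + 1L]
        linker <- sprintf("link%d_%03d", k, target)
        mets[[i]] <- c(private[i], linker)
        mets[[target]] <- unique(c(mets[[target]], linker))
      }
    }
  }
  if (spec$n_hub_metabolites > 0) {
    for (h in seq_len(spec$n_hub_metabolites)) {
      hub <- sprintf("hub%02d", h)
      in_rx <- sample(spec$n_reactions, spec$hub_degree)
      for (i in in_rx) mets[[i]] <- c(mets[[i]], hub)
    }
  }

  ## --- enzymes: nucleotide genes and their translations ---
  enz_ids <- as.vector(t(outer(rx_id, seq_len(spec$enzymes_per_reaction),
                               function(r, k) paste0("E_", r, "_", k))))
  enz_rx <- rep(rx_id, each = spec$enzymes_per_reaction)
  genes <- vapply(enz_ids, function(id) {
    paste(sample(.codons_sense, spec$protein_length, replace = TRUE),
          collapse = "")
  }, "")
  proteins <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(genes), no.init.codon = TRUE))
  names(proteins) <- enz_ids
  enzymes_by_rx <- split(enz_ids, enz_rx)[rx_id]
  reactions <- data.frame(reaction_id = rx_id, metabolites = I(mets),
                          enzymes = I(enzymes_by_rx), tier = tiers,
                          stringsAsFactors = FALSE)

  ## --- taxa, planted 16S clusters ---
  taxa <- sprintf("t%02d", seq_len(spec$n_taxa))
  n_otus <- ceiling(spec$n_taxa / spec$taxa_per_otu)
  cluster <- rep(seq_len(n_otus), each = spec$taxa_per_otu)[seq_len(spec$n_taxa)]
  centroids <- vapply(seq_len(n_otus), function(i) .random_dna(spec$rrna_length), "")
  n_mut <- max(1L, round(spec$rrna_divergence * spec$rrna_length))
  rrna <- character(spec$n_taxa)
  for (i in seq_len(spec$n_taxa)) {
    first_in_cluster <- match(cluster[i], cluster) == i
    rrna[i] <- if (first_in_cluster) centroids[cluster[i]] else
      .mutate_positions(centroids[cluster[i]],
                        sample(spec$rrna_length, n_mut))
  }
  names(rrna) <- paste0("16S_", taxa)
  otu_truth <- data.frame(seq_id = names(rrna), taxon = taxa,
                          cluster = cluster, stringsAsFactors = FALSE)

  ## --- per-taxon gene content, optionally biased towards the interface ---
  wt <- spec$layer_decay^tiers[match(enz_rx, rx_id)]
  gene_content <- lapply(taxa, function(t) {
    sort(sample(enz_ids, spec$genes_per_taxon, prob = wt))
  })
  names(gene_content) <- taxa

  ## --- metabolite taxon counts ---
  all_mets <- unique(unlist(mets))
  tc <- 2L + rpois(length(all_mets), 3)
  if (spec$frac_single_taxon > 0) {
    singles <- runif(length(all_mets)) < spec$frac_single_taxon
    singles[all_mets %in% iface] <- FALSE
    tc[singles] <- 1L
  }
  metabolite_taxa <- data.frame(metabolite_id = all_mets, taxon_count = tc,
                                stringsAsFactors = FALSE)

  ## --- host side: human reactions in two tiers, ortholog map, host-only ---
  h_id <- sprintf("H%03d", seq_len(spec$n_host_reactions))
  h_tier <- rep(0:1, length.out = spec$n_host_reactions)
  h_priv <- sprintf("hm%03d", seq_len(spec$n_host_reactions))
  h_mets <- vector("list", spec$n_host_reactions)
  h0 <- which(h_tier == 0L)
  for (j in seq_along(h0)) {
    i <- h0[j]
    h_mets[[i]] <- c(iface[((j - 1L) %% length(iface)) + 1L], h_priv[i])
  }
  h1 <- which(h_tier == 1L)
  for (j in seq_along(h1)) {
    i <- h1[j]
    target <- h0[((j - 1L) %% length(h0)) + 1L]
    linker <- sprintf("hlink_%03d", target)
    h_mets[[i]] <- c(h_priv[i], linker)
    h_mets[[target]] <- unique(c(h_mets[[target]], linker))
  }
  h_genes <- lapply(seq_along(h_id), function(i) sprintf("HG%03d", i))
  human_reactions <- data.frame(reaction_id = h_id, metabolites = I(h_mets),
                                genes = I(h_genes), stringsAsFactors = FALSE)
  mapped <- runif(length(h_id)) < spec$ortholog_fraction
  ortholog_map <- data.frame(
    human_gene = unlist(h_genes)[mapped],
    host_gene = sprintf("BG%03d", which(mapped)),
    stringsAsFactors = FALSE)
  b_id <- if (spec$n_host_only > 0) sprintf("B%03d", seq_len(spec$n_host_only)) else character(0)
  host_only <- data.frame(
    reaction_id = b_id,
    metabolites = I(lapply(seq_len(spec$n_host_only), function(i)
      sprintf("bm%03d_%d", i, 1:2))),
    stringsAsFactors = FALSE)

  structure(list(spec = spec, reactions = reactions, proteins = proteins,
                 genes = genes, rrna = rrna, taxa = taxa,
                 otu_truth = otu_truth, gene_content = gene_content,
                 metabolite_taxa = metabolite_taxa,
                 enzyme_reactions = data.frame(enzyme = enz_ids,
                                               reaction_id = enz_rx,
                                               stringsAsFactors = FALSE),
                 human_reactions = human_reactions,
                 ortholog_map = ortholog_map, host_only = host_only),
            class = "rumenet_reference")
}

#' Expected rank frequencies under a rank-abundance model
#'
#' @param model `"power_law"` or `"geometric"`.
#' @param param Exponent `alpha` or success probability `q`.
#' @param n_ranks Number of ranks the distribution is truncated to.
#' @return Probability vector over ranks `1..n_ranks` summing to 1.
#' @export
rank_probabilities <- function(model, param, n_ranks) {
  i <- seq_len(n_ranks)
  w <- switch(model,
    power_law = {
      if (param < 0) stop("power-law exponent must be >= 0")
      i^(-param)
    },
    geometric = {
      if (param <= 0 || param >= 1) stop("geometric parameter must be in (0, 1)")
      param * (1 - param)^(i - 1)
    },
    stop("unknown model: ", model))
  w / sum(w)
}

#' Draw a community from a rank-abundance model
#'
#' @param spec A [community_spec()].
#' @param reference A `rumenet_reference` (supplies taxon ids).
#' @return Data frame with columns `taxon`, `rank`, `count`; counts sum to
#'   `spec$n_individuals`.
#' @export
generate_community <- function(spec, reference) {
  stopifnot(inherits(spec, "community_spec"),
            inherits(reference, "rumenet_reference"))
  taxa <- if (is.null(spec$taxa)) reference$taxa else spec$taxa
  if (spec$n_taxa > length(taxa))
    stop("n_taxa exceeds the taxa available in the reference")
  if (!all(taxa %in% reference$taxa))
    stop("community taxa must come from the reference")
  taxa <- taxa[seq_len(spec$n_taxa)]
  p <- rank_probabilities(spec$abundance_model, spec$abundance_param, spec$n_taxa)
  set.seed(spec$seed)
  counts <- as.integer(rmultinom(1, spec$n_individuals, p))
  data.frame(taxon = taxa, rank = seq_len(spec$n_taxa), count = counts,
             stringsAsFactors = FALSE)
}

.add_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  hit <- which(runif(n) < rate)
  if (length(hit) == 0L) return(seq)
  .mutate_positions(seq, hit)
}

#' Simulate paired-end reads from a community
#'
#' Each pair is drawn from one individual: a source taxon is sampled in
#' proportion to community counts, then the pair comes from the taxon's 16S
#' gene (probability `spec$rrna_fraction`) or one of its enzyme genes. The
#' forward read is the 5' end of a fixed-length insert and the reverse read is
#' the reverse complement of its 3' end. Substitution errors are applied at
#' `base_error_rate` and a planted fraction of pairs receives a low-quality
#' tail. Truth labels (source taxon, gene, insert start) are returned as a
#' sidecar table.
#'
#' @param community Output of [generate_community()].
#' @param reference The `rumenet_reference` the community was drawn from.
#' @param spec A [readsim_spec()].
#' @return List with `pairs` (read-pair table), `truth` (sidecar data frame)
#'   and `n_skipped` (pairs skipped because the source gene was shorter than
#'   the insert).
#' @export
generate_reads <- function(community, reference, spec) {
  stopifnot(inherits(spec, "readsim_spec"),
            inherits(reference, "rumenet_reference"))
  set.seed(spec$seed)
  insert <- as.integer(round(spec$insert_mean))
  rl <- spec$read_length
  taxon_p <- community$count / sum(community$count)
  src_taxon <- sample(community$taxon, spec$n_pairs, replace = TRUE,
                      prob = taxon_p)
  use_rrna <- runif(spec$n_pairs) < spec$rrna_fraction
  n_low_tail <- 0L
  rows <- vector("list", spec$n_pairs)
  truth <- vector("list", spec$n_pairs)
  n_skipped <- 0L
  skipped_genes <- character(0)
  for (i in seq_len(spec$n_pairs)) {
    taxon <- src_taxon[i]
    if (use_rrna[i]) {
      gene_id <- paste0("16S_", taxon)
      gene <- reference$rrna[[gene_id]]
      source <- "rrna"
    } else {
      gene_id <- sample(reference$gene_content[[taxon]], 1L)
      gene <- reference$genes[[gene_id]]
      source <- "enzyme"
    }
    if (nchar(gene) < insert) {
      n_skipped <- n_skipped + 1L
      skipped_genes <- c(skipped_genes, gene_id)
      next
    }
    start <- sample.int(nchar(gene) - insert + 1L, 1L)
    frag <- substr(gene, start, start + insert - 1L)
    fwd <- .add_errors(substr(frag, 1L, rl), spec$base_error_rate)
    rev <- .add_errors(.revcomp_one(substr(frag, insert - rl + 1L, insert)),
                       spec$base_error_rate)
    q <- rep(spec$quality_high, rl)
    if (runif(1) < spec$low_quality_fraction) {
      tail_start <- floor(rl * (1 - spec$tail_fraction)) + 1L
      q[tail_start:rl] <- spec$quality_low
      n_low_tail <- n_low_tail + 1L
    }
    qual <- int_to_phred(q)
    pid <- sprintf("pair%06d", i)
    rows[[i]] <- data.frame(pair_id = pid, seq1 = fwd, qual1 = qual,
                            seq2 = rev, qual2 = qual, stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(pair_id = pid, taxon = taxon, gene_id = gene_id,
                             source = source, start = start,
                             stringsAsFactors = FALSE)
  }
  empty_pairs <- data.frame(pair_id = character(0), seq1 = character(0),
                            qual1 = character(0), seq2 = character(0),
                            qual2 = character(0))
  empty_truth <- data.frame(pair_id = character(0), taxon = character(0),
                            gene_id = character(0), source = character(0),
                            start = integer(0))
  if (n_skipped > 0)
    warning(sprintf("%d pair(s) skipped: source gene shorter than insert (%s)",
                    n_skipped,
                    paste(unique(skipped_genes), collapse = ", ")),
            call. = FALSE)
  rows <- rows[!vapply(rows, is.null, TRUE)]
  truth <- truth[!vapply(truth, is.null, TRUE)]
  list(pairs = if (length(rows)) do.call(rbind, rows) else empty_pairs,
       truth = if (length(truth)) do.call(rbind, truth) else empty_truth,
       n_skipped = n_skipped)
}

#' Simulate two taxonomically disjoint but metabolically identical samples
#'
#' Builds a reference carrying `2 * n_taxa_per_sample` taxa, each its own OTU,
#' in which taxon `n + i` carries exactly the same enzyme genes as taxon `i`.
#' Sample 1 is drawn from the first half of the taxa and sample 2 from the
#' second half, so the two communities share no OTUs while drawing reads from
#' an identical enzyme pool — the construction behind the "different taxonomy,
#' similar metabolism" contrast.
#'
#' @param n_taxa_per_sample Taxa per sample.
#' @param n_pairs Read pairs per sample.
#' @param alpha Power-law exponent of both communities.
#' @param seed Integer seed.
#' @param ref_args Extra arguments passed to [reference_spec()].
#' @param read_args Extra arguments passed to [readsim_spec()].
#' @return List with `reference`, `community1`, `community2`, `reads1`,
#'   `reads2`.
#' @export
divergent_pair_experiment <- function(n_taxa_per_sample = 10L, n_pairs = 2000L,
                                      alpha = 1, seed = 1L,
                                      ref_args = list(), read_args = list()) {
  n2 <- 2L * n_taxa_per_sample
  rs <- do.call(reference_spec, utils::modifyList(
    list(n_taxa = n2, taxa_per_otu = 1L, seed = seed), ref_args))
  ref <- generate_reference(rs)
  for (i in seq_len(n_taxa_per_sample))
    ref$gene_content[[n_taxa_per_sample + i]] <- ref$gene_content[[i]]
  com1 <- generate_community(
    community_spec(n_taxa_per_sample, "power_law", alpha, n_pairs,
                   seed = seed + 1L, taxa = ref$taxa[seq_len(n_taxa_per_sample)]),
    ref)
  com2 <- generate_community(
    community_spec(n_taxa_per_sample, "power_law", alpha, n_pairs,
                   seed = seed + 2L,
                   taxa = ref$taxa[(n_taxa_per_sample + 1L):n2]),
    ref)
  reads1 <- generate_reads(com1, ref, do.call(readsim_spec, utils::modifyList(
    list(n_pairs = n_pairs, seed = seed + 3L), read_args)))
  reads2 <- generate_reads(com2, ref, do.call(readsim_spec, utils::modifyList(
    list(n_pairs = n_pairs, seed = seed + 4L), read_args)))
  list(reference = ref, community1 = com1, community2 = com2,
       reads1 = reads1, reads2 = reads2)
}

#' Simulate per-node mapped read counts with planted layer structure
#'
#' Draws node-level read counts for two samples directly from a reference's
#' ground truth, bypassing read simulation and alignment: each reaction node's
#' sampling weight is proportional to its number of annotated enzymes times
#' `occupancy_decay^tier`, so occupancy and depth decline with the planted
#' layer. Sample 2 re-weights each node by `2^delta` with
#' `delta ~ N(0, sd = layer_sigma0 + layer_sigma_slope * tier)`, planting
#' between-sample variability that grows with distance from the interface.
#'
#' @param reference A `rumenet_reference` with a tiered reaction table.
#' @param n_pairs1,n_pairs2 Mapped pairs per sample.
#' @param occupancy_decay Multiplicative weight per tier (default 1).
#' @param weight_sd Log-normal dispersion (sdlog) of per-node sampling
#'   weights, emulating the heavy-tailed read-per-reaction distribution of
#'   real metagenomes (default 0 = equal weights within a tier).
#' @param layer_sigma0 Between-sample log2 dispersion at tier 0 (default 0).
#' @param layer_sigma_slope Added log2 dispersion per tier (default 0).
#' @param layer_sigma_cap Tier at which the dispersion gradient saturates
#'   (default `Inf`: no saturation); the planted dispersion is
#'   `layer_sigma0 + layer_sigma_slope * min(tier, layer_sigma_cap)`.
#' @param seed Integer seed.
#' @return Data frame `node_id`, `c1`, `c2`, `tier` — node ids follow
#'   [merge_identical_reactions()] applied to the reference reactions.
#' @export
simulate_node_counts <- function(reference, n_pairs1, n_pairs2,
                                 occupancy_decay = 1, weight_sd = 0,
                                 layer_sigma0 = 0, layer_sigma_slope = 0,
                                 layer_sigma_cap = Inf, seed = 1L) {
  nodes <- merge_identical_reactions(reference$reactions)
  tier <- reference$reactions$tier[match(
    vapply(nodes$reaction_ids, `[`, "", 1), reference$reactions$reaction_id)]
  set.seed(seed)
  w <- lengths(nodes$enzymes) * occupancy_decay^tier *
    stats::rlnorm(length(tier), 0, weight_sd)
  c1 <- as.integer(rmultinom(1, n_pairs1, w))
  delta <- stats::rnorm(length(w), 0, layer_sigma0 +
                          layer_sigma_slope * pmin(tier, layer_sigma_cap))
  c2 <- as.integer(rmultinom(1, n_pairs2, w * 2^delta))
  data.frame(node_id = nodes$node_id, c1 = c1, c2 = c2, tier = tier,
             stringsAsFactors = FALSE)
}

#' Write a synthetic reference to disk in the pipeline's exchange formats
#'
#' Emits `proteins.faa`, `reactions.tsv`, `metabolite_taxa.tsv`, `rrna.fna`,
#' `human_reactions.tsv`, `ortholog_map.tsv`, `host_reactions.tsv` and the
#' `truth_*.tsv` sidecars into `dir`.
#'
#' @param reference A `rumenet_reference`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  aa <- Biostrings::AAStringSet(reference$proteins)
  Biostrings::writeXStringSet(aa, p("proteins.faa"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference$rrna), p("rrna.fna"))
  write_reactions(reference$reactions, p("reactions.tsv"))
  write.table(reference$metabolite_taxa, p("metabolite_taxa.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  hr <- reference$human_reactions
  write.table(data.frame(reaction_id = hr$reaction_id,
                         metabolites = vapply(hr$metabolites, paste, "", collapse = ","),
                         genes = vapply(hr$genes, paste, "", collapse = ",")),
              p("human_reactions.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(reference$ortholog_map, p("ortholog_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ho <- reference$host_only
  write.table(data.frame(reaction_id = ho$reaction_id,
                         metabolites = vapply(ho$metabolites, paste, "", collapse = ",")),
              p("host_reactions.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(reference$otu_truth, p("truth_otus.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  gc_tab <- data.frame(
    taxon = rep(names(reference$gene_content),
                lengths(reference$gene_content)),
    enzyme = unlist(reference$gene_content, use.names = FALSE))
  write.table(gc_tab, p("truth_gene_content.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list.files(dir, full.names = TRUE))
}
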