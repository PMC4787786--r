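#' Default pipeline configuration
#'
#' Thresholds default to the pipeline's canonical values: 97% OTU identity,
#' ORFs longer than 45 residues, double 7-residue seeds, the 80/80 acceptance
#' rule, 97/97 dereplication, currency threshold 25 (allowed: 25, 50, 100),
#' interface set `vfa_aa`, 1000 randomization replicates.
#'
#' @param ... Named overrides, merged recursively into the defaults.
#' @return Configuration list.
#' @export
pipeline_config <- function(...) {
  base <- list(
    out_dir = tempfile("rumenet_run_"),
    seed = 1L,
    simulate = NULL,   # list(reference=, community1=, community2=, reads=)
    inputs = NULL,     # list(fastq1_1=, fastq1_2=, fastq2_1=, fastq2_2=, reference_dir=)
    qc = list(run_len = 3L, q_min = 15L, min_len = 100L, min_avg_q = 20),
    prepare_db = FALSE,
    otu = list(identity = 0.97, prefilter_k = 12L),
    abundance = list(model = "power_law", n_reps = 1000L),
    enzyme = list(min_orf = 45L, seed_len = 7L, min_seeds = 2L,
                  min_identity = 0.8, min_coverage = 0.8,
                  dereplicate = TRUE, derep_identity = 0.97,
                  derep_coverage = 0.97),
    network = list(currency = 25L, interface = "vfa_aa", min_taxa = 2L,
                   allow_custom_currency = FALSE),
    stats = list(n_reps = 1000L, cutoff = 0.01, min_layer_nodes = 10L)
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1]]))
    overrides <- overrides[[1]]
  cfg <- utils::modifyList(base, overrides)
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' @param cfg Configuration list (see [pipeline_config()]).
#' @return The validated configuration, invisibly usable.
#' @export
validate_config <- function(cfg) {
  if (!cfg$network$allow_custom_currency &&
      !(cfg$network$currency %in% c(25L, 50L, 100L)))
    stop("currency threshold must be 25, 50 or 100 (or set allow_custom_currency)")
  if (!(cfg$network$interface %in% c("vfa", "vfa_aa", "vfa_aa_hum")))
    stop("interface must be one of vfa, vfa_aa, vfa_aa_hum")
  stopifnot(cfg$otu$identity > 0, cfg$otu$identity <= 1,
            cfg$enzyme$min_identity > 0, cfg$enzyme$min_identity <= 1,
            cfg$enzyme$min_coverage > 0, cfg$enzyme$min_coverage <= 1,
            cfg$stats$n_reps >= 1)
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stop("configuration must provide either simulate or inputs")
  cfg
}

#' Read a reference directory written by [write_reference()]
#'
#' @param dir Directory holding `proteins.faa`, `reactions.tsv`,
#'   `metabolite_taxa.tsv`, `rrna.fna`, `human_reactions.tsv`,
#'   `ortholog_map.tsv`, `host_reactions.tsv`.
#' @return A `rumenet_reference`-compatible list (without simulation truth).
#' @export
read_reference_dir <- function(dir) {
  p <- function(f) file.path(dir, f)
  proteins <- as.character(Biostrings::readAAStringSet(p("proteins.faa")))
  rrna <- as.character(Biostrings::readDNAStringSet(p("rrna.fna")))
  reactions <- read_reactions(p("reactions.tsv"))
  hr_raw <- read.delim(p("human_reactions.tsv"), colClasses = "character")
  split_csv <- function(x) lapply(strsplit(x, ",", fixed = TRUE),
                                  function(v) v[nzchar(v)])
  human_reactions <- data.frame(
    reaction_id = hr_raw$reaction_id,
    metabolites = I(split_csv(hr_raw$metabolites)),
    genes = I(split_csv(hr_raw$genes)), stringsAsFactors = FALSE)
  ho_raw <- read.delim(p("host_reactions.tsv"), colClasses = "character")
  host_only <- data.frame(
    reaction_id = ho_raw$reaction_id,
    metabolites = I(split_csv(ho_raw$metabolites)), stringsAsFactors = FALSE)
  structure(list(
    reactions = reactions, proteins = proteins, rrna = rrna,
    metabolite_taxa = read_metabolite_taxa(p("metabolite_taxa.tsv")),
    human_reactions = human_reactions,
    ortholog_map = read.delim(p("ortholog_map.tsv"), colClasses = "character"),
    host_only = host_only), class = "rumenet_reference")
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order — simulate (optional), quality
#' control, OTU clustering/classification/profiling, rank-abundance fits and
#' the common-vs-separate test, enzyme mapping, network construction,
#' layering, and the community statistics — writing every stage's outputs
#' plus a manifest into `cfg$out_dir`. Re-running an identical configuration
#' reproduces identical statistics.
#'
#' @param cfg Configuration from [pipeline_config()] or a path to a YAML file
#'   with the same structure.
#' @return Invisible list with every stage's in-memory results (`reference`,
#'   `qc`, `otus`, `classified`, `otu_profile`, `abundance`, `assignments`,
#'   `network`, `layers`, `stats`, `manifest`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  cfg <- pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  stages <- character(0)

  ## --- stage: inputs / simulation ---
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    ref_spec <- do.call(reference_spec,
                        utils::modifyList(list(seed = cfg$seed), sim$reference))
    reference <- generate_reference(ref_spec)
    com1 <- generate_community(do.call(community_spec,
      utils::modifyList(list(seed = cfg$seed + 1L), sim$community1)), reference)
    com2 <- generate_community(do.call(community_spec,
      utils::modifyList(list(seed = cfg$seed + 2L), sim$community2)), reference)
    rd1 <- generate_reads(com1, reference, do.call(readsim_spec,
      utils::modifyList(list(seed = cfg$seed + 3L), sim$reads)))
    rd2 <- generate_reads(com2, reference, do.call(readsim_spec,
      utils::modifyList(list(seed = cfg$seed + 4L), sim$reads)))
    write_reference(reference, out("reference"))
    write_fastq_pairs(rd1$pairs, out("sample1_R1.fastq"), out("sample1_R2.fastq"))
    write_fastq_pairs(rd2$pairs, out("sample2_R1.fastq"), out("sample2_R2.fastq"))
    raw1 <- rd1$pairs; raw2 <- rd2$pairs
    stages <- c(stages, "simulate")
  } else {
    reference <- read_reference_dir(cfg$inputs$reference_dir)
    raw1 <- read_fastq_pairs(cfg$inputs$fastq1_1, cfg$inputs$fastq1_2)
    raw2 <- read_fastq_pairs(cfg$inputs$fastq2_1, cfg$inputs$fastq2_2)
    stages <- c(stages, "load_inputs")
  }

  ## --- stage: quality control ---
  qc1 <- qc_pairs(raw1, cfg$qc$run_len, cfg$qc$q_min, cfg$qc$min_len,
                  cfg$qc$min_avg_q)
  qc2 <- qc_pairs(raw2, cfg$qc$run_len, cfg$qc$q_min, cfg$qc$min_len,
                  cfg$qc$min_avg_q)
  jsonlite::write_json(list(sample1 = qc1$summary, sample2 = qc2$summary),
                       out("qc_summary.json"), auto_unbox = TRUE)
  stages <- c(stages, "qc")

  ## --- stage: OTU clustering and classification ---
  db <- reference$rrna
  if (isTRUE(cfg$prepare_db)) db <- prepare_db(db)
  otus <- cluster_otus(db, cfg$otu$identity)
  write.table(otus$membership, out("otu_membership.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cl1 <- classify_pairs(qc1$pairs, db, otus, cfg$otu$identity,
                        cfg$otu$prefilter_k)
  cl2 <- classify_pairs(qc2$pairs, db, otus, cfg$otu$identity,
                        cfg$otu$prefilter_k)
  prof <- otu_profile(cl1, cl2)
  write.table(cbind(otu_id = rownames(prof$counts), as.data.frame(prof$counts)),
              out("otu_counts.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  stages <- c(stages, "otu")

  ## --- stage: rank-abundance models ---
  ra1 <- .ra_counts(prof$counts[, 1]); ra2 <- .ra_counts(prof$counts[, 2])
  abund <- list(
    sample1 = if (length(ra1) >= 2) compare_models(ra1) else NULL,
    sample2 = if (length(ra2) >= 2) compare_models(ra2) else NULL,
    test = if (length(ra1) >= 1 && length(ra2) >= 1 && sum(prof$counts) > 0)
      common_vs_separate_test(prof$counts, cfg$abundance$model,
                              cfg$abundance$n_reps, cfg$seed + 10L) else NULL)
  stages <- c(stages, "abundance")

  ## --- stage: enzyme mapping ---
  edb <- enzyme_db_from_reference(reference)
  if (isTRUE(cfg$enzyme$dereplicate))
    edb <- dereplicate_db(edb, cfg$enzyme$derep_identity,
                          cfg$enzyme$derep_coverage, cfg$enzyme$seed_len,
                          cfg$enzyme$min_seeds)
  as1 <- map_enzyme_reads(qc1$pairs, edb, cfg$enzyme$min_orf,
                          cfg$enzyme$seed_len, cfg$enzyme$min_seeds,
                          cfg$enzyme$min_identity, cfg$enzyme$min_coverage)
  as2 <- map_enzyme_reads(qc2$pairs, edb, cfg$enzyme$min_orf,
                          cfg$enzyme$seed_len, cfg$enzyme$min_seeds,
                          cfg$enzyme$min_identity, cfg$enzyme$min_coverage)
  write.table(as1, out("assignments_sample1.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(as2, out("assignments_sample2.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  stages <- c(stages, "map_enzymes")

  ## --- stage: network construction ---
  nodes <- merge_identical_reactions(reference$reactions)
  currency <- find_currency(reference$reactions, cfg$network$currency)
  retained <- filter_metabolites(reference$reactions, reference$metabolite_taxa,
                                 cfg$network$min_taxa)
  mg <- build_network(nodes, currency, retained)
  host_nodes <- build_host_network(reference$human_reactions,
                                   reference$ortholog_map, reference$host_only)
  hg <- build_network(host_nodes, currency, NULL)
  iface <- interface_metabolites(cfg$network$interface)
  merged <- interface_edges(hg, mg, iface)
  write_network(merged, out("merged_network.graphml"), out("merged_edges.tsv"))
  stages <- c(stages, "net_build")

  ## --- stage: layers ---
  layers <- assign_layers(merged)
  write.table(layers, out("layers.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  stages <- c(stages, "net_layers")

  ## --- stage: statistics ---
  counts <- tally_counts(as1, as2, merged)
  node_overlap <- min_overlap(counts$c1, counts$c2)
  ls <- layer_sizes(layers, min_nodes = cfg$stats$min_layer_nodes)
  lstats <- if (length(ls$usable) > 0)
    layer_statistics(counts, layers, cfg$stats$min_layer_nodes) else NULL
  lcorr <- if (length(ls$usable) >= 3)
    layer_correlation_test(counts, layers, cfg$stats$min_layer_nodes,
                           cfg$stats$n_reps, cfg$seed + 20L) else NULL
  diff <- binomial_diff(counts)
  write.table(diff, out("node_diff.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  contrast <- layer_variability_contrast(counts, layers, cfg$stats$cutoff,
                                         n_reps = cfg$stats$n_reps,
                                         seed = cfg$seed + 21L)
  curve <- divergence_curve(counts, n_reps = cfg$stats$n_reps,
                            seed = cfg$seed + 22L)
  write.table(curve, out("divergence_curve.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  mtests <- metabolite_tests(counts, merged, cfg$stats$n_reps, cfg$seed + 23L)
  bias <- reference_bias_correlations(counts, merged, diff)
  stats <- list(
    otu_shared_fraction = prof$shared_fraction,
    node_shared_fraction = node_overlap,
    n_otus = nrow(prof$counts),
    n_nodes = igraph::vcount(merged),
    n_occupied_nodes = sum(counts$c1 + counts$c2 > 0),
    abundance = list(
      better_model1 = if (!is.null(abund$sample1)) abund$sample1$better,
      better_model2 = if (!is.null(abund$sample2)) abund$sample2$better,
      delta_lnl = if (!is.null(abund$test)) abund$test$delta_lnl,
      p_common_vs_separate = if (!is.null(abund$test)) abund$test$p_value),
    layer_correlation = if (!is.null(lcorr))
      lcorr[c("corr_p", "p_value_p", "corr_r", "p_value_r")],
    contrast = contrast,
    metabolites = mtests,
    bias = bias)
  jsonlite::write_json(stats, out("stats.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  stages <- c(stages, "stats")

  ## --- manifest ---
  files <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, out("manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("rumenet")),
    seed = cfg$seed, stages = stages,
    files = as.list(setNames(unname(tools::md5sum(files)),
                             substring(files, nchar(cfg$out_dir) + 2L))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)
  invisible(list(reference = reference, qc = list(qc1, qc2), otus = otus,
                 classified = list(cl1, cl2), otu_profile = prof,
                 abundance = abund, assignments = list(as1, as2),
                 network = merged, layers = layers,
                 counts = counts, stats = stats, manifest = manifest))
}
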