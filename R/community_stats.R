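.microbial_vertices <- function(network) {
  side <- igraph::vertex_attr(network, "side")
  if (is.null(side)) seq_len(igraph::vcount(network)) else which(side == "microbial")
}

#' Tally mapped read pairs onto network nodes
#'
#' A pair assigned to k reactions increments each distinct corresponding node
#' once (no fractional weights). Assignments referencing reactions absent
#' from the network are an error.
#'
#' @param assignments1,assignments2 Assignment tables from
#'   [map_enzyme_reads()] for the two samples.
#' @param network igraph whose vertices carry semicolon-joined `reaction_ids`
#'   (microbial vertices are used when a `side` attribute is present).
#' @return Data frame `node_id`, `c1`, `c2` covering every microbial node;
#'   totals are the column sums.
#' @export
tally_counts <- function(assignments1, assignments2, network) {
  mi <- .microbial_vertices(network)
  node_id <- igraph::vertex_attr(network, "name")[mi]
  rx_lists <- strsplit(igraph::vertex_attr(network, "reaction_ids")[mi],
                       ";", fixed = TRUE)
  rx2node <- setNames(rep(seq_along(mi), lengths(rx_lists)),
                      unlist(rx_lists, use.names = FALSE))
  one <- function(assignments) {
    counts <- integer(length(mi))
    a <- assignments[assignments$status == "assigned", , drop = FALSE]
    for (rxs in strsplit(a$reaction_ids, ";", fixed = TRUE)) {
      nodes <- rx2node[rxs]
      if (anyNA(nodes))
        stop("assignment references unknown reaction id(s): ",
             paste(rxs[is.na(nodes)], collapse = ", "))
      for (v in unique(nodes)) counts[v] <- counts[v] + 1L
    }
    counts
  }
  data.frame(node_id = node_id, c1 = one(assignments1),
             c2 = one(assignments2), stringsAsFactors = FALSE)
}

.layer_of <- function(counts, layers) {
  layers$d[match(counts$node_id, layers$node_id)]
}

#' Per-layer occupancy and depth statistics
#'
#' For each usable layer: `p`, the proportion of the layer's nodes with at
#' least one mapped read pair, and `r`, the mean number of reads per occupied
#' node (NA for layers with no occupied node). Computed on pooled counts
#' (`c1 + c2`).
#'
#' @param counts Node-count table from [tally_counts()].
#' @param layers Layer assignment from [assign_layers()].
#' @param min_nodes Usable-layer size cutoff (default 10).
#' @return Data frame `d`, `n_nodes`, `p`, `r` over usable layers.
#' @export
layer_statistics <- function(counts, layers, min_nodes = 10L) {
  usable <- layer_sizes(layers, min_nodes = min_nodes)$usable
  d <- .layer_of(counts, layers)
  total <- counts$c1 + counts$c2
  rows <- lapply(usable, function(k) {
    in_layer <- !is.na(d) & d == k
    occ <- in_layer & total >= 1L
    data.frame(d = k, n_nodes = sum(in_layer), p = mean(total[in_layer] >= 1L),
               r = if (any(occ)) mean(total[occ]) else NA_real_)
  })
  do.call(rbind, rows)
}

## Pearson correlation that returns NA (without a warning) on constant input.
.cor_or_na <- function(x, y) {
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(NA_real_)
  cor(x, y)
}

.corr_p_r <- function(total, d, usable) {
  p <- vapply(usable, function(k) mean(total[d == k] >= 1L), 0)
  r <- vapply(usable, function(k) {
    occ <- d == k & total >= 1L
    if (any(occ)) mean(total[occ]) else NA_real_
  }, 0)
  list(p = p, r = r)
}

#' Correlation of occupancy and read depth with layer distance
#'
#' Pearson correlations, over usable layers, of the occupancy proportion `p`
#' and the occupied-node mean read count `r` against layer distance `d`, with
#' one-sided randomization p-values (how often a null correlation is as small
#' or smaller). The null for `p` shuffles per-node read counts across all
#' microbial nodes, occupied or not; the null for `r` shuffles counts only
#' within the set of occupied nodes.
#'
#' @inheritParams layer_statistics
#' @param n_reps Randomizations (default 1000).
#' @param seed Integer seed.
#' @return List: `corr_p`, `p_value_p`, `corr_r`, `p_value_r`, `usable`.
#' @export
layer_correlation_test <- function(counts, layers, min_nodes = 10L,
                                   n_reps = 1000L, seed = 1L) {
  usable <- layer_sizes(layers, min_nodes = min_nodes)$usable
  if (length(usable) < 3L)
    stop("fewer than 3 usable layers; layer correlations are not defined")
  d <- .layer_of(counts, layers)
  keep <- !is.na(d) & d %in% usable
  d <- d[keep]
  total <- (counts$c1 + counts$c2)[keep]
  obs <- .corr_p_r(total, d, usable)
  corr_p <- .cor_or_na(obs$p, usable)
  ok_r <- !is.na(obs$r)
  corr_r <- if (sum(ok_r) >= 3) .cor_or_na(obs$r[ok_r], usable[ok_r]) else NA_real_
  set.seed(seed)
  occ_idx <- which(total >= 1L)
  null_p <- numeric(n_reps); null_r <- numeric(n_reps)
  for (b in seq_len(n_reps)) {
    tp <- sample(total)
    sp <- .corr_p_r(tp, d, usable)
    null_p[b] <- .cor_or_na(sp$p, usable)
    tr <- total
    tr[occ_idx] <- total[sample(occ_idx)]
    sr <- .corr_p_r(tr, d, usable)
    okb <- !is.na(sr$r)
    null_r[b] <- if (sum(okb) >= 3) .cor_or_na(sr$r[okb], usable[okb]) else NA_real_
  }
  p_value_p <- if (is.na(corr_p)) NA_real_ else
    (1 + sum(null_p <= corr_p, na.rm = TRUE)) / (1 + n_reps)
  p_value_r <- if (is.na(corr_r)) NA_real_ else
    (1 + sum(null_r <= corr_r, na.rm = TRUE)) / (1 + n_reps)
  list(corr_p = corr_p, p_value_p = p_value_p,
       corr_r = corr_r, p_value_r = p_value_r, usable = usable)
}

.binom_two_sided <- function(c1, tot, p1) {
  lo <- pbinom(c1, tot, p1)
  hi <- pbinom(c1 - 1L, tot, p1, lower.tail = FALSE)
  pmin(1, 2 * pmin(lo, hi))
}

.log2_ratio <- function(c1, c2, n1, n2, pseudocount = 0.5) {
  a1 <- ifelse(c1 == 0 & c2 > 0, pseudocount, c1)
  a2 <- ifelse(c2 == 0 & c1 > 0, pseudocount, c2)
  log2((a1 / n1) / (a2 / n2))
}

#' Exact binomial test of differential node abundance
#'
#' For each node with at least one mapped read, tests whether sample 1's count
#' is compatible with the overall proportion `p1 = n1 / (n1 + n2)` under an
#' exact binomial model (two-sided by tail doubling). The log2 abundance
#' ratio uses per-sample normalized counts; a node with exactly one zero
#' count gets a 0.5 pseudocount on the zero side, and nodes with no reads at
#' all are excluded.
#'
#' @param counts Node-count table from [tally_counts()].
#' @param cutoffs Significance cutoffs for the flag columns
#'   (default 0.05, 0.01, 0.001, 1e-4).
#' @param pseudocount Zero-side pseudocount (default 0.5).
#' @return Data frame `node_id`, `c1`, `c2`, `p_value`, `log2_ratio` and one
#'   logical `sig_<cutoff>` column per cutoff.
#' @export
binomial_diff <- function(counts, cutoffs = c(0.05, 0.01, 0.001, 1e-4),
                          pseudocount = 0.5) {
  n1 <- sum(counts$c1); n2 <- sum(counts$c2)
  if (n1 + n2 == 0) stop("no mapped reads")
  keep <- counts$c1 + counts$c2 > 0
  x <- counts[keep, , drop = FALSE]
  p1 <- n1 / (n1 + n2)
  out <- data.frame(
    node_id = x$node_id, c1 = x$c1, c2 = x$c2,
    p_value = .binom_two_sided(x$c1, x$c1 + x$c2, p1),
    log2_ratio = .log2_ratio(x$c1, x$c2, n1, n2, pseudocount),
    stringsAsFactors = FALSE)
  for (ct in cutoffs)
    out[[paste0("sig_", format(ct, scientific = FALSE))]] <- out$p_value <= ct
  out
}

#' Layer contrast of between-sample variability
#'
#' Among nodes significantly different between the samples at `cutoff`,
#' contrasts the mean absolute log2 abundance ratio of layer 0 against layer
#' k (k = 1, 2): `delta_0k = mean|log2 ratio| (layer 0) - mean|log2 ratio|
#' (layer k)`, so negative values mean the interface layer is the less
#' variable one. The null shuffles per-node count pairs across all microbial
#' nodes, including empty ones; the one-sided p-value asks how often the null
#' contrast is as negative as observed (add-one estimator).
#'
#' @param counts Node-count table.
#' @param layers Layer assignment from [assign_layers()].
#' @param cutoff Binomial significance cutoff (default 0.01).
#' @param compare_to Layers to contrast with layer 0 (default `c(1, 2)`).
#' @param n_reps Randomizations (default 1000).
#' @param seed Integer seed.
#' @param signed Use signed rather than absolute log2 ratios (default FALSE).
#' @return Data frame `layer`, `delta`, `p_value` (NA when a compared layer
#'   has no significant nodes).
#' @export
layer_variability_contrast <- function(counts, layers, cutoff = 0.01,
                                       compare_to = c(1L, 2L),
                                       n_reps = 1000L, seed = 1L,
                                       signed = FALSE) {
  d <- .layer_of(counts, layers)
  n1 <- sum(counts$c1); n2 <- sum(counts$c2)
  p1 <- n1 / (n1 + n2)
  stat_for <- function(c1, c2) {
    tot <- c1 + c2
    pv <- rep(NA_real_, length(c1))
    nz <- tot > 0
    pv[nz] <- .binom_two_sided(c1[nz], tot[nz], p1)
    lr <- .log2_ratio(c1, c2, n1, n2)
    v <- if (signed) lr else abs(lr)
    sig <- nz & pv <= cutoff
    vapply(compare_to, function(k) {
      in0 <- sig & !is.na(d) & d == 0L
      ink <- sig & !is.na(d) & d == k
      if (!any(in0) || !any(ink)) return(NA_real_)
      mean(v[in0]) - mean(v[ink])
    }, 0)
  }
  obs <- stat_for(counts$c1, counts$c2)
  set.seed(seed)
  null <- matrix(NA_real_, n_reps, length(compare_to))
  for (b in seq_len(n_reps)) {
    perm <- sample(nrow(counts))
    null[b, ] <- stat_for(counts$c1[perm], counts$c2[perm])
  }
  p <- vapply(seq_along(compare_to), function(j) {
    if (is.na(obs[j])) return(NA_real_)
    (1 + sum(null[, j] <= obs[j], na.rm = TRUE)) / (1 + n_reps)
  }, 0)
  data.frame(layer = compare_to, delta = obs, p_value = p)
}

## Multivariate hypergeometric split of pooled per-node totals: reassigns each
## mapped pair to sample 1 or 2 uniformly without replacement, preserving n1.
.reassign_hyper <- function(totals, n1) {
  c1 <- integer(length(totals))
  left <- n1
  remaining <- sum(totals)
  for (i in seq_along(totals)) {
    remaining <- remaining - totals[i]
    c1[i] <- rhyper(1, totals[i], remaining, left)
    left <- left - c1[i]
  }
  c1
}

#' Divergence curve of between-sample abundance differences
#'
#' The observed curve counts, for each threshold x, the nodes whose absolute
#' log2 normalized abundance ratio is at least x. Null curves reassign the
#' pooled mapped pairs to the two samples (without replacement, preserving
#' both totals, or independently per pair with `reassignment = "binomial"`)
#' and recount. Per-threshold one-sided add-one p-values ask how often a null
#' curve reaches the observed count.
#'
#' @param counts Node-count table.
#' @param thresholds Positive ascending thresholds (default 0.25..4 in steps
#'   of 0.25).
#' @param n_reps Null reassignments (default 1000).
#' @param seed Integer seed.
#' @param reassignment `"without_replacement"` (default) or `"binomial"`.
#' @return Data frame `threshold`, `observed`, `null_min`, `null_mean`,
#'   `null_max`, `p_value`.
#' @export
divergence_curve <- function(counts, thresholds = seq(0.25, 4, by = 0.25),
                             n_reps = 1000L, seed = 1L,
                             reassignment = c("without_replacement", "binomial")) {
  reassignment <- match.arg(reassignment)
  stopifnot(all(thresholds > 0), !is.unsorted(thresholds))
  n1 <- sum(counts$c1); n2 <- sum(counts$c2)
  totals <- counts$c1 + counts$c2
  curve_of <- function(c1, c2) {
    keep <- c1 + c2 > 0
    v <- abs(.log2_ratio(c1[keep], c2[keep], n1, n2))
    vapply(thresholds, function(x) sum(v >= x), 0L)
  }
  obs <- curve_of(counts$c1, counts$c2)
  set.seed(seed)
  null <- matrix(0L, n_reps, length(thresholds))
  p1 <- n1 / (n1 + n2)
  for (b in seq_len(n_reps)) {
    c1b <- if (reassignment == "without_replacement")
      .reassign_hyper(totals, n1) else rbinom(length(totals), totals, p1)
    null[b, ] <- curve_of(c1b, totals - c1b)
  }
  data.frame(threshold = thresholds, observed = obs,
             null_min = apply(null, 2, min),
             null_mean = colMeans(null),
             null_max = apply(null, 2, max),
             p_value = vapply(seq_along(thresholds), function(j)
               (1 + sum(null[, j] >= obs[j])) / (1 + n_reps), 0))
}

#' Permutation tests on the inferred metabolite profile
#'
#' Two one-sided tests (add-one p-values): `p_presence` asks whether the
#' occupied nodes touch fewer distinct metabolites than the same number of
#' nodes drawn uniformly at random; `p_profile` asks whether the summed
#' per-metabolite net difference in normalized read count between the
#' samples, `S = sum_m |sum_{nodes using m} (c1/n1 - c2/n2)|`, is smaller
#' than when the per-node count pairs are shuffled across occupied nodes.
#'
#' @param counts Node-count table.
#' @param network igraph whose vertices carry semicolon-joined `metabolites`.
#' @param n_reps Randomizations (default 1000).
#' @param seed Integer seed.
#' @return List: `n_metabolites_observed`, `p_presence`, `s_observed`,
#'   `p_profile`.
#' @export
metabolite_tests <- function(counts, network, n_reps = 1000L, seed = 1L) {
  mi <- .microbial_vertices(network)
  node_names <- igraph::vertex_attr(network, "name")[mi]
  mets <- strsplit(igraph::vertex_attr(network, "metabolites")[mi],
                   ";", fixed = TRUE)
  mets <- mets[match(counts$node_id, node_names)]
  occupied <- which(counts$c1 + counts$c2 > 0)
  if (length(occupied) == 0L) stop("no occupied nodes")
  n1 <- sum(counts$c1); n2 <- sum(counts$c2)

  n_obs <- length(unique(unlist(mets[occupied], use.names = FALSE)))
  diff_norm <- counts$c1 / n1 - counts$c2 / n2
  s_of <- function(dn) {
    met_ids <- unlist(mets[occupied], use.names = FALSE)
    per_node <- rep(dn[occupied], lengths(mets[occupied]))
    sums <- tapply(per_node, met_ids, sum)
    sum(abs(sums))
  }
  s_obs <- s_of(diff_norm)
  set.seed(seed)
  null_n <- integer(n_reps); null_s <- numeric(n_reps)
  for (b in seq_len(n_reps)) {
    pick <- sample(nrow(counts), length(occupied))
    null_n[b] <- length(unique(unlist(mets[pick], use.names = FALSE)))
    dn <- diff_norm
    dn[occupied] <- diff_norm[sample(occupied)]
    null_s[b] <- s_of(dn)
  }
  list(n_metabolites_observed = n_obs,
       p_presence = (1 + sum(null_n <= n_obs)) / (1 + n_reps),
       s_observed = s_obs,
       p_profile = (1 + sum(null_s <= s_obs)) / (1 + n_reps))
}

#' First-order partial correlation
#'
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`.
#'
#' @param x,y,z Numeric vectors of equal length.
#' @return Partial Pearson correlation of x and y controlling for z.
#' @export
partial_correlation <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

#' Reference-bias correlations of mapped reads with database size and degree
#'
#' Over occupied nodes: Pearson and Spearman correlations of pooled mapped
#' reads with (i) the number of database sequences annotated to the node and
#' (ii) the node's degree, plus the Pearson partial correlation of degree
#' with the binomial p-value of differential abundance, controlling for the
#' number of mapped reads.
#'
#' @param counts Node-count table.
#' @param network igraph (degree and enzyme annotations are read from it).
#' @param diff Output of [binomial_diff()] (computed when NULL).
#' @return List of correlation estimates; entries are NA when undefined
#'   (constant inputs or fewer than 3 occupied nodes).
#' @export
reference_bias_correlations <- function(counts, network, diff = NULL) {
  mi <- .microbial_vertices(network)
  node_names <- igraph::vertex_attr(network, "name")[mi]
  enz <- strsplit(igraph::vertex_attr(network, "enzymes")[mi], ";", fixed = TRUE)
  n_seqs <- lengths(lapply(enz, function(e) e[nzchar(e)]))
  deg <- igraph::degree(network)[mi]
  ord <- match(counts$node_id, node_names)
  n_seqs <- n_seqs[ord]; deg <- deg[ord]
  reads <- counts$c1 + counts$c2
  occ <- reads > 0
  if (sum(occ) < 3) stop("fewer than 3 occupied nodes")
  safe_cor <- function(x, y, method = "pearson") {
    if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
    cor(x, y, method = method)
  }
  if (is.null(diff)) diff <- binomial_diff(counts)
  pv <- diff$p_value[match(counts$node_id[occ], diff$node_id)]
  list(
    reads_vs_nseqs_pearson = safe_cor(reads[occ], n_seqs[occ]),
    reads_vs_nseqs_spearman = safe_cor(reads[occ], n_seqs[occ], "spearman"),
    reads_vs_degree_pearson = safe_cor(reads[occ], deg[occ]),
    reads_vs_degree_spearman = safe_cor(reads[occ], deg[occ], "spearman"),
    degree_vs_pvalue_partial = if (length(unique(deg[occ])) < 2 ||
                                   length(unique(pv)) < 2) NA_real_ else
      partial_correlation(deg[occ], pv, reads[occ]))
}

#' Over-representation of a reaction subset among mapped reads
#'
#' Ratio of the subset's share of mapped read pairs to its share of database
#' sequences: `(reads_subset / reads_total) / (db_subset / db_total)`. Values
#' above 1 mean reads hit the subset more often than its database
#' representation predicts.
#'
#' @param reads_subset,reads_total Mapped read pairs in the subset and overall.
#' @param db_subset,db_total Database sequences in the subset and overall.
#' @return The over-representation ratio.
#' @export
overrepresentation_ratio <- function(reads_subset, reads_total,
                                     db_subset, db_total) {
  stopifnot(reads_total > 0, db_total > 0, db_subset > 0)
  (reads_subset / reads_total) / (db_subset / db_total)
}
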