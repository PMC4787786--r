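mk_network <- function(reaction_sets, metabolites = NULL) {
  n <- length(reaction_sets)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = sprintf("N%02d", seq_len(n)))
  g <- igraph::set_vertex_attr(g, "reaction_ids",
                               value = vapply(reaction_sets, paste, "",
                                              collapse = ";"))
  if (!is.null(metabolites))
    g <- igraph::set_vertex_attr(g, "metabolites",
                                 value = vapply(metabolites, paste, "",
                                                collapse = ";"))
  g
}

assign_tab <- function(...) {
  rx <- list(...)
  data.frame(pair_id = sprintf("p%d", seq_along(rx)),
             status = ifelse(lengths(rx) > 0, "assigned", "no_hit"),
             reaction_ids = vapply(rx, paste, "", collapse = ";"))
}

test_that("tallying increments every assigned node once per pair", {
  net <- mk_network(list("R1", "R2", c("R3", "R3b")))
  a1 <- assign_tab(c("R1", "R2"), "R1", character(0))
  a2 <- assign_tab(c("R3", "R3b"))   # two reactions, same node: +1 only
  counts <- tally_counts(a1, a2, net)
  expect_equal(counts$c1, c(2L, 1L, 0L))
  expect_equal(counts$c2, c(0L, 0L, 1L))
  expect_equal(sum(counts$c1), 3L)

  empty <- assign_tab()
  z <- tally_counts(empty, empty, net)
  expect_true(all(z$c1 == 0L & z$c2 == 0L))
  expect_error(tally_counts(assign_tab("R99"), empty, net), "unknown reaction")
})

test_that("layer occupancy and depth statistics match hand computations", {
  layers <- data.frame(node_id = sprintf("n%02d", 1:40), side = "microbial",
                       d = rep(0:1, each = 20))
  counts <- data.frame(node_id = layers$node_id,
                       c1 = c(rep(3L, 10), rep(0L, 10), rep(5L, 5), rep(0L, 15)),
                       c2 = 0L)
  st <- layer_statistics(counts, layers)
  expect_equal(st$p, c(0.5, 0.25))
  expect_equal(st$r, c(3, 5))

  # a fully unoccupied layer has p = 0 and undefined r
  counts2 <- counts; counts2$c1[21:40] <- 0L
  st2 <- layer_statistics(counts2, layers)
  expect_equal(st2$p[2], 0)
  expect_true(is.na(st2$r[2]))
})

test_that("perfectly linear occupancy decay gives correlation -1", {
  layers <- data.frame(node_id = sprintf("n%03d", 1:40), side = "microbial",
                       d = rep(0:3, each = 10))
  occ_per_layer <- c(8, 6, 4, 2)
  c1 <- unlist(lapply(occ_per_layer, function(k) c(rep(2L, k), rep(0L, 10 - k))))
  counts <- data.frame(node_id = layers$node_id, c1 = c1, c2 = 0L)
  res <- layer_correlation_test(counts, layers, n_reps = 49, seed = 1)
  expect_equal(res$corr_p, -1)
  expect_lte(res$p_value_p, 0.05)
  expect_error(
    layer_correlation_test(counts, layers[layers$d < 2, ], n_reps = 9),
    "fewer than 3 usable layers")
})

test_that("the exact binomial test matches closed-form tail probabilities", {
  counts <- data.frame(node_id = c("a", "b", "c", "d"),
                       c1 = c(5L, 10L, 0L, 85L),
                       c2 = c(5L, 0L, 10L, 85L))
  d <- binomial_diff(counts)
  expect_equal(d$p_value[d$node_id == "a"], 1)
  # (10, 0) with equal totals: two-sided p = 2 * 0.5^10
  expect_equal(d$p_value[d$node_id == "b"], 2 * 0.5^10)
  expect_true(d$sig_0.01[d$node_id == "b"])
  expect_false(d$`sig_0.0001`[d$node_id == "b"])
  # flag monotonicity across all nodes and cutoffs
  expect_true(all(!d$`sig_0.0001` | d$sig_0.001))
  expect_true(all(!d$sig_0.001 | d$sig_0.01))
  expect_true(all(!d$sig_0.01 | d$sig_0.05))
  # zero-side pseudocount keeps the ratio finite
  expect_true(is.finite(d$log2_ratio[d$node_id == "b"]))
  expect_equal(d$log2_ratio[d$node_id == "b"],
               log2((10 / sum(counts$c1)) / (0.5 / sum(counts$c2))))
})

test_that("the layer contrast reproduces planted arithmetic and sign", {
  layers <- data.frame(node_id = sprintf("n%03d", 1:30), side = "microbial",
                       d = rep(0:2, each = 10))
  # layer 0: balanced (|log2| = 0); layer 1: fourfold both ways (|log2| = 2);
  # per-sample totals stay equal so normalization drops out
  counts <- data.frame(
    node_id = layers$node_id,
    c1 = c(rep(40L, 10), rep(c(80L, 20L), 5), rep(40L, 10)),
    c2 = c(rep(40L, 10), rep(c(20L, 80L), 5), rep(40L, 10)))
  res <- layer_variability_contrast(counts, layers, cutoff = 1,
                                    n_reps = 99, seed = 2)
  expect_equal(res$delta[res$layer == 1], -2)
  expect_equal(res$delta[res$layer == 2], 0)
  expect_lte(res$p_value[res$layer == 1], 0.05)
  # a compared layer without significant nodes is flagged undefined
  res2 <- layer_variability_contrast(counts, layers, cutoff = 1e-12,
                                     n_reps = 9, seed = 2)
  expect_true(is.na(res2$delta[res2$layer == 2]))
})

test_that("divergence curves count nodes beyond each |log2| threshold", {
  counts <- data.frame(node_id = c("a", "b", "c"),
                       c1 = c(8L, 5L, 7L), c2 = c(2L, 5L, 7L))
  n1 <- sum(counts$c1); n2 <- sum(counts$c2)
  curve <- divergence_curve(counts, thresholds = c(0.5, 1.9, 2.1),
                            n_reps = 19, seed = 3)
  v_a <- abs(log2((8 / n1) / (2 / n2)))
  expect_equal(curve$observed, c(sum(abs(log2(c(8/n1/(2/n2), 5/n1/(5/n2),
                                                7/n1/(7/n2)))) >= 0.5),
                                 as.integer(v_a >= 1.9), as.integer(v_a >= 2.1)))
  expect_true(all(curve$null_min <= curve$null_mean &
                  curve$null_mean <= curve$null_max))
  # identical normalized profiles give a flat zero curve
  flat <- data.frame(node_id = c("a", "b"), c1 = c(10L, 30L), c2 = c(5L, 15L))
  curve2 <- divergence_curve(flat, thresholds = c(0.5, 1), n_reps = 9, seed = 1)
  expect_equal(curve2$observed, c(0L, 0L))
  # equal totals, node (8,2): |log2 ratio| = 2 exactly
  eq <- data.frame(node_id = c("a", "b"), c1 = c(8L, 2L), c2 = c(2L, 8L))
  curve3 <- divergence_curve(eq, thresholds = c(1, 2, 2.5), n_reps = 9, seed = 1)
  expect_equal(curve3$observed, c(2L, 2L, 0L))
})

test_that("metabolite-profile statistics hit their analytic floor", {
  net <- mk_network(as.list(sprintf("R%d", 1:6)),
                    metabolites = list(c("m1", "m2"), "m1", "m3",
                                       c("m2", "m3"), "m4", "m5"))
  counts <- data.frame(node_id = sprintf("N%02d", 1:6),
                       c1 = c(4L, 2L, 2L, 0L, 0L, 0L),
                       c2 = c(8L, 4L, 4L, 0L, 0L, 0L))
  mt <- metabolite_tests(counts, net, n_reps = 49, seed = 4)
  expect_equal(mt$n_metabolites_observed, 3L)   # m1, m2, m3
  # identical normalized profiles: S = 0, the smallest possible value
  expect_equal(mt$s_observed, 0)
  expect_true(mt$p_presence > 0 && mt$p_presence <= 1)
  expect_true(mt$p_profile > 0 && mt$p_profile <= 1)
})

test_that("occupancy concentrated on few metabolites is detected", {
  set.seed(5)
  mets <- c(lapply(1:10, function(i) c("hubm", sprintf("s%d", i))),
            lapply(11:40, function(i) sprintf(c("q%d", "r%d"), i)))
  net <- mk_network(as.list(sprintf("R%d", 1:40)), metabolites = mets)
  counts <- data.frame(node_id = sprintf("N%02d", 1:40),
                       c1 = c(rep(5L, 10), rep(0L, 30)),
                       c2 = c(rep(4L, 10), rep(0L, 30)))
  mt <- metabolite_tests(counts, net, n_reps = 199, seed = 6)
  expect_lte(mt$p_presence, 0.05)
})

test_that("partial correlation matches the residual-regression oracle", {
  set.seed(7)
  for (i in 1:5) {
    z <- rnorm(20); x <- 0.7 * z + rnorm(20); y <- -0.4 * z + rnorm(20)
    rx <- resid(lm(x ~ z)); ry <- resid(lm(y ~ z))
    expect_equal(partial_correlation(x, y, z), cor(rx, ry), tolerance = 1e-12)
  }
  # orthogonal control variable collapses to the plain correlation
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 8)
  expect_equal(partial_correlation(x, y, z = c(1, -1, -1, 1)), cor(x, y))
  expect_equal(cor(x, y), 1)
})

test_that("reference-bias correlations behave on planted structure", {
  ref <- small_reference(enzymes_per_reaction = 2L)
  nodes <- merge_identical_reactions(ref$reactions)
  g <- build_network(nodes, find_currency(ref$reactions, 5),
                     filter_metabolites(ref$reactions, ref$metabolite_taxa))
  set.seed(8)
  counts <- data.frame(node_id = nodes$node_id,
                       c1 = rpois(nrow(nodes), 4),
                       c2 = rpois(nrow(nodes), 4))
  bias <- reference_bias_correlations(counts, g)
  expect_true(is.na(bias$reads_vs_nseqs_pearson))  # all nodes have 2 sequences
  expect_true(abs(bias$reads_vs_degree_pearson) <= 1 ||
              is.na(bias$reads_vs_degree_pearson))
  # perfect linear dependence when reads are proportional to degree
  counts2 <- data.frame(node_id = nodes$node_id,
                        c1 = igraph::degree(g) * 2L, c2 = igraph::degree(g))
  bias2 <- reference_bias_correlations(counts2, g)
  expect_equal(bias2$reads_vs_degree_pearson, 1)
})

test_that("the headline over-representation ratio is computed, not stored", {
  expect_equal(overrepresentation_ratio(10, 100, 10, 100), 1)
  expect_equal(overrepresentation_ratio(20, 100, 5, 100), 4)
  expect_error(overrepresentation_ratio(1, 0, 1, 10))
})
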