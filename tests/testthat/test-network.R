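rxn_table <- function(...) {
  mets <- list(...)
  data.frame(reaction_id = sprintf("R%d", seq_along(mets)),
             metabolites = I(mets),
             enzymes = I(lapply(seq_along(mets), function(i)
               sprintf("E%d", i))),
             stringsAsFactors = FALSE)
}

test_that("identical metabolite sets merge into one node, others stay apart", {
  rx <- rxn_table(c("a", "b", "c"), c("c", "b", "a"), c("a", "b"))
  nodes <- merge_identical_reactions(rx)
  expect_equal(nrow(nodes), 2L)
  expect_setequal(nodes$reaction_ids[[1]], c("R1", "R2"))
  expect_setequal(nodes$enzymes[[1]], c("E1", "E2"))
  # merging is idempotent
  again <- merge_identical_reactions(
    data.frame(reaction_id = nodes$node_id, metabolites = nodes$metabolites,
               enzymes = nodes$enzymes))
  expect_equal(nrow(again), nrow(nodes))
  expect_equal(again$metabolites, nodes$metabolites, ignore_attr = TRUE)

  bad <- rxn_table(character(0))
  expect_error(merge_identical_reactions(bad), "empty metabolite")
})

test_that("currency detection is strict and monotone in the threshold", {
  mets <- c(lapply(1:26, function(i) c("w", sprintf("u%d", i))),
            lapply(1:25, function(i) c("atp", sprintf("v%d", i))))
  rx <- do.call(rxn_table, mets)
  expect_identical(find_currency(rx, 25), "w")     # 26 > 25; atp at exactly 25 is not
  expect_identical(find_currency(rx, 24), c("atp", "w"))
  expect_length(find_currency(rx, 100), 0)
  ref <- small_reference()
  for (th in list(c(5, 9), c(9, 25), c(25, 100)))
    expect_true(all(find_currency(ref$reactions, th[2]) %in%
                    find_currency(ref$reactions, th[1])))
})

test_that("the two-taxa rule filters edge metabolites", {
  rx <- rxn_table(c("a", "b"), c("b", "c"))
  taxa <- data.frame(metabolite_id = c("a", "b", "c"), taxon_count = c(2, 1, 5))
  expect_setequal(filter_metabolites(rx, taxa), c("a", "c"))
  expect_warning(
    kept <- filter_metabolites(rx, taxa[1:2, ]),
    "lack taxon counts")
  expect_identical(kept, "a")
  all2 <- data.frame(metabolite_id = c("a", "b", "c"), taxon_count = c(3, 2, 2))
  expect_setequal(filter_metabolites(rx, all2), c("a", "b", "c"))
})

test_that("edges require a shared, retained, non-currency metabolite", {
  rx <- rxn_table(c("a", "b"), c("b", "c"), c("w", "d"), c("w", "e"))
  nodes <- merge_identical_reactions(rx)
  g <- build_network(nodes, currency = "w", retained = c("a", "b", "c", "d", "e"))
  expect_equal(igraph::ecount(g), 1L)   # only the b-sharing pair
  expect_true(igraph::are_adjacent(g, "MN0001", "MN0002"))
  # nodes sharing only currency "w" stay unlinked
  expect_false(igraph::are_adjacent(g, "MN0003", "MN0004"))
  # dropping the currency threshold to nothing adds that edge back
  g2 <- build_network(nodes, currency = character(0),
                      retained = c("a", "b", "c", "d", "e", "w"))
  expect_true(igraph::are_adjacent(g2, "MN0003", "MN0004"))
  expect_true(all(igraph::ecount(g2) >= igraph::ecount(g)))
})

test_that("host assembly keeps ortholog-backed, host-only and pseudo nodes", {
  human <- data.frame(
    reaction_id = c("H1", "H2", "H3"),
    metabolites = I(list(c("a", "b"), c("c", "d"), c("e", "f"))),
    genes = I(list("G1", "G2", "G3")))
  orth <- data.frame(human_gene = c("G1", "G2"), host_gene = c("B1", "B2"))
  host_only <- data.frame(reaction_id = "B9",
                          metabolites = I(list(c("x", "y"))))
  nodes <- build_host_network(human, orth, host_only)
  expect_equal(nrow(nodes), 4L)   # H1 + H2 + B9 + pseudo (H3 unmapped)
  expect_equal(sum(nodes$origin == "host_pseudo"), 1L)
  expect_true(any(vapply(nodes$metabolites, function(m)
    setequal(m, c("butyrate", "butyryl-CoA")), TRUE)))

  # an empty ortholog map leaves host-only reactions plus the pseudo-node
  none <- build_host_network(human, orth[0, ], host_only)
  expect_equal(nrow(none), 2L)
  expect_equal(sum(none$origin == "host_pseudo"), 1L)
})

test_that("interface sets are nested with the documented sizes", {
  vfa <- interface_metabolites("vfa")
  vfa_aa <- interface_metabolites("vfa_aa")
  hum <- interface_metabolites("vfa_aa_hum")
  expect_length(vfa, 3)
  expect_length(vfa_aa, 23)
  expect_true(all(vfa %in% vfa_aa))
  expect_true(all(vfa_aa %in% hum))
  expect_gt(length(hum), length(vfa_aa))
})

test_that("interface edges cross sub-networks, even for currency metabolites", {
  host_nodes <- build_host_network(
    data.frame(reaction_id = "H1",
               metabolites = I(list(c("glutamate", "hm1"))),
               genes = I(list("G1"))),
    data.frame(human_gene = "G1", host_gene = "B1"),
    data.frame(reaction_id = character(0), metabolites = I(list())))
  rx <- rxn_table(c("glutamate", "m1"), c("m1", "m2"), c("butyrate", "m3"))
  micro_nodes <- merge_identical_reactions(rx)
  # glutamate declared currency: no within-side edges through it, but the
  # host-microbe interface edge must still appear
  hg <- build_network(host_nodes, currency = "glutamate")
  mg <- build_network(micro_nodes, currency = "glutamate")
  merged <- interface_edges(hg, mg, interface_metabolites("vfa_aa"))
  iface <- as.logical(igraph::edge_attr(merged, "interface"))
  el <- igraph::as_edgelist(merged)
  expect_true(any(iface & el[, 1] == "HN0001" & el[, 2] == "MN0001"))
  # butyrate-using microbial node links to the pseudo-node under set VFA
  merged_vfa <- interface_edges(hg, mg, interface_metabolites("vfa"))
  el2 <- igraph::as_edgelist(merged_vfa)
  i2 <- as.logical(igraph::edge_attr(merged_vfa, "interface"))
  expect_true(any(i2 & el2[, 1] == "HN_pseudo_butyrate" & el2[, 2] == "MN0003"))
})

test_that("networks survive a GraphML round-trip", {
  ref <- small_reference()
  nodes <- merge_identical_reactions(ref$reactions)
  g <- build_network(nodes, find_currency(ref$reactions, 5),
                     filter_metabolites(ref$reactions, ref$metabolite_taxa))
  host <- build_host_network(ref$human_reactions, ref$ortholog_map,
                             ref$host_only)
  merged <- interface_edges(build_network(host), g,
                            interface_metabolites("vfa_aa"))
  path <- tempfile(fileext = ".graphml")
  write_network(merged, path, edge_tsv = tempfile(fileext = ".tsv"))
  back <- read_network(path)
  expect_equal(igraph::vcount(back), igraph::vcount(merged))
  expect_equal(igraph::ecount(back), igraph::ecount(merged))
  expect_equal(igraph::vertex_attr(back, "name"),
               igraph::vertex_attr(merged, "name"))
  expect_equal(igraph::vertex_attr(back, "side"),
               igraph::vertex_attr(merged, "side"))
  expect_equal(sort(as.logical(igraph::edge_attr(back, "interface"))),
               sort(as.logical(igraph::edge_attr(merged, "interface"))))
  # identical layer structure after the round-trip
  expect_equal(assign_layers(back), assign_layers(merged))
})
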