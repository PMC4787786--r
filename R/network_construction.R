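.VFA <- c("acetate", "propionate", "butyrate")
.AA20 <- c("alanine", "arginine", "asparagine", "aspartate", "cysteine",
           "glutamate", "glutamine", "glycine", "histidine", "isoleucine",
           "leucine", "lysine", "methionine", "phenylalanine", "proline",
           "serine", "threonine", "tryptophan", "tyrosine", "valine")

#' Interface metabolite sets
#'
#' Three nested sets of metabolites posited to be exchanged between microbes
#' and host: `vfa` (the anions of the three volatile fatty acids: acetate,
#' propionate, butyrate), `vfa_aa` (adding the 20 standard amino acids, 23
#' metabolites in total), and `vfa_aa_hum` (further extended by a list of
#' human extracellular-exchange compounds supplied as a text file, one
#' metabolite id per line; the bundled default is a synthetic stand-in).
#'
#' @param set `"vfa"`, `"vfa_aa"` or `"vfa_aa_hum"`.
#' @param hum_file Path to the extension list for `vfa_aa_hum`; defaults to
#'   the synthetic stand-in shipped with the package.
#' @return Character vector of metabolite ids.
#' @export
interface_metabolites <- function(set = c("vfa_aa", "vfa", "vfa_aa_hum"),
                                  hum_file = NULL) {
  set <- match.arg(set)
  base <- switch(set, vfa = .VFA, vfa_aa = c(.VFA, .AA20),
                 vfa_aa_hum = c(.VFA, .AA20))
  if (set == "vfa_aa_hum") {
    if (is.null(hum_file))
      hum_file <- system.file("extdata", "interface_hum_extension_synthetic.txt",
                              package = "rumenet", mustWork = TRUE)
    ext <- readLines(hum_file)
    ext <- trimws(ext[nzchar(trimws(ext)) & !startsWith(trimws(ext), "#")])
    base <- unique(c(base, ext))
  }
  base
}

#' Merge reactions with identical metabolite sets into network nodes
#'
#' Nodes are the equivalence classes of reactions under set equality of their
#' metabolite lists; enzyme annotations are unioned across merged reactions.
#'
#' @param reactions Reaction table (`reaction_id`, `metabolites` list-column,
#'   optionally `enzymes` list-column).
#' @param origin Node origin label (`"microbial"`, `"host"`, `"host_pseudo"`);
#'   recycled.
#' @param id_prefix Prefix for generated node ids.
#' @return Node table: `node_id`, `reaction_ids`, `metabolites`, `enzymes`
#'   (list-columns), `origin`.
#' @export
merge_identical_reactions <- function(reactions, origin = "microbial",
                                      id_prefix = "MN") {
  stopifnot(nrow(reactions) >= 1)
  if (any(lengths(reactions$metabolites) == 0L))
    stop("reaction with empty metabolite list")
  if (is.null(reactions$enzymes))
    reactions$enzymes <- I(rep(list(character(0)), nrow(reactions)))
  origin <- rep(origin, length.out = nrow(reactions))
  key <- vapply(reactions$metabolites,
                function(m) paste(sort(unique(m)), collapse = "\r"), "")
  grp <- factor(key, levels = unique(key))  # first-appearance order
  idx <- split(seq_len(nrow(reactions)), grp)
  data.frame(
    node_id = sprintf("%s%04d", id_prefix, seq_along(idx)),
    reaction_ids = I(lapply(idx, function(i) reactions$reaction_id[i])),
    metabolites = I(lapply(idx, function(i)
      sort(unique(unlist(reactions$metabolites[i]))))),
    enzymes = I(lapply(idx, function(i)
      sort(unique(unlist(reactions$enzymes[i]))))),
    origin = vapply(idx, function(i) origin[i[1]], ""),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Currency metabolites at a reaction-count threshold
#'
#' Metabolites occurring in strictly more than `threshold` reference
#' reactions, counted over the unmerged reaction table.
#'
#' @param reactions Reference reaction table.
#' @param threshold Reaction-count threshold, conventionally 25, 50 or 100.
#' @return Character vector of currency metabolite ids.
#' @export
find_currency <- function(reactions, threshold = 25L) {
  counts <- table(unlist(lapply(reactions$metabolites, unique),
                         use.names = FALSE))
  names(counts)[counts > threshold]
}

#' Metabolites retained by the two-taxa rule
#'
#' Only metabolites annotated in at least `min_taxa` taxa are considered for
#' edge formation; metabolites missing from the taxon-count table are excluded
#' with a warning.
#'
#' @param reactions Reaction table (defines which metabolites occur at all).
#' @param metabolite_taxa Data frame `metabolite_id`, `taxon_count`.
#' @param min_taxa Minimum taxon count (default 2).
#' @return Character vector of retained metabolite ids.
#' @export
filter_metabolites <- function(reactions, metabolite_taxa, min_taxa = 2L) {
  mets <- unique(unlist(reactions$metabolites, use.names = FALSE))
  known <- setNames(metabolite_taxa$taxon_count, metabolite_taxa$metabolite_id)
  missing <- setdiff(mets, names(known))
  if (length(missing))
    warning(length(missing), " metabolites lack taxon counts; excluded")
  mets <- intersect(mets, names(known))
  mets[known[mets] >= min_taxa]
}

#' Build a (sub-)network from merged reaction nodes
#'
#' Two nodes are linked when they share at least one metabolite that is
#' retained (two-taxa rule) and not a currency metabolite. The graph is
#' simple and undirected; node attributes carry the merged reaction ids,
#' metabolites and enzyme annotations (semicolon-joined for serialization).
#'
#' @param nodes Node table from [merge_identical_reactions()].
#' @param currency Character vector of currency metabolites to exclude.
#' @param retained Character vector of metabolites allowed to form edges
#'   (NULL = all).
#' @return An igraph object.
#' @export
build_network <- function(nodes, currency = character(0), retained = NULL) {
  usable <- lapply(nodes$metabolites, function(m) {
    m <- setdiff(m, currency)
    if (!is.null(retained)) m <- intersect(m, retained)
    m
  })
  met2node <- split(rep(seq_len(nrow(nodes)), lengths(usable)),
                    unlist(usable, use.names = FALSE))
  edges <- unique(do.call(rbind, lapply(met2node, function(v) {
    if (length(v) < 2L) return(NULL)
    t(combn(sort(v), 2L))
  })))
  g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes$node_id)
  g <- igraph::set_vertex_attr(g, "origin", value = nodes$origin)
  join <- function(col) vapply(col, paste, "", collapse = ";")
  g <- igraph::set_vertex_attr(g, "reaction_ids", value = join(nodes$reaction_ids))
  g <- igraph::set_vertex_attr(g, "metabolites", value = join(nodes$metabolites))
  g <- igraph::set_vertex_attr(g, "enzymes", value = join(nodes$enzymes))
  if (!is.null(edges) && nrow(edges) > 0)
    g <- igraph::add_edges(g, t(edges))
  igraph::simplify(g)
}

#' Assemble the host reaction set
#'
#' Host nodes are (i) human reactions whose annotating enzyme genes include at
#' least one gene with a 1:1 host ortholog, (ii) host-only reactions (ids
#' absent from the human set), and (iii) one pseudo-reaction converting
#' butyrate to butyryl-CoA, always present exactly once and tagged
#' `host_pseudo`. Reactions with identical metabolite sets are merged.
#'
#' @param human_reactions Data frame `reaction_id`, `metabolites`
#'   (list-column), `genes` (list-column of annotating enzyme genes).
#' @param ortholog_map Data frame `human_gene`, `host_gene` (1:1 orthologs).
#' @param host_reactions Data frame `reaction_id`, `metabolites` for reactions
#'   known only in the host species.
#' @return Node table with origins `host` / `host_pseudo`.
#' @export
build_host_network <- function(human_reactions, ortholog_map, host_reactions) {
  mapped_genes <- ortholog_map$human_gene
  keep <- vapply(human_reactions$genes,
                 function(g) any(g %in% mapped_genes), TRUE)
  human_kept <- human_reactions[keep, c("reaction_id", "metabolites")]
  host_only <- host_reactions[
    !(host_reactions$reaction_id %in% human_reactions$reaction_id),
    c("reaction_id", "metabolites")]
  all_rx <- rbind(human_kept, host_only)
  nodes <- if (nrow(all_rx) > 0)
    merge_identical_reactions(all_rx, origin = "host", id_prefix = "HN")
  else
    data.frame(node_id = character(0), reaction_ids = I(list()),
               metabolites = I(list()), enzymes = I(list()),
               origin = character(0))
  pseudo <- data.frame(
    node_id = "HN_pseudo_butyrate",
    reaction_ids = I(list("pseudo_butyrate_to_butyryl_CoA")),
    metabolites = I(list(c("butyrate", "butyryl-CoA"))),
    enzymes = I(list(character(0))),
    origin = "host_pseudo", stringsAsFactors = FALSE)
  rbind(nodes, pseudo)
}

#' Merge the host and microbial networks through interface metabolites
#'
#' Adds a host-microbe edge wherever a host node and a microbial node share an
#' interface metabolite. Interface metabolites create these cross edges even
#' when they are also currency metabolites (they never create
#' within-sub-network edges when currency). Vertices carry a `side` attribute
#' and cross edges an `interface` attribute.
#'
#' @param host_graph,microbial_graph igraph objects from [build_network()],
#'   built at the same currency threshold.
#' @param interface Character vector of interface metabolites (see
#'   [interface_metabolites()]).
#' @return A merged igraph object.
#' @export
interface_edges <- function(host_graph, microbial_graph, interface) {
  hv <- igraph::vertex_attr(host_graph)
  mv <- igraph::vertex_attr(microbial_graph)
  g <- igraph::disjoint_union(host_graph, microbial_graph)
  side <- c(rep("host", igraph::vcount(host_graph)),
            rep("microbial", igraph::vcount(microbial_graph)))
  g <- igraph::set_vertex_attr(g, "side", value = side)
  g <- igraph::set_edge_attr(g, "interface", value = rep(FALSE, igraph::ecount(g)))
  mets_of <- function(x) strsplit(x, ";", fixed = TRUE)
  h_mets <- lapply(mets_of(hv$metabolites), intersect, x = interface)
  m_mets <- lapply(mets_of(mv$metabolites), intersect, x = interface)
  seen <- FALSE
  new_edges <- list()
  for (i in seq_along(h_mets)) {
    if (length(h_mets[[i]]) == 0L) next
    for (j in seq_along(m_mets)) {
      if (length(intersect(h_mets[[i]], m_mets[[j]])) > 0L) {
        new_edges[[length(new_edges) + 1L]] <-
          c(i, igraph::vcount(host_graph) + j)
        seen <- TRUE
      }
    }
  }
  if (length(interface) > 0 && !seen)
    warning("no interface metabolite is shared by a host and a microbial node")
  if (length(new_edges)) {
    g <- igraph::add_edges(g, unlist(new_edges),
                           attr = list(interface = TRUE))
  }
  igraph::simplify(g, edge.attr.comb = list(interface = "max"))
}

#' Write or read a network as GraphML
#'
#' @param graph igraph object.
#' @param path File path (`.graphml`).
#' @param edge_tsv Optional path for an additional edge-list TSV.
#' @return Invisibly, the graph.
#' @export
write_network <- function(graph, path, edge_tsv = NULL) {
  igraph::write_graph(graph, path, format = "graphml")
  if (!is.null(edge_tsv)) {
    el <- igraph::as_edgelist(graph)
    write.table(data.frame(from = el[, 1], to = el[, 2]), edge_tsv,
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(graph)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if ("interface" %in% igraph::edge_attr_names(g))
    g <- igraph::set_edge_attr(g, "interface",
                               value = as.logical(igraph::edge_attr(g, "interface")))
  g
}
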