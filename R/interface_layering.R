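#' Assign interface-distance layers in a merged host-microbe network
#'
#' A node incident to an interface edge (it shares an interface metabolite
#' with a node of the other sub-network) has distance 0. Every other node's
#' distance is the shortest-path distance, within its own sub-network, to the
#' nearest distance-0 node of its side — equivalently, the number of
#' intermediate nodes crossed before the other sub-network can be reached.
#' Paths never traverse the other sub-network. Edges are unweighted, so the
#' shortest-path search is breadth-first (identical to unit-weight Dijkstra).
#' Nodes with no path to any distance-0 node are reported as unreachable
#' (`d = NA`).
#'
#' @param merged Merged igraph from [interface_edges()].
#' @return Data frame `node_id`, `side`, `d` (non-negative integer or NA).
#' @export
assign_layers <- function(merged) {
  side <- igraph::vertex_attr(merged, "side")
  iface_attr <- igraph::edge_attr(merged, "interface")
  if (is.null(side) || is.null(iface_attr))
    stop("assign_layers() expects a merged network with side and interface attributes")
  iface_attr <- as.logical(iface_attr)
  if (!any(iface_attr))
    stop("merged network has no interface edges; layers are undefined")
  iface_ends <- igraph::ends(merged, igraph::E(merged)[iface_attr],
                             names = FALSE)
  zero_nodes <- unique(as.vector(iface_ends))
  names_all <- igraph::vertex_attr(merged, "name")
  d <- rep(NA_real_, igraph::vcount(merged))
  for (s in unique(side)) {
    on_side <- which(side == s)
    sub <- igraph::induced_subgraph(merged, on_side)
    zero_local <- match(intersect(zero_nodes, on_side), on_side)
    if (length(zero_local) == 0L) next
    dist <- igraph::distances(sub, to = zero_local)
    d[on_side] <- apply(dist, 1L, min)
  }
  d[is.infinite(d)] <- NA_real_
  data.frame(node_id = names_all, side = side, d = as.integer(d),
             stringsAsFactors = FALSE)
}

#' Layer sizes and the usable-layer cutoff
#'
#' Orders layers by distance from 0 and reports the usable set: the maximal
#' prefix of layers in which every layer holds at least `min_nodes` nodes
#' (layers are no longer considered after the first one falling below that
#' size). Unreachable nodes are excluded.
#'
#' @param assignment Output of [assign_layers()].
#' @param side Which sub-network to tabulate (default `"microbial"`).
#' @param min_nodes Minimum layer size (default 10).
#' @return List with `sizes` (data frame `d`, `n`) and `usable` (integer
#'   vector of usable layer distances, possibly empty).
#' @export
layer_sizes <- function(assignment, side = "microbial", min_nodes = 10L) {
  a <- assignment[assignment$side == side & !is.na(assignment$d), ]
  if (nrow(a) == 0L)
    return(list(sizes = data.frame(d = integer(0), n = integer(0)),
                usable = integer(0)))
  tab <- table(factor(a$d, levels = 0:max(a$d)))
  sizes <- data.frame(d = as.integer(names(tab)), n = as.integer(tab))
  ok <- sizes$n >= min_nodes
  n_usable <- if (!ok[1]) 0L else {
    first_bad <- which(!ok)
    if (length(first_bad) == 0L) nrow(sizes) else first_bad[1] - 1L
  }
  list(sizes = sizes, usable = if (n_usable > 0) sizes$d[seq_len(n_usable)]
       else integer(0))
}
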