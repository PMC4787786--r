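# Plain-R dynamic-programming oracles, written independently of the compiled
# kernels but under the same documented conventions (linear gaps, traceback
# tie-break diagonal > up > left, wildcards mismatch everything).

.o_score <- function(a, b, match, mismatch, wild) {
  if (a %in% wild || b %in% wild) return(mismatch)
  if (a == b) match else mismatch
}

oracle_nw <- function(sa, sb, match = 1, mismatch = -1, gap = -2, wild = "N") {
  a <- strsplit(sa, "")[[1]]; b <- strsplit(sb, "")[[1]]
  m <- length(a); n <- length(b)
  S <- matrix(0, m + 1, n + 1); TB <- matrix(0L, m + 1, n + 1)
  S[, 1] <- gap * (0:m); TB[, 1] <- 2L
  S[1, ] <- gap * (0:n); TB[1, ] <- 3L
  TB[1, 1] <- 0L
  for (i in 1:m) for (j in 1:n) {
    d <- S[i, j] + .o_score(a[i], b[j], match, mismatch, wild)
    u <- S[i, j + 1] + gap
    l <- S[i + 1, j] + gap
    if (d >= u && d >= l) { S[i + 1, j + 1] <- d; TB[i + 1, j + 1] <- 1L }
    else if (u >= l) { S[i + 1, j + 1] <- u; TB[i + 1, j + 1] <- 2L }
    else { S[i + 1, j + 1] <- l; TB[i + 1, j + 1] <- 3L }
  }
  i <- m + 1; j <- n + 1; matches <- 0L; columns <- 0L
  while (TB[i, j] != 0L) {
    mv <- TB[i, j]
    columns <- columns + 1L
    if (mv == 1L) {
      if (!(a[i - 1] %in% wild) && !(b[j - 1] %in% wild) && a[i - 1] == b[j - 1])
        matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) i <- i - 1L else j <- j - 1L
  }
  list(score = S[m + 1, n + 1], matches = matches, columns = columns,
       identity = if (columns > 0) matches / columns else 0)
}

oracle_sw <- function(sa, sb, match = 2, mismatch = -1, gap = -3, wild = "X") {
  a <- strsplit(sa, "")[[1]]; b <- strsplit(sb, "")[[1]]
  m <- length(a); n <- length(b)
  S <- matrix(0, m + 1, n + 1); TB <- matrix(0L, m + 1, n + 1)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in 1:m) for (j in 1:n) {
    d <- S[i, j] + .o_score(a[i], b[j], match, mismatch, wild)
    u <- S[i, j + 1] + gap
    l <- S[i + 1, j] + gap
    if (d >= u && d >= l) { v <- d; mv <- 1L }
    else if (u >= l) { v <- u; mv <- 2L }
    else { v <- l; mv <- 3L }
    if (v <= 0) { v <- 0; mv <- 0L }
    S[i + 1, j + 1] <- v; TB[i + 1, j + 1] <- mv
    if (v > best) { best <- v; bi <- i; bj <- j }
  }
  matches <- 0L; columns <- 0L
  i <- bi + 1L; j <- bj + 1L
  if (best > 0) {
    while (TB[i, j] != 0L) {
      mv <- TB[i, j]
      columns <- columns + 1L
      if (mv == 1L) {
        if (!(a[i - 1] %in% wild) && !(b[j - 1] %in% wild) &&
            a[i - 1] == b[j - 1])
          matches <- matches + 1L
        i <- i - 1L; j <- j - 1L
      } else if (mv == 2L) i <- i - 1L else j <- j - 1L
    }
  }
  list(score = best, matches = matches, columns = columns,
       identity = if (columns > 0) matches / columns else 0,
       a_start = if (best > 0) i else 0L, a_end = bi,
       b_start = if (best > 0) j else 0L, b_end = bj)
}

oracle_overlap <- function(sread, sref, match = 1, mismatch = -1, gap = -2,
                           wild = "N") {
  a <- strsplit(sread, "")[[1]]; b <- strsplit(sref, "")[[1]]
  m <- length(a); n <- length(b)
  S <- matrix(0, m + 1, n + 1); TB <- matrix(0L, m + 1, n + 1)
  S[, 1] <- gap * (0:m); TB[, 1] <- 2L
  S[1, ] <- 0; TB[1, ] <- 0L
  for (i in 1:m) for (j in 1:n) {
    d <- S[i, j] + .o_score(a[i], b[j], match, mismatch, wild)
    u <- S[i, j + 1] + gap
    l <- S[i + 1, j] + gap
    if (d >= u && d >= l) { S[i + 1, j + 1] <- d; TB[i + 1, j + 1] <- 1L }
    else if (u >= l) { S[i + 1, j + 1] <- u; TB[i + 1, j + 1] <- 2L }
    else { S[i + 1, j + 1] <- l; TB[i + 1, j + 1] <- 3L }
  }
  bj <- which.max(S[m + 1, ]) - 1L  # leftmost maximum
  score <- S[m + 1, bj + 1]
  matches <- 0L; columns <- 0L
  i <- m + 1L; j <- bj + 1L
  while (TB[i, j] != 0L) {
    mv <- TB[i, j]
    columns <- columns + 1L
    if (mv == 1L) {
      if (!(a[i - 1] %in% wild) && !(b[j - 1] %in% wild) && a[i - 1] == b[j - 1])
        matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) i <- i - 1L else j <- j - 1L
  }
  list(score = score, matches = matches, columns = columns,
       identity = if (columns > 0) matches / columns else 0)
}

# Breadth-first-search layer oracle over a merged network, written directly on
# adjacency lists: a node's layer is the minimum, over own-side nodes incident
# to an interface edge, of the within-side BFS distance.
oracle_layers <- function(merged) {
  n <- igraph::vcount(merged)
  side <- igraph::vertex_attr(merged, "side")
  el <- igraph::as_edgelist(merged, names = FALSE)
  iface <- as.logical(igraph::edge_attr(merged, "interface"))
  adj <- rep(list(integer(0)), n)  # within-side adjacency only
  zero <- rep(FALSE, n)
  for (e in seq_len(nrow(el))) {
    v <- el[e, 1]; w <- el[e, 2]
    if (iface[e]) {
      zero[v] <- TRUE; zero[w] <- TRUE
    } else if (side[v] == side[w]) {
      adj[[v]] <- c(adj[[v]], w)
      adj[[w]] <- c(adj[[w]], v)
    }
  }
  d <- rep(NA_integer_, n)
  for (v in seq_len(n)) {
    if (zero[v]) { d[v] <- 0L; next }
    seen <- rep(FALSE, n); seen[v] <- TRUE
    frontier <- v; depth <- 0L
    while (length(frontier) > 0) {
      depth <- depth + 1L
      nxt <- integer(0)
      for (u in frontier) for (w in adj[[u]]) if (!seen[w]) {
        seen[w] <- TRUE
        nxt <- c(nxt, w)
      }
      if (any(zero[nxt])) { d[v] <- depth; break }
      frontier <- nxt
    }
  }
  d
}

# Random merged two-sided network with side/interface attributes, for oracle
# tests of the layering code.
random_merged_network <- function(n_host, n_micro, p_within = 0.1,
                                  p_cross = 0.05) {
  n <- n_host + n_micro
  side <- c(rep("host", n_host), rep("microbial", n_micro))
  edges <- integer(0); iface <- logical(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (side[i] == side[j]) {
      if (runif(1) < p_within) { edges <- c(edges, i, j); iface <- c(iface, FALSE) }
    } else if (runif(1) < p_cross) { edges <- c(edges, i, j); iface <- c(iface, TRUE) }
  }
  if (!any(iface)) {  # guarantee at least one interface edge
    edges <- c(edges, 1L, n_host + 1L); iface <- c(iface, TRUE)
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = sprintf("v%02d", 1:n))
  g <- igraph::set_vertex_attr(g, "side", value = side)
  g <- igraph::add_edges(g, edges)
  igraph::set_edge_attr(g, "interface", value = iface)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

AA20_CHARS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Substitute exactly k positions of a sequence (never to the original char).
mutate_seq <- function(seq, k, alphabet = c("A", "C", "G", "T")) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(alphabet, ch[p]), 1)
  paste(ch, collapse = "")
}

# A small tiered reference shared by several test files.
small_reference <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(n_taxa = 6L, n_reactions = 20L, n_metabolites = 30L,
         n_hub_metabolites = 1L, hub_degree = 10L, n_tiers = 4L,
         rrna_length = 300L, taxa_per_otu = 2L, genes_per_taxon = 10L,
         seed = seed),
    list(...))
  generate_reference(do.call(reference_spec, args))
}
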