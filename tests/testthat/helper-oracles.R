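# Independent brute-force oracles the implementation is checked against ------

# Minimum Steiner tree edge count by exhaustive search: the smallest
# connected vertex superset of the terminals induces a spanning tree with
# |S| - 1 edges, so enumerate candidate Steiner-node subsets in increasing
# size and stop at the first connected one.
oracle_steiner_opt <- function(net, terminals) {
  nodes <- igraph::V(net)$name
  nonterm <- setdiff(nodes, terminals)
  is_conn <- function(S) {
    sg <- igraph::induced_subgraph(net, S)
    igraph::is_connected(sg)
  }
  for (k in 0:length(nonterm)) {
    if (k == 0L) {
      if (is_conn(terminals)) return(length(terminals) - 1L)
      next
    }
    combos <- utils::combn(nonterm, k)
    for (j in seq_len(ncol(combos))) {
      if (is_conn(c(terminals, combos[, j])))
        return(length(terminals) + k - 1L)
    }
  }
  Inf
}

# Naive clique-percolation oracle: enumerate every k-subset of nodes, keep
# the complete ones, link cliques sharing exactly k-1 nodes by pairwise
# comparison, and take connected components.  `subsets` may be passed in
# (precomputed utils::combn over node indices) to amortize enumeration.
oracle_clique_percolation <- function(net, k, subsets = NULL) {
  n <- igraph::vcount(net)
  nm <- igraph::V(net)$name
  A <- as.matrix(igraph::as_adjacency_matrix(net))
  if (is.null(subsets)) subsets <- utils::combn(n, k)
  pairs <- utils::combn(k, 2L)
  ok <- rep(TRUE, ncol(subsets))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    ok <- ok & (A[(subsets[j, ] - 1L) * n + subsets[i, ]] > 0)
  }
  cl <- subsets[, ok, drop = FALSE]
  nc <- ncol(cl)
  if (nc == 0L) return(list())
  parent <- seq_len(nc)
  root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nc)) {
    for (j in seq_len(i - 1L)) {
      if (length(intersect(cl[, i], cl[, j])) == k - 1L) {
        ri <- root(i); rj <- root(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(nc), root, integer(1))
  comms <- lapply(split(seq_len(nc), roots), function(ix)
    sort(nm[unique(as.vector(cl[, ix, drop = FALSE]))]))
  unname(comms)
}

# canonical form for comparing community lists as sets
canon_communities <- function(comms) {
  sort(vapply(comms, function(x) paste(sort(x), collapse = ","), character(1)))
}

# Full-enumeration Fisher oracle built from choose() only (independent of
# dhyper): conditional probability of each table with the observed margins.
oracle_fisher <- function(a, b, c, d, alternative) {
  N <- a + b + c + d
  row1 <- a + b; col1 <- a + c
  support <- max(0, row1 + col1 - N):min(row1, col1)
  probs <- vapply(support, function(x)
    choose(row1, x) * choose(N - row1, col1 - x), numeric(1))
  probs <- probs / sum(probs)
  if (alternative == "greater") {
    sum(probs[support >= a])
  } else {
    obs <- probs[support == a]
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
}
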