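#' k-clique percolation community detection
#'
#' Enumerates all k-cliques (fixed size `k`; larger cliques contribute all
#' their k-subsets) and links two k-cliques when they share exactly `k - 1`
#' nodes.  Communities are the node unions of the connected components of
#' that clique-adjacency relation; a k-clique adjacent to no other forms a
#' community of its own `k` nodes.  Communities are returned sorted by
#' decreasing size, ties broken by the lexicographically smallest member.
#'
#' Two distinct k-cliques share exactly `k - 1` nodes precisely when they
#' have a common `(k - 1)`-subset, so adjacency is resolved by hashing each
#' clique's `k` leave-one-out subsets instead of comparing cliques pairwise.
#'
#' @param net igraph network.
#' @param k clique size, at least 3.
#' @param max_cliques enumeration budget; exceeding it raises an error with
#'   guidance (default 1e6).
#' @return an object of class `community_set` with fields `k`,
#'   `communities` (list of sorted node-name vectors), `clique_count`,
#'   `nodes_in_communities` and `net_nodes`.
#' @export
clique_percolation <- function(net, k, max_cliques = 1e6) {
  if (k < 3L) stop("k must be >= 3")
  k <- as.integer(k)
  cl <- igraph::cliques(net, min = k, max = k)
  nc <- length(cl)
  if (nc > max_cliques)
    stop(nc, " k-cliques exceeds the enumeration budget (", max_cliques,
         "); raise max_cliques or use a larger k / smaller network")
  empty <- structure(list(k = k, communities = list(), clique_count = 0L,
                          nodes_in_communities = character(0),
                          net_nodes = igraph::V(net)$name),
                     class = "community_set")
  if (nc == 0L) return(empty)
  # k x nc matrix of sorted member names
  M <- vapply(cl, function(x) sort(igraph::V(net)$name[as.integer(x)]),
              character(k))
  # leave-one-out (k-1)-subset keys; cliques sharing a key are adjacent
  keys <- character(k * nc)
  for (i in seq_len(k)) {
    keys[seq.int(i, by = k, length.out = nc)] <-
      apply(M[-i, , drop = FALSE], 2L, paste, collapse = "\001")
  }
  idx <- rep(seq_len(nc), each = k)
  parent <- uf_new(nc)
  for (grp in split(idx, keys)) {
    if (length(grp) > 1L) {
      for (j in grp[-1L]) parent <- uf_union(parent, grp[1L], j)
    }
  }
  roots <- uf_roots(parent)
  comms <- lapply(split(seq_len(nc), roots), function(ix)
    sort(unique(as.vector(M[, ix]))))
  ord <- order(-lengths(comms),
               vapply(comms, `[`, character(1), 1L))
  comms <- unname(comms[ord])
  structure(list(k = k, communities = comms, clique_count = nc,
                 nodes_in_communities = sort(unique(unlist(comms))),
                 net_nodes = igraph::V(net)$name),
            class = "community_set")
}

#' @export
print.community_set <- function(x, ...) {
  cat("<community_set> k =", x$k, "-", length(x$communities),
      "communities from", x$clique_count, "k-cliques covering",
      length(x$nodes_in_communities), "nodes\n")
  invisible(x)
}

#' Fraction of a gene set inside k-clique communities
#'
#' `|gs and community nodes| / |gs and network nodes|`.
#'
#' @param cs `community_set` from [clique_percolation()].
#' @param gs `gene_set`.
#' @return a fraction in `[0, 1]`.
#' @export
membership_fraction <- function(cs, gs) {
  stopifnot(inherits(cs, "community_set"), inherits(gs, "gene_set"))
  mapped <- intersect(gs$members, cs$net_nodes)
  if (length(mapped) == 0L)
    stop("gene set '", gs$name, "' is disjoint from the network")
  length(intersect(mapped, cs$nodes_in_communities)) / length(mapped)
}

#' Split a network into community core and periphery
#'
#' @param net igraph network the communities were detected on.
#' @param cs `community_set`.
#' @return a list with `core` (induced subgraph on community nodes) and
#'   `periphery` (induced subgraph on the remaining nodes).
#' @export
community_core_split <- function(net, cs) {
  stopifnot(inherits(cs, "community_set"))
  core_nodes <- cs$nodes_in_communities
  list(core = induced_subnetwork(net, core_nodes),
       periphery = induced_subnetwork(
         net, setdiff(igraph::V(net)$name, core_nodes)))
}
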