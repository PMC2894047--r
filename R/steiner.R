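# Lexicographically smallest shortest path from `from` to `to`.
# `dist_to` is the vector of hop distances to `to` for all nodes (named).
# At each step the smallest-named neighbor lying on a shortest path is taken,
# which yields the lexicographically smallest node sequence starting at
# `from`.
.lex_shortest_path <- function(net, from, to, dist_to) {
  path <- from
  cur <- from
  while (cur != to) {
    nb <- names(igraph::neighbors(net, cur))
    cand <- nb[dist_to[nb] == dist_to[cur] - 1]
    cur <- min(cand)
    path <- c(path, cur)
  }
  path
}

# Kruskal MST of the terminal metric closure.  `D` is the symmetric hop
# distance matrix over sorted terminal names.  Ties are broken by the
# lexicographic order of the terminal pair, so the tree is deterministic.
.metric_closure_mst <- function(D) {
  term <- rownames(D)
  nt <- length(term)
  ij <- which(upper.tri(D), arr.ind = TRUE)
  w <- D[ij]
  keep <- is.finite(w)
  ij <- ij[keep, , drop = FALSE]; w <- w[keep]
  ord <- order(w, term[ij[, 1L]], term[ij[, 2L]])
  parent <- uf_new(nt)
  edges <- matrix(integer(0), ncol = 2L)
  for (e in ord) {
    i <- ij[e, 1L]; j <- ij[e, 2L]
    if (uf_root(parent, i) != uf_root(parent, j)) {
      parent <- uf_union(parent, i, j)
      edges <- rbind(edges, c(i, j))
      if (nrow(edges) == nt - 1L) break
    }
  }
  edges
}

#' Extract a disease-specific subnetwork by the Steiner minimal-tree
#' heuristic
#'
#' Implements the classic metric-closure/MST 2-approximation: pairwise hop
#' distances among mapped terminals form the closure graph, its minimum
#' spanning tree is taken (ties broken by lexicographic terminal pair), each
#' closure edge is expanded to an actual shortest path (lexicographically
#' smallest node sequence), the paths are unioned, and non-terminal leaves
#' are pruned iteratively.  Components of `net` holding at least two
#' terminals are processed independently; a terminal alone in its component
#' is reported unreachable.
#'
#' With `include_induced_edges = TRUE` (the default) the returned
#' subnetwork is the induced subgraph of `net` on the resulting node set,
#' which is typically much edge-richer than the bare tree; `FALSE` returns
#' the tree itself.
#'
#' @param net igraph network.
#' @param terminals `gene_set` of terminal genes; at least 2 must map.
#' @param include_induced_edges logical flag (see Details).
#' @return an object of class `steiner_result` with fields `subnetwork`,
#'   `terminals_included`, `terminals_unreachable`, `steiner_nodes`,
#'   `tree_edge_count`, plus `method` metadata.
#' @export
steiner_subnetwork <- function(net, terminals, include_induced_edges = TRUE) {
  mapped <- map_gene_set(net, terminals)
  term <- mapped$members
  if (length(term) < 2L)
    stop("need >= 2 mapped terminals; got ", length(term))
  comp <- igraph::components(net)
  memb <- comp$membership[term]
  groups <- split(term, memb)
  sizes <- lengths(groups)
  unreachable <- sort(unlist(groups[sizes < 2L], use.names = FALSE))
  groups <- groups[sizes >= 2L]

  tree_nodes <- character(0)
  tree_edges_a <- character(0)
  tree_edges_b <- character(0)
  for (grp in groups) {
    tset <- sort(grp)
    D <- igraph::distances(net, v = tset, to = tset)
    mst <- .metric_closure_mst(D)
    for (r in seq_len(nrow(mst))) {
      u <- tset[mst[r, 1L]]; v <- tset[mst[r, 2L]]
      lo <- min(u, v); hi <- max(u, v)
      dist_hi <- igraph::distances(net, v = hi)[1L, ]
      p <- .lex_shortest_path(net, lo, hi, dist_hi)
      if (length(p) > 1L) {
        tree_edges_a <- c(tree_edges_a, p[-length(p)])
        tree_edges_b <- c(tree_edges_b, p[-1L])
      }
      tree_nodes <- c(tree_nodes, p)
    }
  }
  included <- sort(unlist(groups, use.names = FALSE))

  # de-duplicate union-of-paths edges
  if (length(tree_edges_a)) {
    key <- edge_key(tree_edges_a, tree_edges_b)
    dup <- duplicated(key)
    ea <- pmin(tree_edges_a, tree_edges_b)[!dup]
    eb <- pmax(tree_edges_a, tree_edges_b)[!dup]
  } else {
    ea <- eb <- character(0)
  }
  # iterative pruning of non-terminal leaves
  repeat {
    degs <- table(c(ea, eb))
    leaves <- setdiff(names(degs)[degs == 1L], included)
    if (length(leaves) == 0L) break
    drop <- ea %in% leaves | eb %in% leaves
    ea <- ea[!drop]; eb <- eb[!drop]
  }
  nodes <- sort(unique(c(ea, eb, included)))
  tree_edge_count <- length(ea)

  subnetwork <- if (include_induced_edges) {
    induced_subnetwork(net, nodes)
  } else {
    as_interactome(cbind(ea, eb), nodes = nodes,
                   name = paste0(terminals$name, "_steiner_tree"))
  }
  subnetwork <- igraph::set_vertex_attr(
    subnetwork, "is_terminal",
    value = igraph::V(subnetwork)$name %in% included)
  structure(list(
    subnetwork = subnetwork,
    terminals_included = included,
    terminals_unreachable = unreachable,
    steiner_nodes = setdiff(nodes, included),
    tree_edge_count = tree_edge_count,
    n_unmapped = attr(mapped, "n_unmapped"),
    include_induced_edges = include_induced_edges,
    method = "metric-closure MST heuristic, lexicographic tie-breaks"
  ), class = "steiner_result")
}

#' @export
print.steiner_result <- function(x, ...) {
  cat("<steiner_result>",
      igraph::vcount(x$subnetwork), "nodes,",
      igraph::ecount(x$subnetwork), "edges;",
      length(x$terminals_included), "terminals,",
      length(x$steiner_nodes), "Steiner nodes,",
      length(x$terminals_unreachable), "unreachable\n")
  invisible(x)
}

#' Uniform Erdos-Renyi G(n, m) random graph
#'
#' @param n_nodes number of nodes.
#' @param n_edges exact number of edges; must not exceed `n(n-1)/2`.
#' @param seed integer RNG seed.
#' @return a simple undirected igraph with nodes named `N1..Nn`.
#' @export
erdos_renyi_gnm <- function(n_nodes, n_edges, seed = 1L) {
  max_e <- n_nodes * (n_nodes - 1) / 2
  if (n_edges > max_e)
    stop("n_edges (", n_edges, ") exceeds maximum ", max_e)
  g <- withr::with_seed(seed, igraph::sample_gnm(n_nodes, n_edges))
  igraph::set_vertex_attr(g, "name", value = paste0("N", seq_len(n_nodes)))
}

#' Non-randomness test of a subnetwork against matched G(n, m) nulls
#'
#' Simulates `n_reps` Erdos-Renyi graphs with the observed node and edge
#' counts and compares average degree, average shortest-path distance over
#' reachable pairs, and average (local) clustering coefficient.  Counts are
#' of strictly more extreme null values, per the resampling convention, so
#' `p = 0` means no random network outperformed the observed one.  The
#' shortest-path metric is reported two-sided (both tail counts retained;
#' `empirical_p` is twice the smaller tail, capped at 1); degree and
#' clustering use the `greater` direction.  Average degree is constant
#' across G(n, m) draws matched on n and m, so its test is degenerate and
#' reported for completeness only.
#'
#' @param observed igraph network with at least 3 nodes.
#' @param n_reps number of random networks (default 1000).
#' @param seed integer RNG seed.
#' @return an object of class `null_model_report`: a data.frame of metrics
#'   plus `n_reps` and `seed` attributes.
#' @export
nonrandomness_test <- function(observed, n_reps = 1000L, seed = 1L) {
  n <- igraph::vcount(observed)
  m <- igraph::ecount(observed)
  if (n < 3L) stop("observed network needs >= 3 nodes")
  obs <- c(average_degree = 2 * m / n,
           average_spd = igraph::mean_distance(observed, unconnected = TRUE),
           clustering_coefficient = mean_local_clustering(observed))
  nulls <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      g <- igraph::sample_gnm(n, m)
      c(2 * igraph::ecount(g) / igraph::vcount(g),
        igraph::mean_distance(g, unconnected = TRUE),
        mean_local_clustering(g))
    }, numeric(3))
  })
  metrics <- data.frame(
    metric = names(obs), observed = unname(obs),
    null_mean = apply(nulls, 1L, mean), null_sd = apply(nulls, 1L, stats::sd),
    n_greater = as.integer(rowSums(nulls > obs)),
    n_less = as.integer(rowSums(nulls < obs)),
    stringsAsFactors = FALSE)
  metrics$direction <- c("greater", "two-sided", "greater")
  metrics$empirical_p <- with(metrics, ifelse(
    direction == "greater", n_greater / n_reps,
    pmin(1, 2 * pmin(n_greater, n_less) / n_reps)))
  structure(metrics, class = c("null_model_report", "data.frame"),
            n_reps = as.integer(n_reps), seed = as.integer(seed))
}
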