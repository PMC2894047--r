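#' Build a normalized interaction network
#'
#' The interactome and every derived subnetwork are simple undirected
#' [igraph] graphs whose vertex names are case-normalized (upper-cased) gene
#' identifiers.  Normalization drops self-loops and collapses duplicate
#' edges (an edge and its reverse are the same edge); the counts of dropped
#' records are attached as graph attributes `dropped_self_loops` and
#' `dropped_duplicates`.
#'
#' @param edges two-column character matrix or data.frame of endpoints, or an
#'   igraph object to renormalize.
#' @param nodes optional character vector of additional (possibly isolated)
#'   node identifiers.
#' @param name label stored as the graph's `name` attribute.
#' @return a simple undirected igraph object.
#' @export
as_interactome <- function(edges, nodes = NULL, name = "network") {
  if (igraph::is_igraph(edges)) {
    enm <- igraph::as_edgelist(edges, names = TRUE)
    nodes <- union(nodes, igraph::V(edges)$name)
    edges <- enm
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L)
    stop("edge input must have exactly two identifier columns")
  storage.mode(edges) <- "character"
  a <- toupper(trimws(edges[, 1L]))
  b <- toupper(trimws(edges[, 2L]))
  keep <- a != b
  n_self <- sum(!keep)
  a <- a[keep]; b <- b[keep]
  key <- edge_key(a, b)
  dup <- duplicated(key)
  n_dup <- sum(dup)
  a <- a[!dup]; b <- b[!dup]
  verts <- sort(unique(c(a, b, toupper(trimws(nodes)))))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
  g <- igraph::set_graph_attr(g, "name", name)
  g <- igraph::set_graph_attr(g, "dropped_self_loops", n_self)
  g <- igraph::set_graph_attr(g, "dropped_duplicates", n_dup)
  g
}

#' Read a network from disk
#'
#' Supported dialects: whitespace/tab-delimited two-column edge lists
#' (`"#"` comment lines skipped), SIF (`node relation target [target ...]`;
#' a single-field line declares an isolated node; the relation is ignored),
#' and GraphML.  All inputs are normalized via [as_interactome()].
#'
#' @param path file path.
#' @param format one of `"auto"`, `"edgelist"`, `"sif"`, `"graphml"`; `"auto"`
#'   dispatches on the file extension (`.sif`, `.graphml`/`.xml`, else
#'   edge list).
#' @return a simple undirected igraph object.
#' @export
read_network <- function(path, format = c("auto", "edgelist", "sif", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sif = "sif", graphml = "graphml", xml = "graphml",
                     "edgelist")
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (igraph::vcount(g) == 0L) stop("empty graph in ", path)
    return(as_interactome(g, name = basename(path)))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  from <- character(0); to <- character(0); nodes <- character(0)
  for (i in idx) {
    fields <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (format == "edgelist") {
      if (length(fields) != 2L)
        stop("malformed edge-list line ", i, " in ", path,
             ": expected 2 fields, got ", length(fields))
      from <- c(from, fields[1L]); to <- c(to, fields[2L])
    } else { # sif
      if (length(fields) == 1L) {
        nodes <- c(nodes, fields[1L])
      } else if (length(fields) >= 3L) {
        tg <- fields[-(1:2)]
        from <- c(from, rep(fields[1L], length(tg))); to <- c(to, tg)
      } else {
        stop("malformed SIF line ", i, " in ", path,
             ": expected 'node relation target...' or a bare node")
      }
    }
  }
  if (length(from) == 0L && length(nodes) == 0L)
    stop("empty graph: no records in ", path)
  as_interactome(cbind(from, to), nodes = nodes, name = basename(path))
}

#' Write a network to disk deterministically
#'
#' Nodes and edges are emitted in lexicographic order so output is
#' byte-stable across runs and platforms.  GraphML export preserves vertex
#' attributes (set membership flags, degrees, GWAS p-values and the like).
#'
#' @param net igraph object.
#' @param path output file path.
#' @param format one of `"edgelist"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edgelist", "sif", "graphml")) {
  format <- match.arg(format)
  perm <- order(igraph::V(net)$name)
  g <- igraph::permute(net, order(perm))
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) > 0L) {
    swap <- el[, 1L] > el[, 2L]
    tmp <- el[swap, 1L]; el[swap, 1L] <- el[swap, 2L]; el[swap, 2L] <- tmp
    el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  }
  lines <- if (format == "edgelist") {
    paste(el[, 1L], el[, 2L], sep = "\t")
  } else {
    paste(el[, 1L], "pp", el[, 2L], sep = "\t")
  }
  iso <- sort(setdiff(igraph::V(g)$name, unique(c(el))))
  if (format == "sif" && length(iso)) lines <- c(lines, iso)
  writeLines(lines, path)
  invisible(path)
}

#' Create a named gene set
#'
#' Members are upper-cased, de-duplicated and sorted.
#'
#' @param name label for the set.
#' @param members character vector of gene identifiers.
#' @return an object of class `gene_set` with fields `name` and `members`.
#' @export
gene_set <- function(name, members) {
  members <- sort(unique(toupper(trimws(as.character(members)))))
  members <- members[nzchar(members)]
  structure(list(name = as.character(name), members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set>", x$name, "-", length(x$members), "genes\n")
  invisible(x)
}

#' Read a one-gene-per-line gene set file
#'
#' @param path file path; blank lines and `"#"` comments are skipped.
#' @param name set label; defaults to the file name without extension.
#' @return a `gene_set`.
#' @export
read_gene_set <- function(path, name = NULL) {
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  lines <- trimws(readLines(path, warn = FALSE))
  gene_set(name, lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Map a gene set onto a network
#'
#' @param net igraph network.
#' @param gs `gene_set`.
#' @return a `gene_set` restricted to genes present in `net`, with
#'   attributes `n_unmapped` and `unmapped`.
#' @export
map_gene_set <- function(net, gs) {
  stopifnot(inherits(gs, "gene_set"))
  nodes <- igraph::V(net)$name
  mapped <- intersect(gs$members, nodes)
  out <- gene_set(gs$name, mapped)
  attr(out, "n_unmapped") <- length(gs$members) - length(mapped)
  attr(out, "unmapped") <- setdiff(gs$members, mapped)
  out
}

#' Degree of one node
#'
#' @param net igraph network.
#' @param node node identifier.
#' @return non-negative integer count of distinct neighbors.
#' @export
node_degree <- function(net, node) {
  if (!node %in% igraph::V(net)$name) stop("unknown node: ", node)
  unname(igraph::degree(net, v = node))
}

#' Breadth-first shortest-path lengths from one source
#'
#' Distances are in hops; the self-distance is 0 and unreachable nodes are
#' absent from the result.
#'
#' @param net igraph network.
#' @param source node identifier.
#' @return named numeric vector of hop counts to every reachable node.
#' @export
shortest_path_lengths <- function(net, source) {
  if (!source %in% igraph::V(net)$name) stop("unknown source: ", source)
  d <- igraph::distances(net, v = source)[1L, ]
  d[is.finite(d)]
}

#' Local clustering coefficient of one node
#'
#' `2 * triangles / (k * (k - 1))` for degree `k >= 2`; defined as 0 for
#' `k < 2`.
#'
#' @param net igraph network.
#' @param node node identifier.
#' @return a fraction in `[0, 1]`.
#' @export
clustering_coefficient <- function(net, node) {
  if (!node %in% igraph::V(net)$name) stop("unknown node: ", node)
  unname(igraph::transitivity(net, type = "localundirected", vids = node,
                              isolates = "zero"))
}

# Mean local clustering over all nodes (degenerate nodes count as 0); the
# network-level summary used by the Erdos-Renyi null-model test.
mean_local_clustering <- function(net) {
  mean(igraph::transitivity(net, type = "localundirected", isolates = "zero"))
}

#' Induced subgraph on a node set
#'
#' @param net igraph network.
#' @param keep character vector of node identifiers; identifiers absent from
#'   `net` are ignored.
#' @return the induced subnetwork (nodes `keep` intersected with `net`,
#'   all edges of `net` with both endpoints kept).
#' @export
induced_subnetwork <- function(net, keep) {
  keep <- intersect(toupper(keep), igraph::V(net)$name)
  igraph::induced_subgraph(net, keep)
}

#' Largest connected component
#'
#' Ties on component size are broken toward the component containing the
#' lexicographically smallest node identifier.
#'
#' @param net igraph network (non-empty).
#' @return the induced subnetwork on the maximum-cardinality component.
#' @export
largest_connected_component <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty network")
  comp <- igraph::components(net)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    firsts <- vapply(best, function(k)
      min(igraph::V(net)$name[comp$membership == k]), character(1))
    best <- best[order(firsts)[1L]]
  }
  induced_subnetwork(net, igraph::V(net)$name[comp$membership == best])
}
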