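#' Create a pathway collection
#'
#' @param pathways named list of character vectors of gene identifiers;
#'   identifiers are case-normalized; empty pathways are an error.
#' @param source label describing where the collection came from.
#' @return an object of class `pathway_collection`.
#' @export
pathway_collection <- function(pathways, source = "unknown") {
  stopifnot(is.list(pathways), length(names(pathways)) == length(pathways))
  pathways <- lapply(pathways, function(g)
    sort(unique(toupper(trimws(as.character(g))))))
  if (any(lengths(pathways) == 0L))
    stop("empty pathway: ",
         paste(names(pathways)[lengths(pathways) == 0L], collapse = ", "))
  structure(list(pathways = pathways, source = source),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat("<pathway_collection>", length(x$pathways), "pathways from",
      x$source, "\n")
  invisible(x)
}

#' Read a GMT pathway file
#'
#' Standard GMT: one pathway per line, tab-delimited
#' `name <TAB> description <TAB> gene [gene ...]`.
#'
#' @param path GMT file path.
#' @param source label; defaults to the file name.
#' @return a `pathway_collection`.
#' @export
read_gmt <- function(path, source = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pw <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("malformed GMT line ", i, ": need name, description, >= 1 gene")
    pw[[fields[1L]]] <- fields[-(1:2)]
  }
  pathway_collection(pw, source = source)
}

#' Write a pathway collection as GMT
#'
#' @param pc `pathway_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pc, path) {
  stopifnot(inherits(pc, "pathway_collection"))
  nm <- sort(names(pc$pathways))
  writeLines(vapply(nm, function(n) paste(
    c(n, pc$source, pc$pathways[[n]]), collapse = "\t"), character(1)), path)
  invisible(path)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric tail for the table `(a, b; c, d)` with the first
#' row and column as the focal margins.  `"greater"` sums the upper tail
#' `P(X >= a)`; `"two.sided"` sums all tables (at fixed margins) whose
#' probability does not exceed the observed table's, the same rule
#' [stats::fisher.test()] uses.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param alternative `"greater"` or `"two.sided"`.
#' @return the p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  if (sum(counts) == 0) stop("all margins are zero")
  N <- a + b + c + d
  row1 <- a + b
  col1 <- a + c
  support <- max(0, row1 + col1 - N):min(row1, col1)
  dens <- stats::dhyper(support, row1, N - row1, col1)
  p <- if (alternative == "greater") {
    sum(dens[support >= a])
  } else {
    obs <- stats::dhyper(a, row1, N - row1, col1)
    sum(dens[dens <= obs * (1 + 1e-7)])
  }
  min(1, max(0, p))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values `q_(i) = min_(j >= i) p_(j) * m / j`, clipped at
#' 1 and mapped back to input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Pathway enrichment of a disease gene set
#'
#' Per pathway, a one-sided Fisher's exact test on the 2x2 table
#' (in-pathway & disease, in-pathway & not, out-of-pathway & disease,
#' neither) against a background gene universe.  The score is
#' `-log10(p)`; a pathway passes the enrichment filter when its score
#' exceeds 2 (p < 0.01) and it contains more than 5 disease genes.
#'
#' @param pc `pathway_collection`.
#' @param disease `gene_set` of disease genes (intersected with the
#'   background).
#' @param background `gene_set` universe; defaults to the union of all
#'   pathway genes and the disease set.  Pathway genes outside the
#'   background are dropped with a warning.
#' @return data.frame of class `enrichment_result`, sorted by p-value,
#'   with columns `pathway`, `pathway_size`, `overlap_count`, `p_value`,
#'   `score`, `passes_filter`.
#' @export
pathway_enrichment <- function(pc, disease, background = NULL) {
  stopifnot(inherits(pc, "pathway_collection"), inherits(disease, "gene_set"))
  all_pw_genes <- unique(unlist(pc$pathways))
  bg <- if (is.null(background)) union(all_pw_genes, disease$members)
        else background$members
  outside <- setdiff(all_pw_genes, bg)
  if (length(outside))
    warning(length(outside), " pathway genes outside the background dropped")
  dis <- intersect(disease$members, bg)
  if (length(dis) == 0L)
    stop("disease set is empty after mapping to the background")
  nb <- length(bg)
  nd <- length(dis)
  res <- lapply(names(pc$pathways), function(nm) {
    pg <- intersect(pc$pathways[[nm]], bg)
    k <- length(intersect(pg, dis))
    p <- fisher_exact_2x2(k, length(pg) - k, nd - k,
                          nb - length(pg) - nd + k, "greater")
    data.frame(pathway = nm, pathway_size = length(pg), overlap_count = k,
               p_value = p, score = -log10(p),
               passes_filter = (-log10(p) > 2) && (k > 5),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p_value, out$pathway), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Interactome edges internal to a pathway
#'
#' @param net igraph network.
#' @param pathway_genes character vector of gene identifiers.
#' @return character vector of canonical edge keys (`"A\tB"` with
#'   `A < B`) for every network edge with both endpoints in the pathway.
#' @export
pathway_link_set <- function(net, pathway_genes) {
  sg <- induced_subnetwork(net, pathway_genes)
  el <- igraph::as_edgelist(sg, names = TRUE)
  if (nrow(el) == 0L) return(character(0))
  sort(edge_key(el[, 1L], el[, 2L]))
}

#' Pairwise pathway-crosstalk statistics
#'
#' For each unordered pair of pathways the 2x2 contingency table
#' `(n, N - n, r, R - r)` is assembled, where `n` is the shared count (genes,
#' or interactome edges internal to both pathways), `N` the combined count
#' of the pair, and `r`, `R` the across-all-pairs averages of `n` and `N`.
#' A one-sided Fisher's exact test gives `p_nodes` and `p_links` per pair;
#' Benjamini-Hochberg adjustment is applied separately to the node and link
#' p-vectors.  A pair has crosstalk when the smaller of its two p-values is
#' below `alpha`.
#'
#' Averages `r` and `R` are rounded half-up for the exact test (which needs
#' integer counts); the unrounded values are retained in the result.  `N`
#' defaults to the sum of the two pathway sizes (shared members counted
#' twice); `n_total = "union"` uses the union size instead.
#'
#' @param pc `pathway_collection` (typically already filtered to enriched
#'   pathways); at least 3 pathways are required.
#' @param net igraph network supplying the interaction links.
#' @param alpha crosstalk significance threshold on `p_min` (default 0.01).
#' @param n_total `"sum"` (default) or `"union"`.
#' @return data.frame of class `crosstalk_result`, one row per pair, with
#'   shared/total counts for nodes and links, the pair-average columns
#'   `mean_common_*` / `mean_total_*`, raw and FDR-adjusted p-values,
#'   `p_min` and `significant`.
#' @export
crosstalk_all_pairs <- function(pc, net, alpha = 0.01,
                                n_total = c("sum", "union")) {
  stopifnot(inherits(pc, "pathway_collection"))
  n_total <- match.arg(n_total)
  nms <- sort(names(pc$pathways))
  if (length(nms) < 3L)
    stop("need >= 3 pathways to define the pair averages; got ", length(nms))
  genes <- pc$pathways[nms]
  links <- lapply(nms, function(nm) pathway_link_set(net, genes[[nm]]))
  names(links) <- nms
  pair <- utils::combn(nms, 2L)
  np <- ncol(pair)
  n_nodes <- N_nodes <- n_links <- N_links <- numeric(np)
  for (i in seq_len(np)) {
    a <- pair[1L, i]; b <- pair[2L, i]
    shared_g <- length(intersect(genes[[a]], genes[[b]]))
    shared_l <- length(intersect(links[[a]], links[[b]]))
    n_nodes[i] <- shared_g
    n_links[i] <- shared_l
    if (n_total == "sum") {
      N_nodes[i] <- length(genes[[a]]) + length(genes[[b]])
      N_links[i] <- length(links[[a]]) + length(links[[b]])
    } else {
      N_nodes[i] <- length(union(genes[[a]], genes[[b]]))
      N_links[i] <- length(union(links[[a]], links[[b]]))
    }
  }
  r_nodes <- mean(n_nodes); R_nodes <- mean(N_nodes)
  r_links <- mean(n_links); R_links <- mean(N_links)
  p_nodes <- vapply(seq_len(np), function(i) fisher_exact_2x2(
    n_nodes[i], N_nodes[i] - n_nodes[i],
    round_half_up(r_nodes), round_half_up(R_nodes - r_nodes),
    "greater"), numeric(1))
  p_links <- vapply(seq_len(np), function(i) fisher_exact_2x2(
    n_links[i], N_links[i] - n_links[i],
    round_half_up(r_links), round_half_up(R_links - r_links),
    "greater"), numeric(1))
  out <- data.frame(
    pathway_a = pair[1L, ], pathway_b = pair[2L, ],
    n_common_nodes = as.integer(n_nodes), total_nodes = as.integer(N_nodes),
    mean_common_nodes = r_nodes, mean_total_nodes = R_nodes,
    n_common_links = as.integer(n_links), total_links = as.integer(N_links),
    mean_common_links = r_links, mean_total_links = R_links,
    p_nodes = p_nodes, p_links = p_links,
    q_nodes = bh_fdr(p_nodes), q_links = bh_fdr(p_links),
    stringsAsFactors = FALSE)
  out$p_min <- pmin(out$p_nodes, out$p_links)
  out$significant <- out$p_min < alpha
  class(out) <- c("crosstalk_result", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "n_total") <- n_total
  out
}

#' Pathway-level crosstalk graph
#'
#' Nodes are pathways; edges connect significantly linked pairs.  An
#' optional named vector of enrichment scores is stored as a node
#' attribute.
#'
#' @param results `crosstalk_result` data.frame.
#' @param scores optional named numeric vector of enrichment scores.
#' @return an igraph object.
#' @export
crosstalk_graph <- function(results, scores = NULL) {
  stopifnot(inherits(results, "crosstalk_result") || is.data.frame(results))
  nms <- sort(unique(c(results$pathway_a, results$pathway_b)))
  sig <- results[results$significant, c("pathway_a", "pathway_b"),
                 drop = FALSE]
  g <- igraph::graph_from_data_frame(sig, directed = FALSE,
                                     vertices = nms)
  if (!is.null(scores)) {
    g <- igraph::set_vertex_attr(g, "score",
                                 value = unname(scores[igraph::V(g)$name]))
  }
  g
}
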