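#' Configuration for the synthetic fixture generator
#'
#' Defines a complete, deterministic study fixture: a scale-free
#' interactome grown by preferential attachment with tunable triangle
#' closure; five gene sets with graded hub bias emulating the
#' cancer / essential / disease / neurodevelopment / neutral contrast;
#' an overlapping pathway collection seeded from the disease set; and a
#' pair of GWAS p-value tables that are Uniform(0,1) under the null with a
#' Beta-distributed signal planted on the disease subnetwork.  Every draw
#' derives from `master_seed` through [derive_seed()], so the whole fixture
#' is a pure function of this configuration.
#'
#' @param n_nodes interactome size (default 10000).
#' @param attachment_edges edges added per new node (default 3).
#' @param triangle_closure_prob probability of closing one triangle among a
#'   new node's neighbors after attachment (default 0.15).
#' @param set_specs named list of gene-set specs, each a list with `size`,
#'   `degree_bias_exponent` and `clique_planting`.
#' @param pathway_specs list with `count`, `size_range`, `overlaps` (a
#'   data.frame `a`, `b`, `jaccard` with `a < b`), `disease_seeded`
#'   (pathway indices initialized from the disease set) and
#'   `disease_fraction`.
#' @param gwas_specs list with `signal_set` (`"disease_subnetwork"` or the
#'   name of a gene set) and `beta_shape` in `(0, 1]`.
#' @param disease_set name of the gene set treated as the disease
#'   (terminal) set.
#' @param master_seed integer master seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_nodes = 10000L,
    attachment_edges = 3L,
    triangle_closure_prob = 0.15,
    set_specs = list(
      cancer_like    = list(size = 300L, degree_bias_exponent = 2,
                            clique_planting = TRUE),
      essential_like = list(size = 400L, degree_bias_exponent = 1.2,
                            clique_planting = FALSE),
      disease_like   = list(size = 160L, degree_bias_exponent = 0.7,
                            clique_planting = FALSE),
      neuro_like     = list(size = 250L, degree_bias_exponent = 0.35,
                            clique_planting = FALSE),
      neutral        = list(size = 300L, degree_bias_exponent = 0,
                            clique_planting = FALSE)),
    pathway_specs = list(
      count = 12L, size_range = c(30L, 50L),
      overlaps = data.frame(a = c(1L, 3L), b = c(2L, 4L),
                            jaccard = c(0.4, 0.4)),
      disease_seeded = 1:4, disease_fraction = 0.4),
    gwas_specs = list(signal_set = "disease_subnetwork", beta_shape = 0.1),
    disease_set = "disease_like",
    master_seed = 20100526L) {
  stopifnot(n_nodes >= 10L, attachment_edges >= 1L,
            attachment_edges < n_nodes,
            triangle_closure_prob >= 0, triangle_closure_prob <= 1,
            master_seed == round(master_seed), abs(master_seed) < 2^31)
  sizes <- vapply(set_specs, function(s) s$size, numeric(1))
  if (any(sizes > n_nodes)) stop("gene-set size exceeds n_nodes")
  ov <- pathway_specs$overlaps
  if (!is.null(ov) && nrow(ov)) {
    stopifnot(all(ov$a < ov$b), all(ov$jaccard >= 0), all(ov$jaccard <= 1),
              all(ov$b <= pathway_specs$count))
  }
  stopifnot(disease_set %in% names(set_specs),
            gwas_specs$beta_shape > 0, gwas_specs$beta_shape <= 1)
  structure(list(n_nodes = as.integer(n_nodes),
                 attachment_edges = as.integer(attachment_edges),
                 triangle_closure_prob = triangle_closure_prob,
                 set_specs = set_specs, pathway_specs = pathway_specs,
                 gwas_specs = gwas_specs, disease_set = disease_set,
                 master_seed = as.integer(master_seed)),
            class = "synthetic_config")
}

#' Generate a scale-free interactome with tunable clustering
#'
#' Growth model: the graph starts as a clique on `attachment_edges` nodes;
#' each new node attaches to `attachment_edges` distinct existing nodes
#' chosen with probability proportional to current degree, and then, with
#' probability `triangle_closure_prob`, one extra edge is added between two
#' random neighbors of the new node (closing a triangle).  The result is
#' connected by construction with a heavy-tailed degree distribution.
#'
#' @param cfg a `synthetic_config` (only the interactome fields are used).
#' @param seed integer seed; defaults to stream 1 of the config's master
#'   seed.
#' @return an igraph interactome with nodes named `G000001, ...`.
#' @export
generate_interactome <- function(cfg, seed = derive_seed(cfg$master_seed, 1L)) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_nodes; m <- cfg$attachment_edges; q <- cfg$triangle_closure_prob
  max_e <- choose(m, 2L) + (n - m) * (m + 1L)
  ea <- integer(max_e); eb <- integer(max_e); ne <- 0L
  replist <- integer(2L * max_e); nr <- 0L
  seen <- new.env(hash = TRUE, parent = emptyenv())
  add_edge <- function(u, v) {
    ne <<- ne + 1L
    ea[ne] <<- u; eb[ne] <<- v
    replist[nr + 1L] <<- u; replist[nr + 2L] <<- v
    nr <<- nr + 2L
    assign(paste(min(u, v), max(u, v)), TRUE, envir = seen)
  }
  withr::with_seed(seed, {
    if (m >= 2L) {
      for (i in 1:(m - 1L)) for (j in (i + 1L):m) add_edge(i, j)
    }
    for (v in (m + 1L):n) {
      k <- min(m, v - 1L)
      if (nr == 0L) {
        targets <- sample.int(v - 1L, k)
      } else {
        targets <- integer(0)
        while (length(targets) < k) {
          cand <- replist[sample.int(nr, 1L)]
          if (!(cand %in% targets)) targets <- c(targets, cand)
        }
      }
      for (t in targets) add_edge(v, t)
      if (q > 0 && length(targets) >= 2L && stats::runif(1) < q) {
        pr <- sample(targets, 2L)
        if (!exists(paste(min(pr), max(pr)), envir = seen))
          add_edge(pr[1L], pr[2L])
      }
    }
  })
  nm <- sprintf("G%06d", seq_len(n))
  g <- igraph::graph_from_edgelist(
    cbind(nm[ea[seq_len(ne)]], nm[eb[seq_len(ne)]]), directed = FALSE)
  igraph::set_graph_attr(g, "name", "synthetic_interactome")
}

# Deterministic multi-source BFS ball: grows `seeds` outward in
# lexicographic frontier order until `size` nodes are collected, skipping
# `exclude`.  Errors if the reachable ball is too small.
grow_ball <- function(net, seeds, size, exclude = character(0)) {
  visited <- setdiff(unique(seeds), exclude)
  if (length(visited) == 0L) stop("infeasible ball: all seeds excluded")
  frontier <- visited
  while (length(visited) < size && length(frontier) > 0L) {
    nb <- unique(unlist(lapply(frontier, function(x)
      names(igraph::neighbors(net, x))), use.names = FALSE))
    nb <- sort(setdiff(nb, c(visited, exclude)))
    if (length(nb) == 0L) break
    take <- utils::head(nb, size - length(visited))
    visited <- c(visited, take)
    frontier <- take
  }
  if (length(visited) < size)
    stop("infeasible: neighborhood ball exhausted at ", length(visited),
         " of ", size, " nodes")
  visited
}

#' Plant a gene set with controlled degree bias and clustering
#'
#' Samples `size` nodes with probability proportional to
#' `degree^degree_bias_exponent` (0 = uniform, positive = hub-biased,
#' negative = periphery-biased).  With `clique_planting`, half the set is
#' sampled first and the remainder is drawn from the 2-hop neighborhoods of
#' the current members (degree-weighted), which concentrates the set in
#' densely interconnected regions.
#'
#' @param net igraph network.
#' @param name set label.
#' @param size number of genes.
#' @param degree_bias_exponent real exponent (default 0).
#' @param clique_planting logical (default FALSE).
#' @param seed integer RNG seed.
#' @return a `gene_set`.
#' @export
plant_gene_set <- function(net, name, size, degree_bias_exponent = 0,
                           clique_planting = FALSE, seed = 1L) {
  nodes <- igraph::V(net)$name
  if (size > length(nodes))
    stop("size (", size, ") exceeds node count (", length(nodes), ")")
  degs <- igraph::degree(net)
  w <- pmax(degs, 1)^degree_bias_exponent
  names(w) <- nodes
  members <- withr::with_seed(seed, {
    if (!clique_planting || size < 4L) {
      sample(nodes, size, prob = w)
    } else {
      sel <- sample(nodes, ceiling(size / 2), prob = w)
      while (length(sel) < size) {
        hood <- unique(unlist(lapply(
          igraph::ego(net, order = 2L, nodes = sel),
          function(x) names(x)), use.names = FALSE))
        cand <- setdiff(hood, sel)
        if (length(cand) == 0L) cand <- setdiff(nodes, sel)
        take <- min(length(cand), size - length(sel),
                    max(1L, ceiling(size / 5)))
        sel <- c(sel, sample(cand, take, prob = w[cand]))
      }
      sel
    }
  })
  gene_set(name, members)
}

#' Generate an overlapping pathway collection
#'
#' Pathways are grown as breadth-first neighborhood balls around random
#' centers, which guarantees internal interactome links.  A requested
#' pairwise Jaccard overlap `J` between pathways `a < b` is realized by
#' seeding pathway `b` with `s = J (|a| + |b|) / (1 + J)` members of `a`
#' (a connected sub-ball of `a`) and expanding outside `a`, so the realized
#' intersection is exactly `s`.  `J = 0` forces an empty intersection and
#' `J = 1` an identical member set.  Pathways listed in `disease_seeded`
#' draw `disease_fraction` of their members from `seed_set` first, making
#' them enriched for that set; seeded pathways use disjoint portions of the
#' seed set and avoid each other's members while growing, so that member
#' overlap among them arises only where an overlap constraint plants it.
#'
#' @param net igraph network.
#' @param specs pathway spec list (see [synthetic_config()]); an optional
#'   logical `disjoint` makes every unconstrained pathway avoid all earlier
#'   ones.
#' @param seed integer RNG seed.
#' @param seed_set optional `gene_set` backing `disease_seeded` pathways.
#' @return a `pathway_collection` with pathways named `PW01, PW02, ...`.
#' @export
generate_pathways <- function(net, specs, seed = 1L, seed_set = NULL) {
  count <- specs$count
  szr <- specs$size_range
  ov <- specs$overlaps
  seeded_idx <- specs$disease_seeded %||% integer(0)
  dfrac <- specs$disease_fraction %||% 0.4
  disjoint <- isTRUE(specs$disjoint)
  nodes <- igraph::V(net)$name
  dis <- if (!is.null(seed_set)) intersect(seed_set$members, nodes)
         else character(0)
  pw <- vector("list", count)
  names(pw) <- sprintf("PW%02d", seq_len(count))
  used_disease <- character(0)
  withr::with_seed(seed, {
    for (i in seq_len(count)) {
      size_i <- if (szr[1L] == szr[2L]) szr[1L]
                else sample(szr[1L]:szr[2L], 1L)
      con <- if (!is.null(ov) && nrow(ov)) ov[ov$b == i, , drop = FALSE]
             else ov
      # seeded pathways stay out of each other's territory so overlap among
      # them is planted, never incidental; 'disjoint' extends this to all
      prev_idx <- seq_len(i - 1L)
      avoid <- if (disjoint) unique(unlist(pw[prev_idx])) else
        unique(unlist(pw[intersect(prev_idx, seeded_idx)]))
      if (!(i %in% seeded_idx) && !disjoint) avoid <- character(0)
      if (!is.null(con) && nrow(con) >= 1L) {
        con <- con[1L, ]
        A <- pw[[con$a]]
        if (con$jaccard == 1) {
          pw[[i]] <- A
          next
        }
        if (con$jaccard == 0) {
          center <- sample(setdiff(nodes, union(A, avoid)), 1L)
          pw[[i]] <- grow_ball(net, center, size_i,
                               exclude = union(A, avoid))
          next
        }
        s <- max(1L, round_half_up(
          con$jaccard * (length(A) + size_i) / (1 + con$jaccard)))
        s <- min(s, length(A), size_i)
        pref <- if (i %in% seeded_idx) intersect(A, dis) else character(0)
        pool <- c(sample(pref), sample(setdiff(A, pref)))
        shared <- pool[seq_len(s)]
        pw[[i]] <- grow_ball(net, shared, size_i,
                             exclude = union(setdiff(A, shared),
                                             setdiff(avoid, A)))
      } else if (i %in% seeded_idx && length(dis)) {
        pool_d <- setdiff(dis, used_disease)
        if (length(pool_d) == 0L) pool_d <- dis
        nd <- min(length(pool_d), max(1L, round_half_up(dfrac * size_i)))
        core <- sample(pool_d, nd)
        pw[[i]] <- grow_ball(net, core, size_i, exclude = avoid)
      } else {
        center <- sample(setdiff(nodes, avoid), 1L)
        pw[[i]] <- grow_ball(net, center, size_i, exclude = avoid)
      }
      if (i %in% seeded_idx)
        used_disease <- union(used_disease, intersect(pw[[i]], dis))
    }
  })
  pathway_collection(pw, source = "synthetic")
}

#' Generate a gene-level GWAS p-value table
#'
#' Non-signal genes receive `p ~ Uniform(0, 1)`; signal genes receive
#' `p ~ Beta(beta_shape, 1)`, which is stochastically small for
#' `beta_shape < 1` (`P(p < t) = t^beta_shape`) and exactly uniform at
#' `beta_shape = 1`.  Distinct seeds give independent studies.
#'
#' @param genes character vector of gene identifiers (the study universe).
#' @param signal `gene_set` (or character vector) of signal genes; must be
#'   a subset of `genes`.
#' @param beta_shape shape parameter in `(0, 1]`.
#' @param seed integer RNG seed.
#' @param study_name label for the study.
#' @return a `gwas_table`.
#' @export
generate_gwas <- function(genes, signal, beta_shape = 0.1, seed = 1L,
                          study_name = "study") {
  genes <- sort(unique(toupper(trimws(genes))))
  sig <- if (inherits(signal, "gene_set")) signal$members
         else sort(unique(toupper(signal)))
  if (length(setdiff(sig, genes)))
    stop("signal genes must be a subset of the study universe")
  stopifnot(beta_shape > 0, beta_shape <= 1)
  p <- withr::with_seed(seed, {
    x <- stats::runif(length(genes))
    is_sig <- genes %in% sig
    x[is_sig] <- stats::rbeta(sum(is_sig), beta_shape, 1)
    x
  })
  gwas_table(study_name, genes, pmin(pmax(p, 1e-300), 1))
}

#' Generate the complete synthetic study fixture
#'
#' Builds, in order: the interactome; the five gene sets; the disease
#' (terminal-set) Steiner subnetwork; the pathway collection seeded from
#' the disease set; and two independent GWAS tables over all interactome
#' genes with the signal planted on the disease subnetwork (or on a named
#' gene set, per `gwas_specs$signal_set`).  Each stage draws from its own
#' [derive_seed()] stream of `master_seed`, so the fixture is a pure
#' function of the configuration.
#'
#' @param cfg a `synthetic_config`.
#' @return an object of class `synthetic_fixture`: a list with `network`,
#'   `gene_sets`, `disease_subnet` (a `steiner_result`), `pathways`,
#'   `gwas` (list of two `gwas_table`s), `signal_genes` and `config`.
#' @export
generate_fixture <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  net <- generate_interactome(cfg)
  sets <- vector("list", length(cfg$set_specs))
  names(sets) <- names(cfg$set_specs)
  for (i in seq_along(cfg$set_specs)) {
    sp <- cfg$set_specs[[i]]
    sets[[i]] <- plant_gene_set(net, names(cfg$set_specs)[i], sp$size,
                                sp$degree_bias_exponent, sp$clique_planting,
                                seed = derive_seed(cfg$master_seed, 1L + i))
  }
  disease <- sets[[cfg$disease_set]]
  sres <- steiner_subnetwork(net, disease, include_induced_edges = TRUE)
  pc <- generate_pathways(net, cfg$pathway_specs,
                          seed = derive_seed(cfg$master_seed, 7L),
                          seed_set = disease)
  signal <- if (identical(cfg$gwas_specs$signal_set, "disease_subnetwork")) {
    igraph::V(sres$subnetwork)$name
  } else {
    sets[[cfg$gwas_specs$signal_set]]$members
  }
  gwas <- list(
    a = generate_gwas(igraph::V(net)$name, signal, cfg$gwas_specs$beta_shape,
                      seed = derive_seed(cfg$master_seed, 8L),
                      study_name = "STUDY_A"),
    b = generate_gwas(igraph::V(net)$name, signal, cfg$gwas_specs$beta_shape,
                      seed = derive_seed(cfg$master_seed, 9L),
                      study_name = "STUDY_B"))
  structure(list(network = net, gene_sets = sets, disease_subnet = sres,
                 pathways = pc, gwas = gwas, signal_genes = sort(signal),
                 config = cfg),
            class = "synthetic_fixture")
}

#' @export
print.synthetic_fixture <- function(x, ...) {
  cat("<synthetic_fixture>", igraph::vcount(x$network), "nodes,",
      igraph::ecount(x$network), "edges;",
      length(x$gene_sets), "gene sets;",
      length(x$pathways$pathways), "pathways; disease subnetwork",
      igraph::vcount(x$disease_subnet$subnetwork), "nodes\n")
  invisible(x)
}
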