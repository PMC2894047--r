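# Small deterministic graphs used across tests --------------------------------

triangle_net <- function() {
  as_interactome(rbind(c("A", "B"), c("B", "C"), c("C", "A")))
}

path_net <- function(nodes = c("A", "B", "C")) {
  as_interactome(cbind(nodes[-length(nodes)], nodes[-1L]))
}

star_net <- function(n_leaves = 5L) {
  as_interactome(cbind("HUB", paste0("L", seq_len(n_leaves))))
}

# two triangles A-B-C and B-C-D sharing the edge B-C
bowtie_edge_net <- function() {
  as_interactome(rbind(c("A", "B"), c("B", "C"), c("C", "A"),
                       c("B", "D"), c("C", "D")))
}

# two triangles sharing only the node C
bowtie_node_net <- function() {
  as_interactome(rbind(c("A", "B"), c("B", "C"), c("C", "A"),
                       c("C", "D"), c("D", "E"), c("E", "C")))
}

complete_net <- function(n) {
  nm <- LETTERS[seq_len(n)]
  as_interactome(t(utils::combn(nm, 2L)))
}

# random connected G(n, m) graph (resamples until connected)
random_connected_net <- function(n, m, seed) {
  for (off in 0:100) {
    g <- erdos_renyi_gnm(n, m, seed = seed + 7919L * off)
    if (igraph::is_connected(g)) return(g)
  }
  stop("could not draw a connected graph")
}

# Session-cached default synthetic objects (built once, shared by tests) ------

.cache <- new.env(parent = emptyenv())

cached_interactome <- function() {
  if (is.null(.cache$net)) .cache$net <- generate_interactome(synthetic_config())
  .cache$net
}

cached_fixture <- function() {
  if (is.null(.cache$fix)) .cache$fix <- generate_fixture(synthetic_config())
  .cache$fix
}

# small-scale synthetic configuration for fast end-to-end tests
small_config <- function(seed = 424242L) {
  synthetic_config(
    n_nodes = 1500L, attachment_edges = 3L, triangle_closure_prob = 0.15,
    set_specs = list(
      cancer_like    = list(size = 80L, degree_bias_exponent = 2,
                            clique_planting = TRUE),
      essential_like = list(size = 90L, degree_bias_exponent = 1.2,
                            clique_planting = FALSE),
      disease_like   = list(size = 60L, degree_bias_exponent = 0.7,
                            clique_planting = FALSE),
      neuro_like     = list(size = 70L, degree_bias_exponent = 0.35,
                            clique_planting = FALSE),
      neutral        = list(size = 80L, degree_bias_exponent = 0,
                            clique_planting = FALSE)),
    pathway_specs = list(
      count = 8L, size_range = c(20L, 30L),
      overlaps = data.frame(a = c(1L, 3L), b = c(2L, 4L),
                            jaccard = c(0.4, 0.4)),
      disease_seeded = 1:4, disease_fraction = 0.4),
    master_seed = seed)
}
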