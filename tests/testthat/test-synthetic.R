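test_that("interactome growth matches the closed-form edge count", {
  cfg <- synthetic_config(n_nodes = 1000L, attachment_edges = 3L,
                          triangle_closure_prob = 0, master_seed = 1L)
  g <- generate_interactome(cfg)
  expect_equal(igraph::ecount(g), 3L * (1000L - 3L) + choose(3L, 2L))
  expect_true(igraph::is_connected(g))
  degs <- igraph::degree(g)
  expect_gt(max(degs), 10 * stats::median(degs))  # heavy upper tail

  tree_cfg <- synthetic_config(
    n_nodes = 10L, attachment_edges = 1L, triangle_closure_prob = 0,
    set_specs = list(disease_like = list(size = 4L, degree_bias_exponent = 0,
                                         clique_planting = FALSE)),
    master_seed = 2L)
  t10 <- generate_interactome(tree_cfg)
  expect_equal(igraph::ecount(t10), 9L)
  expect_true(igraph::is_connected(t10))
})

test_that("triangle closure raises the clustering coefficient", {
  base <- list(n_nodes = 800L, attachment_edges = 3L, master_seed = 7L)
  g0 <- generate_interactome(do.call(synthetic_config,
                                     c(base, triangle_closure_prob = 0)))
  g9 <- generate_interactome(do.call(synthetic_config,
                                     c(base, triangle_closure_prob = 0.9)))
  cc0 <- igraph::transitivity(g0, type = "average", isolates = "zero")
  cc9 <- igraph::transitivity(g9, type = "average", isolates = "zero")
  expect_gt(cc9, cc0)
})

test_that("degree-bias exponent controls the planted set's mean degree", {
  cfg <- small_config()
  net <- generate_interactome(cfg)
  net_mean <- mean(igraph::degree(net))
  means0 <- vapply(1:50, function(s)
    mean(igraph::degree(net, plant_gene_set(net, "u", 50L, 0,
                                            seed = s)$members)), numeric(1))
  expect_lt(abs(mean(means0) - net_mean), 2 * stats::sd(means0))
  for (s in 1:5) {
    m2 <- mean(igraph::degree(net, plant_gene_set(net, "h", 50L, 2,
                                                  seed = s)$members))
    expect_gt(m2, means0[s])
  }
  all_nodes <- plant_gene_set(net, "all", igraph::vcount(net), 3, seed = 1L)
  expect_equal(length(all_nodes$members), igraph::vcount(net))
  expect_error(plant_gene_set(net, "x", igraph::vcount(net) + 1L), "exceeds")
})

test_that("pathway overlap constraints realize the requested Jaccard", {
  cfg <- small_config()
  net <- generate_interactome(cfg)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  pc0 <- generate_pathways(net, list(count = 2L, size_range = c(25L, 25L),
                                     overlaps = data.frame(a = 1L, b = 2L,
                                                           jaccard = 0)),
                           seed = 3L)
  expect_equal(jac(pc0$pathways$PW01, pc0$pathways$PW02), 0)
  pc1 <- generate_pathways(net, list(count = 2L, size_range = c(25L, 25L),
                                     overlaps = data.frame(a = 1L, b = 2L,
                                                           jaccard = 1)),
                           seed = 3L)
  expect_identical(pc1$pathways$PW01, pc1$pathways$PW02)
  for (s in 1:5) {
    pc3 <- generate_pathways(net, list(count = 2L, size_range = c(30L, 30L),
                                       overlaps = data.frame(a = 1L, b = 2L,
                                                             jaccard = 0.3)),
                             seed = 100L + s)
    expect_lt(abs(jac(pc3$pathways$PW01, pc3$pathways$PW02) - 0.3), 0.1)
  }
})

test_that("GWAS generator produces the right null and signal mixtures", {
  genes <- sprintf("g%04d", 1:5000)
  sig <- gene_set("sig", genes[1:1000])
  gt <- generate_gwas(genes, sig, beta_shape = 0.1, seed = 9L)
  frac_small <- mean(gt$p_by_gene[sig$members] < 0.05)
  expect_lt(abs(frac_small - 0.05^0.1), 0.05)  # P(p < t) = t^a
  # shape 1 makes the signal indistinguishable from uniform
  gt1 <- generate_gwas(genes, sig, beta_shape = 1, seed = 9L)
  ks <- stats::ks.test(gt1$p_by_gene[sig$members], "punif")$p.value
  expect_gt(ks, 0.001)
  # independent studies have uncorrelated null p-values
  ga <- generate_gwas(genes, sig, 0.1, seed = 1L)
  gb <- generate_gwas(genes, sig, 0.1, seed = 2L)
  null_genes <- setdiff(names(ga$p_by_gene), sig$members)
  expect_lt(abs(stats::cor(ga$p_by_gene[null_genes],
                           gb$p_by_gene[null_genes])), 0.1)
  expect_error(generate_gwas(genes[1:10], sig, 0.1), "subset")
})

test_that("the whole fixture is a pure function of its configuration", {
  cfg <- small_config(seed = 555L)
  f1 <- generate_fixture(cfg)
  f2 <- generate_fixture(cfg)
  el1 <- igraph::as_edgelist(f1$network)
  el2 <- igraph::as_edgelist(f2$network)
  expect_identical(el1, el2)
  expect_identical(lapply(f1$gene_sets, `[[`, "members"),
                   lapply(f2$gene_sets, `[[`, "members"))
  expect_identical(f1$pathways$pathways, f2$pathways$pathways)
  expect_identical(f1$gwas$a$p_by_gene, f2$gwas$a$p_by_gene)
  expect_identical(sort(igraph::V(f1$disease_subnet$subnetwork)$name),
                   sort(igraph::V(f2$disease_subnet$subnetwork)$name))
  # a different master seed changes the draw
  f3 <- generate_fixture(small_config(seed = 556L))
  expect_false(identical(f1$gwas$a$p_by_gene, f3$gwas$a$p_by_gene))
})

test_that("config validation rejects impossible requests", {
  expect_error(synthetic_config(n_nodes = 5L), ">=")
  expect_error(synthetic_config(
    set_specs = list(big = list(size = 1e6, degree_bias_exponent = 0,
                                clique_planting = FALSE)),
    disease_set = "big"), "exceeds")
  expect_error(synthetic_config(
    pathway_specs = list(count = 3L, size_range = c(10L, 20L),
                         overlaps = data.frame(a = 2L, b = 1L, jaccard = 0.5),
                         disease_seeded = integer(0),
                         disease_fraction = 0.4)))
})
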