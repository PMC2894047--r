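test_that("Fisher exact test matches enumeration and the stats reference", {
  expect_equal(fisher_exact_2x2(2, 0, 0, 2, "greater"), 1 / 6,
               tolerance = 1e-12)
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "zero")
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "non-negative")
  expect_gt(fisher_exact_2x2(5, 5, 5, 5, "greater"), 0.5)
  withr::with_seed(31L, {
    for (i in 1:25) {
      tb <- sample(0:8, 4L, replace = TRUE)
      if (sum(tb) == 0) tb[1] <- 1
      for (alt in c("greater", "two.sided")) {
        mine <- fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4], alt)
        expect_equal(mine, oracle_fisher(tb[1], tb[2], tb[3], tb[4], alt),
                     tolerance = 1e-9)
        ref <- stats::fisher.test(matrix(tb, 2L, byrow = TRUE),
                                  alternative = ifelse(alt == "greater",
                                                       "greater", "two.sided"))
        expect_equal(mine, ref$p.value, tolerance = 1e-7)
      }
    }
  })
})

test_that("BH adjustment reproduces the hand-worked example and properties", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(1.0), 1.0)
  expect_equal(bh_fdr(rep(0.2, 5L)), rep(0.2, 5L))
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
  withr::with_seed(5L, {
    p <- runif(40L)
    q <- bh_fdr(p)
    expect_true(all(q >= p))
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-12))
  })
})

test_that("GMT files round-trip and bad lines error", {
  pc <- pathway_collection(list(P1 = c("a", "b", "C"), P2 = c("C", "d")),
                           source = "unit")
  tmp <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(pc, tmp)
  back <- read_gmt(tmp)
  expect_equal(back$pathways, pc$pathways)
  writeLines("P1\tdesc", tmp)
  expect_error(read_gmt(tmp), "line 1")
  expect_error(pathway_collection(list(P1 = character(0))), "empty")
})

test_that("pathway enrichment applies the score and gene-count filters", {
  bg <- gene_set("bg", sprintf("G%03d", 1:100))
  dis <- gene_set("dis", sprintf("G%03d", 1:6))
  pc <- pathway_collection(list(HIT = sprintf("G%03d", 1:6),
                                MISS = sprintf("G%03d", 50:60)),
                           source = "unit")
  res <- pathway_enrichment(pc, dis, background = bg)
  hit <- res[res$pathway == "HIT", ]
  expect_equal(hit$overlap_count, 6L)
  expect_lt(hit$p_value, 0.01)
  expect_true(hit$passes_filter)
  miss <- res[res$pathway == "MISS", ]
  expect_equal(miss$overlap_count, 0L)
  expect_false(miss$passes_filter)
  expect_error(pathway_enrichment(pc, gene_set("d", "ZZZ"), background = bg),
               "empty")
  # overlap above the gene-count threshold but expected by chance:
  # 6 of 10 pathway genes hit a disease set covering 60% of the background
  dis60 <- gene_set("dis", sprintf("G%03d", 1:60))
  pc2 <- pathway_collection(list(CHANCE = sprintf("G%03d", c(1:6, 90:93))),
                            source = "unit")
  res2 <- pathway_enrichment(pc2, dis60, background = bg)
  expect_equal(res2$overlap_count, 6L)
  expect_lte(res2$score, 2)
  expect_false(res2$passes_filter)
})

test_that("pathway link sets are the induced edges", {
  tri <- triangle_net()
  expect_equal(pathway_link_set(tri, c("A", "B")), "A\tB")
  expect_equal(length(pathway_link_set(tri, c("A", "B", "C"))), 3L)
  expect_equal(length(pathway_link_set(tri, c("A"))), 0L)
  expect_equal(length(pathway_link_set(path_net(), c("A", "C"))), 0L)
})

test_that("crosstalk evaluates all pairs with consistent contingency input", {
  net <- cached_fixture()$network
  nodes <- igraph::V(net)$name
  pw24 <- lapply(1:24, function(i) nodes[((i - 1) * 30 + 1):(i * 30)])
  names(pw24) <- sprintf("Q%02d", 1:24)
  ct <- crosstalk_all_pairs(pathway_collection(pw24, "unit"), net)
  expect_equal(nrow(ct), choose(24L, 2L))  # 276 pairs from 24 pathways
  expect_true(all(ct$n_common_nodes <= ct$total_nodes))
  expect_true(all(ct$p_min == pmin(ct$p_nodes, ct$p_links)))
  expect_true(all(ct$q_nodes >= ct$p_nodes - 1e-12))

  pw <- list(A = nodes[1:20], B = nodes[1:20], C = nodes[30:49],
             D = nodes[60:79])
  ct2 <- crosstalk_all_pairs(pathway_collection(pw, "unit"), net)
  ab <- ct2[ct2$pathway_a == "A" & ct2$pathway_b == "B", ]
  expect_equal(ab$n_common_nodes, 20L)
  expect_equal(ab$total_nodes, 40L)  # identical pathways: n = N/2
  expect_equal(min(ct2$p_nodes), ab$p_nodes)
  cd <- ct2[ct2$pathway_a == "C" & ct2$pathway_b == "D", ]
  expect_equal(cd$n_common_nodes, 0L)
  expect_gte(cd$p_nodes, ab$p_nodes)
  expect_false(cd$significant)
  expect_error(crosstalk_all_pairs(pathway_collection(pw[1:2], "u"), net),
               ">= 3")
})

test_that("crosstalk graph mirrors the significant pairs", {
  df <- data.frame(pathway_a = c("P1", "P1", "P2"),
                   pathway_b = c("P2", "P3", "P3"),
                   significant = c(TRUE, FALSE, TRUE))
  class(df) <- c("crosstalk_result", "data.frame")
  g <- crosstalk_graph(df, scores = c(P1 = 3, P2 = 4, P3 = 5))
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 2L)
  expect_equal(igraph::V(g)$score[igraph::V(g)$name == "P2"], 4)
  df$significant <- FALSE
  expect_equal(igraph::ecount(crosstalk_graph(df)), 0L)
  df$significant <- TRUE
  expect_equal(igraph::ecount(crosstalk_graph(df)), 3L)
})

test_that("planted pathway overlap is detected, disjoint pathways are not", {
  cfg <- small_config()
  net <- generate_interactome(cfg)
  n_rep <- 40L
  hit_planted <- 0L; false_flags <- 0L; n_null_pairs <- 0L
  for (r in seq_len(n_rep)) {
    pcs <- generate_pathways(net, list(
      count = 6L, size_range = c(20L, 30L),
      overlaps = data.frame(a = 1L, b = 2L, jaccard = 0.4),
      disjoint = TRUE), seed = 3000L + r)
    ct <- crosstalk_all_pairs(pcs, net, alpha = 0.01)
    planted <- ct$pathway_a == "PW01" & ct$pathway_b == "PW02"
    hit_planted <- hit_planted + ct$significant[planted]
    false_flags <- false_flags + sum(ct$significant[!planted])
    n_null_pairs <- n_null_pairs + sum(!planted)
  }
  expect_gte(hit_planted / n_rep, 0.9)
  expect_lte(false_flags / n_null_pairs, 0.05)
})

test_that("an enriched pathway reliably passes the filter", {
  withr::with_seed(99L, {
    bg_genes <- sprintf("B%04d", 1:2000)
    hits <- 0L
    for (r in 1:60) {
      dis <- sample(bg_genes, 100L)
      pw <- c(sample(dis, 10L), sample(setdiff(bg_genes, dis), 40L))
      pc <- pathway_collection(list(PL = pw), source = "sim")
      res <- pathway_enrichment(pc, gene_set("d", dis),
                                background = gene_set("bg", bg_genes))
      hits <- hits + res$passes_filter[1L]
    }
    expect_gte(hits / 60, 0.95)
  })
})
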