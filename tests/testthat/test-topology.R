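test_that("topology summary reproduces hand-worked path and triangle cases", {
  p <- path_net()
  ts <- summarize_topology(p, gene_set("s", "A"), hub_cutoff = 2L)
  expect_equal(unname(ts$characteristic_spd["A"]), 1.5)

  ts2 <- summarize_topology(p, gene_set("s", c("A", "C")), hub_cutoff = 2L)
  expect_equal(unname(ts2$global_centrality["A"]), 2)
  expect_equal(unname(ts2$global_centrality["C"]), 2)

  tri <- triangle_net()
  ts3 <- summarize_topology(tri, gene_set("s", c("A", "B", "C")),
                            hub_cutoff = 2L)
  expect_equal(ts3$average_degree, 2)
  expect_equal(ts3$hub_fraction, 1.0)
  expect_error(summarize_topology(tri, gene_set("s", "Z")), "maps")
})

test_that("characteristic SPD excludes unreachable pairs and counts them", {
  g <- as_interactome(rbind(c("A", "B"), c("B", "C"), c("X", "Y")))
  ts <- summarize_topology(g, gene_set("s", c("A", "X")), hub_cutoff = 1L)
  expect_equal(unname(ts$characteristic_spd["A"]), 1.5)  # B at 1, C at 2
  expect_equal(unname(ts$characteristic_spd["X"]), 1)    # only Y reachable
  expect_true(ts$excluded_pairs[["characteristic_spd"]] > 0)
})

test_that("hub cutoff follows the tail-fraction rule", {
  # 20 of 100 nodes at degree >= 8, 25 at degree >= 6, none at degree 7:
  # the smallest integer degree whose upper-tail share is <= 0.21 is 7
  degseq <- c(rep(8L, 20L), rep(6L, 5L), rep(2L, 75L))
  g <- as_interactome(igraph::realize_degseq(degseq, method = "smallest"))
  expect_equal(as.integer(hub_cutoff_auto(g, 0.21)), 7L)
  expect_equal(as.integer(hub_cutoff_auto(g, 1.0)), min(igraph::degree(g)))
  expect_error(hub_cutoff_auto(complete_net(4L)), "degenerate")
})

test_that("degree interval table uses half-open width-3 bins", {
  dt <- degree_interval_table(c(4, 5, 6, 7, 9, 10), width = 3L, origin = 1L)
  r47 <- dt[dt$interval == "[4,7)", ]
  expect_equal(r47$count, 3L)
  r710 <- dt[dt$interval == "[7,10)", ]
  expect_equal(r710$count, 2L)
  expect_equal(sum(dt$count), 6L)
})

test_that("resampling p-values hit their extremes and are reproducible", {
  g <- star_net(6L)
  # no 2-node sample can average above the hub degree
  r0 <- resample_empirical_p(g, "average_degree", observed = 10, set_size = 2L,
                             direction = "greater", n_reps = 50L, seed = 3L)
  expect_equal(r0$empirical_p, 0)
  # every sample beats an observed value below the minimum degree
  r1 <- resample_empirical_p(g, "average_degree", observed = 0.5,
                             set_size = 2L, direction = "greater",
                             n_reps = 50L, seed = 3L)
  expect_equal(r1$empirical_p, 1)
  expect_error(resample_empirical_p(g, "average_degree", 1, set_size = 100L),
               "exceeds")
  ra <- resample_empirical_p(g, "average_degree", 2, 3L, n_reps = 30L,
                             seed = 11L)
  rb <- resample_empirical_p(g, "average_degree", 2, 3L, n_reps = 30L,
                             seed = 11L)
  expect_identical(ra$null_values, rb$null_values)
  expect_equal(ra$empirical_p, ra$n_exceeding / ra$n_reps)
})

test_that("for fixed draws, empirical p is monotone in the observed value", {
  g <- random_connected_net(40L, 80L, seed = 5L)
  obs_grid <- seq(1, 8, by = 0.5)
  ps <- vapply(obs_grid, function(o)
    resample_empirical_p(g, "average_degree", o, 10L, "greater",
                         n_reps = 100L, seed = 21L)$empirical_p, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("a degree-squared-biased planted set is detected by resampling", {
  cfg <- small_config()
  net <- generate_interactome(cfg)
  planted <- plant_gene_set(net, "hubs", 60L, degree_bias_exponent = 2,
                            seed = 77L)
  obs <- mean(igraph::degree(net, planted$members))
  r <- resample_empirical_p(net, "average_degree", obs, 60L, "greater",
                            n_reps = 1000L, seed = 13L)
  expect_lte(r$empirical_p, 0.01)
})

test_that("path statistics can be resampled too", {
  g <- random_connected_net(30L, 60L, seed = 8L)
  for (st in c("characteristic_spd", "global_centrality",
               "clustering_coefficient")) {
    r <- resample_empirical_p(g, st, observed = 1, set_size = 5L,
                              direction = "less", n_reps = 20L, seed = 2L)
    expect_true(r$empirical_p >= 0 && r$empirical_p <= 1)
    expect_equal(r$n_reps, 20L)
  }
})

test_that("Wilcoxon rank-sum matches exact enumeration and symmetry cases", {
  p <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(as.numeric(p), 0.1)
  expect_equal(attr(p, "method"), "exact-enumeration")
  expect_equal(as.numeric(wilcoxon_rank_sum(c(1, 2), c(1, 2))), 1.0)
  expect_equal(as.numeric(wilcoxon_rank_sum(1, 2)), 1.0)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
  # agreement with the reference exact implementation on tie-free data
  withr::with_seed(42L, {
    for (i in 1:5) {
      a <- sample(100L, 6L); b <- sample(200L, 7L) + 0.5
      expect_equal(as.numeric(wilcoxon_rank_sum(a, b)),
                   stats::wilcox.test(a, b, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  })
  # large samples fall back to the tie-corrected normal approximation
  big <- wilcoxon_rank_sum(rnorm(30), rnorm(30))
  expect_equal(attr(big, "method"), "normal-approximation")
})

test_that("planted degree-bias ordering of the five sets is reproduced", {
  fix <- cached_fixture()
  md <- vapply(fix$gene_sets, function(s)
    mean(igraph::degree(fix$network, s$members)), numeric(1))
  expect_true(md[["cancer_like"]] > md[["essential_like"]])
  expect_true(md[["essential_like"]] > md[["disease_like"]])
  expect_true(md[["disease_like"]] > md[["neuro_like"]])
  expect_true(md[["neuro_like"]] > md[["neutral"]])
})
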