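#' Assemble a pipeline run configuration
#'
#' Exactly one of `synthetic` (a [synthetic_config()]) or `network_path`
#' must be supplied.  File-based runs read the interactome, gene-set files
#' (one gene per line), an optional GMT pathway collection and an optional
#' pair of gene-level GWAS TSVs.
#'
#' @param synthetic `synthetic_config` for a fully synthetic run, or NULL.
#' @param network_path interactome file for a file-based run, or NULL.
#' @param gene_set_paths named character vector of gene-set file paths.
#' @param gmt_path optional GMT file path.
#' @param gwas_paths optional length-2 character vector of GWAS TSV paths.
#' @param disease_set name of the gene set used as disease/terminal set.
#' @param n_reps resampling and null-model replicates (default 1000).
#' @param resample_statistics statistics to test by resampling per set.
#' @param k_range clique-percolation sizes (default 3:7).
#' @param tail_fraction hub-cutoff tail fraction (default 0.21).
#' @param crosstalk_alpha crosstalk threshold on `p_min` (default 0.01).
#' @param gwas_alpha per-study GWAS threshold (default 0.05).
#' @param n_sets,n_repeats GWAS randomization scale (defaults 1000, 10).
#' @param seed master seed governing all pipeline randomness.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, network_path = NULL,
                            gene_set_paths = NULL, gmt_path = NULL,
                            gwas_paths = NULL, disease_set = "disease_like",
                            n_reps = 1000L,
                            resample_statistics = c("average_degree",
                                                    "clustering_coefficient"),
                            k_range = 3:7, tail_fraction = 0.21,
                            crosstalk_alpha = 0.01, gwas_alpha = 0.05,
                            n_sets = 1000L, n_repeats = 10L, seed = 1L) {
  if (is.null(synthetic) == is.null(network_path))
    stop("supply exactly one of 'synthetic' or 'network_path'")
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_config"))
  if (!is.null(gwas_paths)) stopifnot(length(gwas_paths) == 2L)
  structure(list(synthetic = synthetic, network_path = network_path,
                 gene_set_paths = gene_set_paths, gmt_path = gmt_path,
                 gwas_paths = gwas_paths, disease_set = disease_set,
                 n_reps = as.integer(n_reps),
                 resample_statistics = resample_statistics,
                 k_range = as.integer(k_range),
                 tail_fraction = tail_fraction,
                 crosstalk_alpha = crosstalk_alpha,
                 gwas_alpha = gwas_alpha, n_sets = as.integer(n_sets),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a JSON file
#'
#' JSON fields mirror the arguments of [pipeline_config()]; a
#' `"synthetic": true` field (or a nested object of [synthetic_config()]
#' overrides) requests a synthetic run.
#'
#' @param path JSON file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  syn <- NULL
  if (isTRUE(j$synthetic)) {
    syn <- synthetic_config()
  } else if (is.list(j$synthetic)) {
    syn <- do.call(synthetic_config, j$synthetic)
  }
  args <- j[setdiff(names(j), "synthetic")]
  do.call(pipeline_config, c(list(synthetic = syn), args))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: data loading/generation, per-set topology
#' with resampling significance, Steiner subnetwork extraction with the
#' Erdos-Renyi non-randomness test, k-clique percolation on the
#' subnetwork, pathway enrichment and crosstalk, and GWAS-based candidate
#' prioritization.  Every stage writes TSV/GraphML artifacts into `outdir`
#' and contributes a block to the JSON report (`report.json`), which
#' records every statistic with its seed and parameters.  A `MANIFEST.tsv`
#' of completed stages is maintained as the run progresses, so partial
#' output survives a failing stage.  Reruns with an identical configuration
#' are byte-identical.
#'
#' @param config `pipeline_config` or path to a JSON configuration.
#' @param outdir output directory (created if missing).
#' @param stages subset of
#'   `c("topology", "subnet", "communities", "pathways", "gwas")`.
#' @param quiet suppress progress messages (default FALSE).
#' @return the report, invisibly.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("topology", "subnet", "communities",
                                    "pathways", "gwas"),
                         quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  note <- function(...) if (!quiet) message(sprintf(...))
  done <- character(0)
  manifest <- function() .write_tsv(
    data.frame(stage = done, status = rep("complete", length(done))),
    file.path(outdir, "MANIFEST.tsv"))
  report <- list(schema_version = "1.0",
                 parameters = config[setdiff(names(config), "synthetic")],
                 stages = list())

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e) {
      manifest()
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    note("stage %-12s %.1fs", name, proc.time()[["elapsed"]] - t0)
    done <<- c(done, name)
    manifest()
    out
  }

  # ---- data ----
  env <- new.env()
  run_stage("data", function() {
    if (!is.null(config$synthetic)) {
      fix <- generate_fixture(config$synthetic)
      env$net <- fix$network
      env$sets <- fix$gene_sets
      env$pc <- fix$pathways
      env$gwas <- fix$gwas
      env$sres <- fix$disease_subnet
    } else {
      env$net <- read_network(config$network_path)
      env$sets <- lapply(config$gene_set_paths, read_gene_set)
      for (nm in names(env$sets)) env$sets[[nm]]$name <- nm
      env$pc <- if (!is.null(config$gmt_path)) read_gmt(config$gmt_path)
      env$gwas <- if (!is.null(config$gwas_paths)) list(
        a = read_gwas_table(config$gwas_paths[1L]),
        b = read_gwas_table(config$gwas_paths[2L]))
      env$sres <- NULL
    }
    if (!config$disease_set %in% names(env$sets))
      stop("disease set '", config$disease_set, "' not among gene sets")
    write_network(env$net, file.path(outdir, "network.tsv"), "edgelist")
    for (nm in names(env$sets))
      writeLines(env$sets[[nm]]$members,
                 file.path(outdir, paste0("geneset_", nm, ".txt")))
    report$stages$data <<- list(
      n_nodes = igraph::vcount(env$net), n_edges = igraph::ecount(env$net),
      gene_sets = lapply(env$sets, function(s) length(s$members)),
      synthetic = !is.null(config$synthetic))
    NULL
  })

  disease <- env$sets[[config$disease_set]]

  # ---- topology ----
  if ("topology" %in% stages) run_stage("topology", function() {
    cutoff <- hub_cutoff_auto(env$net, config$tail_fraction)
    rows <- list(); hist_rows <- list(); wrows <- list()
    blocks <- list()
    deg_by_set <- list()
    for (i in seq_along(env$sets)) {
      nm <- names(env$sets)[i]
      ts <- summarize_topology(env$net, env$sets[[i]],
                               hub_cutoff = as.integer(cutoff))
      tests <- list()
      for (j in seq_along(config$resample_statistics)) {
        st <- config$resample_statistics[j]
        obs <- switch(st,
          average_degree = ts$average_degree,
          clustering_coefficient =
            mean(vapply(names(ts$per_gene_degree), function(g)
              clustering_coefficient(env$net, g), numeric(1))),
          characteristic_spd = mean(ts$characteristic_spd, na.rm = TRUE),
          global_centrality = mean(ts$global_centrality, na.rm = TRUE))
        dirn <- if (st %in% c("characteristic_spd", "global_centrality"))
          "less" else "greater"
        tests[[st]] <- resample_empirical_p(
          env$net, st, obs, ts$n_mapped, direction = dirn,
          n_reps = config$n_reps,
          seed = derive_seed(config$seed, 100L + 10L * i + j))
      }
      rows[[nm]] <- write_topology_tsv(
        ts, tests, file.path(outdir, paste0("topology_", nm, ".tsv")))
      hist_rows[[nm]] <- data.frame(
        set = nm, degree = as.integer(names(ts$degree_histogram)),
        count = as.integer(ts$degree_histogram))
      blocks[[nm]] <- list(
        n_mapped = ts$n_mapped, average_degree = ts$average_degree,
        mean_characteristic_spd = mean(ts$characteristic_spd, na.rm = TRUE),
        mean_global_centrality = mean(ts$global_centrality, na.rm = TRUE),
        hub_cutoff = ts$hub_cutoff, hub_fraction = ts$hub_fraction,
        empirical_tests = lapply(tests, function(t)
          t[c("statistic_name", "observed", "n_reps", "n_exceeding",
              "empirical_p", "direction", "seed")]))
      deg_by_set[[nm]] <- ts$per_gene_degree
    }
    for (nm in setdiff(names(env$sets), config$disease_set)) {
      p <- wilcoxon_rank_sum(deg_by_set[[config$disease_set]],
                             deg_by_set[[nm]])
      wrows[[nm]] <- data.frame(set_a = config$disease_set, set_b = nm,
                                statistic = "degree", p_value = as.numeric(p),
                                method = attr(p, "method"))
    }
    .write_tsv(do.call(rbind, rows), file.path(outdir, "topology.tsv"))
    .write_tsv(do.call(rbind, hist_rows),
               file.path(outdir, "degree_histogram.tsv"))
    .write_tsv(do.call(rbind, wrows), file.path(outdir, "wilcoxon.tsv"))
    report$stages$topology <<- list(
      hub_cutoff = as.integer(cutoff),
      tail_fraction = config$tail_fraction, sets = blocks,
      wilcoxon_vs_disease = lapply(wrows, function(r)
        list(set_b = r$set_b, p_value = r$p_value, method = r$method)))
    NULL
  })

  # ---- subnet ----
  if ("subnet" %in% stages) run_stage("subnet", function() {
    sres <- env$sres
    if (is.null(sres))
      sres <- steiner_subnetwork(env$net, disease,
                                 include_induced_edges = TRUE)
    env$sres <- sres
    write_network(sres$subnetwork, file.path(outdir, "subnetwork.tsv"),
                  "edgelist")
    write_network(sres$subnetwork, file.path(outdir, "subnetwork.graphml"),
                  "graphml")
    nulls <- nonrandomness_test(sres$subnetwork, n_reps = config$n_reps,
                                seed = derive_seed(config$seed, 200L))
    .write_tsv(as.data.frame(nulls), file.path(outdir, "null_model.tsv"))
    report$stages$subnet <<- list(
      method = sres$method,
      n_nodes = igraph::vcount(sres$subnetwork),
      n_edges = igraph::ecount(sres$subnetwork),
      n_terminals = length(sres$terminals_included),
      n_steiner_nodes = length(sres$steiner_nodes),
      n_unreachable = length(sres$terminals_unreachable),
      tree_edge_count = sres$tree_edge_count,
      null_model = list(n_reps = attr(nulls, "n_reps"),
                        seed = attr(nulls, "seed"),
                        metrics = as.data.frame(nulls)))
    NULL
  })

  # ---- communities ----
  if ("communities" %in% stages) run_stage("communities", function() {
    if (is.null(env$sres)) stop("communities stage requires subnet stage")
    sg <- env$sres$subnetwork
    rows <- list()
    for (k in config$k_range) {
      cs <- clique_percolation(sg, k)
      for (nm in names(env$sets)) {
        mf <- tryCatch(membership_fraction(cs, env$sets[[nm]]),
                       error = function(e) NA_real_)
        rows[[paste(k, nm)]] <- data.frame(
          k = k, set = nm, clique_count = cs$clique_count,
          n_communities = length(cs$communities),
          nodes_in_communities = length(cs$nodes_in_communities),
          membership_fraction = mf)
      }
    }
    df <- do.call(rbind, rows)
    .write_tsv(df, file.path(outdir, "communities.tsv"))
    report$stages$communities <<- list(k_range = config$k_range, table = df)
    NULL
  })

  # ---- pathways ----
  if ("pathways" %in% stages) run_stage("pathways", function() {
    if (is.null(env$pc)) {
      report$stages$pathways <<- list(skipped = "no pathway collection")
      return(NULL)
    }
    bg <- gene_set("background",
                   union(igraph::V(env$net)$name,
                         unlist(env$pc$pathways)))
    enr <- pathway_enrichment(env$pc, disease, background = bg)
    .write_tsv(enr, file.path(outdir, "enrichment.tsv"))
    passing <- enr$pathway[enr$passes_filter]
    blk <- list(n_pathways = length(env$pc$pathways),
                n_passing = length(passing), passing = passing,
                enrichment = enr)
    if (length(passing) >= 3L) {
      sub_pc <- pathway_collection(env$pc$pathways[passing],
                                   source = env$pc$source)
      ct <- crosstalk_all_pairs(sub_pc, env$net,
                                alpha = config$crosstalk_alpha)
      .write_tsv(ct, file.path(outdir, "crosstalk.tsv"))
      scores <- stats::setNames(enr$score, enr$pathway)
      write_network(crosstalk_graph(ct, scores),
                    file.path(outdir, "crosstalk.graphml"), "graphml")
      blk$n_pairs <- nrow(ct)
      blk$n_significant <- sum(ct$significant)
      blk$crosstalk_alpha <- config$crosstalk_alpha
      blk$significant_pairs <- ct[ct$significant,
                                  c("pathway_a", "pathway_b", "p_min")]
    } else {
      blk$crosstalk <- "skipped: fewer than 3 enriched pathways"
    }
    report$stages$pathways <<- blk
    NULL
  })

  # ---- gwas ----
  if ("gwas" %in% stages) run_stage("gwas", function() {
    if (is.null(env$gwas)) {
      report$stages$gwas <<- list(skipped = "no GWAS tables")
      return(NULL)
    }
    if (is.null(env$sres)) stop("gwas stage requires subnet stage")
    sg <- env$sres$subnetwork
    a <- env$gwas$a; b <- env$gwas$b
    joint <- joint_significant_genes(igraph::V(sg)$name, a, b,
                                     alpha = config$gwas_alpha)
    universe <- intersect(names(a$p_by_gene), names(b$p_by_gene))
    rand <- enrichment_randomization(
      universe, igraph::vcount(sg), length(joint), a, b,
      alpha = config$gwas_alpha, n_sets = config$n_sets,
      n_repeats = config$n_repeats, seed = derive_seed(config$seed, 300L))
    pri <- nominate_candidates(sg, disease, joint)
    cand <- pri$novel_candidates
    cand_df <- data.frame(
      gene = cand,
      p_a = unname(a$p_by_gene[cand]), p_b = unname(b$p_by_gene[cand]),
      seed_neighbors = vapply(cand, function(g)
        sum(names(igraph::neighbors(sg, g)) %in% disease$members),
        numeric(1)))
    .write_tsv(cand_df, file.path(outdir, "candidates.tsv"))
    ego_rows <- lapply(cand, function(g) {
      el <- igraph::as_edgelist(pri$ego_subnetworks[[g]], names = TRUE)
      if (nrow(el) == 0L) return(NULL)
      data.frame(candidate = g, from = pmin(el[, 1L], el[, 2L]),
                 to = pmax(el[, 1L], el[, 2L]))
    })
    ego_df <- do.call(rbind, ego_rows)
    if (is.null(ego_df))
      ego_df <- data.frame(candidate = character(0), from = character(0),
                           to = character(0))
    .write_tsv(ego_df, file.path(outdir, "ego_subnetworks.tsv"))
    .write_tsv(data.frame(repeat_index = seq_along(rand$empirical_p_per_repeat),
                          empirical_p = rand$empirical_p_per_repeat),
               file.path(outdir, "gwas_randomization.tsv"))
    report$stages$gwas <<- list(
      alpha = config$gwas_alpha, universe_size = rand$universe_size,
      set_size = igraph::vcount(sg),
      joint_significant_count = length(joint),
      novel_candidate_count = length(cand),
      novel_candidates = cand,
      mean_joint_count_random = rand$mean_joint_count,
      empirical_p_per_repeat = rand$empirical_p_per_repeat,
      n_sets = rand$n_sets, n_repeats = rand$n_repeats, seed = rand$seed,
      caveat = rand$caveat)
    NULL
  })

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE,
                       dataframe = "columns", null = "null")
  invisible(report)
}
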