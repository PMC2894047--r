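#' Degree-distribution hub cutoff
#'
#' The hub cutoff is operationalized as the smallest degree `d` at which the
#' cumulative fraction of nodes with degree `>= d` first drops to at most
#' `tail_fraction` (default 0.21, the hub share reported for the human
#' interactome at its degree-13 cutoff).  A manual cutoff can always be
#' supplied to [summarize_topology()] instead, and is the recommended mode
#' for replication work.
#'
#' @param net igraph network with at least 3 distinct degree values.
#' @param tail_fraction target upper-tail share in `(0, 1]`.
#' @return integer degree cutoff, with attributes `method` and
#'   `tail_fraction`.
#' @export
hub_cutoff_auto <- function(net, tail_fraction = 0.21) {
  stopifnot(tail_fraction > 0, tail_fraction <= 1)
  degs <- igraph::degree(net)
  if (length(unique(degs)) < 3L)
    stop("degenerate degree distribution: need >= 3 distinct degree values")
  n <- length(degs)
  dd <- min(degs):max(degs)
  ccdf <- vapply(dd, function(d) sum(degs >= d) / n, numeric(1))
  hit <- which(ccdf <= tail_fraction)
  if (length(hit) == 0L)
    stop("no degree reaches tail fraction ", tail_fraction)
  structure(as.integer(dd[hit[1L]]),
            method = "tail-fraction", tail_fraction = tail_fraction)
}

#' Topology summary of a gene set in a network
#'
#' For every mapped member the summary reports its degree, its
#' characteristic shortest-path distance (mean hops to every other reachable
#' node in the whole network), and its global centrality (mean hops to every
#' other reachable mapped member of the same set, paths free to traverse
#' non-member nodes).  Unreachable pairs are excluded from the averages and
#' counted in `excluded_pairs`.
#'
#' @param net igraph network.
#' @param gs `gene_set`; at least one member must map into `net`.
#' @param hub_cutoff integer degree cutoff, or `"auto"` to derive one from
#'   the degree distribution via [hub_cutoff_auto()].
#' @param tail_fraction passed to [hub_cutoff_auto()] when `hub_cutoff` is
#'   `"auto"`.
#' @return an object of class `topology_summary`.
#' @export
summarize_topology <- function(net, gs, hub_cutoff = "auto",
                               tail_fraction = 0.21) {
  mapped <- map_gene_set(net, gs)
  members <- mapped$members
  if (length(members) == 0L)
    stop("no member of '", gs$name, "' maps into the network")
  degs_all <- igraph::degree(net)
  per_gene_degree <- degs_all[members]
  D <- igraph::distances(net, v = members)
  fin <- is.finite(D)
  # characteristic SPD: mean over reachable non-self targets
  n_reach <- rowSums(fin) - 1L
  spd <- ifelse(n_reach > 0, (rowSums(ifelse(fin, D, 0))) / pmax(n_reach, 1L),
                NA_real_)
  names(spd) <- members
  excluded_spd <- sum(!fin)
  # global centrality: restrict targets to the mapped members
  Dm <- D[, members, drop = FALSE]
  finm <- is.finite(Dm)
  n_reach_m <- rowSums(finm) - 1L
  gc <- ifelse(n_reach_m > 0,
               rowSums(ifelse(finm, Dm, 0)) / pmax(n_reach_m, 1L), NA_real_)
  names(gc) <- members
  excluded_gc <- sum(!finm)
  cutoff <- if (identical(hub_cutoff, "auto")) {
    hub_cutoff_auto(net, tail_fraction)
  } else {
    as.integer(hub_cutoff)
  }
  structure(list(
    set_name = gs$name,
    n_mapped = length(members),
    n_unmapped = attr(mapped, "n_unmapped"),
    per_gene_degree = per_gene_degree,
    average_degree = mean(per_gene_degree),
    degree_histogram = table(per_gene_degree),
    characteristic_spd = spd,
    global_centrality = gc,
    excluded_pairs = c(characteristic_spd = excluded_spd,
                       global_centrality = excluded_gc),
    hub_cutoff = as.integer(cutoff),
    hub_cutoff_method = attr(cutoff, "method") %||% "manual",
    hub_fraction = mean(per_gene_degree >= as.integer(cutoff))
  ), class = "topology_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.topology_summary <- function(x, ...) {
  cat("<topology_summary>", x$set_name, "\n",
      " mapped genes:      ", x$n_mapped, " (", x$n_unmapped, " unmapped)\n",
      " average degree:    ", round(x$average_degree, 2), "\n",
      " mean char. SPD:    ", round(mean(x$characteristic_spd, na.rm = TRUE), 2), "\n",
      " mean glob. centr.: ", round(mean(x$global_centrality, na.rm = TRUE), 2), "\n",
      " hub cutoff / frac: ", x$hub_cutoff, " / ", round(x$hub_fraction, 3), "\n",
      sep = "")
  invisible(x)
}

#' Tabulate a degree vector into half-open intervals
#'
#' Formatting helper reproducing interval-of-3 degree tables: bins
#' `[origin + i*width, origin + (i+1)*width)`.
#'
#' @param degrees integer vector of degrees.
#' @param width bin width (default 3).
#' @param origin left edge of the first bin (default 1).
#' @return data.frame with columns `interval`, `lo`, `hi`, `count`,
#'   `fraction`.
#' @export
degree_interval_table <- function(degrees, width = 3L, origin = 1L) {
  stopifnot(width >= 1L)
  degrees <- as.integer(degrees)
  bin <- (degrees - origin) %/% width
  bins <- seq(min(bin), max(bin))
  count <- vapply(bins, function(b) sum(bin == b), integer(1))
  lo <- origin + bins * width
  data.frame(interval = sprintf("[%d,%d)", lo, lo + width),
             lo = lo, hi = lo + width, count = count,
             fraction = count / length(degrees))
}

# Statistic evaluators over a node sample; degree and clustering work off
# precomputed per-node vectors, the two path statistics need fresh BFS runs.
.resample_stat_fun <- function(net, statistic) {
  switch(statistic,
    average_degree = {
      degs <- igraph::degree(net)
      function(s) mean(degs[s])
    },
    clustering_coefficient = {
      cc <- igraph::transitivity(net, type = "localundirected",
                                 isolates = "zero")
      names(cc) <- igraph::V(net)$name
      function(s) mean(cc[s])
    },
    characteristic_spd = function(s) {
      D <- igraph::distances(net, v = s)
      fin <- is.finite(D)
      n_reach <- rowSums(fin) - 1L
      mean(rowSums(ifelse(fin, D, 0))[n_reach > 0] / n_reach[n_reach > 0])
    },
    global_centrality = function(s) {
      D <- igraph::distances(net, v = s, to = s)
      fin <- is.finite(D)
      n_reach <- rowSums(fin) - 1L
      mean(rowSums(ifelse(fin, D, 0))[n_reach > 0] / n_reach[n_reach > 0])
    },
    stop("unknown statistic: ", statistic))
}

#' Resampling empirical p-value for a gene-set statistic
#'
#' Draws `n_reps` uniform node samples of the observed set's size (without
#' replacement, from all network nodes) and counts draws whose statistic is
#' strictly more extreme than the observed value in the stated direction.
#' The empirical p-value is `n_exceeding / n_reps`, so `p = 0` means no
#' random set was more extreme and `p = 1` means every random set was.
#'
#' @param net igraph network.
#' @param statistic one of `"average_degree"`, `"characteristic_spd"`,
#'   `"global_centrality"`, `"clustering_coefficient"`.
#' @param observed observed value of the statistic.
#' @param set_size number of genes to draw per replicate.
#' @param direction `"greater"` counts replicates exceeding `observed`,
#'   `"less"` counts replicates below it.
#' @param n_reps number of resampling replicates (default 1000).
#' @param seed integer RNG seed.
#' @return an object of class `empirical_test` with fields `statistic_name`,
#'   `observed`, `n_reps`, `n_exceeding`, `empirical_p`, `direction`, `seed`
#'   and the vector of `null_values`.
#' @export
resample_empirical_p <- function(net, statistic, observed, set_size,
                                 direction = c("greater", "less"),
                                 n_reps = 1000L, seed = 1L) {
  direction <- match.arg(direction)
  statistic <- match.arg(statistic, c("average_degree", "characteristic_spd",
                                      "global_centrality",
                                      "clustering_coefficient"))
  nodes <- igraph::V(net)$name
  if (set_size > length(nodes))
    stop("set_size (", set_size, ") exceeds node count (", length(nodes), ")")
  stopifnot(set_size >= 1L, n_reps >= 1L)
  f <- .resample_stat_fun(net, statistic)
  null_values <- withr::with_seed(seed, vapply(seq_len(n_reps), function(i) {
    f(sample(nodes, set_size))
  }, numeric(1)))
  n_exc <- if (direction == "greater") sum(null_values > observed)
           else sum(null_values < observed)
  structure(list(statistic_name = statistic, observed = observed,
                 n_reps = as.integer(n_reps), n_exceeding = as.integer(n_exc),
                 empirical_p = n_exc / n_reps, direction = direction,
                 seed = as.integer(seed), null_values = null_values),
            class = "empirical_test")
}

#' @export
print.empirical_test <- function(x, ...) {
  cat("<empirical_test>", x$statistic_name,
      sprintf("observed=%.4g", x$observed),
      sprintf("p=%g (%d/%d, direction=%s, seed=%d)\n", x$empirical_p,
              x$n_exceeding, x$n_reps, x$direction, x$seed))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Uses exact enumeration over all rank assignments when the combined sample
#' size is at most 20 (ties handled through midranks), and the
#' tie-corrected normal approximation otherwise.  The method used is
#' recorded in the `"method"` attribute of the returned p-value.
#'
#' @param values_a,values_b non-empty numeric vectors.
#' @return two-sided p-value with attribute `method`.
#' @export
wilcoxon_rank_sum <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop("both samples must be non-empty")
  n <- length(values_a)
  N <- n + length(values_b)
  if (N <= 20L) {
    r <- rank(c(values_a, values_b))
    W <- sum(r[seq_len(n)])
    combos <- utils::combn(N, n)
    Wnull <- colSums(matrix(r[combos], nrow = n))
    eps <- sqrt(.Machine$double.eps)
    p_le <- mean(Wnull <= W + eps)
    p_ge <- mean(Wnull >= W - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    attr(p, "method") <- "exact-enumeration"
  } else {
    p <- stats::wilcox.test(values_a, values_b, exact = FALSE,
                            correct = TRUE)$p.value
    attr(p, "method") <- "normal-approximation"
  }
  p
}

#' Write a topology summary (plus optional empirical tests) as TSV
#'
#' One row per statistic: observed value, empirical p, replicate count and
#' seed where a resampling test was run.
#'
#' @param ts `topology_summary`.
#' @param tests optional named list of `empirical_test` objects keyed by
#'   statistic name.
#' @param path output TSV path.
#' @return the summary data.frame, invisibly.
#' @export
write_topology_tsv <- function(ts, tests = list(), path) {
  obs <- c(average_degree = ts$average_degree,
           characteristic_spd = mean(ts$characteristic_spd, na.rm = TRUE),
           global_centrality = mean(ts$global_centrality, na.rm = TRUE),
           hub_fraction = ts$hub_fraction)
  df <- data.frame(set = ts$set_name, statistic = names(obs),
                   observed = unname(obs),
                   empirical_p = NA_real_, n_reps = NA_integer_,
                   seed = NA_integer_, stringsAsFactors = FALSE)
  for (nm in names(tests)) {
    i <- match(nm, df$statistic)
    if (!is.na(i)) {
      df$empirical_p[i] <- tests[[nm]]$empirical_p
      df$n_reps[i] <- tests[[nm]]$n_reps
      df$seed[i] <- tests[[nm]]$seed
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
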