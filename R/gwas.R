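#' Create a gene-level GWAS p-value table
#'
#' One smallest association p-value per gene for one study.
#'
#' @param study_name label for the study.
#' @param genes character vector of gene identifiers.
#' @param p numeric vector in `(0, 1]`, parallel to `genes`.
#' @return an object of class `gwas_table` with fields `study_name` and
#'   `p_by_gene` (named numeric vector).
#' @export
gwas_table <- function(study_name, genes, p) {
  genes <- toupper(trimws(as.character(genes)))
  if (length(genes) != length(p)) stop("genes and p differ in length")
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  names(p) <- genes
  structure(list(study_name = as.character(study_name),
                 p_by_gene = p[order(genes)]),
            class = "gwas_table")
}

#' @export
print.gwas_table <- function(x, ...) {
  cat("<gwas_table>", x$study_name, "-", length(x$p_by_gene), "genes\n")
  invisible(x)
}

#' Read a two-column gene/p TSV into a GWAS table
#'
#' @param path TSV path with columns gene and p (header optional; a first
#'   line whose second field is non-numeric is treated as a header).
#' @param study_name label; defaults to the file name without extension.
#' @return a `gwas_table`.
#' @export
read_gwas_table <- function(path, study_name = NULL) {
  if (is.null(study_name))
    study_name <- tools::file_path_sans_ext(basename(path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("gene", "p"),
                          colClasses = c("character", "character"))
  if (nrow(df) && is.na(suppressWarnings(as.numeric(df$p[1L]))))
    df <- df[-1L, , drop = FALSE]
  gwas_table(study_name, df$gene, as.numeric(df$p))
}

#' Write a GWAS table as TSV
#'
#' @param gt `gwas_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gwas_table <- function(gt, path) {
  stopifnot(inherits(gt, "gwas_table"))
  utils::write.table(
    data.frame(gene = names(gt$p_by_gene), p = unname(gt$p_by_gene)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genes significant in two independent GWAS
#'
#' @param genes character vector of candidate genes.
#' @param study_a,study_b `gwas_table` objects.
#' @param alpha significance threshold (default 0.05).
#' @return sorted character vector of genes present in both tables with
#'   `p < alpha` in both.
#' @export
joint_significant_genes <- function(genes, study_a, study_b, alpha = 0.05) {
  stopifnot(inherits(study_a, "gwas_table"), inherits(study_b, "gwas_table"))
  genes <- toupper(genes)
  common <- intersect(intersect(genes, names(study_a$p_by_gene)),
                      names(study_b$p_by_gene))
  sort(common[study_a$p_by_gene[common] < alpha &
              study_b$p_by_gene[common] < alpha])
}

#' Randomization test for joint GWAS-signal enrichment
#'
#' Per repeat, draws `n_sets` uniform gene subsets of size `set_size` from
#' the universe of genes present in both studies, counts per subset the
#' genes significant in both studies at `alpha`, and reports the empirical
#' p-value: the fraction of subsets whose count is at least
#' `observed_count` ("not less than", i.e. `>=`).  Repeats use distinct
#' seeds derived from `seed` so the whole list is reproducible.
#'
#' @param universe character vector of genes to sample from (genes missing
#'   from either study are dropped first).
#' @param set_size genes per random subset.
#' @param observed_count observed joint-significant count to compare with.
#' @param study_a,study_b `gwas_table` objects.
#' @param alpha per-study significance threshold (default 0.05).
#' @param n_sets random subsets per repeat (default 1000).
#' @param n_repeats number of repeats (default 10).
#' @param seed integer master seed.
#' @return list with `empirical_p_per_repeat` (numeric vector), the matrix
#'   is not retained; `mean_joint_count` (mean per-subset count over all
#'   repeats), `n_sets`, `n_repeats`, `universe_size`, `seed`.
#' @export
enrichment_randomization <- function(universe, set_size, observed_count,
                                     study_a, study_b, alpha = 0.05,
                                     n_sets = 1000L, n_repeats = 10L,
                                     seed = 1L) {
  stopifnot(inherits(study_a, "gwas_table"), inherits(study_b, "gwas_table"))
  universe <- intersect(intersect(toupper(universe),
                                  names(study_a$p_by_gene)),
                        names(study_b$p_by_gene))
  nu <- length(universe)
  if (set_size > nu)
    stop("set_size (", set_size, ") exceeds universe size (", nu, ")")
  joint <- study_a$p_by_gene[universe] < alpha &
           study_b$p_by_gene[universe] < alpha
  ps <- numeric(n_repeats)
  count_sum <- 0
  for (r in seq_len(n_repeats)) {
    counts <- withr::with_seed(derive_seed(seed, r), {
      vapply(seq_len(n_sets), function(i)
        sum(joint[sample.int(nu, set_size)]), numeric(1))
    })
    ps[r] <- mean(counts >= observed_count)
    count_sum <- count_sum + sum(counts)
  }
  list(empirical_p_per_repeat = ps,
       mean_joint_count = count_sum / (n_sets * n_repeats),
       n_sets = as.integer(n_sets), n_repeats = as.integer(n_repeats),
       universe_size = nu, alpha = alpha, seed = as.integer(seed),
       caveat = paste("gene-level smallest-p statistics carry a gene-length",
                      "bias that this randomization does not correct"))
}

#' Nominate novel candidate genes from a disease subnetwork
#'
#' Novel candidates are subnetwork genes outside the seed list that carry a
#' joint GWAS signal.  For each candidate an ego subnetwork is extracted:
#' the induced subgraph on the candidate plus those of its subnetwork
#' neighbors that are seeds or joint-significant.
#'
#' @param subnet igraph disease subnetwork.
#' @param seeds `gene_set` of seed (known disease) genes.
#' @param joint character vector of joint-significant genes.
#' @return an object of class `prioritization_result` with fields
#'   `joint_significant`, `novel_candidates`, `ego_subnetworks` (named list
#'   of igraphs).
#' @export
nominate_candidates <- function(subnet, seeds, joint) {
  stopifnot(inherits(seeds, "gene_set"))
  joint <- toupper(joint)
  nodes <- igraph::V(subnet)$name
  joint_in <- sort(intersect(joint, nodes))
  cand <- sort(setdiff(joint_in, seeds$members))
  egos <- lapply(cand, function(g) {
    nb <- names(igraph::neighbors(subnet, g))
    keep <- nb[nb %in% seeds$members | nb %in% joint]
    induced_subnetwork(subnet, c(g, keep))
  })
  names(egos) <- cand
  stopifnot(length(intersect(cand, seeds$members)) == 0L)
  structure(list(joint_significant = joint_in, novel_candidates = cand,
                 ego_subnetworks = egos),
            class = "prioritization_result")
}

#' @export
print.prioritization_result <- function(x, ...) {
  cat("<prioritization_result>", length(x$joint_significant),
      "joint-significant genes,", length(x$novel_candidates),
      "novel candidates\n")
  invisible(x)
}

#' Pathway-guided candidate genes
#'
#' Extracts the pathway-specific subnetwork from the interactome via the
#' Steiner heuristic (pathway genes as terminals) and returns the non-seed
#' nodes of that subnetwork ranked by their degree within it (descending,
#' lexicographic tie-break) - the most central connectors first.
#'
#' @param net igraph interactome.
#' @param pathway_genes character vector of pathway member genes (>= 2 must
#'   map).
#' @param seeds `gene_set` of known disease genes.
#' @return character vector of ranked candidate genes, with the subnetwork
#'   attached as attribute `subnetwork` and their in-subnetwork degrees as
#'   attribute `degree`.
#' @export
pathway_guided_candidates <- function(net, pathway_genes, seeds) {
  stopifnot(inherits(seeds, "gene_set"))
  sres <- steiner_subnetwork(net, gene_set("pathway", pathway_genes),
                             include_induced_edges = TRUE)
  sg <- sres$subnetwork
  cand <- setdiff(igraph::V(sg)$name, seeds$members)
  degs <- igraph::degree(sg, v = cand)
  ord <- order(-degs, cand)
  out <- cand[ord]
  attr(out, "degree") <- unname(degs[ord])
  attr(out, "subnetwork") <- sg
  out
}
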