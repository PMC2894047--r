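#' Derive a reproducible sub-seed from a master seed
#'
#' Stochastic stages each draw from an independent stream keyed by
#' `(master_seed, index)`, so adding a generator call to a workflow never
#' perturbs draws made by earlier stages.  The scheme is a fixed affine map
#' modulo 2^31 - 1 (a Mersenne prime), kept strictly below 2^31 so the result
#' is always a valid R integer seed.
#'
#' @param master_seed integer master seed.
#' @param index non-negative integer stream index.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, index) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147483647
  s <- (abs(as.numeric(master_seed)) %% m + as.numeric(index) * 48271) %% m
  as.integer(s %% (m - 1) + 1)
}

# round() in R is round-half-even; contingency counts use half-up by
# convention so a .5 average always moves away from zero exceedance.
round_half_up <- function(x) floor(x + 0.5)

# Canonical key for an undirected edge between two named nodes.
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}

# Minimal union-find (used by Kruskal and clique percolation).  Operates on
# integer indices 1..n.
uf_new <- function(n) seq_len(n)

# Returns updated parent vector with roots of i and j merged.
uf_union <- function(parent, i, j) {
  ri <- i
  while (parent[ri] != ri) ri <- parent[ri]
  rj <- j
  while (parent[rj] != rj) rj <- parent[rj]
  if (ri != rj) parent[rj] <- ri
  parent
}

uf_root <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# Resolve every element to its root (vectorized over all indices).
uf_roots <- function(parent) {
  vapply(seq_along(parent), function(i) uf_root(parent, i), integer(1))
}
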