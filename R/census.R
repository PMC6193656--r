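# Exact induced-subgraph census. Enumeration is ESU-style recursive
# extension over exclusive neighborhoods, implemented in C++; every
# occurrence is reported once as a sorted node tuple together with the
# adjacency bit code of its induced subgraph, which indexes the catalog's
# orbit lookup table.

.census_raw <- function(snap, k) {
  stopifnot(inherits(snap, "snapshot"))
  k <- as.integer(k)
  if (k < 2L || k > 6L) stop("k must be between 2 and 6")
  edges <- snap$edges
  storage.mode(edges) <- "integer"
  .esu_census_cpp(edges, snap$n_nodes, k)
}

#' Enumerate connected induced k-subgraphs
#'
#' Yields every node set of size `k` whose induced subgraph in the snapshot
#' is connected, exactly once. Two occurrences differ iff they differ in at
#' least one node (edges are implied: occurrences are induced).
#'
#' @param snap a [snapshot()].
#' @param k subgraph size, 2 to 6.
#' @return Integer matrix with one row per occurrence and `k` columns; node
#'   ids within a row are strictly increasing.
#' @export
enumerate_connected <- function(snap, k) {
  res <- .census_raw(snap, k)
  res$nodes
}

#' Per-node orbit frequencies (graphlet degree vectors)
#'
#' Counts, for every node `u` and every orbit `j` of the catalog, the number
#' of connected induced k-subgraph occurrences in which `u` sits in orbit
#' `j`. Row `u` is the graphlet degree vector GDV(u); the full matrix is the
#' orbit-frequency matrix Fr. The grand total equals `k` times the number of
#' occurrences.
#'
#' @param snap a [snapshot()].
#' @param catalog an undirected [build_catalog()] whose `k` sets the
#'   subgraph size.
#' @return Integer matrix of dimension `n_nodes` x `orbit_count`, with
#'   columns named by global orbit id.
#' @export
orbit_frequency_matrix <- function(snap, catalog) {
  stopifnot(inherits(catalog, "graphlet_catalog"))
  if (catalog$directed) stop("census requires an undirected catalog")
  res <- .census_raw(snap, catalog$k)
  n <- snap$n_nodes
  n_orb <- catalog$orbit_count
  fr <- matrix(0L, n, n_orb,
               dimnames = list(NULL, paste0("O", seq_len(n_orb))))
  if (length(res$codes) > 0L) {
    orbits <- catalog$orbit_table[res$codes + 1L, , drop = FALSE]
    idx <- (as.vector(orbits) - 1L) * n + as.vector(res$nodes)
    counts <- tabulate(idx, nbins = n * n_orb)
    fr <- matrix(as.integer(counts), n, n_orb,
                 dimnames = list(NULL, paste0("O", seq_len(n_orb))))
  }
  fr
}

#' Graphlet frequencies of a snapshot
#'
#' The classic subgraph census: number of induced occurrences of each
#' connected k-graphlet, in catalog order.
#'
#' @inheritParams orbit_frequency_matrix
#' @return Named integer vector of length `n_graphlets`.
#' @export
graphlet_frequencies <- function(snap, catalog) {
  stopifnot(inherits(catalog, "graphlet_catalog"))
  if (catalog$directed) stop("census requires an undirected catalog")
  res <- .census_raw(snap, catalog$k)
  cls <- catalog$code_to_graphlet[res$codes + 1L]
  out <- tabulate(cls, nbins = catalog$n_graphlets)
  names(out) <- paste0("G", seq_len(catalog$n_graphlets))
  out
}

#' Graphlet degree distribution from an orbit-frequency matrix
#'
#' `GDD[j, p]` is the number of nodes that appear exactly `p >= 1` times in
#' orbit `j` (nodes with zero count are not tabulated). For the 2-node
#' catalog the single row is the node degree distribution.
#'
#' @param fr matrix from [orbit_frequency_matrix()] (nodes x orbits).
#' @return Integer matrix orbits x multiplicity (`p = 1..max`), possibly
#'   with zero columns when no node appears in any orbit.
#' @export
gdd_from_fr <- function(fr) {
  n_orb <- ncol(fr)
  maxp <- if (length(fr) > 0L) max(fr) else 0L
  gdd <- matrix(0L, n_orb, maxp,
                dimnames = list(colnames(fr),
                                if (maxp > 0L) paste0("p", seq_len(maxp))))
  if (maxp > 0L) {
    for (j in seq_len(n_orb)) {
      v <- fr[, j]
      v <- v[v > 0L]
      if (length(v) > 0L) gdd[j, ] <- tabulate(v, nbins = maxp)
    }
  }
  gdd
}

#' Node degree distribution
#'
#' `NDD[p]` is the number of nodes of degree `p >= 1`; equivalently the
#' degree-orbit row of the 2-node graphlet degree distribution.
#'
#' @param snap a [snapshot()].
#' @return Integer vector indexed by degree `1..max`.
#' @export
ndd <- function(snap) {
  deg <- tabulate(as.vector(snap$edges), nbins = snap$n_nodes)
  deg <- deg[deg > 0L]
  if (length(deg) == 0L) return(integer(0))
  tabulate(deg, nbins = max(deg))
}
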