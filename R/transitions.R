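# Orbit-transition matrices: for every node set whose induced subgraph is
# connected in two consecutive snapshots, each node's orbit before (x) and
# after (y) increments T[x, y]. Node sets connected in only one of the two
# snapshots contribute nothing. Matching uses the sorted node tuple as key;
# only two snapshots' occurrence indexes are held at a time.

.occurrence_index <- function(snap, catalog) {
  res <- .census_raw(snap, catalog$k)
  keys <- if (nrow(res$nodes) > 0L) {
    do.call(paste, c(as.data.frame(res$nodes), sep = "_"))
  } else character(0)
  list(keys = keys,
       nodes = res$nodes,
       orbits = catalog$orbit_table[res$codes + 1L, , drop = FALSE])
}

.transition_pairs <- function(prev, cur) {
  hit <- match(prev$keys, cur$keys)
  sel <- which(!is.na(hit))
  list(x = prev$orbits[sel, , drop = FALSE],
       y = cur$orbits[hit[sel], , drop = FALSE],
       nodes = prev$nodes[sel, , drop = FALSE])
}

#' Graphlet-orbit transition matrix
#'
#' Builds the `|O| x |O|` count matrix `T[x, y]` of orbit transitions of a
#' temporal network: over every pair of consecutive snapshots `(t, t + 1)`,
#' every k-node set whose induced subgraph is connected in both snapshots
#' contributes one count per node, from its orbit at `t` to its orbit at
#' `t + 1`. Self-transitions populate the diagonal; a node set may occupy
#' different graphlets at the two times (transitions are orbit-to-orbit,
#' not graphlet-restricted).
#'
#' @param net a [temporal_network()] with at least two snapshots.
#' @param catalog an undirected [build_catalog()].
#' @return Integer matrix `orbit_count x orbit_count` with orbit-id
#'   dimnames.
#' @export
got_matrix <- function(net, catalog) {
  stopifnot(inherits(net, "temporal_network"),
            inherits(catalog, "graphlet_catalog"))
  if (catalog$directed) stop("transition matrices require an undirected catalog")
  s <- length(net$snapshots)
  if (s < 2L) stop("orbit transitions need at least two snapshots")
  n_orb <- catalog$orbit_count
  counts <- integer(n_orb * n_orb)
  prev <- .occurrence_index(net$snapshots[[1L]], catalog)
  for (t in 2:s) {
    cur <- .occurrence_index(net$snapshots[[t]], catalog)
    tp <- .transition_pairs(prev, cur)
    if (nrow(tp$x) > 0L) {
      idx <- (as.vector(tp$x) - 1L) * n_orb + as.vector(tp$y)
      counts <- counts + tabulate(idx, nbins = n_orb * n_orb)
    }
    prev <- cur
  }
  orb <- paste0("O", seq_len(n_orb))
  matrix(as.integer(counts), n_orb, n_orb, byrow = TRUE,
         dimnames = list(from = orb, to = orb))
}

#' Per-node orbit-transition vectors
#'
#' Same accounting as [got_matrix()], but attributed to the individual
#' nodes: row `u` of the result is node `u`'s flattened `|O| x |O|`
#' transition count matrix. Summing the rows over all nodes reproduces
#' [got_matrix()] exactly.
#'
#' @inheritParams got_matrix
#' @return Integer matrix `n_nodes x orbit_count^2`; columns are labeled
#'   `Ox->Oy` in row-major order of the transition matrix.
#' @export
node_transition_vectors <- function(net, catalog) {
  stopifnot(inherits(net, "temporal_network"),
            inherits(catalog, "graphlet_catalog"))
  if (catalog$directed) stop("transition matrices require an undirected catalog")
  s <- length(net$snapshots)
  if (s < 2L) stop("orbit transitions need at least two snapshots")
  n_orb <- catalog$orbit_count
  n <- length(net$nodes)
  i_acc <- integer(0)
  j_acc <- integer(0)
  prev <- .occurrence_index(net$snapshots[[1L]], catalog)
  for (t in 2:s) {
    cur <- .occurrence_index(net$snapshots[[t]], catalog)
    tp <- .transition_pairs(prev, cur)
    if (nrow(tp$x) > 0L) {
      i_acc <- c(i_acc, as.vector(tp$nodes))
      j_acc <- c(j_acc, (as.vector(tp$x) - 1L) * n_orb + as.vector(tp$y))
    }
    prev <- cur
  }
  orb <- paste0("O", seq_len(n_orb))
  cn <- as.vector(t(outer(orb, orb, function(a, b) paste0(a, "->", b))))
  if (length(i_acc) == 0L) {
    return(matrix(0L, n, n_orb * n_orb, dimnames = list(net$nodes, cn)))
  }
  m <- Matrix::sparseMatrix(i = i_acc, j = j_acc, x = 1,
                            dims = c(n, n_orb * n_orb))
  out <- as.matrix(m)
  storage.mode(out) <- "integer"
  dimnames(out) <- list(net$nodes, cn)
  out
}

#' Row-normalize a transition matrix
#'
#' Divides every row by its sum so each row becomes a probability
#' distribution over destination orbits; all-zero rows stay all-zero. Row
#' (rather than global) normalization gives rare and common source orbits
#' the same weight in downstream comparison.
#'
#' @param t_mat square count matrix from [got_matrix()].
#' @return Numeric matrix of the same shape with rows summing to 1 or 0.
#' @export
row_normalize <- function(t_mat) {
  if (nrow(t_mat) != ncol(t_mat)) stop("transition matrix must be square")
  rs <- rowSums(t_mat)
  out <- t_mat / ifelse(rs == 0, 1, rs)
  out
}

#' Discretize a normalized transition matrix
#'
#' Maps each normalized frequency to one of three visualization categories:
#' `rare` for values in `[0, 1/3]`, `common` in `(1/3, 2/3]` and `frequent`
#' in `(2/3, 1]`.
#'
#' @param ntr numeric matrix with entries in `[0, 1]`, typically from
#'   [row_normalize()].
#' @return Character matrix of the same shape.
#' @export
discretize <- function(ntr) {
  if (any(ntr < 0 | ntr > 1)) stop("entries must lie in [0, 1]")
  out <- ifelse(ntr <= 1 / 3, "rare", ifelse(ntr <= 2 / 3, "common", "frequent"))
  dim(out) <- dim(ntr)
  dimnames(out) <- dimnames(ntr)
  out
}
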