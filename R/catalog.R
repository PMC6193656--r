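# Graphlet catalogs: all non-isomorphic connected k-node (di)graphs with
# automorphism-orbit partitions, plus a lookup table mapping ANY labeled
# induced k-subgraph (encoded as an adjacency bit code) directly to the
# global orbit id of each of its positions. The census never canonicalizes
# at enumeration time; it only indexes this table.

.catalog_cache <- new.env(parent = emptyenv())

# all permutations of 1..k in lexicographic order (k! <= 720)
.permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- vector("list", factorial(k))
  i <- 0L
  rec <- function(prefix, rest) {
    if (length(rest) == 0L) {
      i <<- i + 1L
      out[[i]] <<- prefix
      return(invisible())
    }
    for (j in seq_along(rest)) {
      rec(c(prefix, rest[j]), rest[-j])
    }
  }
  rec(integer(0), seq_len(k))
  out
}

# ordered list of node pairs defining the adjacency bit positions
.code_pairs <- function(k, directed) {
  if (directed) {
    idx <- expand.grid(j = seq_len(k), i = seq_len(k))
    idx <- idx[idx$i != idx$j, c("i", "j")]
    idx <- idx[order(idx$i, idx$j), ]
    as.matrix(idx)
  } else {
    t(combn(seq_len(k), 2L))
  }
}

.code_from_adjacency <- function(adj, pairs) {
  bits <- adj[pairs] != 0
  sum(2^(seq_along(bits) - 1L) * bits)
}

.adjacency_from_code <- function(code, pairs, k, directed) {
  m <- nrow(pairs)
  bits <- (code %/% 2^(0:(m - 1L))) %% 2
  adj <- matrix(0L, k, k)
  on <- which(bits == 1)
  if (length(on) > 0L) {
    adj[pairs[on, , drop = FALSE]] <- 1L
    if (!directed) adj[pairs[on, c(2L, 1L), drop = FALSE]] <- 1L
  }
  adj
}

.is_connected_adj <- function(adj) {
  k <- nrow(adj)
  if (k == 1L) return(TRUE)
  sym <- (adj + t(adj)) > 0
  seen <- logical(k)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(sym[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# permutation weight vector: code of the graph relabeled by p equals
# bits %*% w, where w[m] = 2^(target bit of pair m under p - 1)
.perm_weights <- function(p, pairs, directed) {
  a <- p[pairs[, 1L]]
  b <- p[pairs[, 2L]]
  if (!directed) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    a <- lo; b <- hi
  }
  key_all <- pairs[, 1L] * (length(p) + 1L) + pairs[, 2L]
  key_new <- a * (length(p) + 1L) + b
  2^(match(key_new, key_all) - 1)
}

#' Canonical code of a small graph
#'
#' A label-invariant encoding: the minimum, over all `k!` node relabelings,
#' of the adjacency bit string (upper triangle for undirected graphs, all
#' ordered pairs for directed ones). Two k-node graphs share a code if and
#' only if they are isomorphic.
#'
#' @param adjacency square 0/1 adjacency matrix, 2 to 6 nodes. For
#'   undirected graphs the matrix must be symmetric.
#' @param directed logical; treat the matrix as a digraph (reciprocal arcs
#'   allowed).
#' @return The canonical code as a single number.
#' @export
canonical_code <- function(adjacency, directed = FALSE) {
  k <- nrow(adjacency)
  if (is.null(k) || k != ncol(adjacency) || k < 2L || k > 6L) {
    stop("adjacency must be a square matrix with 2 to 6 nodes")
  }
  if (!directed && !isTRUE(all.equal(adjacency, t(adjacency)))) {
    stop("undirected adjacency must be symmetric")
  }
  pairs <- .code_pairs(k, directed)
  bits <- as.numeric(adjacency[pairs] != 0)
  best <- Inf
  for (p in .permutations(k)) {
    cand <- sum(bits * .perm_weights(p, pairs, directed))
    if (cand < best) best <- cand
  }
  best
}

.uf_find <- function(parent, x) {
  while (parent[x] != x) x <- parent[x]
  x
}

.orbit_partition_from_auts <- function(auts, k) {
  parent <- seq_len(k)
  for (p in auts) {
    for (i in seq_len(k)) {
      ri <- .uf_find(parent, i)
      rj <- .uf_find(parent, p[i])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(k), function(i) .uf_find(parent, i), integer(1))
  unname(split(seq_len(k), roots))
}

#' Automorphism orbits of a connected graphlet
#'
#' Partitions the node positions of a connected k-node graph into
#' automorphism orbits: positions `u` and `v` fall in the same block iff
#' some automorphism (self-isomorphism) maps `u` to `v`. The orbit is the
#' topological "role" of a node inside the graphlet (e.g. a 4-star has two
#' orbits: its center and its three leaves).
#'
#' @inheritParams canonical_code
#' @return A list of integer vectors (the orbit blocks), ordered by their
#'   smallest member.
#' @export
automorphism_orbits <- function(adjacency, directed = FALSE) {
  k <- nrow(adjacency)
  if (is.null(k) || k != ncol(adjacency) || k < 2L || k > 6L) {
    stop("adjacency must be a square matrix with 2 to 6 nodes")
  }
  if (!.is_connected_adj(adjacency)) {
    stop("only connected graphlets have a cataloged orbit partition")
  }
  perms <- .permutations(k)
  auts <- Filter(function(p) all(adjacency[p, p] == adjacency), perms)
  blocks <- .orbit_partition_from_auts(auts, k)
  blocks[order(vapply(blocks, min, integer(1)))]
}

# canonical degree-sequence order used to pin the 4-node undirected catalog:
# star, path, cycle, paw (triangle + pendant), diamond, clique
.k4_pinned_order <- list(
  c(1L, 1L, 1L, 3L), c(1L, 1L, 2L, 2L), c(2L, 2L, 2L, 2L),
  c(1L, 2L, 2L, 3L), c(2L, 2L, 3L, 3L), c(3L, 3L, 3L, 3L)
)

#' Build a graphlet-orbit catalog
#'
#' Enumerates every labeled k-node graph, keeps the connected ones, groups
#' them into isomorphism classes by canonical code, computes the
#' automorphism-orbit partition of each class, and assigns global orbit ids
#' `1..|O|` in a fixed deterministic order. The resulting catalog carries a
#' lookup table from any labeled adjacency code to the per-position global
#' orbit ids, so classifying an induced subgraph during a census is a single
#' table access.
#'
#' Graphlets are ordered by (edge count, canonical code). For the 4-node
#' undirected catalog the order is pinned to star, path, cycle, paw,
#' diamond, clique with higher-degree orbits first within a graphlet, so
#' that the star center is orbit 1, the star leaf orbit 2, the cycle orbit 5
#' and the clique orbit 11; remaining ids follow from the deterministic
#' sort and are reported in the catalog itself (see [export_catalog_json()]).
#'
#' @param k graphlet size: 2 to 6 nodes undirected, 2 to 4 directed (the
#'   directed transition space beyond k = 4 is impractically large).
#' @param directed logical; catalog weakly connected digraphs instead.
#' @return An object of class `graphlet_catalog` with fields `k`,
#'   `directed`, `graphlets` (list of canonical adjacency, edge list, orbit
#'   partition and per-position orbit ids), `orbit_count`, `orbits` (data
#'   frame describing each orbit), and the internal lookup tables.
#' @examples
#' cat3 <- build_catalog(3)
#' cat3$orbit_count  # 3 orbits: chain center, chain periphery, triangle
#' @export
build_catalog <- function(k, directed = FALSE) {
  k <- as.integer(k)
  if (k < 2L || k > 6L) stop("k must be between 2 and 6")
  if (directed && k > 4L) {
    stop("directed catalogs are limited to k <= 4 (orbit space grows past 44k orbits)")
  }
  key <- paste0(if (directed) "d" else "u", k)
  if (!is.null(.catalog_cache[[key]])) return(.catalog_cache[[key]])

  pairs <- .code_pairs(k, directed)
  m <- nrow(pairs)
  ncodes <- 2L^m
  codes <- 0:(ncodes - 1L)

  B <- matrix(0, ncodes, m)
  for (j in seq_len(m)) B[, j] <- (codes %/% 2^(j - 1L)) %% 2

  perms <- .permutations(k)
  W <- matrix(vapply(perms, .perm_weights, numeric(m), pairs = pairs,
                     directed = directed), nrow = m)

  mincode <- rep(Inf, ncodes)
  bestperm <- integer(ncodes)
  for (pi in seq_along(perms)) {
    newcode <- as.vector(B %*% W[, pi])
    upd <- newcode < mincode
    mincode[upd] <- newcode[upd]
    bestperm[upd] <- pi
  }

  repcodes <- sort(unique(mincode))
  cls <- match(mincode, repcodes)

  rep_adj <- lapply(repcodes, .adjacency_from_code, pairs = pairs,
                    k = k, directed = directed)
  connected <- vapply(rep_adj, .is_connected_adj, logical(1))

  # deterministic graphlet order: edge count, then canonical code
  conn_idx <- which(connected)
  edge_counts <- vapply(conn_idx, function(i) sum(rep_adj[[i]]) /
                          if (directed) 1L else 2L, numeric(1))
  ord <- conn_idx[order(edge_counts, repcodes[conn_idx])]
  if (k == 4L && !directed) {
    degseqs <- lapply(ord, function(i) sort(as.integer(rowSums(rep_adj[[i]]))))
    pin <- match(vapply(degseqs, paste, character(1), collapse = ","),
                 vapply(.k4_pinned_order, paste, character(1), collapse = ","))
    ord <- ord[order(pin)]
  }

  graphlets <- vector("list", length(ord))
  orbit_mat <- matrix(NA_integer_, length(repcodes), k)
  orbit_rows <- list()
  next_orbit <- 1L
  for (gi in seq_along(ord)) {
    ci <- ord[gi]
    adj <- rep_adj[[ci]]
    bits <- as.numeric((repcodes[ci] %/% 2^(0:(m - 1L))) %% 2)
    codes_under <- as.vector(bits %*% W)
    auts <- perms[codes_under == repcodes[ci]]
    blocks <- .orbit_partition_from_auts(auts, k)
    if (k == 4L && !directed) {
      deg <- rowSums(adj)
      blocks <- blocks[order(-vapply(blocks, function(b) deg[b[1L]], numeric(1)),
                             vapply(blocks, min, integer(1)))]
    } else {
      blocks <- blocks[order(vapply(blocks, min, integer(1)))]
    }
    pos_orbit <- integer(k)
    for (b in seq_along(blocks)) {
      pos_orbit[blocks[[b]]] <- next_orbit
      orbit_rows[[next_orbit]] <- data.frame(
        orbit = next_orbit, graphlet = gi,
        positions = paste(blocks[[b]], collapse = ","),
        degree = if (directed) sum(adj[blocks[[b]][1L], ]) + sum(adj[, blocks[[b]][1L]])
                 else sum(adj[blocks[[b]][1L], ]))
      next_orbit <- next_orbit + 1L
    }
    orbit_mat[ci, ] <- pos_orbit
    on <- which(bits == 1)
    graphlets[[gi]] <- list(
      code = repcodes[ci],
      adjacency = adj,
      edges = pairs[on, , drop = FALSE],
      orbit_ids = pos_orbit,
      orbit_partition = blocks
    )
  }

  # labeled-code -> per-position global orbit id (NA when disconnected)
  orbit_table <- matrix(NA_integer_, ncodes, k)
  conn_code <- connected[cls]
  for (pi in unique(bestperm[conn_code])) {
    sel <- which(bestperm == pi & conn_code)
    p <- perms[[pi]]
    for (i in seq_len(k)) {
      orbit_table[sel, i] <- orbit_mat[cbind(cls[sel], p[i])]
    }
  }

  code_to_graphlet <- rep(NA_integer_, ncodes)
  conn_class_to_graphlet <- rep(NA_integer_, length(repcodes))
  conn_class_to_graphlet[ord] <- seq_along(ord)
  code_to_graphlet[conn_code] <- conn_class_to_graphlet[cls[conn_code]]

  out <- structure(list(
    k = k,
    directed = directed,
    graphlets = graphlets,
    n_graphlets = length(graphlets),
    orbit_count = next_orbit - 1L,
    orbits = do.call(rbind, orbit_rows),
    pairs = pairs,
    code_to_graphlet = code_to_graphlet,
    orbit_table = orbit_table
  ), class = "graphlet_catalog")
  .catalog_cache[[key]] <- out
  out
}

#' @export
print.graphlet_catalog <- function(x, ...) {
  cat(sprintf("<graphlet_catalog: k=%d %s, %d graphlets, %d orbits, %d possible transitions>\n",
              x$k, if (x$directed) "directed" else "undirected",
              x$n_graphlets, x$orbit_count, x$orbit_count^2))
  invisible(x)
}

#' Orbit ids of the nodes of one induced subgraph
#'
#' Maps a connected induced k-subgraph, given as an adjacency matrix in a
#' chosen node order, to the global orbit id of each node in that order.
#'
#' @param catalog a [build_catalog()] object.
#' @param adjacency k x k 0/1 adjacency matrix of the induced subgraph, in
#'   the node order for which orbits are requested.
#' @return Integer vector of global orbit ids, one per node.
#' @export
orbit_lookup <- function(catalog, adjacency) {
  k <- catalog$k
  if (is.null(nrow(adjacency)) || nrow(adjacency) != k || ncol(adjacency) != k) {
    stop("adjacency must be ", k, " x ", k)
  }
  code <- .code_from_adjacency(adjacency, catalog$pairs)
  res <- catalog$orbit_table[code + 1L, ]
  if (anyNA(res)) stop("induced subgraph is disconnected; no orbit assignment")
  res
}

#' Export a catalog as JSON
#'
#' Writes the graphlet list (edges in canonical labeling), the orbit
#' partition of each graphlet and the global orbit-id table, making the
#' deterministic orbit numbering explicit.
#'
#' @param catalog a [build_catalog()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_catalog_json <- function(catalog, path) {
  doc <- list(
    k = catalog$k,
    directed = catalog$directed,
    n_graphlets = catalog$n_graphlets,
    orbit_count = catalog$orbit_count,
    graphlets = lapply(seq_along(catalog$graphlets), function(i) {
      g <- catalog$graphlets[[i]]
      list(index = i,
           canonical_code = g$code,
           edges = apply(g$edges, 1L, function(e) paste(e, collapse = "-")),
           orbit_ids = g$orbit_ids)
    }),
    orbits = catalog$orbits
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
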