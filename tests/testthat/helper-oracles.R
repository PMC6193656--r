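# Independent brute-force oracles used to validate enumeration, orbit
# assignment and transition counting on small inputs, plus small graph
# builders. Deliberately naive implementations: all C(n, k) subsets, all k!
# permutations.

# all permutations of 1..n as a list (independent of the package internals)
oracle_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- oracle_perms(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

adj_from_edges <- function(edges, n) {
  a <- matrix(0L, n, n)
  if (length(edges) > 0L) {
    e <- matrix(edges, ncol = 2L)
    a[e] <- 1L
    a[e[, c(2L, 1L), drop = FALSE]] <- 1L
  }
  a
}

oracle_is_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier) > 0L) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

# every size-k node subset inducing a connected subgraph, as a sorted-row
# matrix in lexicographic order
oracle_connected_subsets <- function(snap, k) {
  n <- snap$n_nodes
  adj <- adj_from_edges(snap$edges, n)
  if (n < k) return(matrix(integer(0), ncol = k))
  subsets <- combn(n, k)
  keep <- apply(subsets, 2L, function(s) oracle_is_connected(adj[s, s]))
  t(subsets[, keep, drop = FALSE])
}

# orbit partition by definition: u ~ v iff some permutation is an
# automorphism mapping u to v
oracle_orbits <- function(adj) {
  k <- nrow(adj)
  equiv <- diag(TRUE, k)
  for (p in oracle_perms(k)) {
    if (all(adj[p, p] == adj)) {
      for (i in seq_len(k)) equiv[i, p[i]] <- equiv[p[i], i] <- TRUE
    }
  }
  # transitive closure
  repeat {
    nxt <- (equiv %*% equiv) > 0
    if (all(nxt == equiv)) break
    equiv <- nxt
  }
  blocks <- unique(apply(equiv, 1L, function(r) paste(which(r), collapse = ",")))
  lapply(blocks, function(b) as.integer(strsplit(b, ",")[[1L]]))
}

# transition matrix by definition: scan all C(n, k) subsets of every
# consecutive snapshot pair; subsets connected in both contribute one count
# per node from its orbit before to its orbit after
oracle_got <- function(net, catalog) {
  k <- catalog$k
  n_orb <- catalog$orbit_count
  tm <- matrix(0L, n_orb, n_orb)
  for (t in seq_len(length(net$snapshots) - 1L)) {
    s1 <- net$snapshots[[t]]
    s2 <- net$snapshots[[t + 1L]]
    n <- max(s1$n_nodes, s2$n_nodes)
    a1 <- adj_from_edges(s1$edges, n)
    a2 <- adj_from_edges(s2$edges, n)
    if (n < k) next
    subsets <- combn(n, k)
    for (ci in seq_len(ncol(subsets))) {
      s <- subsets[, ci]
      if (max(s) <= s1$n_nodes && max(s) <= s2$n_nodes &&
          oracle_is_connected(a1[s, s]) && oracle_is_connected(a2[s, s])) {
        o1 <- orbit_lookup(catalog, a1[s, s])
        o2 <- orbit_lookup(catalog, a2[s, s])
        for (i in seq_len(k)) tm[o1[i], o2[i]] <- tm[o1[i], o2[i]] + 1L
      }
    }
  }
  tm
}

# small random temporal network for property tests
random_toy_network <- function(n, snapshots, p = 0.3) {
  snaps <- lapply(seq_len(snapshots), function(i) {
    pairs <- t(combn(n, 2L))
    snapshot(pairs[runif(nrow(pairs)) < p, , drop = FALSE], n)
  })
  temporal_network(snaps, as.character(seq_len(n)), name = "toy")
}

# named small graphs as snapshots
toy_triangle <- function() snapshot(rbind(c(1, 2), c(2, 3), c(1, 3)), 3)
toy_path3 <- function() snapshot(rbind(c(1, 2), c(2, 3)), 3)
toy_star <- function(leaves = 3L) {
  snapshot(cbind(1L, 1L + seq_len(leaves)), leaves + 1L)
}
toy_k4 <- function() snapshot(t(combn(4L, 2L)), 4)
toy_cycle <- function(n) snapshot(cbind(seq_len(n), c(seq_len(n)[-1L], 1L)), n)
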