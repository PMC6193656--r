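# Seeded generators for evolving random-graph models: growing Erdos-Renyi
# and Barabasi-Albert variants with optional edge-deletion noise, and a
# growing Watts-Strogatz ring with optional rewiring. All models grow the
# node count by 10% per snapshot (floor rounding) and, for the Erdos and
# Barabasi families, hold the density E/N^2 fixed by topping edges up to
# round(density * N^2) after deletions.

#' Specify an evolving-graph model
#'
#' @param model one of `"erdos"`, `"barabasi"`, `"strogatz"`.
#' @param snapshots number of snapshots (default 5).
#' @param n0 nodes in the first snapshot (default 250).
#' @param growth per-snapshot node growth rate; the next node count is
#'   `floor(N + growth * N)` (default 0.1).
#' @param density edge-density target `E / N^2` for the Erdos and Barabasi
#'   families (default 0.01); for Strogatz it sets the ring degree (nearest
#'   even integer to `2 * density * N`, halves rounded up).
#' @param p_del probability that an edge of snapshot `i` is deleted before
#'   snapshot `i + 1` (Erdos/Barabasi only; the reference setting uses 0 or
#'   0.5).
#' @param beta per-edge rewiring probability per snapshot (Strogatz only; 0
#'   gives regular rings, 0.2 small-world networks).
#' @param seed optional integer seed making [generate_temporal()]
#'   deterministic.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(model = c("erdos", "barabasi", "strogatz"),
                       snapshots = 5L, n0 = 250L, growth = 0.1,
                       density = 0.01, p_del = 0, beta = 0, seed = NULL) {
  model <- match.arg(model)
  stopifnot(snapshots >= 1L, n0 >= 2L, growth >= 0,
            density > 0, density <= 0.5,
            p_del >= 0, p_del <= 1, beta >= 0, beta <= 1)
  structure(list(model = model, snapshots = as.integer(snapshots),
                 n0 = as.integer(n0), growth = growth, density = density,
                 p_del = p_del, beta = beta, seed = seed),
            class = "model_spec")
}

#' Label of a model variant
#' @param spec a [model_spec()].
#' @return Short string such as `"erdos_p0.5"` or `"strogatz_b0.2"`.
#' @export
model_label <- function(spec) {
  if (spec$model == "strogatz") {
    sprintf("strogatz_b%g", spec$beta)
  } else {
    sprintf("%s_p%g", spec$model, spec$p_del)
  }
}

# node counts per snapshot under floor(N + growth * N)
.node_schedule <- function(n0, growth, snapshots) {
  n <- integer(snapshots)
  n[1L] <- n0
  if (snapshots > 1L) {
    for (i in 2:snapshots) n[i] <- as.integer(floor(n[i - 1L] + growth * n[i - 1L]))
  }
  n
}

.edge_target <- function(density, n) as.integer(round(density * n^2))

# uniform edge addition up to the target count; existing edges respected
.add_edges_uniform <- function(adj, n, target) {
  cur <- sum(adj) / 2L
  while (cur < target) {
    need <- target - cur
    u <- sample.int(n, 2L * need, replace = TRUE)
    v <- sample.int(n, 2L * need, replace = TRUE)
    for (i in seq_along(u)) {
      if (cur >= target) break
      a <- u[i]; b <- v[i]
      if (a != b && !adj[a, b]) {
        adj[a, b] <- adj[b, a] <- TRUE
        cur <- cur + 1L
      }
    }
  }
  adj
}

# preferential edge addition: both endpoints sampled with weight degree + 1
.add_edges_preferential <- function(adj, n, target) {
  deg <- colSums(adj)
  cur <- sum(deg) / 2L
  while (cur < target) {
    a <- sample.int(n, 1L, prob = deg + 1)
    b <- sample.int(n, 1L, prob = deg + 1)
    if (a != b && !adj[a, b]) {
      adj[a, b] <- adj[b, a] <- TRUE
      deg[a] <- deg[a] + 1L
      deg[b] <- deg[b] + 1L
      cur <- cur + 1L
    }
  }
  adj
}

.adj_to_edges <- function(adj) {
  which(adj & upper.tri(adj), arr.ind = TRUE)
}

.ring_degree <- function(density, n) {
  d <- 2L * as.integer(floor(2 * density * n / 2 + 0.5))
  max(d, 2L)
}

# ring-lattice edges for a given circular ordering of node ids
.ring_edges <- function(ring, degree) {
  n <- length(ring)
  half <- degree %/% 2L
  e <- matrix(0L, n * half, 2L)
  r <- 1L
  for (off in seq_len(half)) {
    to <- c(ring[(off + 1L):n], ring[seq_len(off)])
    e[r:(r + n - 1L), ] <- cbind(ring, to)
    r <- r + n
  }
  e
}

#' Generate an evolving synthetic temporal network
#'
#' Produces a [temporal_network()] following a [model_spec()]. Per snapshot
#' transition: the node count grows by the growth rate (floor rounding, new
#' ids appended); for Erdos/Barabasi each surviving edge is kept with
#' probability `1 - p_del` and new edges are added -- uniformly at random or
#' preferentially by degree + 1 -- until the edge count reaches
#' `round(density * N^2)`. The Strogatz family instead keeps nodes on a
#' circular ordering (new nodes spliced in uniformly at random), wires every
#' node to its ring neighbors, and rewires each edge independently with
#' probability `beta` (one endpoint kept, the other resampled uniformly,
#' collisions rejected).
#'
#' @param spec a [model_spec()].
#' @return A [temporal_network()] with `spec$snapshots` snapshots; metadata
#'   records the model label and parameters.
#' @export
generate_temporal <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  ns <- .node_schedule(spec$n0, spec$growth, spec$snapshots)
  n_final <- ns[spec$snapshots]
  snaps <- vector("list", spec$snapshots)

  if (spec$model %in% c("erdos", "barabasi")) {
    add <- if (spec$model == "erdos") .add_edges_uniform else .add_edges_preferential
    adj <- matrix(FALSE, ns[1L], ns[1L])
    target <- .edge_target(spec$density, ns[1L])
    if (target > choose(ns[1L], 2L)) stop("density target exceeds the number of node pairs")
    adj <- add(adj, ns[1L], target)
    snaps[[1L]] <- snapshot(.adj_to_edges(adj), ns[1L])
    if (spec$snapshots > 1L) {
      for (i in 2:spec$snapshots) {
        n <- ns[i]
        target <- .edge_target(spec$density, n)
        if (target > choose(n, 2L)) stop("density target exceeds the number of node pairs")
        grown <- matrix(FALSE, n, n)
        e <- .adj_to_edges(adj)
        if (nrow(e) > 0L && spec$p_del > 0) {
          e <- e[runif(nrow(e)) >= spec$p_del, , drop = FALSE]
        }
        if (nrow(e) > 0L) grown[rbind(e, e[, c(2L, 1L), drop = FALSE])] <- TRUE
        adj <- add(grown, n, max(target, sum(grown) / 2L))
        snaps[[i]] <- snapshot(.adj_to_edges(adj), n)
      }
    }
  } else {
    ring <- sample.int(ns[1L])
    for (i in seq_len(spec$snapshots)) {
      n <- ns[i]
      if (i > 1L) {
        for (newid in (ns[i - 1L] + 1L):n) {
          pos <- sample.int(length(ring) + 1L, 1L)
          ring <- append(ring, newid, after = pos - 1L)
        }
      }
      e <- .ring_edges(ring, .ring_degree(spec$density, n))
      adj <- matrix(FALSE, n, n)
      adj[rbind(e, e[, c(2L, 1L), drop = FALSE])] <- TRUE
      if (spec$beta > 0) {
        rew <- which(runif(nrow(e)) < spec$beta)
        for (r in rew) {
          a <- e[r, 1L]; b <- e[r, 2L]
          keep <- if (runif(1) < 0.5) a else b
          for (try in 1:100) {
            cand <- sample.int(n, 1L)
            if (cand != keep && !adj[keep, cand]) {
              adj[a, b] <- adj[b, a] <- FALSE
              adj[keep, cand] <- adj[cand, keep] <- TRUE
              break
            }
          }
        }
      }
      snaps[[i]] <- snapshot(.adj_to_edges(adj), n)
    }
  }

  temporal_network(snaps, paste0("v", seq_len(n_final)),
                   name = model_label(spec),
                   meta = list(model = model_label(spec), spec = spec))
}

#' The six reference model variants
#'
#' Erdos and Barabasi with deletion probability 0 and 0.5, and Strogatz with
#' rewiring 0 and 0.2, all sharing the snapshot count, initial size, growth
#' and density defaults.
#'
#' @inheritParams model_spec
#' @return List of six [model_spec()] objects.
#' @export
table1_models <- function(snapshots = 5L, n0 = 250L, growth = 0.1,
                          density = 0.01) {
  specs <- list(
    model_spec("erdos", snapshots, n0, growth, density, p_del = 0),
    model_spec("erdos", snapshots, n0, growth, density, p_del = 0.5),
    model_spec("barabasi", snapshots, n0, growth, density, p_del = 0),
    model_spec("barabasi", snapshots, n0, growth, density, p_del = 0.5),
    model_spec("strogatz", snapshots, n0, growth, density, beta = 0),
    model_spec("strogatz", snapshots, n0, growth, density, beta = 0.2)
  )
  names(specs) <- vapply(specs, model_label, character(1))
  specs
}

#' Generate a replicated suite of synthetic networks
#'
#' Instantiates `replicates` networks per model with per-network seeds
#' derived deterministically from one master seed; network names encode the
#' model label and replicate index, and the label is kept in the metadata
#' for use as ground truth in grouping experiments.
#'
#' @param models list of [model_spec()] objects (e.g. [table1_models()]).
#' @param replicates instances per model (the reference protocol uses 25).
#' @param seed master integer seed.
#' @return List of `length(models) * replicates` [temporal_network()]s.
#' @export
generate_suite <- function(models, replicates = 25L, seed = 1L) {
  stopifnot(replicates >= 1L)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, length(models) * replicates)
  out <- vector("list", length(models) * replicates)
  idx <- 1L
  for (m in seq_along(models)) {
    for (r in seq_len(replicates)) {
      spec <- models[[m]]
      spec$seed <- seeds[idx]
      net <- generate_temporal(spec)
      net$name <- sprintf("%s_r%02d", model_label(spec), r)
      out[[idx]] <- net
      idx <- idx + 1L
    }
  }
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}
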