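#' Construct a snapshot
#'
#' A snapshot is one time slice of a temporal network: a set of undirected
#' edges over a dense node index `1..n_nodes`. Edges are stored with the
#' smaller endpoint first; self-loops are forbidden and duplicate pairs are
#' collapsed. Isolated nodes are represented implicitly by `n_nodes`.
#'
#' @param edges integer matrix with two columns (one edge per row), or a
#'   zero-row matrix for an empty snapshot.
#' @param n_nodes number of nodes in the snapshot (at least the largest
#'   endpoint).
#' @return An object of class `snapshot` with fields `edges` and `n_nodes`.
#' @export
snapshot <- function(edges, n_nodes) {
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (any(is.na(edges)) || any(edges < 1L)) {
      stop("edge endpoints must be positive integers")
    }
    if (any(edges[, 1L] == edges[, 2L])) {
      stop("self-loops are not allowed in a snapshot")
    }
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  n_nodes <- as.integer(n_nodes)
  if (nrow(edges) > 0L && max(edges) > n_nodes) {
    stop("n_nodes smaller than largest edge endpoint")
  }
  structure(list(edges = edges, n_nodes = n_nodes), class = "snapshot")
}

#' @export
print.snapshot <- function(x, ...) {
  cat(sprintf("<snapshot: %d nodes, %d edges>\n", x$n_nodes, nrow(x$edges)))
  invisible(x)
}

#' Construct a temporal network
#'
#' An ordered sequence of snapshots over a shared node universe with
#' active-edge semantics: an edge is present only in the snapshots where it
#' is listed. Node ids are opaque strings mapped to a dense integer index
#' that is stable across snapshots (required so that node sets can be
#' matched between consecutive snapshots).
#'
#' @param snapshots list of [snapshot()] objects, in temporal order.
#' @param nodes character vector of node names; `nodes[i]` is the name of
#'   internal id `i`.
#' @param name label for the network.
#' @param meta optional list of metadata (e.g. start time and interval
#'   length; informational only).
#' @return An object of class `temporal_network`.
#' @export
temporal_network <- function(snapshots, nodes, name = "network", meta = list()) {
  if (length(snapshots) < 1L) stop("a temporal network needs at least one snapshot")
  if (!all(vapply(snapshots, inherits, logical(1), "snapshot"))) {
    stop("snapshots must be a list of snapshot objects")
  }
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("node names must be unique")
  for (s in snapshots) {
    if (s$n_nodes > length(nodes)) stop("snapshot references nodes outside the universe")
  }
  structure(list(snapshots = snapshots, nodes = nodes,
                 name = name, meta = meta),
            class = "temporal_network")
}

#' @export
print.temporal_network <- function(x, ...) {
  cat(sprintf("<temporal_network '%s': %d snapshots, %d nodes>\n",
              x$name, length(x$snapshots), length(x$nodes)))
  invisible(x)
}

#' Number of snapshots
#' @param net a [temporal_network()].
#' @return integer count of snapshots.
#' @export
n_snapshots <- function(net) length(net$snapshots)

.parse_edge_lines <- function(lines) {
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  list(fields = fields, line_no = idx)
}

#' Read a temporal edge list
#'
#' Plain-text format: one edge per line, whitespace-separated
#' `source target snapshot`, where the snapshot index is a non-negative
#' integer (0-based). Lines starting with `#` and blank lines are skipped.
#' The network gets `max(index) + 1` snapshots; intermediate indices with no
#' edges yield empty snapshots. Edges are undirected (`b a` equals `a b`),
#' duplicates within a snapshot are collapsed, and self-loops are dropped
#' with a warning.
#'
#' @param path path to the edge-list file.
#' @param name network label; defaults to the file name.
#' @return A [temporal_network()].
#' @export
read_temporal_edgelist <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  parsed <- .parse_edge_lines(lines)
  if (length(parsed$fields) == 0L) stop("empty edge list: ", path)
  nf <- lengths(parsed$fields)
  if (any(nf < 3L)) {
    stop(sprintf("malformed line %d: expected 'source target snapshot'",
                 parsed$line_no[which(nf < 3L)[1L]]))
  }
  src <- vapply(parsed$fields, `[[`, character(1), 1L)
  dst <- vapply(parsed$fields, `[[`, character(1), 2L)
  t_raw <- vapply(parsed$fields, `[[`, character(1), 3L)
  t <- suppressWarnings(as.integer(t_raw))
  bad <- which(is.na(t) | t < 0L | as.character(t) != sub("^\\+", "", t_raw))
  if (length(bad) > 0L) {
    stop(sprintf("malformed line %d: snapshot index '%s' is not a non-negative integer",
                 parsed$line_no[bad[1L]], t_raw[bad[1L]]))
  }
  loops <- src == dst
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s) in %s", sum(loops), path))
    src <- src[!loops]; dst <- dst[!loops]; t <- t[!loops]
  }
  if (length(src) == 0L) stop("edge list contains only self-loops: ", path)
  nodes <- sort(unique(c(src, dst)))
  u <- match(src, nodes)
  v <- match(dst, nodes)
  n_snap <- max(t) + 1L
  snaps <- lapply(seq_len(n_snap) - 1L, function(ti) {
    sel <- t == ti
    snapshot(cbind(u[sel], v[sel]), length(nodes))
  })
  temporal_network(snaps, nodes, name = name)
}

#' Write a temporal edge list
#'
#' Inverse of [read_temporal_edgelist()] up to line order and edge
#' orientation: emits TSV lines `source target snapshot` (0-based index).
#'
#' @param net a [temporal_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_temporal_edgelist <- function(net, path) {
  rows <- lapply(seq_along(net$snapshots), function(i) {
    e <- net$snapshots[[i]]$edges
    if (nrow(e) == 0L) return(NULL)
    data.frame(source = net$nodes[e[, 1L]], target = net$nodes[e[, 2L]],
               snapshot = i - 1L, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(source = character(0), target = character(0),
                                    snapshot = integer(0))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a static edge list as a single-snapshot network
#'
#' Format: whitespace-separated `source target` per line; `#` comments
#' allowed. A third column, if present, is ignored.
#'
#' @inheritParams read_temporal_edgelist
#' @return A [temporal_network()] with one snapshot.
#' @export
read_static_edgelist <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  parsed <- .parse_edge_lines(lines)
  if (length(parsed$fields) == 0L) stop("empty edge list: ", path)
  nf <- lengths(parsed$fields)
  if (any(nf < 2L)) {
    stop(sprintf("malformed line %d: expected 'source target'",
                 parsed$line_no[which(nf < 2L)[1L]]))
  }
  src <- vapply(parsed$fields, `[[`, character(1), 1L)
  dst <- vapply(parsed$fields, `[[`, character(1), 2L)
  loops <- src == dst
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s) in %s", sum(loops), path))
    src <- src[!loops]; dst <- dst[!loops]
  }
  nodes <- sort(unique(c(src, dst)))
  temporal_network(list(snapshot(cbind(match(src, nodes), match(dst, nodes)),
                                 length(nodes))),
                   nodes, name = name)
}

#' Aggregate a temporal network into one static snapshot
#'
#' Union of all snapshot edge sets over the full node universe. Static
#' baseline methods (motif fingerprints, graphlet degree distributions) are
#' evaluated on this aggregate.
#'
#' @param net a [temporal_network()].
#' @return A [snapshot()] over the network's node universe.
#' @export
aggregate_network <- function(net) {
  e <- do.call(rbind, lapply(net$snapshots, `[[`, "edges"))
  snapshot(e, length(net$nodes))
}

.snapshot_igraph <- function(snap) {
  g <- igraph::make_empty_graph(n = snap$n_nodes, directed = FALSE)
  if (nrow(snap$edges) > 0L) g <- igraph::add_edges(g, t(snap$edges))
  g
}

#' Per-snapshot global summary metrics
#'
#' For each snapshot: node count, edge count, average degree `2|E|/|V|`,
#' global clustering coefficient (transitivity, 3 x triangles / connected
#' triples), and characteristic path length (mean shortest-path distance on
#' the largest connected component). Snapshots with fewer than two nodes in
#' the largest component report a path length of 0.
#'
#' @param net a [temporal_network()].
#' @return A data frame with one row per snapshot and columns `snapshot`
#'   (0-based index), `nodes`, `edges`, `avg_degree`, `clustering`,
#'   `path_length`.
#' @export
global_metrics <- function(net) {
  rows <- lapply(seq_along(net$snapshots), function(i) {
    snap <- net$snapshots[[i]]
    g <- .snapshot_igraph(snap)
    n <- snap$n_nodes
    m <- nrow(snap$edges)
    cc <- igraph::transitivity(g, type = "global")
    if (is.nan(cc)) cc <- 0
    comp <- igraph::components(g)
    big <- which.max(comp$csize)
    if (comp$csize[big] < 2L) {
      cpl <- 0
    } else {
      sub <- igraph::induced_subgraph(g, which(comp$membership == big))
      cpl <- igraph::mean_distance(sub)
    }
    data.frame(snapshot = i - 1L, nodes = n, edges = m,
               avg_degree = if (n > 0L) 2 * m / n else 0,
               clustering = cc, path_length = cpl)
  })
  do.call(rbind, rows)
}
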