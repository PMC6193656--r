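# Grouping experiment: per-network feature representations for four
# subgraph-based methods, PCA at a variance threshold, min-max-normalized
# Euclidean distances, precision-recall threshold sweep and AUPR, plus
# complete-linkage clustering of similarity matrices.

.net_labels <- function(networks) {
  vapply(networks, function(n) {
    lbl <- n$meta$model
    if (is.null(lbl)) n$name else lbl
  }, character(1))
}

#' Build a method-specific feature matrix over a set of networks
#'
#' One row per network. Methods:
#' * `"sm"`  -- normalized motif scores on the aggregate network
#'   (length `n_graphlets`),
#' * `"sg"`  -- total orbit frequencies on the aggregate network
#'   (length `orbit_count`),
#' * `"stg"` -- concatenated per-snapshot orbit frequencies
#'   (length `snapshots x orbit_count`; all networks must share the
#'   snapshot count),
#' * `"got"` -- flattened orbit-transition count matrix
#'   (length `orbit_count^2`).
#'
#' @param networks list of [temporal_network()] objects.
#' @param method feature tag, one of `"got"`, `"sg"`, `"stg"`, `"sm"`.
#' @param catalog an undirected [build_catalog()].
#' @param n_random randomized replicates for the `"sm"` null model.
#' @param seed optional seed for the `"sm"` null model.
#' @return Numeric matrix with one row per network, row names from network
#'   names and attributes `labels` (model labels) and `method`.
#' @export
build_features <- function(networks, method = c("got", "sg", "stg", "sm"),
                           catalog, n_random = 100L, seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  rows <- switch(method,
    got = lapply(networks, function(n) as.vector(got_matrix(n, catalog))),
    sg = lapply(networks, function(n) {
      colSums(orbit_frequency_matrix(aggregate_network(n), catalog))
    }),
    stg = {
      ns <- vapply(networks, n_snapshots, integer(1))
      if (length(unique(ns)) != 1L) {
        stop("STG features need a common snapshot count across networks")
      }
      lapply(networks, function(n) {
        unlist(lapply(n$snapshots, function(s) {
          colSums(orbit_frequency_matrix(s, catalog))
        }), use.names = FALSE)
      })
    },
    sm = lapply(networks, function(n) {
      motif_fingerprint(aggregate_network(n), catalog,
                        n_random = n_random)$delta_norm
    })
  )
  x <- do.call(rbind, rows)
  rownames(x) <- vapply(networks, `[[`, character(1), "name")
  attr(x, "labels") <- .net_labels(networks)
  attr(x, "method") <- toupper(method)
  x
}

#' Reduce features by PCA at a variance threshold
#'
#' Centers the columns (no per-feature rescaling: features are counts on a
#' common scale within a method) and keeps the smallest number of principal
#' components whose cumulative explained variance reaches the threshold. A
#' constant feature matrix collapses to a single zero component.
#'
#' @param features matrix from [build_features()].
#' @param variance fraction of variance to retain (default 0.99).
#' @return Score matrix (rows preserved) carrying the same `labels`
#'   attribute.
#' @export
pca_reduce <- function(features, variance = 0.99) {
  stopifnot(nrow(features) >= 2L, variance > 0, variance <= 1)
  labels <- attr(features, "labels")
  vars <- apply(features, 2L, stats::var)
  if (all(vars == 0)) {
    out <- matrix(0, nrow(features), 1L, dimnames = list(rownames(features), "PC1"))
  } else {
    p <- prcomp(features, center = TRUE, scale. = FALSE)
    ev <- p$sdev^2
    ncomp <- which(cumsum(ev) / sum(ev) >= variance)[1L]
    out <- p$x[, seq_len(ncomp), drop = FALSE]
  }
  attr(out, "labels") <- labels
  attr(out, "method") <- attr(features, "method")
  out
}

#' Normalized pairwise distance matrix
#'
#' Euclidean distances between feature rows, rescaled affinely so the
#' closest off-diagonal pair is at 0 and the farthest at 1. If all rows are
#' identical the matrix is all-zero and a warning is raised.
#'
#' @param features matrix from [build_features()] or [pca_reduce()].
#' @return Symmetric matrix in `[0, 1]` with attribute
#'   `kind = "euclidean-distance"` and the `labels` attribute carried over.
#' @export
distance_matrix <- function(features) {
  stopifnot(nrow(features) >= 2L)
  d <- as.matrix(dist(features))
  off <- d[upper.tri(d)]
  lo <- min(off)
  hi <- max(off)
  if (hi == lo) {
    warning("all pairwise distances are equal; returning an all-zero matrix")
    d[] <- 0
  } else {
    d <- (d - lo) / (hi - lo)
    d[d < 0] <- 0
    diag(d) <- 0
  }
  attr(d, "kind") <- "euclidean-distance"
  attr(d, "labels") <- attr(features, "labels")
  d
}

#' Precision-recall sweep and AUPR
#'
#' Sweeps a grouping threshold `eps` from 0 to 1 in steps of `step`: at each
#' step, pairs at distance `<= eps` are "grouped"; precision is the fraction
#' of grouped pairs sharing a label (1 when nothing is grouped yet) and
#' recall the fraction of same-label pairs already grouped. The area under
#' the curve is `AUPR = sum_k Pr(k) * (Rec(k) - Rec(k-1))`.
#'
#' @param dist symmetric distance matrix in `[0, 1]` from
#'   [distance_matrix()].
#' @param labels ground-truth label per row; taken from the matrix's
#'   `labels` attribute when omitted.
#' @param step threshold increment (default 0.001, i.e. 1000 steps).
#' @return Object of class `prc_result`: list with `curve` (data frame of
#'   `eps`, `precision`, `recall`) and `aupr`.
#' @export
precision_recall <- function(dist, labels = attr(dist, "labels"),
                             step = 0.001) {
  nn <- nrow(dist)
  stopifnot(nn >= 2L, length(labels) == nn)
  if (length(unique(labels)) < 2L) {
    stop("precision-recall needs at least two label classes")
  }
  up <- upper.tri(dist)
  d <- dist[up]
  same <- outer(labels, labels, `==`)[up]
  n_same <- sum(same)
  if (n_same == 0L) stop("no same-label pair exists; recall is undefined")
  eps <- seq(0, 1, by = step)
  sd_all <- sort(d)
  sd_same <- sort(d[same])
  grouped <- findInterval(eps, sd_all)
  correct <- findInterval(eps, sd_same)
  precision <- ifelse(grouped == 0L, 1, correct / pmax(grouped, 1L))
  recall <- correct / n_same
  aupr <- sum(precision[-1L] * diff(recall))
  structure(list(curve = data.frame(eps = eps, precision = precision,
                                    recall = recall),
                 aupr = aupr),
            class = "prc_result")
}

#' @export
print.prc_result <- function(x, ...) {
  cat(sprintf("<precision-recall sweep: %d steps, AUPR = %.4f>\n",
              nrow(x$curve) - 1L, x$aupr))
  invisible(x)
}

#' Complete-linkage hierarchical clustering of a similarity matrix
#'
#' Agglomerative clustering where the distance between clusters is their
#' maximum pairwise distance. Agreement matrices (OTA/nOTA/GDA, unit
#' diagonal) are converted to distances as `1 - value`; distance matrices
#' are used as-is.
#'
#' @param sim symmetric similarity or distance matrix (the `kind` attribute
#'   set by [ota_matrix()], [gda_matrix()] or [distance_matrix()] decides
#'   the conversion; otherwise set `is_similarity`).
#' @param is_similarity override: `TRUE` to treat values as agreements.
#' @return An [stats::hclust] tree.
#' @export
cluster_complete_linkage <- function(sim, is_similarity = NULL) {
  if (!isTRUE(all.equal(sim, t(sim), check.attributes = FALSE))) {
    stop("input matrix must be symmetric")
  }
  if (is.null(is_similarity)) {
    kind <- attr(sim, "kind")
    is_similarity <- !is.null(kind) && kind %in% c("OTA", "nOTA", "GDA")
  }
  d <- if (is_similarity) 1 - sim else sim
  hclust(as.dist(d), method = "complete")
}

#' Run the synthetic-model grouping experiment
#'
#' End-to-end protocol: generate a replicated suite of model networks,
#' build per-network features for each method, reduce by PCA, normalize
#' pairwise distances, sweep the precision-recall threshold and report the
#' AUPR per method.
#'
#' @param models list of [model_spec()]s (default the six reference
#'   variants at full scale; pass `table1_models(n0 = 100)` etc. to scale
#'   down).
#' @param replicates networks per model.
#' @param k graphlet size used by every method (default 4).
#' @param methods feature methods to evaluate.
#' @param seed master seed for the generator suite.
#' @param step precision-recall threshold increment.
#' @param variance PCA variance retention.
#' @param n_random null-model replicates for the `"sm"` method.
#' @return List with `aupr` (named vector), `prc` (list of `prc_result`),
#'   and `labels`.
#' @export
run_grouping_experiment <- function(models = table1_models(),
                                    replicates = 5L, k = 4L,
                                    methods = c("got", "sg", "stg"),
                                    seed = 1L, step = 0.001,
                                    variance = 0.99, n_random = 100L) {
  catalog <- build_catalog(k)
  nets <- generate_suite(models, replicates = replicates, seed = seed)
  labels <- .net_labels(nets)
  prc <- lapply(methods, function(m) {
    f <- build_features(nets, m, catalog, n_random = n_random)
    precision_recall(distance_matrix(pca_reduce(f, variance)), labels,
                     step = step)
  })
  names(prc) <- toupper(methods)
  list(aupr = vapply(prc, `[[`, numeric(1), "aupr"),
       prc = prc,
       labels = labels)
}
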