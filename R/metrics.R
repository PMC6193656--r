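# Network-comparison metrics: orbit-transition agreement over row-normalized
# transition matrices, GDD-agreement over normalized graphlet degree
# distributions, and motif fingerprints scored against a degree-preserving
# null model.

#' Orbit-transition agreement (OTA)
#'
#' Mean cellwise agreement of two row-normalized transition matrices:
#' `OTA = (1/|O|^2) * sum(1 - |a - b|)`. Symmetric, bounded in `[0, 1]`, and
#' equal to 1 iff the matrices coincide.
#'
#' @param a,b row-normalized transition matrices ([row_normalize()]) built
#'   from the same catalog.
#' @return A single agreement value in `[0, 1]`.
#' @export
ota <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("transition matrices have different dimensions")
  mean(1 - abs(a - b))
}

#' Pairwise OTA similarity matrix
#'
#' Applies [got_matrix()] + [row_normalize()] to each network and computes
#' [ota()] for every pair.
#'
#' @param networks list of [temporal_network()] objects.
#' @param catalog an undirected [build_catalog()].
#' @return Symmetric matrix of OTA values with unit diagonal, network names
#'   as dimnames and attribute `kind = "OTA"`.
#' @export
ota_matrix <- function(networks, catalog) {
  ntrs <- lapply(networks, function(n) row_normalize(got_matrix(n, catalog)))
  nn <- length(ntrs)
  out <- diag(1, nn)
  if (nn >= 2L) {
    for (i in 1:(nn - 1L)) {
      for (j in (i + 1L):nn) {
        out[i, j] <- out[j, i] <- ota(ntrs[[i]], ntrs[[j]])
      }
    }
  }
  nms <- vapply(networks, `[[`, character(1), "name")
  dimnames(out) <- list(nms, nms)
  attr(out, "kind") <- "OTA"
  out
}

#' Relative orbit-transition agreement (nOTA)
#'
#' Min-max rescaling of an OTA matrix over its off-diagonal pairs: the two
#' most similar networks of the set get 1, the two most different get 0.
#' The diagonal is kept at 1. If all off-diagonal agreements are equal the
#' set is degenerate; every pair is set to 1 with a warning.
#'
#' @param ota_mat symmetric OTA matrix from [ota_matrix()].
#' @return Matrix of the same shape with attribute `kind = "nOTA"`.
#' @export
nota <- function(ota_mat) {
  nn <- nrow(ota_mat)
  if (is.null(nn) || nn < 2L) stop("nOTA needs at least two networks")
  off <- ota_mat[upper.tri(ota_mat)]
  lo <- min(off)
  hi <- max(off)
  out <- ota_mat
  if (hi == lo) {
    warning("all pairwise OTA values are equal; nOTA set to 1 for every pair")
    out[] <- 1
  } else {
    out[] <- (ota_mat - lo) / (hi - lo)
    diag(out) <- 1
  }
  attr(out, "kind") <- "nOTA"
  out
}

#' Normalize a graphlet degree distribution
#'
#' Divides every cell by the grand total (the matrix "area") so that the
#' cells sum to 1.
#'
#' @param gdd matrix from [gdd_from_fr()].
#' @return Numeric matrix of the same shape summing to 1.
#' @export
gdd_normalize <- function(gdd) {
  tot <- sum(gdd)
  if (tot == 0) stop("all-zero GDD cannot be normalized")
  gdd / tot
}

#' GDD-agreement (GDA)
#'
#' Arithmetic-mean agreement of two graphlet degree distributions: the
#' multiplicity axes are padded to a common length, both matrices are
#' normalized by total area, each orbit contributes
#' `1 - (1/sqrt(2)) * sqrt(sum_p (nG - nH)^2)`, and the mean over orbits is
#' returned. Equal networks score 1.
#'
#' @param g,h GDD matrices from [gdd_from_fr()] over the same orbit catalog
#'   (equal row counts).
#' @return Agreement value in `[0, 1]`.
#' @export
gda <- function(g, h) {
  if (nrow(g) != nrow(h)) stop("GDDs come from different orbit catalogs")
  maxp <- max(ncol(g), ncol(h))
  pad <- function(x) {
    if (ncol(x) < maxp) {
      x <- cbind(x, matrix(0, nrow(x), maxp - ncol(x)))
    }
    x
  }
  ng <- gdd_normalize(pad(g))
  nh <- gdd_normalize(pad(h))
  per_orbit <- 1 - sqrt(rowSums((ng - nh)^2)) / sqrt(2)
  mean(per_orbit)
}

#' Pairwise GDA similarity matrix
#'
#' Computes the orbit-frequency matrix of each network's aggregate snapshot,
#' derives its GDD and scores every pair with [gda()].
#'
#' @inheritParams ota_matrix
#' @return Symmetric matrix with unit diagonal and attribute `kind = "GDA"`.
#' @export
gda_matrix <- function(networks, catalog) {
  gdds <- lapply(networks, function(n) {
    gdd_from_fr(orbit_frequency_matrix(aggregate_network(n), catalog))
  })
  nn <- length(gdds)
  out <- diag(1, nn)
  if (nn >= 2L) {
    for (i in 1:(nn - 1L)) {
      for (j in (i + 1L):nn) {
        out[i, j] <- out[j, i] <- gda(gdds[[i]], gdds[[j]])
      }
    }
  }
  nms <- vapply(networks, `[[`, character(1), "name")
  dimnames(out) <- list(nms, nms)
  attr(out, "kind") <- "GDA"
  out
}

#' Degree-preserving randomization of a snapshot
#'
#' Applies repeated double-edge swaps (rejecting self-loops and multi-edges)
#' so the degree sequence is preserved exactly while the wiring is
#' randomized. Used as the null model for motif scores.
#'
#' @param snap a [snapshot()].
#' @param swaps number of attempted swaps; defaults to 10 x |E|.
#' @param seed optional integer seed for reproducibility.
#' @return A randomized [snapshot()] with the same degree sequence.
#' @export
randomize_degree_preserving <- function(snap, swaps = 10L * nrow(snap$edges),
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(snap$edges) < 2L) return(snap)
  g <- .snapshot_igraph(snap)
  g <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = swaps))
  e <- igraph::as_edgelist(g, names = FALSE)
  snapshot(e, snap$n_nodes)
}

#' Motif fingerprint of a snapshot
#'
#' Scores each k-graphlet against an ensemble of degree-preserving
#' randomizations: with real frequency `f` and null mean `f0`, the motif
#' score is `delta = (f - f0) / (f + f0)` (0 when both are 0) and the
#' normalized score is `Delta = delta / sqrt(sum(delta^2))`. The vector of
#' normalized scores is the network's motif fingerprint.
#'
#' @param snap a [snapshot()].
#' @param catalog an undirected [build_catalog()].
#' @param n_random number of randomized replicates (the reference protocol
#'   uses 100).
#' @param seed optional integer seed.
#' @param swaps attempted double-edge swaps per replicate.
#' @return Object of class `motif_fingerprint`: a data frame with columns
#'   `graphlet`, `freq`, `null_mean`, `delta`, `delta_norm`.
#' @export
motif_fingerprint <- function(snap, catalog, n_random = 100L, seed = NULL,
                              swaps = 10L * nrow(snap$edges)) {
  stopifnot(n_random >= 1L)
  if (!is.null(seed)) set.seed(seed)
  f <- graphlet_frequencies(snap, catalog)
  null_acc <- numeric(length(f))
  for (r in seq_len(n_random)) {
    rsnap <- randomize_degree_preserving(snap, swaps = swaps)
    null_acc <- null_acc + graphlet_frequencies(rsnap, catalog)
  }
  f0 <- null_acc / n_random
  denom <- f + f0
  delta <- ifelse(denom == 0, 0, (f - f0) / denom)
  norm <- sqrt(sum(delta^2))
  delta_norm <- if (norm > 0) delta / norm else delta
  structure(data.frame(graphlet = names(f), freq = as.numeric(f),
                       null_mean = f0, delta = delta,
                       delta_norm = delta_norm, row.names = NULL),
            class = c("motif_fingerprint", "data.frame"))
}

#' Euclidean distance between fingerprint vectors
#'
#' @param a,b numeric vectors of equal length (e.g. `delta_norm` columns of
#'   two [motif_fingerprint()] results).
#' @return Non-negative distance.
#' @export
fingerprint_distance <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprints have different lengths")
  sqrt(sum((a - b)^2))
}
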