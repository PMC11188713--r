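# Descriptive cell-assembly analysis: non-linear 3-D embedding of cell
# activity vectors, graph-based clustering, dominant-cluster time series
# and sequential transition graphs.  This module is a simplified, pinned
# reproduction of the published visualization pipeline and is not part of
# the inference path.

#' Embed and cluster cells by their activity time series
#'
#' Cells (rows of the binary raster) are compared by Jaccard distance,
#' embedded in three dimensions by non-metric multidimensional scaling
#' (a non-linear embedding), and clustered on a k-nearest-neighbour graph
#' of the embedding with Louvain community detection.  Duplicate rows are
#' collapsed before embedding and share coordinates.  Clusters smaller than
#' `min_size` are merged into the nearest larger cluster by centroid
#' distance.  Deterministic given `seed`.
#'
#' @param raster a `ca_raster` with at least 10 active cells.
#' @param n_neighbors neighbourhood size of the graph.
#' @param dims embedding dimensionality.
#' @param min_size minimum cluster size.
#' @param seed integer seed.
#' @return A list of class `assembly_clustering`: `labels` (0-based,
#'   contiguous), `embedding` (cells x dims), `k` (number of clusters).
#' @export
embed_and_cluster <- function(raster, n_neighbors = 15, dims = 3,
                              min_size = 5, seed = 1) {
  m <- raster$mat
  n <- nrow(m)
  if (n < 10) stop("need at least 10 active cells")
  if (n_neighbors >= n)
    stop("config error: fewer cells than the neighbours parameter")
  key <- apply(m, 1, paste, collapse = "")
  uniq <- !duplicated(key)
  mu <- m[uniq, , drop = FALSE]
  grp <- match(key, key[uniq])
  if (nrow(mu) <= dims) {
    # degenerate: few distinct patterns; each pattern is its own cluster
    emb <- matrix(0, nrow(mu), dims)
    if (nrow(mu) > 1) emb[, 1] <- seq_len(nrow(mu))
    labs_u <- seq_len(nrow(mu))
  } else {
    dj <- .jaccard_dist(mu)
    dj[dj == 0] <- 1e-9
    set.seed(derive_seed(seed, "embed"))
    emb <- tryCatch(
      MASS::isoMDS(dj, k = dims, trace = FALSE)$points,
      error = function(e) stats::cmdscale(dj, k = dims))
    if (ncol(emb) < dims)
      emb <- cbind(emb, matrix(0, nrow(emb), dims - ncol(emb)))
    kk <- min(n_neighbors, nrow(mu) - 1)
    nn <- apply(as.matrix(dist(emb)), 1, function(dr)
      order(dr)[2:(kk + 1)])
    el <- cbind(rep(seq_len(nrow(mu)), each = kk), as.vector(nn))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::simplify(g)
    set.seed(derive_seed(seed, "cluster"))
    labs_u <- igraph::membership(igraph::cluster_louvain(g))
  }
  labels <- as.integer(labs_u[grp])
  # merge undersized clusters into the nearest cluster by centroid
  repeat {
    tab <- table(labels)
    small <- names(tab)[tab < min_size]
    if (!length(small) || length(tab) <= 1) break
    s <- as.integer(small[1])
    cent <- vapply(as.integer(names(tab)), function(l)
      colMeans(emb[grp, , drop = FALSE][labels == l, , drop = FALSE]),
      numeric(dims))
    others <- setdiff(as.integer(names(tab)), s)
    dcent <- vapply(others, function(l)
      sum((cent[, match(s, as.integer(names(tab)))] -
             cent[, match(l, as.integer(names(tab)))])^2), numeric(1))
    labels[labels == s] <- others[which.min(dcent)]
  }
  labels <- as.integer(factor(labels)) - 1L
  structure(list(labels = labels, embedding = emb[grp, , drop = FALSE],
                 k = length(unique(labels))),
            class = "assembly_clustering")
}

.jaccard_dist <- function(m) {
  inter <- tcrossprod(m)
  rs <- rowSums(m)
  un <- outer(rs, rs, `+`) - inter
  d <- 1 - inter / pmax(un, 1)
  stats::as.dist(d)
}

#' Dominant cluster per time bin
#'
#' For every bin, the cluster with the highest fraction of its member cells
#' active, provided that fraction reaches `threshold`; bins with no
#' qualifying cluster, or with a tie at the top, yield `NA`.
#'
#' @param raster a `ca_raster`.
#' @param labels per-cell cluster labels (0-based), as from
#'   [embed_and_cluster()].
#' @param threshold minimum active fraction (default 0.5).
#' @return Integer vector of length `n_bins` (cluster label or `NA`).
#' @export
dominant_cluster_series <- function(raster, labels, threshold = 0.5) {
  m <- raster$mat
  stopifnot(length(labels) == nrow(m))
  ks <- sort(unique(labels))
  frac <- vapply(ks, function(l)
    colMeans(m[labels == l, , drop = FALSE]), numeric(ncol(m)))
  if (is.null(dim(frac))) frac <- matrix(frac, ncol = length(ks))
  apply(frac, 1, function(fr) {
    top <- max(fr)
    if (top < threshold || sum(fr == top) > 1) return(NA_integer_)
    ks[which.max(fr)]
  })
}

#' Sequential cluster-transition graph
#'
#' Counts directed transitions between successive distinct dominant
#' clusters; bins without a dominant cluster are skipped and repeats of the
#' same cluster are ignored, so the total edge weight equals the number of
#' dominant-cluster changes.
#'
#' @param series output of [dominant_cluster_series()].
#' @return A data.frame of class `transition_graph` with columns `src`,
#'   `dst`, `weight` (positive integer counts, no self-edges).
#' @export
transition_graph <- function(series) {
  s <- series[!is.na(series)]
  s <- s[c(TRUE, diff(s) != 0)]            # collapse repeats
  if (length(s) < 2) {
    out <- data.frame(src = integer(0), dst = integer(0), weight = integer(0))
  } else {
    e <- data.frame(src = s[-length(s)], dst = s[-1])
    out <- aggregate(list(weight = rep(1L, nrow(e))), e, sum)
    out <- out[order(out$src, out$dst), ]
    rownames(out) <- NULL
  }
  class(out) <- c("transition_graph", "data.frame")
  out
}
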