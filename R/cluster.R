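# Dimensionality reduction and SNN community detection.
#
# The clustering strategy mirrors the standard single-cell recipe: PCA, a
# shared-nearest-neighbor graph on the retained PCs, modularity-based
# community detection over a resolution grid, and selection of the resolution
# by minimal total within-cluster sum-of-squares with average silhouette
# width breaking near-ties, considering partitions with more than 3 clusters.

#' Reduce a matrix and cluster its rows
#'
#' @param X Numeric matrix (observations x features), typically a scaled
#'   expression layer or a perturbation-score assay.
#' @param n_pcs Number of PCs to retain; default: smallest number explaining
#'   at least `var_target` of the variance captured by the top `max_pcs` PCs
#'   (a formalized elbow rule).
#' @param max_pcs Cap on computed PCs (default 50).
#' @param var_target Variance fraction for the elbow rule (default 0.8).
#' @param k SNN neighborhood size (default 20).
#' @param resolutions Resolution grid for modularity clustering
#'   (default 0.2 to 1.6 by 0.2).
#' @param min_dist UMAP min.dist (default 0.01).
#' @param prune SNN Jaccard pruning threshold (default 1/15).
#' @param min_clusters Partitions must exceed this many clusters to be
#'   eligible for selection (default 3); all partitions are considered when
#'   none qualifies.
#' @param seed Integer seed controlling community detection and UMAP.
#' @param umap Compute UMAP coordinates (default TRUE).
#' @return List: `pcs`, `umap` (or NULL), `cluster` (integer vector),
#'   `resolution`, `grid` (per-resolution diagnostics: n_clusters, wss,
#'   silhouette).
#' @export
reduce_and_cluster <- function(X, n_pcs = NULL, max_pcs = 50L, var_target = 0.8,
                               k = 20L, resolutions = seq(0.2, 1.6, by = 0.2),
                               min_dist = 0.01, prune = 1 / 15,
                               min_clusters = 3L, seed = 1L, umap = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n <= k) stop("fewer observations (", n, ") than SNN neighbors k = ", k)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)

  rank_max <- min(max_pcs, n - 1L, ncol(X))
  if (rank_max >= 3L && rank_max < min(n, ncol(X)) / 2) {
    set.seed(seed)
    pc <- irlba::prcomp_irlba(X, n = rank_max, center = TRUE, scale. = FALSE)
  } else {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = rank_max)
  }
  varfrac <- pc$sdev[seq_len(rank_max)]^2
  varfrac <- varfrac / sum(varfrac)
  if (is.null(n_pcs)) {
    n_pcs <- which(cumsum(varfrac) >= var_target)[1L]
    if (is.na(n_pcs)) n_pcs <- rank_max
  }
  n_pcs <- max(2L, min(n_pcs, rank_max))
  pcs <- pc$x[, seq_len(n_pcs), drop = FALSE]
  rownames(pcs) <- rownames(X)

  g <- .snn_graph(pcs, k = k, prune = prune)
  dmat <- stats::dist(pcs)

  grid <- data.frame(resolution = resolutions, n_clusters = NA_integer_,
                     wss = NA_real_, silhouette = NA_real_)
  memberships <- vector("list", length(resolutions))
  for (i in seq_along(resolutions)) {
    set.seed(seed + i)
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolutions[i],
                                 n_iterations = 5L)
    m <- igraph::membership(cl)
    memberships[[i]] <- as.integer(m)
    grid$n_clusters[i] <- length(unique(m))
    grid$wss[i] <- .total_wss(pcs, m)
    grid$silhouette[i] <- if (grid$n_clusters[i] >= 2L && grid$n_clusters[i] < n) {
      mean(cluster::silhouette(as.integer(m), dmat)[, "sil_width"])
    } else NA_real_
  }
  # Total WSS decreases monotonically as partitions get finer, so it cannot
  # select a resolution on its own; the silhouette is the primary criterion
  # (restricted to partitions with more than `min_clusters` clusters) and
  # WSS breaks silhouette near-ties in favor of the tighter partition.
  eligible <- which(grid$n_clusters > min_clusters & !is.na(grid$silhouette))
  if (!length(eligible)) eligible <- which(!is.na(grid$silhouette))
  if (!length(eligible)) eligible <- seq_along(resolutions)
  sil_max <- max(grid$silhouette[eligible], na.rm = TRUE)
  near <- eligible[!is.na(grid$silhouette[eligible]) &
                     grid$silhouette[eligible] >= sil_max - 0.01]
  if (!length(near)) near <- eligible
  best <- near[which.min(grid$wss[near])]

  um <- NULL
  if (umap) {
    set.seed(seed)
    um <- uwot::umap(pcs, n_neighbors = min(15L, n - 1L), min_dist = min_dist,
                     n_threads = 1L, n_sgd_threads = 1L)
    rownames(um) <- rownames(X)
  }
  list(pcs = pcs, umap = um, cluster = memberships[[best]],
       resolution = resolutions[best], grid = grid)
}

# shared-nearest-neighbor graph with Jaccard weights, pruned
.snn_graph <- function(pcs, k = 20L, prune = 1 / 15) {
  n <- nrow(pcs)
  dm <- as.matrix(stats::dist(pcs))
  nb <- t(apply(dm, 1L, function(r) order(r)[seq_len(k)]))  # incl. self
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                            j = as.integer(t(nb)), x = 1,
                            dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  jac <- shared
  jac@x <- jac@x / (2 * k - jac@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  jac <- Matrix::drop0(jac)
  igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

.total_wss <- function(pcs, membership) {
  s <- 0
  for (cl in unique(membership)) {
    xs <- pcs[membership == cl, , drop = FALSE]
    s <- s + sum(sweep(xs, 2L, colMeans(xs), "-")^2)
  }
  s
}
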