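# Mixscape-style perturbation analysis.
#
# A spot's perturbation signature is its log-normalized expression minus the
# mean of its k nearest non-perturbed (NP) neighbors in PC space, so shared
# local biology cancels and the perturbation-specific component remains.
# Per-target perturbation scores project each signature onto the target's
# mean differential vector; spots are classified perturbed / NP by fixed
# score thresholds (+0.2 / -0.2), and score profiles are clustered (pUMAP)
# to group spots by perturbation response.

#' Map spot assignments onto expression spots as perturbation targets
#'
#' Joins a [assign_spots()] table to the spots of an expression matrix and
#' returns, per expression spot, the target gene of its uniquely assigned or
#' resolved sgRNA (NA otherwise), restricted to sgRNAs whose detection area
#' passes `area_min`, plus the NP flag for sgRNA-free spots.
#'
#' @param E An `expression_matrix`.
#' @param assignment A `spot_assignment`.
#' @param lib A [sgrna_library()] (maps sgRNA to target gene).
#' @param areas Named vector from [sgrna_area()].
#' @param area_min Minimum sgRNA detection area, in spots, for a perturbation
#'   to participate (default 4).
#' @return List: `target` (character per expression spot, NA when
#'   unassigned), `np` (logical: spot has no detected sgRNA).
#' @export
perturbation_targets <- function(E, assignment, lib, areas, area_min = 4L) {
  key_e <- paste0(E$spots$x, "_", E$spots$y)
  key_a <- paste0(assignment$x, "_", assignment$y)
  m <- match(key_e, key_a)
  if (anyNA(m)) stop("expression spots missing from the assignment table")
  lab <- assignment$label[m]
  sg <- assignment$sgrna[m]
  eligible <- names(areas)[areas >= area_min]
  ok <- lab %in% c("unique", "resolved") & sg %in% eligible
  target <- rep(NA_character_, length(lab))
  target[ok] <- lib$gene[match(sg[ok], lib$sgrna_name)]
  ntc <- logical(length(lab))
  ntc[ok] <- lib$is_ntc[match(sg[ok], lib$sgrna_name)]
  target[ntc] <- "NTC"
  list(target = target, np = lab == "non_perturbed")
}

#' Compute perturbation signatures
#'
#' For every spot, signature = lognorm expression minus the mean lognorm
#' expression of its `k` nearest NP spots in PC space. Neighbor search is
#' split by expression cluster: when the spot's cluster contains at least `k`
#' NP spots, neighbors are drawn from that cluster's NP pool, otherwise from
#' the global NP pool.
#'
#' @param E A normalized `expression_matrix`.
#' @param np Logical vector: which expression spots are non-perturbed.
#' @param pcs PC scores of the spots (from [reduce_and_cluster()]); computed
#'   from the scaled layer when NULL.
#' @param clusters Optional integer cluster ids per spot (for split-by-cluster
#'   neighbor search); global pool when NULL.
#' @param k Number of NP neighbors (default 20).
#' @return A `perturbation_signature`: spots x genes dense matrix.
#' @export
calc_signature <- function(E, np, pcs = NULL, clusters = NULL, k = 20L) {
  stopifnot(inherits(E, "expression_matrix"), E$state == "scaled")
  n <- nrow(E$lognorm)
  stopifnot(length(np) == n)
  if (!any(np)) stop("no non-perturbed spots available")
  if (is.null(pcs)) {
    rank_max <- min(30L, n - 1L, ncol(E$scaled))
    pcs <- stats::prcomp(E$scaled, rank. = rank_max)$x
  }
  np_idx <- which(np)
  k_eff <- min(k, length(np_idx))
  sig <- E$lognorm
  pool_for <- function(i) {
    if (!is.null(clusters)) {
      pool <- np_idx[clusters[np_idx] == clusters[i]]
      if (length(pool) >= k_eff) return(pool)
    }
    np_idx
  }
  if (is.null(clusters)) {
    # single global pool: vectorized distance to all NP spots
    d2 <- .cross_dist2(pcs, pcs[np_idx, , drop = FALSE])
    for (i in seq_len(n)) {
      nb <- np_idx[order(d2[i, ])[seq_len(k_eff)]]
      sig[i, ] <- E$lognorm[i, ] - colMeans(E$lognorm[nb, , drop = FALSE])
    }
  } else {
    for (i in seq_len(n)) {
      pool <- pool_for(i)
      d2 <- colSums((t(pcs[pool, , drop = FALSE]) - pcs[i, ])^2)
      nb <- pool[order(d2)[seq_len(min(k_eff, length(pool)))]]
      sig[i, ] <- E$lognorm[i, ] - colMeans(E$lognorm[nb, , drop = FALSE])
    }
  }
  structure(sig, class = c("perturbation_signature", class(sig)))
}

# squared Euclidean distances between rows of A and rows of B
.cross_dist2 <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d[d < 0] <- 0
  d
}

#' Compute per-target perturbation scores and classify spots
#'
#' Per target `t`, the differential vector `v_t` is the mean signature of
#' t-assigned spots minus the mean signature of NP spots, restricted to the
#' `top_m` genes by absolute differential. The raw score of spot `i` for `t`
#' is the projection `<s_i, v_t> / ||v_t||`; scores are scaled by the 95th
#' percentile of |raw score| over t-spots and NP spots so that typical scores
#' lie in about [-1, 1] and the fixed +-0.2 thresholds are meaningful (the
#' scaling convention is this package's own and is configurable).
#'
#' A t-assigned spot is classified `perturbed` when its own-target scaled
#' score exceeds `hi` (default 0.2), `NP` when below `lo` (default -0.2),
#' `unresolved` otherwise. Targets with fewer than 3 spots get NaN scores and
#' are excluded downstream with a warning.
#'
#' @param S A `perturbation_signature`.
#' @param target Character per spot: its perturbation target (NA when none).
#' @param np Logical per spot: NP pool membership.
#' @param top_m Number of top differential genes per target (default 100).
#' @param hi,lo Classification thresholds (default +0.2 / -0.2).
#' @param scale_quantile Quantile of |raw score| used for scaling
#'   (default 0.95).
#' @return A `perturbation_scores` object: list with `scores` (spots x
#'   targets), `class` (character per spot: perturbed/NP/unresolved/NA),
#'   `target`, `np`, `targets` (usable targets).
#' @export
calc_scores <- function(S, target, np, top_m = 100L, hi = 0.2, lo = -0.2,
                        scale_quantile = 0.95) {
  S <- unclass(S)
  n <- nrow(S)
  stopifnot(length(target) == n, length(np) == n)
  targets <- setdiff(unique(target[!is.na(target)]), NA)
  np_idx <- which(np)
  if (!length(np_idx)) stop("no NP spots")
  mu_np <- colMeans(S[np_idx, , drop = FALSE])
  scores <- matrix(NA_real_, n, length(targets),
                   dimnames = list(rownames(S), targets))
  usable <- character(0)
  for (t in targets) {
    t_idx <- which(!is.na(target) & target == t)
    if (length(t_idx) < 3L) {
      warning("target ", t, " has fewer than 3 spots; scores set to NaN")
      scores[, t] <- NaN
      next
    }
    v <- colMeans(S[t_idx, , drop = FALSE]) - mu_np
    sel <- order(abs(v), decreasing = TRUE)[seq_len(min(top_m, length(v)))]
    vs <- v[sel]
    nv <- sqrt(sum(vs^2))
    if (nv == 0) { scores[, t] <- 0; usable <- c(usable, t); next }
    raw <- as.numeric(S[, sel, drop = FALSE] %*% vs) / nv
    ref <- stats::quantile(abs(raw[c(t_idx, np_idx)]), scale_quantile,
                           names = FALSE)
    if (ref == 0) ref <- 1
    scores[, t] <- raw / ref
    usable <- c(usable, t)
  }
  cls <- rep(NA_character_, n)
  cls[np] <- "NP"
  for (t in usable) {
    t_idx <- which(!is.na(target) & target == t)
    s <- scores[t_idx, t]
    cls[t_idx] <- ifelse(s > hi, "perturbed", ifelse(s < lo, "NP", "unresolved"))
  }
  structure(list(scores = scores, class = cls, target = target, np = np,
                 targets = usable, hi = hi, lo = lo),
            class = "perturbation_scores")
}

#' Label perturbation clusters by their major perturbations
#'
#' A perturbation is "major" in a cluster when its perturbed spots are
#' strictly more than `major_frac` (default 20%) of the cluster's spots.
#' Clusters with at least one major perturbation are labeled by them
#' (joined by `+`); clusters with none are labeled `"NP + n"`, where `n`
#' counts the distinct perturbations detected in the cluster.
#'
#' @param cluster Integer cluster ids (1-based) per spot.
#' @param class Per-spot classification (`perturbed`/`NP`/...).
#' @param target Per-spot perturbation target (NA when none).
#' @param major_frac Major-perturbation threshold (strict `>`).
#' @return Character vector of labels, one per cluster id.
#' @export
label_perturbation_clusters <- function(cluster, class, target,
                                        major_frac = 0.2) {
  lab <- character(max(cluster))
  for (c_id in seq_len(max(cluster))) {
    members <- which(cluster == c_id)
    pert <- target[members][class[members] == "perturbed" &
                              !is.na(target[members])]
    frac <- table(pert) / length(members)
    major <- names(frac)[frac > major_frac]
    lab[c_id] <- if (length(major)) paste(sort(major), collapse = "+")
                 else paste0("NP + ", length(unique(pert)))
  }
  lab
}

#' Cluster spots by perturbation-score profiles (pUMAP)
#'
#' Restricts the score assay to classified spots (perturbed or NP), reduces
#' and clusters it with the standard strategy, and labels each cluster by its
#' major perturbations: every perturbation whose perturbed spots exceed
#' `major_frac` (default 20%) of the cluster. Clusters with no major
#' perturbation are labeled `"NP + n"` with `n` the number of distinct
#' perturbations detected in the cluster.
#'
#' @param A A `perturbation_scores` object.
#' @param major_frac Major-perturbation fraction threshold (default 0.2,
#'   strict greater-than).
#' @param k SNN neighbors (default 20, reduced to fit small assays).
#' @param seed Seed for clustering/UMAP.
#' @param ... Passed to [reduce_and_cluster()].
#' @return A `pumap_result`: list with `spots` (indices into the assay),
#'   `cluster`, `label` (per cluster id), `umap`, `resolution`.
#' @export
pumap_cluster <- function(A, major_frac = 0.2, k = 20L, seed = 1L, ...) {
  stopifnot(inherits(A, "perturbation_scores"))
  if (length(A$targets) < 2L) stop("need at least 2 perturbation targets")
  keep <- which(A$class %in% c("perturbed", "NP"))
  X <- A$scores[keep, A$targets, drop = FALSE]
  X[!is.finite(X)] <- 0
  k_eff <- max(2L, min(k, nrow(X) - 1L))
  rc <- reduce_and_cluster(X, k = k_eff, seed = seed, ...)
  cl <- rc$cluster
  lab <- label_perturbation_clusters(cl, A$class[keep], A$target[keep],
                                     major_frac = major_frac)
  structure(list(spots = keep, cluster = cl, label = lab,
                 cluster_label = lab[cl], umap = rc$umap,
                 resolution = rc$resolution, grid = rc$grid),
            class = "pumap_result")
}
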