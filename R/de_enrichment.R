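# Differential expression, preranked gene-set enrichment, tRNA isotype
# aggregation, and miRNA-target correlation.

#' Wilcoxon rank-sum differential expression between spot groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test on the lognorm layer using the
#' normal approximation with tie correction (no continuity correction), BH
#' adjustment across tested genes. Log fold-change is computed on the
#' de-logged lognorm means with a small pseudocount:
#' `log2((mean_A + eps) / (mean_B + eps))` on `expm1(lognorm)`.
#'
#' @param E A normalized `expression_matrix`.
#' @param groupA,groupB Spot indices (rows of the expression matrix); both
#'   must have at least 3 spots.
#' @param eps Fold-change pseudocount (default 1e-9).
#' @return A `de_result` data.frame: `gene, lfc, p, padj, det_a, det_b`
#'   (detection fractions: share of group spots with raw count >= 1).
#' @export
wilcoxon_de <- function(E, groupA, groupB, eps = 1e-9) {
  stopifnot(inherits(E, "expression_matrix"), E$state == "scaled")
  if (!length(groupA) || !length(groupB)) stop("empty group")
  if (length(groupA) < 3L || length(groupB) < 3L) stop("both groups need >= 3 spots")
  ln <- E$lognorm
  nA <- length(groupA); nB <- length(groupB); N <- nA + nB
  comb <- ln[c(groupA, groupB), , drop = FALSE]
  stats_pg <- apply(comb, 2L, function(v) {
    r <- rank(v)
    U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
    ties <- table(v)
    tiecorr <- sum(ties^3 - ties)
    sigma2 <- nA * nB / 12 * ((N + 1) - tiecorr / (N * (N - 1)))
    c(U = U, sigma2 = sigma2)
  })
  U <- stats_pg["U", ]; sigma2 <- stats_pg["sigma2", ]
  z <- (U - nA * nB / 2) / sqrt(pmax(sigma2, 0))
  p <- 2 * stats::pnorm(-abs(z))
  p[!is.finite(z) | sigma2 <= 0] <- 1   # fully tied genes
  p <- pmin(p, 1)
  mA <- colMeans(expm1(ln[groupA, , drop = FALSE]))
  mB <- colMeans(expm1(ln[groupB, , drop = FALSE]))
  lfc <- log2((mA + eps) / (mB + eps))
  detA <- Matrix::colMeans(E$counts[groupA, , drop = FALSE] >= 1)
  detB <- Matrix::colMeans(E$counts[groupB, , drop = FALSE] >= 1)
  res <- data.frame(gene = colnames(ln), lfc = lfc, p = p,
                    padj = stats::p.adjust(p, "BH"),
                    det_a = as.numeric(detA), det_b = as.numeric(detB),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "method") <- "wilcoxon"
  class(res) <- c("de_result", "data.frame")
  res
}

#' Pseudo-replicate Wilcoxon differential expression
#'
#' Spots of each group are randomly partitioned (seeded) into `r`
#' pseudo-replicates; per-gene mean lognorm of each partition forms a
#' pseudobulk value, and an exact r-vs-r Wilcoxon rank-sum test compares the
#' pseudobulks. Each pseudo-replicate needs at least `min_spots` spots,
#' otherwise the function falls back to spot-level [wilcoxon_de()] with a
#' warning (flagged via the `method` attribute).
#'
#' @inheritParams wilcoxon_de
#' @param r Number of pseudo-replicates per group (default 3).
#' @param min_spots Minimum spots per pseudo-replicate (default 5).
#' @param seed Integer seed for the random partition.
#' @return A `de_result` data.frame (see [wilcoxon_de()]); `method` attribute
#'   is `"pseudo_replicate"` or `"wilcoxon"` after fallback.
#' @export
pseudo_replicate_de <- function(E, groupA, groupB, r = 3L, min_spots = 5L,
                                seed = 1L, eps = 1e-9) {
  stopifnot(r >= 3L)
  if (length(groupA) < r * min_spots || length(groupB) < r * min_spots) {
    warning("groups too small for ", r, " pseudo-replicates of >= ", min_spots,
            " spots; falling back to spot-level Wilcoxon")
    return(wilcoxon_de(E, groupA, groupB, eps = eps))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  split_idx <- function(g) split(sample(g), rep_len(seq_len(r), length(g)))
  pa <- split_idx(groupA); pb <- split_idx(groupB)
  ln <- E$lognorm
  bulk <- function(parts) t(vapply(parts, function(i) {
    colMeans(ln[i, , drop = FALSE])
  }, numeric(ncol(ln))))
  bA <- bulk(pa); bB <- bulk(pb)
  p <- vapply(seq_len(ncol(ln)), function(j) {
    suppressWarnings(stats::wilcox.test(bA[, j], bB[, j])$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  mA <- colMeans(expm1(ln[groupA, , drop = FALSE]))
  mB <- colMeans(expm1(ln[groupB, , drop = FALSE]))
  detA <- Matrix::colMeans(E$counts[groupA, , drop = FALSE] >= 1)
  detB <- Matrix::colMeans(E$counts[groupB, , drop = FALSE] >= 1)
  res <- data.frame(gene = colnames(ln), lfc = log2((mA + eps) / (mB + eps)),
                    p = p, padj = stats::p.adjust(p, "BH"),
                    det_a = as.numeric(detA), det_b = as.numeric(detB),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "method") <- "pseudo_replicate"
  class(res) <- c("de_result", "data.frame")
  res
}

#' Filter a DE result to significant genes
#'
#' Two filter modes used downstream of clustering:
#' `cluster_markers` keeps genes with adjusted p < 0.05 and detection in the
#' cluster (group A) above 20%; `heatmap` keeps genes with adjusted p < 0.05,
#' absolute log2 fold-change above 1, and absolute detection-fraction
#' difference between groups above 25%.
#'
#' @param res A `de_result`.
#' @param mode `"cluster_markers"` or `"heatmap"`.
#' @param padj_max,det_min,lfc_min,det_diff_min Threshold overrides.
#' @param signed_detection Use the signed rather than absolute detection
#'   difference in heatmap mode (default FALSE).
#' @return Character vector of passing gene names.
#' @export
de_filter <- function(res, mode = c("cluster_markers", "heatmap"),
                      padj_max = 0.05, det_min = 0.20, lfc_min = 1,
                      det_diff_min = 0.25, signed_detection = FALSE) {
  mode <- match.arg(mode)
  if (mode == "cluster_markers") {
    keep <- res$padj < padj_max & res$det_a > det_min
  } else {
    dd <- if (signed_detection) res$det_a - res$det_b else abs(res$det_a - res$det_b)
    keep <- res$padj < padj_max & abs(res$lfc) > lfc_min & dd > det_diff_min
  }
  res$gene[keep & !is.na(keep)]
}

# weighted Kolmogorov-Smirnov running-sum enrichment score
.gsea_es <- function(stat_sorted, in_set, p = 0.1) {
  N <- length(stat_sorted)
  n_set <- sum(in_set)
  w <- abs(stat_sorted)^p
  nr <- sum(w[in_set])
  if (nr == 0) nr <- 1
  step <- ifelse(in_set, w / nr, -1 / (N - n_set))
  run <- cumsum(step)
  peak <- which.max(abs(run))
  list(es = run[peak], peak = peak, run = run)
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment with weight
#' `|rank|^gsea_param` (default exponent 0.1), significance by seeded
#' gene-label permutation. Sets are filtered to those with `min_size` to
#' `max_size` members present in the ranking (defaults 2 and 500), and sets
#' named exactly `"Translation"`, `"Transcription"`, or `"Gene Expression"`
#' are removed as uninformatively broad. The ranking is expected to be
#' already restricted upstream (e.g. DE genes at adjusted p < 0.2) with
#' log2 fold-changes as the rank statistic.
#'
#' @param ranks Named numeric vector: gene -> rank statistic (log2FC).
#' @param sets Named list of character vectors (gene sets, e.g. from
#'   [read_gmt()]).
#' @param gsea_param Weight exponent (default 0.1).
#' @param min_size,max_size Set-size bounds after intersection with `ranks`
#'   (defaults 2 and 500).
#' @param nperm Gene-label permutations (default 10000).
#' @param seed Integer seed.
#' @param exclude Set names removed verbatim.
#' @return A `gsea_result` data.frame: `pathway, size, es, nes, p, padj,
#'   leading_edge` (semicolon-joined genes).
#' @export
gsea_preranked <- function(ranks, sets, gsea_param = 0.1, min_size = 2L,
                           max_size = 500L, nperm = 10000L, seed = 1L,
                           exclude = c("Translation", "Transcription",
                                       "Gene Expression")) {
  stopifnot(!is.null(names(ranks)))
  ranks <- ranks[!is.na(ranks)]
  o <- order(ranks, decreasing = TRUE)
  stat <- ranks[o]
  genes <- names(stat)
  sets <- sets[setdiff(names(sets), exclude)]
  sizes <- vapply(sets, function(s) length(intersect(s, genes)), integer(1))
  sets <- sets[sizes >= min_size & sizes <= max_size]
  if (!length(sets)) {
    warning("no gene sets survive the size filter")
    out <- data.frame(pathway = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0), p = numeric(0),
                      padj = numeric(0), leading_edge = character(0))
    class(out) <- c("gsea_result", "data.frame")
    return(out)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  N <- length(genes)
  res <- vector("list", length(sets))
  for (si in seq_along(sets)) {
    in_set <- genes %in% sets[[si]]
    n_set <- sum(in_set)
    obs <- .gsea_es(stat, in_set, p = gsea_param)
    set.seed(seed + si)
    perm_es <- vapply(seq_len(nperm), function(b) {
      idx <- sample.int(N, n_set)
      flag <- logical(N); flag[idx] <- TRUE
      .gsea_es(stat, flag, p = gsea_param)$es
    }, numeric(1))
    same_sign <- perm_es * sign(obs$es) > 0
    pval <- (1 + sum(perm_es * sign(obs$es) >= abs(obs$es))) / (1 + nperm)
    denom <- mean(abs(perm_es[same_sign]))
    nes <- if (is.finite(denom) && denom > 0) obs$es / denom else NA_real_
    le <- if (obs$es >= 0) genes[seq_len(obs$peak)][in_set[seq_len(obs$peak)]]
          else genes[obs$peak:N][in_set[obs$peak:N]]
    res[[si]] <- data.frame(pathway = names(sets)[si], size = n_set,
                            es = obs$es, nes = nes, p = pval,
                            leading_edge = paste(le, collapse = ";"),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$padj <- stats::p.adjust(out$p, "BH")
  out <- out[, c("pathway", "size", "es", "nes", "p", "padj", "leading_edge")]
  rownames(out) <- NULL
  class(out) <- c("gsea_result", "data.frame")
  out
}

# canonical amino-acid isotype tokens (20 AAs + initiator Met + SeC bucket)
.trna_isotypes <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                    "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                    "Thr", "Trp", "Tyr", "Val", "iMet", "SeC")

#' Aggregate tRNA counts by amino-acid isotype
#'
#' Sums raw counts of all tRNA features decoding the same amino acid, per
#' spot. Features of class `tRNA` are parsed for an isotype token in their
#' name (e.g. `tRNA-His-GTG`); features without a recognizable token are
#' collected under `unknown` with a warning. Conservation holds by
#' construction: isotype sums plus `unknown` equal total tRNA counts per
#' spot.
#'
#' @param E An `expression_matrix` whose `feature_class` marks tRNA genes.
#' @param isotypes Recognized isotype tokens (default: 20 amino acids plus
#'   `iMet` and `SeC`).
#' @return spots x isotypes dense matrix (plus an `unknown` column when
#'   needed).
#' @export
trna_isotype_aggregate <- function(E, isotypes = .trna_isotypes) {
  trna <- names(E$feature_class)[E$feature_class == "tRNA"]
  out <- matrix(0, nrow(E$counts), length(isotypes),
                dimnames = list(rownames(E$counts), isotypes))
  if (!length(trna)) return(out)
  # longest token first so iMet wins over Met, SeC over Ser/Cys patterns
  toks <- isotypes[order(nchar(isotypes), decreasing = TRUE)]
  assign_iso <- vapply(trna, function(g) {
    hit <- toks[vapply(toks, function(t) grepl(t, g, fixed = TRUE), logical(1))]
    if (length(hit)) hit[1L] else NA_character_
  }, character(1))
  unknown <- trna[is.na(assign_iso)]
  if (length(unknown)) {
    warning("unmappable tRNA feature(s): ", paste(unknown, collapse = ", "))
    out <- cbind(out, unknown = 0)
  }
  cm <- as.matrix(E$counts[, trna, drop = FALSE])
  for (i in seq_along(trna)) {
    iso <- ifelse(is.na(assign_iso[i]), "unknown", assign_iso[i])
    out[, iso] <- out[, iso] + cm[, i]
  }
  out
}

#' Correlate a miRNA with candidate target genes across spots
#'
#' Rank (Spearman) correlation of a miRNA's lognorm expression with each
#' user-supplied target gene's lognorm across spots; a negative rho flags
#' candidate repression. Requires at least `min_nonzero` spots with nonzero
#' miRNA counts. Target prediction itself is out of scope; the target list
#' comes from the user.
#'
#' @param E A normalized `expression_matrix`.
#' @param mirna miRNA feature name.
#' @param targets Character vector of target gene names.
#' @param method Correlation method (default `"spearman"`).
#' @param min_nonzero Minimum spots with nonzero miRNA (default 10).
#' @return data.frame: `target, rho, p, q` (BH-adjusted); `rho` is NA for
#'   constant vectors.
#' @export
mirna_target_correlation <- function(E, mirna, targets, method = "spearman",
                                     min_nonzero = 10L) {
  stopifnot(inherits(E, "expression_matrix"), E$state == "scaled")
  if (!mirna %in% colnames(E$lognorm)) stop("unknown miRNA feature: ", mirna)
  mv <- E$lognorm[, mirna]
  if (sum(E$counts[, mirna] > 0) < min_nonzero) {
    stop("fewer than ", min_nonzero, " spots with nonzero ", mirna)
  }
  res <- lapply(targets, function(g) {
    if (!g %in% colnames(E$lognorm)) {
      return(data.frame(target = g, rho = NA_real_, p = NA_real_))
    }
    tv <- E$lognorm[, g]
    if (stats::sd(tv) == 0 || stats::sd(mv) == 0) {
      return(data.frame(target = g, rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(stats::cor.test(mv, tv, method = method))
    data.frame(target = g, rho = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}
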