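# Wilcoxon DE, pseudo-replicates, filters, GSEA, tRNA isotypes, miRNA
# correlation.

make_de_fixture <- function(n = 24L, genes = 30L, seed = 61L) {
  set.seed(seed)
  counts <- matrix(rpois(n * genes, 5), n, genes,
                   dimnames = list(NULL, paste0("g", seq_len(genes))))
  normalize_expression(expression_matrix(counts, x = seq_len(n),
                                         y = rep(1L, n)))
}

test_that("identical groups give zero fold-change and flat p-values", {
  E <- make_de_fixture()
  res <- wilcoxon_de(E, 1:8, 1:8)
  expect_true(all(res$lfc == 0))
  expect_true(all(res$p == 1))
  expect_error(wilcoxon_de(E, integer(0), 1:5), "empty group")
  expect_error(wilcoxon_de(E, 1:2, 3:8), ">= 3 spots")
})

test_that("rank-sum statistic and p match the standard test per gene", {
  E <- make_de_fixture(n = 20L, genes = 25L, seed = 67L)
  res <- wilcoxon_de(E, 1:9, 10:20)
  for (j in seq_len(25)) {
    w <- suppressWarnings(
      stats::wilcox.test(E$lognorm[1:9, j], E$lognorm[10:20, j],
                         exact = FALSE, correct = FALSE))
    if (stats::sd(E$lognorm[c(1:9, 10:20), j]) == 0) {
      expect_equal(res$p[j], 1)
    } else {
      expect_equal(res$p[j], w$p.value, tolerance = 1e-12)
    }
  }
  # U statistic equals exhaustive pair counting for a hand-built gene
  a <- c(3, 4, 5); b <- c(0, 0, 1)
  U <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  r <- rank(c(a, b))
  expect_equal(sum(r[1:3]) - 3 * 4 / 2, U)
})

test_that("a constant gene across all spots yields p = 1", {
  E <- make_de_fixture()
  E$lognorm[, "g1"] <- 1.5
  res <- wilcoxon_de(E, 1:10, 11:24)
  expect_equal(res$p[res$gene == "g1"], 1)
})

test_that("pseudo-replicate DE is seeded, sane under null, sharp under shift", {
  E <- make_de_fixture(n = 40L, genes = 40L, seed = 71L)
  r1 <- pseudo_replicate_de(E, 1:20, 21:40, seed = 5L)
  r2 <- pseudo_replicate_de(E, 1:20, 21:40, seed = 5L)
  expect_identical(r1, r2)
  expect_equal(attr(r1, "method"), "pseudo_replicate")
  expect_gte(stats::median(r1$p), 0.1)  # null data
  # a strong deterministic shift on one gene ranks it first
  E2 <- E; E2$lognorm[1:20, "g7"] <- E2$lognorm[1:20, "g7"] + 10
  r3 <- pseudo_replicate_de(E2, 1:20, 21:40, seed = 5L)
  # exact r-vs-r Wilcoxon p-values floor at 2/choose(2r, r), so ties are
  # possible: the shifted gene must attain the minimal p and the top LFC
  expect_equal(r3$p[r3$gene == "g7"], min(r3$p))
  expect_equal(r3$gene[which.max(r3$lfc)], "g7")
  # too-small groups fall back with a warning
  expect_warning(rf <- pseudo_replicate_de(E, 1:6, 7:12, seed = 1L),
                 "falling back")
  expect_equal(attr(rf, "method"), "wilcoxon")
})

test_that("DE filters apply the printed thresholds strictly", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    lfc = c(1.2, 0.9, 1.5, 2.0),
                    p = c(0.001, 0.001, 0.002, 0.001),
                    padj = c(0.04, 0.04, 0.051, 0.04),
                    det_a = c(0.50, 0.50, 0.60, 0.30),
                    det_b = c(0.20, 0.20, 0.10, 0.10))
  class(res) <- c("de_result", "data.frame")
  expect_true("a" %in% de_filter(res, "heatmap"))     # passes all three
  expect_false("b" %in% de_filter(res, "heatmap"))    # |LFC| <= 1
  expect_false("c" %in% de_filter(res, "heatmap"))    # padj >= 0.05
  expect_false("c" %in% de_filter(res, "cluster_markers"))
  expect_true("a" %in% de_filter(res, "cluster_markers"))
  # heatmap filter is a subset of any relaxed variant
  relaxed <- de_filter(res, "heatmap", lfc_min = 0.5, det_diff_min = 0.1)
  expect_true(all(de_filter(res, "heatmap") %in% relaxed))
  expect_error(de_filter(res, "volcano"), "arg")
})

# independent running-sum oracle, written against the textbook definition
oracle_es <- function(ranks, set, p = 0.1) {
  o <- order(ranks, decreasing = TRUE)
  stat <- ranks[o]
  genes <- names(stat)
  inset <- genes %in% set
  nr <- sum(abs(stat[inset])^p)
  run <- 0; best <- 0
  miss <- 1 / (length(genes) - sum(inset))
  for (i in seq_along(genes)) {
    run <- run + if (inset[i]) abs(stat[i])^p / nr else -miss
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

test_that("GSEA enrichment scores equal the running-sum oracle exactly", {
  set.seed(73)
  for (rep in 1:50) {
    ng <- sample(20:60, 1)
    ranks <- setNames(rnorm(ng), paste0("G", seq_len(ng)))
    set <- sample(names(ranks), sample(3:8, 1))
    res <- gsea_preranked(ranks, list(S = set), nperm = 10L, seed = rep)
    expect_equal(res$es, oracle_es(ranks, set), tolerance = 1e-12)
  }
})

test_that("GSEA agrees with the reference implementation's statistic", {
  skip_if_not_installed("fgsea")
  set.seed(79)
  ranks <- setNames(rnorm(40), paste0("G", 1:40))
  set <- sample(names(ranks), 6)
  res <- gsea_preranked(ranks, list(S = set), nperm = 10L, seed = 1L)
  stat_sorted <- sort(ranks, decreasing = TRUE)
  ref <- fgsea::calcGseaStat(stat_sorted,
                             which(names(stat_sorted) %in% set),
                             gseaParam = 0.1)
  expect_equal(res$es, ref, tolerance = 1e-10)
})

test_that("GSEA applies size bounds, exclusions and scale invariance", {
  ranks <- setNames(seq(2, -2, length.out = 20), paste0("G", 1:20))
  sets <- list(top = paste0("G", 1:5),
               absent = paste0("X", 1:5),
               Translation = paste0("G", 6:10))
  expect_warning(res_all <- gsea_preranked(ranks, sets["absent"], nperm = 10L),
                 "no gene sets")
  res <- gsea_preranked(ranks, sets, nperm = 99L, seed = 2L)
  expect_equal(res$pathway, "top")         # absent filtered, Translation excluded
  expect_gt(res$es, 0)
  expect_lte(abs(res$es), 1)
  # ES is invariant to positive rescaling of the ranks
  res2 <- gsea_preranked(ranks * 7.3, sets, nperm = 10L, seed = 2L)
  expect_equal(res2$es, res$es, tolerance = 1e-12)
  # a top-k set scores higher than same-size random sets
  set.seed(83)
  rand_es <- replicate(30, {
    gsea_preranked(ranks, list(R = sample(names(ranks), 5)), nperm = 10L)$es
  })
  expect_gte(res$es, max(rand_es))
})

test_that("tRNA isotype aggregation sums by amino acid and conserves counts", {
  counts <- cbind("tRNA-His-GTG" = c(2L, 0L), "tRNA-His-ATG" = c(3L, 1L),
                  "tRNA-Ser-AGA" = c(1L, 4L), GENE1 = c(9L, 9L))
  E <- expression_matrix(counts, x = 1:2, y = c(1L, 1L),
                         feature_class = c("tRNA", "tRNA", "tRNA",
                                           "protein_coding"))
  iso <- trna_isotype_aggregate(E)
  expect_equal(unname(iso[, "His"]), c(5, 1))
  expect_equal(unname(iso[, "Ser"]), c(1, 4))
  expect_equal(unname(rowSums(iso)),
               unname(Matrix::rowSums(E$counts[, 1:3])))
  # no tRNA features -> all-zero matrix
  E2 <- expression_matrix(cbind(GENE1 = 1:2), x = 1:2, y = c(1L, 1L))
  expect_true(all(trna_isotype_aggregate(E2) == 0))
  # unmappable features are collected under "unknown" with a warning
  counts3 <- cbind("tRNA-weird" = c(2L, 2L), "tRNA-His-GTG" = c(1L, 0L))
  E3 <- expression_matrix(counts3, x = 1:2, y = c(1L, 1L),
                          feature_class = c("tRNA", "tRNA"))
  expect_warning(iso3 <- trna_isotype_aggregate(E3), "unmappable")
  expect_equal(unname(iso3[, "unknown"]), c(2, 2))
  expect_equal(unname(rowSums(iso3)), unname(Matrix::rowSums(E3$counts)))
})

test_that("miRNA-target correlation recovers signed monotone relations", {
  set.seed(89)
  n <- 40
  mir <- rpois(n, 20)
  up <- mir * 2L + 1L
  down <- as.integer(max(mir) - mir + 1L)
  noise <- rpois(n, 10)
  flat <- rep(3L, n)
  # padding gene equalizes library sizes so lognorm is monotone per gene
  pad <- max(mir + up + down + noise) - (mir + up + down + noise) + 100L
  counts <- cbind("miR-1" = mir, up = up, down = down, flat = flat,
                  noise = noise, pad = pad)
  E <- normalize_expression(expression_matrix(counts, x = 1:n, y = rep(1L, n)))
  res <- mirna_target_correlation(E, "miR-1", c("up", "down", "flat", "noise"))
  expect_gt(res$rho[res$target == "up"], 0.95)
  expect_lt(res$rho[res$target == "down"], -0.95)
  expect_true(is.na(res$rho[res$target == "flat"]))
  expect_lt(abs(res$rho[res$target == "noise"]), 0.5)
  expect_error(mirna_target_correlation(E, "absent", "up"), "unknown miRNA")
})

test_that("BH adjustment preserves the p-value ordering", {
  E <- make_de_fixture(n = 30L, genes = 50L, seed = 97L)
  E$lognorm[1:15, 1:5] <- E$lognorm[1:15, 1:5] + 2
  res <- wilcoxon_de(E, 1:15, 16:30)
  expect_equal(order(res$p), order(res$padj + res$p * 1e-12))
  expect_true(all(res$padj >= res$p))
})
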