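# The ground-truth generator: determinism, geometry, expression, reads,
# pooled tables.

test_that("tissue generation is deterministic and respects geometry", {
  t1 <- generate_tissue(c(20L, 20L), n_regions = 2L, seed = 5L)
  t2 <- generate_tissue(c(20L, 20L), n_regions = 2L, seed = 5L)
  expect_identical(t1, t2)
  expect_error(generate_tissue(c(5L, 20L)), "at least 10x10")

  # a single region on a 20x20 grid is 4-connected
  t3 <- generate_tissue(c(20L, 20L), n_regions = 1L, tissue_frac = 0.3,
                        seed = 7L)
  spots <- which(t3$tissue)
  seen <- spots[1]
  frontier <- spots[1]
  while (length(frontier)) {
    nb <- unique(unlist(lapply(frontier, spotscreen:::.grid_neighbors,
                               grid_dims = c(20L, 20L))))
    frontier <- setdiff(intersect(nb, spots), seen)
    seen <- c(seen, frontier)
  }
  expect_setequal(seen, spots)
})

test_that("clones are contiguous, sized as requested, and within tissue", {
  tis <- generate_tissue(c(20L, 20L), n_regions = 1L, tissue_frac = 0.8,
                         seed = 11L)
  lib <- tiny_library()
  cl <- seed_clones(tis, lib, n_clones = 1L, size_mean = 30, size_sdlog = 0,
                    seed = 13L)
  got <- which(cl$clone == 1L)
  expect_equal(length(got), sum(!is.na(cl$sgrna)))
  expect_equal(cl$clones$size, length(got))
  expect_true(all(tis$tissue[got]))
  # 4-connectivity of the clone
  seen <- got[1]; frontier <- got[1]
  while (length(frontier)) {
    nb <- unique(unlist(lapply(frontier, spotscreen:::.grid_neighbors,
                               grid_dims = c(20L, 20L))))
    frontier <- setdiff(intersect(nb, got), seen)
    seen <- c(seen, frontier)
  }
  expect_setequal(seen, got)
  expect_error(seed_clones(tis, lib, n_clones = 100L, size_mean = 10,
                           size_sdlog = 0, seed = 1L), "exceeds")
  # oversized draws are rescaled into the tissue budget instead of failing
  big <- seed_clones(tis, lib, n_clones = 2L, size_mean = 1000,
                     size_sdlog = 0, seed = 1L)
  expect_lte(sum(big$clones$size), sum(tis$tissue))
})

test_that("NB expression responds to effect factors and zero means", {
  tis <- generate_tissue(c(20L, 20L), n_regions = 1L, tissue_frac = 1.0,
                         seed = 17L)
  lib <- tiny_library()
  panel <- data.frame(gene = c("gA", "gB", "gZero"),
                      class = rep("protein_coding", 3),
                      base_mean = c(20, 20, 0), dispersion = c(0.05, 0.05, 0.1))
  clone <- integer(400); sgr <- rep(NA_character_, 400)
  clone[1:200] <- 1L; sgr[1:200] <- lib$sgrna_name[1]
  clones <- structure(list(clone = clone, sgrna = sgr,
                           clones = data.frame(clone_id = 1L,
                                               sgrna = lib$sgrna_name[1],
                                               size = 200L),
                           grid_dims = c(20L, 20L)), class = "sim_clones")
  target <- lib$gene[1]
  effects <- setNames(list(c(gA = 4)), target)
  se <- sample_expression(clones, tis, panel, effects, lib, seed = 19L)
  cm <- as.matrix(se$expression$counts)
  in_clone <- !is.na(se$target)
  ratio <- mean(cm[in_clone, "gA"]) / mean(cm[!in_clone, "gA"])
  expect_lt(abs(ratio - 4) / 4, 0.1)   # 4x effect within 10% at n = 200
  expect_true(all(cm[, "gZero"] == 0))
  # unperturbed gene is unaffected
  r2 <- mean(cm[in_clone, "gB"]) / mean(cm[!in_clone, "gB"])
  expect_lt(abs(r2 - 1), 0.1)
  expect_error(sample_expression(clones, tis,
                                 transform(panel, base_mean = -1),
                                 effects, lib, seed = 1L), "negative")
})

test_that("read emission is the exact inverse of demultiplexing at zero error", {
  sc <- simulate_screen(grid_dims = c(16L, 16L), n_sgrna = 6L, n_clones = 3L,
                        clone_size_mean = 12, umi_mean = 6, reads_per_umi = 3L,
                        seed = 23L)
  expect_equal(length(sc$reads$read_id), 3L * nrow(sc$truth))
  dx <- demux_reads(sc$reads$read_id, sc$reads$payload, sc$reads$barcode_read,
                    sc$profile, sc$lib)
  expect_true(all(dx$records$status == "assigned"))
  tr <- dedup_umis(dx)
  M <- build_matrix(tr, sc$profile$grid_dims, sc$lib,
                    tissue = sc$tissue$tissue)
  expect_equal(as.matrix(M$counts), as.matrix(sc$truth_matrix$counts))
  # sgRNA areas of the emitted matrix match clone sizes plus recorded strays
  areas <- sgrna_area(M)
  truth_areas <- vapply(sc$lib$sgrna_name, function(g) {
    length(unique(paste(sc$truth$x[sc$truth$sgrna == g],
                        sc$truth$y[sc$truth$sgrna == g])))
  }, integer(1))
  expect_equal(areas, truth_areas)
})

test_that("simulation is byte-identical under a fixed seed", {
  s1 <- simulate_screen(grid_dims = c(14L, 14L), n_sgrna = 5L, n_clones = 2L,
                        clone_size_mean = 10, umi_mean = 4, seed = 29L)
  s2 <- simulate_screen(grid_dims = c(14L, 14L), n_sgrna = 5L, n_clones = 2L,
                        clone_size_mean = 10, umi_mean = 4, seed = 29L)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  expect_identical(as.matrix(s1$expression$counts),
                   as.matrix(s2$expression$counts))
  expect_identical(s1$pooled, s2$pooled)
})

test_that("pooled tables follow the logistic detection model", {
  truth <- data.frame(x = rep(1:10, 2), y = rep(1:2, each = 10),
                      sgrna = rep(c("sgA", "sgB"), each = 10),
                      umi = paste0("u", 1:20))
  lib <- sgrna_library(c("sgA", "sgB", "sgC"),
                       c("AAAAAAAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCCCCCCC",
                         "GGGGGGGGGGGGGGGGGGGG"), c("A", "B", "C"))
  # absent sgRNA always at fraction 0
  tab <- emit_pooled_table(truth, lib, n_lobes = 5L, seed = 31L)
  expect_equal(tab$pooled_fraction[tab$sgrna == "sgC"], 0)
  expect_equal(tab$spatial_area, c(10L, 10L, 0L))
  # saturating detection probability gives fraction 1
  tab2 <- emit_pooled_table(truth, lib, n_lobes = 5L, midpoint = -1000,
                            seed = 31L)
  expect_true(all(tab2$pooled_fraction[tab2$spatial_area > 0] == 1))
  expect_error(emit_pooled_table(truth, lib, n_lobes = 0L), "n_lobes")
})

test_that("benchmark AUC on emitted tables exceeds chance", {
  sc <- simulate_screen(grid_dims = c(24L, 24L), n_sgrna = 12L, n_clones = 8L,
                        clone_size_mean = 12, umi_mean = 4, seed = 37L)
  auc_at <- function(scale) {
    # average over detection draws: single draws are noisy at 12 sgRNAs
    mean(vapply(41:50, function(s) {
      tab <- emit_pooled_table(sc$truth, sc$lib, n_lobes = 8L, midpoint = 8,
                               scale = scale, seed = s)
      b <- build_benchmark(tab)
      roc_auc(b$scores, b$labels)$auc
    }, numeric(1)))
  }
  # pooled detection tracks clonal area under sharp and diffuse logistics;
  # absent sgRNAs are floored at fraction 0, so both are informative
  expect_gt(auc_at(1), 0.5)
  expect_gt(auc_at(50), 0.5)
})

test_that("conservation holds end-to-end on randomized small scenes", {
  set.seed(59)
  for (seed in c(43L, 47L, 53L)) {
    sc <- simulate_screen(grid_dims = c(12L, 12L),
                          n_sgrna = sample(4:8, 1), n_clones = sample(2:4, 1),
                          clone_size_mean = 8, umi_mean = 3,
                          reads_per_umi = 2L, seed = seed)
    dx <- demux_reads(sc$reads$read_id, sc$reads$payload,
                      sc$reads$barcode_read, sc$profile, sc$lib)
    expect_equal(sum(dx$attrition), length(sc$reads$read_id))
    tr <- dedup_umis(dx)
    M <- build_matrix(tr, sc$profile$grid_dims, sc$lib)
    expect_equal(sum(M$counts), nrow(tr))
    expect_equal(as.matrix(M$counts), as.matrix(sc$truth_matrix$counts))
  }
})
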