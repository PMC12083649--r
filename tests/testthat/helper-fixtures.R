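# Shared fixtures: everything is generated in code at test time.

# wrap a dense count matrix (spots x sgRNAs) into a spot_sgrna_matrix;
# grid dims are chosen to exactly cover the rows
wrap_spot_matrix <- function(counts, grid_dims = NULL, tissue = NULL) {
  if (is.null(colnames(counts))) colnames(counts) <- paste0("g", seq_len(ncol(counts)))
  n <- nrow(counts)
  if (is.null(grid_dims)) {
    nx <- ceiling(sqrt(n))
    ny <- ceiling(n / nx)
    if (nx * ny > n) {
      counts <- rbind(counts, matrix(0, nx * ny - n, ncol(counts)))
    }
    grid_dims <- c(nx, ny)
  }
  if (is.null(tissue)) tissue <- rep(TRUE, nrow(counts))
  nz <- which(counts != 0, arr.ind = TRUE)
  sp <- Matrix::sparseMatrix(i = nz[, 1L], j = nz[, 2L],
                             x = as.numeric(counts[nz]), dims = dim(counts),
                             dimnames = dimnames(counts))
  structure(list(counts = sp, grid_dims = as.integer(grid_dims),
                 sgrnas = colnames(counts), tissue = tissue),
    class = "spot_sgrna_matrix")
}

# small chemistry: 6x6 grid, distance-separated 8-mer whitelists
tiny_profile <- function(grid_dims = c(6L, 6L), seed = 101L) {
  setA <- random_barcode_set(grid_dims[1L], role = "spatial-A", seed = seed)
  setB <- random_barcode_set(grid_dims[2L], role = "spatial-B", seed = seed + 1L)
  chemistry_profile("PAC", default_sgrna_layout("PAC"),
                    list("spatial-A" = setA, "spatial-B" = setB),
                    grid_dims = grid_dims)
}

tiny_library <- function(n = 6L, seed = 202L) {
  random_sgrna_library(n, n_ntc = 1L, seed = seed)
}

# assemble an error-free barcode-mate read for spot (x, y) and a given UMI
assemble_read2 <- function(profile, x, y, umi) {
  lay <- profile$sgrna_layout
  anchors <- Filter(function(s) s$kind == "anchor", lay$segments)
  paste0(profile$barcode_sets[["spatial-A"]]$entries[x],
         anchors[[1L]]$sequence,
         profile$barcode_sets[["spatial-B"]]$entries[y],
         anchors[[2L]]$sequence, umi)
}

assemble_read1 <- function(lib, sgrna, flank = "GTTTTAGAGCTAGAA", fill = "ACGT") {
  paste0(lib$spacer[match(sgrna, lib$sgrna_name)], flank,
         strrep(fill, 5))
}

# substitute the base at position `pos` of each string
sub_base <- function(seqs, pos, to = NULL) {
  vapply(seq_along(seqs), function(i) {
    s <- strsplit(seqs[i], "")[[1L]]
    cur <- s[pos]
    s[pos] <- if (is.null(to)) setdiff(c("A", "C", "G", "T"), cur)[1L] else to
    paste(s, collapse = "")
  }, character(1))
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

# reference (slow) minimum pairwise distance
oracle_min_dist <- function(entries) {
  n <- length(entries)
  best <- nchar(entries[1L])
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    best <- min(best, hamming(entries[i], entries[j]))
  }
  best
}

# knockout-recovery scenario: one 200-spot clone, 500 NP spots, NB noise,
# 50 affected genes; returns classification performance at a given effect
knockout_recovery <- function(effect, seed = 1L) {
  tis <- generate_tissue(c(30L, 30L), n_regions = 1L, tissue_frac = 1.0,
                         seed = seed + 1L)
  lib <- random_sgrna_library(5L, 1L, seed = seed + 2L)
  panel <- default_gene_panel(seed = seed + 3L)
  clone <- integer(900); sgr <- rep(NA_character_, 900)
  clone[1:200] <- 1L; sgr[1:200] <- "sgTG01"
  clones <- structure(list(clone = clone, sgrna = sgr,
                           clones = data.frame(clone_id = 1L, sgrna = "sgTG01",
                                               size = 200L),
                           grid_dims = c(30L, 30L)), class = "sim_clones")
  eff <- make_effect_vectors(panel, "TG01", n_genes = 50L, effect = effect,
                             seed = seed + 4L)
  se <- sample_expression(clones, tis, panel, eff, lib, seed = seed + 5L)
  E <- normalize_expression(se$expression)
  gex <- reduce_and_cluster(E$scaled, seed = seed + 6L, umap = FALSE)
  npv <- logical(900); npv[which(is.na(se$target))[1:500]] <- TRUE
  sig <- calc_signature(E, npv, pcs = gex$pcs, clusters = gex$cluster)
  sco <- calc_scores(sig, se$target, npv)
  list(recall = mean(sco$class[1:200] == "perturbed"),
       np_fp = mean(sco$scores[npv, "TG01"] > 0.2))
}
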