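# On-disk formats and the all-in-one pipeline driver.
#
# Conventions at the disk boundary: spot indices are 1-based channel
# numbers; the spot matrix is written as Matrix Market coordinate format
# with `spots.tsv` / `sgrnas.tsv` sidecars in canonical row-major (x, y)
# order. FASTQ is gzip-transparent by extension.

#' Write sequences as FASTQ
#'
#' @param seqs Character vector of sequences.
#' @param ids Read identifiers.
#' @param path Output path (`.gz` for gzip).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, ids, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  q <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write a spot-by-sgRNA matrix to Matrix Market plus sidecars
#'
#' Produces `matrix.mtx` (sparse coordinate), `spots.tsv` (`x, y, tissue`,
#' one row per grid spot in row-major order) and `sgrnas.tsv` in `dir`.
#'
#' @param M A `spot_sgrna_matrix`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_spot_matrix <- function(M, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(M$counts, file.path(dir, "matrix.mtx"))
  g <- expand.grid(y = seq_len(M$grid_dims[2L]), x = seq_len(M$grid_dims[1L]))
  utils::write.table(data.frame(x = g$x, y = g$y, tissue = M$tissue),
                     file.path(dir, "spots.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sgrna = M$sgrnas),
                     file.path(dir, "sgrnas.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}

#' Read a spot-by-sgRNA matrix written by [write_spot_matrix()]
#'
#' @param dir Directory containing `matrix.mtx`, `spots.tsv`, `sgrnas.tsv`.
#' @return A `spot_sgrna_matrix`.
#' @export
read_spot_matrix <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  spots <- utils::read.delim(file.path(dir, "spots.tsv"))
  sgrnas <- utils::read.delim(file.path(dir, "sgrnas.tsv"))$sgrna
  if (nrow(counts) != nrow(spots)) {
    stop("matrix rows (", nrow(counts), ") != spots sidecar rows (",
         nrow(spots), ")")
  }
  if (ncol(counts) != length(sgrnas)) {
    stop("matrix columns != sgRNA sidecar rows")
  }
  grid_dims <- c(max(spots$x), max(spots$y))
  dimnames(counts) <- list(paste0(spots$x, "_", spots$y), sgrnas)
  structure(list(counts = counts, grid_dims = as.integer(grid_dims),
                 sgrnas = as.character(sgrnas),
                 tissue = as.logical(spots$tissue)),
            class = "spot_sgrna_matrix")
}

#' Read/write a region mask TSV (`region_name  x  y`)
#'
#' @param path TSV path.
#' @return Named list of [region_mask()]s.
#' @export
read_region_masks <- function(path) {
  tab <- utils::read.delim(path)
  lapply(split(tab, tab$region_name), function(d) {
    region_mask(d$x, d$y, name = d$region_name[1L])
  })
}

#' @rdname read_region_masks
#' @param masks Named list of `region_mask`s.
#' @export
write_region_masks <- function(masks, path) {
  tab <- do.call(rbind, lapply(masks, function(m) {
    data.frame(region_name = attr(m, "name"), x = m$x, y = m$y)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(p) unique(p[-(1:2)])),
           vapply(parts, `[[`, "", 1L))
}

#' Run the full synthetic-screen pipeline
#'
#' Executes simulate -> demultiplex -> deduplicate -> quantify -> assign ->
#' perturbation analysis -> differential expression (-> enrichment when gene
#' sets are given) -> pooled-vs-spatial ROC, writing every artifact plus a
#' manifest (parameters, seeds, stage summaries) to `out_dir`. All
#' randomness flows from `seed`, so a rerun with the same configuration
#' reproduces identical outputs.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param sim_params Named list of overrides for [simulate_screen()].
#' @param gene_sets Optional named list of gene sets for enrichment.
#' @param write_reads Also write the FASTQ pair (default FALSE; they are the
#'   largest artifacts).
#' @param max_mm_barcode,max_mm_spacer Demultiplexing budgets.
#' @return Invisibly, a list with every stage result (`scene, demux,
#'   triples, matrix, assignment, expression, gex, scores, pumap, de, gsea,
#'   roc, manifest`).
#' @export
run_pipeline <- function(out_dir, seed = 1L, sim_params = list(),
                         gene_sets = NULL, write_reads = FALSE,
                         max_mm_barcode = 1L, max_mm_spacer = 2L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  scene <- do.call(simulate_screen, c(sim_params, list(seed = seed)))
  lib <- scene$lib; profile <- scene$profile

  if (write_reads) {
    write_fastq(scene$reads$payload, scene$reads$read_id,
                file.path(out_dir, "reads_R1.fastq.gz"))
    write_fastq(scene$reads$barcode_read, scene$reads$read_id,
                file.path(out_dir, "reads_R2.fastq.gz"))
  }
  write_whitelist(profile$barcode_sets[["spatial-A"]],
                  file.path(out_dir, "whitelist_A.tsv"))
  write_whitelist(profile$barcode_sets[["spatial-B"]],
                  file.path(out_dir, "whitelist_B.tsv"))
  write_sgrna_library(lib, file.path(out_dir, "library.tsv"))

  seg <- extract_segments(scene$reads$barcode_read, profile$sgrna_layout)
  umi_wl <- build_umi_whitelist(seg$umi[seg$status == "ok"])
  dx <- demux_reads(scene$reads$read_id, scene$reads$payload,
                    scene$reads$barcode_read, profile, lib,
                    umi_whitelist = umi_wl, max_mm_barcode = max_mm_barcode,
                    max_mm_spacer = max_mm_spacer)
  triples <- dedup_umis(dx)
  M <- build_matrix(triples, profile$grid_dims, lib,
                    tissue = scene$tissue$tissue)
  write_spot_matrix(M, file.path(out_dir, "spot_matrix"))
  asn <- assign_spots(M)
  utils::write.table(asn, file.path(out_dir, "assignment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  E <- normalize_expression(scene$expression)
  gex <- reduce_and_cluster(E$scaled, seed = seed)
  pt <- perturbation_targets(E, asn, lib, sgrna_area(M), area_min = 4L)
  sig <- calc_signature(E, pt$np, pcs = gex$pcs, clusters = gex$cluster)
  sc <- calc_scores(sig, pt$target, pt$np)
  pu <- tryCatch(pumap_cluster(sc, seed = seed), error = function(e) NULL)
  utils::write.table(
    data.frame(spot = rownames(sc$scores), class = sc$class, sc$scores,
               check.names = FALSE),
    file.path(out_dir, "perturbation_scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  # DE: most perturbed target group vs NP spots
  de <- NULL; gsea <- NULL
  tgt_counts <- sort(table(pt$target[sc$class == "perturbed"]),
                     decreasing = TRUE)
  np_idx <- which(pt$np)
  if (length(tgt_counts) && tgt_counts[1L] >= 3L && length(np_idx) >= 3L) {
    top_t <- names(tgt_counts)[1L]
    grpA <- which(!is.na(pt$target) & pt$target == top_t &
                    sc$class == "perturbed")
    de <- wilcoxon_de(E, grpA, np_idx)
    utils::write.table(de, file.path(out_dir, "de_top_perturbation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(gene_sets)) {
      ranks <- setNames(de$lfc, de$gene)[de$padj < 0.2]
      if (length(ranks) >= 2L) {
        gsea <- gsea_preranked(ranks, gene_sets, nperm = 1000L, seed = seed)
        utils::write.table(gsea, file.path(out_dir, "gsea.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    }
  }

  bench_tab <- scene$pooled
  bench_tab$spatial_area <- as.integer(sgrna_area(M)[bench_tab$sgrna])
  roc <- tryCatch({
    b <- build_benchmark(bench_tab)
    r <- roc_auc(b$scores, b$labels)
    utils::write.table(r$curve, file.path(out_dir, "roc_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    r
  }, error = function(e) NULL)

  manifest <- list(
    package = "spotscreen",
    version = as.character(utils::packageVersion("spotscreen")),
    seed = seed,
    params = scene$params,
    thresholds = list(max_mm_barcode = max_mm_barcode,
                      max_mm_spacer = max_mm_spacer,
                      resolve_top_min = 10, area_min = 4,
                      score_hi = 0.2, score_lo = -0.2, major_frac = 0.2),
    stages = list(
      n_reads = dx$n_reads, attrition = as.list(dx$attrition),
      n_triples = nrow(triples), matrix_total = sum(M$counts),
      n_spots_assigned = sum(asn$label %in% c("unique", "resolved")),
      gex_resolution = gex$resolution,
      n_targets = length(sc$targets),
      auc = if (!is.null(roc)) roc$auc else NA
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(scene = scene, demux = dx, triples = triples, matrix = M,
                 assignment = asn, expression = E, gex = gex, targets = pt,
                 signature = sig, scores = sc, pumap = pu, de = de,
                 gsea = gsea, roc = roc, manifest = manifest))
}
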