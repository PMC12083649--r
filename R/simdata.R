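# Ground-truth simulator: tissue geometry, clonal sgRNA geography,
# negative-binomial expression with knockout effects, and chemistry-faithful
# read emission. Every stage is deterministic given (params, seed), and the
# generated truth is the oracle the rest of the package is validated
# against.

.bases <- c("A", "C", "G", "T")

.random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(.bases, n * len, replace = TRUE), nrow = n)
  do.call(paste0, lapply(seq_len(len), function(j) m[, j]))
}

#' Generate a random barcode whitelist with guaranteed separation
#'
#' Samples distinct 8-mers with a guaranteed minimum pairwise Hamming
#' distance, so that single-substitution correction is unambiguous (safe
#' correction of m substitutions needs distance >= 2m + 1) and
#' double-substitution reads are rejected rather than misassigned (distance
#' 4). For short barcodes the full k-mer space is enumerated and picks are
#' drawn from the shrinking feasible set; longer barcodes fall back to
#' rejection sampling.
#'
#' @param n Number of barcodes.
#' @param length Barcode length (default 8).
#' @param min_dist Minimum pairwise Hamming distance (default 4).
#' @param role Barcode role.
#' @param seed Integer seed.
#' @param max_tries Sampling attempts before giving up.
#' @return A [barcode_set()].
#' @export
random_barcode_set <- function(n, length = 8L, min_dist = 4L,
                               role = "spatial-A", seed = 1L,
                               max_tries = 200000L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (4^length <= 2^20) {
    # enumerate the full k-mer space and sample from the shrinking feasible set
    m <- as.matrix(do.call(expand.grid, rep(list(1:4), length)))
    feasible <- rep(TRUE, nrow(m))
    picked <- integer(0)
    for (i in seq_len(n)) {
      cand <- which(feasible)
      if (!length(cand)) {
        stop("could not sample ", n, " barcodes at min distance ", min_dist)
      }
      p <- if (length(cand) == 1L) cand else sample(cand, 1L)
      picked <- c(picked, p)
      d <- rowSums(m != matrix(m[p, ], nrow(m), length, byrow = TRUE))
      feasible <- feasible & d >= min_dist
    }
    seqs <- apply(m[picked, , drop = FALSE], 1L, function(r) {
      paste(.bases[r], collapse = "")
    })
    return(barcode_set(unname(seqs), role = role))
  }
  picked <- character(0)
  picked_m <- NULL
  tries <- 0L
  while (length(picked) < n && tries < max_tries) {
    tries <- tries + 1L
    cand <- sample(.bases, length, replace = TRUE)
    if (is.null(picked_m) || all(colSums(picked_m != cand) >= min_dist)) {
      picked <- c(picked, paste(cand, collapse = ""))
      picked_m <- cbind(picked_m, cand)
    }
  }
  if (length(picked) < n) {
    stop("could not sample ", n, " barcodes at min distance ", min_dist)
  }
  barcode_set(picked, role = role)
}

#' Generate a tissue mask with labeled regions
#'
#' Tissue is the union of seeded random-growth blobs: each region starts at a
#' random spot and grows by annexing random 4-connected frontier spots until
#' the target tissue fraction is reached. Deterministic per seed.
#'
#' @param grid_dims Integer `c(N_A, N_B)`, at least 10x10.
#' @param n_regions Number of regions (e.g. tumors; default 3).
#' @param tissue_frac Target fraction of grid spots under tissue
#'   (default 0.6).
#' @param seed Integer seed.
#' @return A `sim_tissue`: list with `grid_dims`, `tissue` (logical, spot
#'   row-major by (x, y)), `region` (integer, 0 = non-tissue).
#' @export
generate_tissue <- function(grid_dims = c(50L, 50L), n_regions = 3L,
                            tissue_frac = 0.6, seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  if (any(grid_dims < 10L)) stop("grid must be at least 10x10")
  nspot <- prod(grid_dims)
  target <- ceiling(tissue_frac * nspot)
  if (n_regions > target) stop("more regions than target tissue spots")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  region <- integer(nspot)
  frontier <- vector("list", n_regions)
  seeds <- sample.int(nspot, n_regions)
  for (r in seq_len(n_regions)) {
    region[seeds[r]] <- r
    frontier[[r]] <- .grid_neighbors(seeds[r], grid_dims)
  }
  filled <- n_regions
  while (filled < target) {
    r <- sample.int(n_regions, 1L)
    fr <- frontier[[r]][region[frontier[[r]]] == 0L]
    if (!length(fr)) { frontier[[r]] <- integer(0);
      if (all(!lengths(lapply(frontier, function(f) f[region[f] == 0L])))) break
      next }
    s <- if (length(fr) == 1L) fr else sample(fr, 1L)
    region[s] <- r
    filled <- filled + 1L
    frontier[[r]] <- unique(c(fr[fr != s], .grid_neighbors(s, grid_dims)))
  }
  structure(list(grid_dims = grid_dims, tissue = region > 0L, region = region),
            class = "sim_tissue")
}

# 4-connected neighbors of a linear spot index
.grid_neighbors <- function(i, grid_dims) {
  ny <- grid_dims[2L]
  x <- (i - 1L) %/% ny + 1L
  y <- (i - 1L) %% ny + 1L
  nb <- rbind(c(x - 1L, y), c(x + 1L, y), c(x, y - 1L), c(x, y + 1L))
  nb <- nb[nb[, 1L] >= 1L & nb[, 1L] <= grid_dims[1L] &
           nb[, 2L] >= 1L & nb[, 2L] <= ny, , drop = FALSE]
  (nb[, 1L] - 1L) * ny + nb[, 2L]
}

#' Seed clonal sgRNA geography on a tissue mask
#'
#' Each clone is a contiguous (4-connected) set of tissue spots carrying one
#' sgRNA, emulating clonal outgrowth of singly transduced tumor cells.
#' Clones do not overlap; different clones may carry the same sgRNA;
#' non-clone tissue spots carry no sgRNA.
#'
#' @param tissue A `sim_tissue`.
#' @param lib A [sgrna_library()]; clone sgRNAs are drawn from it (NTCs
#'   included).
#' @param n_clones Number of clones (default 12).
#' @param size_mean Mean clone size in spots. Sizes are log-normal (clonal
#'   growth is multiplicative, so clone sizes span an order of magnitude)
#'   with this mean and `size_sdlog` spread, floored at 5 spots.
#' @param size_sdlog Log-scale SD of clone sizes (default 0.8); set 0 for
#'   near-constant sizes.
#' @param contiguous Grow clones as 4-connected blobs (default TRUE;
#'   otherwise random tissue spots).
#' @param seed Integer seed.
#' @return A `sim_clones`: list with `clone` (integer per spot, 0 = none),
#'   `sgrna` (character per spot, NA = none), `clones` (data.frame clone_id,
#'   sgrna, size).
#' @export
seed_clones <- function(tissue, lib, n_clones = 12L, size_mean = 30,
                        size_sdlog = 0.8, contiguous = TRUE, seed = 1L) {
  stopifnot(inherits(tissue, "sim_tissue"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sizes <- pmax(5L, round(stats::rlnorm(n_clones,
                                        log(size_mean) - size_sdlog^2 / 2,
                                        size_sdlog)))
  if (n_clones * 5L > sum(tissue$tissue)) {
    stop("requested clone area exceeds available tissue")
  }
  # heavy-tailed draws can overshoot the section; rescale to a tissue budget
  budget <- floor(0.8 * sum(tissue$tissue))
  if (sum(sizes) > budget) {
    sizes <- pmax(5L, floor(sizes * budget / sum(sizes)))
  }
  nspot <- prod(tissue$grid_dims)
  clone <- integer(nspot)
  sgrna <- rep(NA_character_, nspot)
  clone_sg <- sample(lib$sgrna_name, n_clones, replace = n_clones > nrow(lib))
  for (ci in seq_len(n_clones)) {
    free <- which(tissue$tissue & clone == 0L)
    if (!length(free)) stop("no free tissue spots left for clone ", ci)
    if (!contiguous) {
      got <- sample(free, min(sizes[ci], length(free)))
    } else {
      start <- if (length(free) == 1L) free else sample(free, 1L)
      got <- start
      frontier <- .grid_neighbors(start, tissue$grid_dims)
      while (length(got) < sizes[ci]) {
        frontier <- setdiff(frontier, got)
        frontier <- frontier[tissue$tissue[frontier] & clone[frontier] == 0L]
        if (!length(frontier)) break
        s <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
        got <- c(got, s)
        frontier <- c(frontier, .grid_neighbors(s, tissue$grid_dims))
      }
    }
    clone[got] <- ci
    sgrna[got] <- clone_sg[ci]
  }
  clones <- data.frame(clone_id = seq_len(n_clones), sgrna = clone_sg,
                       size = as.integer(tabulate(clone, n_clones)))
  structure(list(clone = clone, sgrna = sgrna, clones = clones,
                 grid_dims = tissue$grid_dims),
            class = "sim_clones")
}

#' Default synthetic gene panel
#'
#' 600 genes by default: 500 protein-coding, 40 tRNAs spread over 20
#' amino-acid isotypes, 30 miRNAs, 30 lncRNAs. Baseline means are
#' log-normal; per-gene NB dispersions are moderate.
#'
#' @param n_coding,n_trna,n_mirna,n_lncrna Panel composition.
#' @param seed Integer seed.
#' @return data.frame: `gene, class, base_mean, dispersion`.
#' @export
default_gene_panel <- function(n_coding = 500L, n_trna = 40L, n_mirna = 30L,
                               n_lncrna = 30L, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  iso <- .trna_isotypes[1:20]
  genes <- c(sprintf("GENE%04d", seq_len(n_coding)),
             paste0("tRNA-", rep_len(iso, n_trna), "-",
                    .random_dna(n_trna, 3)),
             sprintf("miR-%03d", seq_len(n_mirna)),
             sprintf("LINC%04d", seq_len(n_lncrna)))
  cls <- c(rep("protein_coding", n_coding), rep("tRNA", n_trna),
           rep("miRNA", n_mirna), rep("lncRNA", n_lncrna))
  n <- length(genes)
  data.frame(gene = make.unique(genes), class = cls,
             base_mean = stats::rlnorm(n, meanlog = 0.7, sdlog = 0.8),
             dispersion = stats::runif(n, 0.2, 0.8),
             stringsAsFactors = FALSE)
}

#' Build knockout effect vectors for a set of target genes
#'
#' Each target perturbation multiplies the NB means of `n_genes` randomly
#' chosen panel genes by `effect` in the spots carrying that perturbation.
#'
#' @param panel Gene panel (see [default_gene_panel()]).
#' @param targets Character vector of perturbation target names.
#' @param n_genes Genes affected per target (default 50).
#' @param effect Multiplicative effect size (default 2).
#' @param seed Integer seed.
#' @return Named list: target -> named numeric vector of factors.
#' @export
make_effect_vectors <- function(panel, targets, n_genes = 50L, effect = 2,
                                seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  setNames(lapply(seq_along(targets), function(i) {
    g <- sample(panel$gene, n_genes)
    setNames(rep(effect, n_genes), g)
  }), targets)
}

#' Sample NB-distributed expression over a clone map
#'
#' Counts are drawn independently per (spot, gene) from a negative binomial
#' with mean `base_mean * factor` and size `1/dispersion`, where the factor
#' comes from the effect vector of the spot's perturbation target (1
#' elsewhere).
#'
#' @param clones A `sim_clones`.
#' @param tissue A `sim_tissue` (defines which spots get expression).
#' @param panel Gene panel data.frame.
#' @param effects Named list from [make_effect_vectors()], keyed by target
#'   gene; clone sgRNAs map to targets via `lib`.
#' @param lib A [sgrna_library()].
#' @param seed Integer seed.
#' @return List: `expression` (an `expression_matrix` over tissue spots),
#'   `target` (character per tissue spot, NA = no perturbation).
#' @export
sample_expression <- function(clones, tissue, panel, effects, lib, seed = 1L) {
  if (any(panel$base_mean < 0)) stop("negative baseline means")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  idx <- which(tissue$tissue)
  ny <- tissue$grid_dims[2L]
  x <- (idx - 1L) %/% ny + 1L
  y <- (idx - 1L) %% ny + 1L
  sg <- clones$sgrna[idx]
  target <- rep(NA_character_, length(idx))
  has <- !is.na(sg)
  target[has] <- lib$gene[match(sg[has], lib$sgrna_name)]
  ntc <- logical(length(sg))
  ntc[has] <- lib$is_ntc[match(sg[has], lib$sgrna_name)]
  target[ntc] <- "NTC"
  n <- length(idx); G <- nrow(panel)
  mu <- matrix(rep(panel$base_mean, each = n), n, G)
  for (t in names(effects)) {
    rows <- which(!is.na(target) & target == t)
    if (!length(rows)) next
    ev <- effects[[t]]
    cols <- match(names(ev), panel$gene)
    ok <- !is.na(cols)
    mu[rows, cols[ok]] <- sweep(mu[rows, cols[ok], drop = FALSE], 2L,
                                ev[ok], "*")
  }
  size <- matrix(rep(1 / panel$dispersion, each = n), n, G)
  counts <- matrix(stats::rnbinom(n * G, mu = mu, size = size), n, G)
  colnames(counts) <- panel$gene
  rownames(counts) <- paste0(x, "_", y)
  E <- expression_matrix(counts, x, y, feature_class = panel$class)
  list(expression = E, target = target)
}

# substitute bases i.i.d. at `rate`, always to a different base
.corrupt <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  L <- nchar(seqs[1L])
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = L)
  hit <- which(stats::runif(length(m)) < rate)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    cur <- match(m[hit], .bases)
    m[hit] <- .bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  do.call(paste0, lapply(seq_len(L), function(i) m[i, ]))
}

#' Emit chemistry-faithful paired reads from a clone map
#'
#' For every sgRNA-bearing spot, the number of true molecules (UMIs) is drawn
#' from a Poisson (mean `umi_mean`, floor 1); each molecule is sequenced
#' `reads_per_umi` times. The barcode mate is assembled exactly as the layout
#' prescribes (spatial barcodes + ligation linkers + UMI) and the payload
#' mate is spacer + scaffold flank + random filler. Substitution errors are
#' applied i.i.d. per base at `error_rate` after truth triples are recorded.
#'
#' @param clones A `sim_clones`.
#' @param profile A [chemistry_profile()].
#' @param lib A [sgrna_library()].
#' @param umi_mean Mean true molecules per sgRNA-bearing spot (default 25).
#' @param reads_per_umi Reads sequenced per molecule (default 6).
#' @param error_rate Per-base substitution rate (default 0).
#' @param ambient_rate Fraction of sgRNA-free tissue spots receiving one
#'   stray single-UMI sgRNA molecule (default 0.05), plus the same fraction
#'   of clone spots receiving a 1-UMI second sgRNA, to exercise the
#'   resolved/ambiguous assignment logic.
#' @param tissue Optional `sim_tissue` for ambient placement.
#' @param payload_length Total payload mate length (default 60).
#' @param spacer_flank Scaffold flank appended after the spacer.
#' @param seed Integer seed.
#' @return List: `read_id`, `payload`, `barcode_read` (character vectors),
#'   `truth` (data.frame `x, y, sgrna, umi` of true triples, pre-error).
#' @export
emit_reads <- function(clones, profile, lib, umi_mean = 25, reads_per_umi = 6L,
                       error_rate = 0, ambient_rate = 0.05, tissue = NULL,
                       payload_length = 60L,
                       spacer_flank = "GTTTTAGAGCTAGAA", seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  layout <- profile$sgrna_layout
  roles <- vapply(Filter(function(s) s$kind == "barcode", layout$segments),
                  `[[`, "", "barcode_role")
  setA <- profile$barcode_sets[[roles[1L]]]
  setB <- profile$barcode_sets[[roles[2L]]]
  anchors <- Filter(function(s) s$kind == "anchor", layout$segments)
  umi_len <- profile$umi_length
  ny <- clones$grid_dims[2L]

  spots <- which(!is.na(clones$sgrna))
  mol <- data.frame(spot = spots, sgrna = clones$sgrna[spots],
                    n_umi = pmax(1L, stats::rpois(length(spots), umi_mean)))
  present <- unique(clones$sgrna[!is.na(clones$sgrna)])
  if (ambient_rate > 0 && length(present)) {
    # stray molecules diffuse from clones actually present in the tissue
    pool <- if (!is.null(tissue)) which(tissue$tissue & is.na(clones$sgrna))
            else integer(0)
    if (length(pool)) {
      amb <- pool[stats::runif(length(pool)) < ambient_rate]
      if (length(amb)) {
        mol <- rbind(mol, data.frame(
          spot = amb, sgrna = sample(present, length(amb), replace = TRUE),
          n_umi = 1L))
      }
    }
    if (length(present) > 1L) {
      cross <- spots[stats::runif(length(spots)) < ambient_rate]
      if (length(cross)) {
        other <- vapply(clones$sgrna[cross], function(s) {
          pres <- setdiff(present, s)
          if (length(pres) == 1L) pres else sample(pres, 1L)
        }, character(1))
        mol <- rbind(mol, data.frame(spot = cross, sgrna = other, n_umi = 1L))
      }
    }
  }
  # one row per true molecule, with a fresh UMI unique within (spot, sgRNA)
  tr_spot <- rep(mol$spot, mol$n_umi)
  tr_sg <- rep(mol$sgrna, mol$n_umi)
  umi <- .random_dna(length(tr_spot), umi_len)
  key <- paste(tr_spot, tr_sg, umi)
  while (anyDuplicated(key)) {
    d <- duplicated(key)
    umi[d] <- .random_dna(sum(d), umi_len)
    key <- paste(tr_spot, tr_sg, umi)
  }
  x <- (tr_spot - 1L) %/% ny + 1L
  y <- (tr_spot - 1L) %% ny + 1L
  truth <- data.frame(x = x, y = y, sgrna = tr_sg, umi = umi,
                      stringsAsFactors = FALSE)

  rep_i <- rep(seq_along(tr_spot), each = reads_per_umi)
  barcode_read <- paste0(setA$entries[x[rep_i]], anchors[[1L]]$sequence,
                         setB$entries[y[rep_i]], anchors[[2L]]$sequence,
                         umi[rep_i])
  spacer <- lib$spacer[match(tr_sg, lib$sgrna_name)]
  core <- paste0(spacer[rep_i], spacer_flank)
  fill_len <- payload_length - nchar(core)
  mx_fill <- max(fill_len)
  filler <- if (mx_fill > 0) substring(.random_dna(length(core), mx_fill),
                                       1L, pmax(fill_len, 0L)) else ""
  payload <- paste0(core, filler)
  if (error_rate > 0) {
    barcode_read <- .corrupt(barcode_read, error_rate)
    # payload lengths may vary with spacer length; corrupt per length group
    for (L in unique(nchar(payload))) {
      sel <- nchar(payload) == L
      payload[sel] <- .corrupt(payload[sel], error_rate)
    }
  }
  list(read_id = sprintf("read%07d", seq_along(rep_i)),
       payload = payload, barcode_read = barcode_read, truth = truth)
}

#' Emit a pooled-screen detection table paired with spatial areas
#'
#' Per-lobe detection of each sgRNA is Bernoulli with a logistic probability
#' increasing in the sgRNA's total clonal area; sgRNAs absent from the tissue
#' have detection probability 0. The pooled fraction is detected lobes over
#' `n_lobes`.
#'
#' @param truth Truth triples (or any data.frame with `x, y, sgrna`).
#' @param lib A [sgrna_library()].
#' @param n_lobes Number of sample lobes (default 5).
#' @param midpoint,scale Logistic parameters on the spot-area axis
#'   (defaults 10 and 5).
#' @param seed Integer seed.
#' @return data.frame: `sgrna, pooled_fraction, spatial_area`.
#' @export
emit_pooled_table <- function(truth, lib, n_lobes = 5L, midpoint = 10,
                              scale = 5, seed = 1L) {
  if (n_lobes < 1L) stop("n_lobes must be >= 1")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  area <- vapply(lib$sgrna_name, function(g) {
    length(unique(paste(truth$x[truth$sgrna == g], truth$y[truth$sgrna == g])))
  }, integer(1))
  p <- ifelse(area == 0L, 0, stats::plogis((area - midpoint) / scale))
  det <- stats::rbinom(length(p), n_lobes, p)
  data.frame(sgrna = lib$sgrna_name, pooled_fraction = det / n_lobes,
             spatial_area = as.integer(area), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Generate a random sgRNA library
#'
#' @param n_sgrna Library size (default 20).
#' @param n_ntc Non-targeting controls among them (default 2).
#' @param spacer_length Spacer length (default 20).
#' @param seed Integer seed.
#' @return A [sgrna_library()]; targeting sgRNAs get synthetic gene symbols
#'   `TG01...`.
#' @export
random_sgrna_library <- function(n_sgrna = 20L, n_ntc = 2L,
                                 spacer_length = 20L, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  repeat {
    spacers <- .random_dna(n_sgrna, spacer_length)
    if (!anyDuplicated(spacers)) break
  }
  is_ntc <- c(rep(FALSE, n_sgrna - n_ntc), rep(TRUE, n_ntc))
  gene <- ifelse(is_ntc, "", sprintf("TG%02d", seq_len(n_sgrna)))
  name <- ifelse(is_ntc, sprintf("NTC%02d", cumsum(is_ntc)),
                 paste0("sg", gene))
  sgrna_library(name, spacers, gene, is_ntc)
}

#' Simulate a complete spatial screen scene
#'
#' One call builds the whole study scene: barcode whitelists, sgRNA library,
#' tissue with regions, clonal sgRNA geography, NB expression with knockout
#' effects, chemistry-faithful paired reads, and the pooled-screen detection
#' table. The defaults define the standard desk-scale scene: 50x50 grid, 60%
#' tissue, 12 clones, 20 sgRNAs (2 NTCs), a 600-gene panel and roughly 2e5
#' reads. All stage seeds are derived deterministically from `seed`.
#'
#' @param grid_dims Grid dimensions (default 50x50).
#' @param n_sgrna,n_ntc Library size and NTC count (defaults 20, 2).
#' @param n_regions,tissue_frac Tissue geometry (defaults 3, 0.6).
#' @param n_clones,clone_size_mean Clonal geography (defaults 12, 100).
#' @param umi_mean,reads_per_umi Read depth (defaults 25, 6).
#' @param error_rate Per-base substitution rate (default 0).
#' @param ambient_rate Stray-molecule rate (default 0.05).
#' @param effect,effect_genes Knockout effect size and number of affected
#'   genes per target (defaults 2, 50).
#' @param panel Gene panel; default [default_gene_panel()].
#' @param n_lobes Pooled-screen lobes (default 5).
#' @param seed Master seed.
#' @return A `sim_scene` list: `profile, lib, tissue, clones, expression,
#'   target, reads` (read_id/payload/barcode_read), `truth` (triples),
#'   `truth_matrix` (spot_sgrna_matrix built from truth), `pooled`,
#'   `effects`, `params`.
#' @export
simulate_screen <- function(grid_dims = c(50L, 50L), n_sgrna = 20L, n_ntc = 2L,
                            n_regions = 3L, tissue_frac = 0.6, n_clones = 12L,
                            clone_size_mean = 100, umi_mean = 25,
                            reads_per_umi = 6L, error_rate = 0,
                            ambient_rate = 0.05, effect = 2,
                            effect_genes = 50L, panel = NULL, n_lobes = 5L,
                            seed = 1L) {
  seed <- as.integer(seed)
  setA <- random_barcode_set(grid_dims[1L], role = "spatial-A", seed = seed + 11L)
  setB <- random_barcode_set(grid_dims[2L], role = "spatial-B", seed = seed + 12L)
  layout <- default_sgrna_layout("PAC")
  profile <- chemistry_profile("PAC", layout,
                               list("spatial-A" = setA, "spatial-B" = setB),
                               grid_dims = grid_dims)
  lib <- random_sgrna_library(n_sgrna, n_ntc, seed = seed + 13L)
  tissue <- generate_tissue(grid_dims, n_regions, tissue_frac, seed = seed + 14L)
  clones <- seed_clones(tissue, lib, n_clones, clone_size_mean, seed = seed + 15L)
  if (is.null(panel)) panel <- default_gene_panel(seed = seed + 16L)
  targets <- setdiff(unique(lib$gene[match(unique(clones$clones$sgrna),
                                           lib$sgrna_name)]), "")
  effects <- make_effect_vectors(panel, targets, n_genes = effect_genes,
                                 effect = effect, seed = seed + 17L)
  expr <- sample_expression(clones, tissue, panel, effects, lib,
                            seed = seed + 18L)
  reads <- emit_reads(clones, profile, lib, umi_mean = umi_mean,
                      reads_per_umi = reads_per_umi, error_rate = error_rate,
                      ambient_rate = ambient_rate, tissue = tissue,
                      seed = seed + 19L)
  truth_matrix <- build_matrix(reads$truth, grid_dims, lib,
                               tissue = tissue$tissue)
  pooled <- emit_pooled_table(reads$truth, lib, n_lobes = n_lobes,
                              seed = seed + 20L)
  structure(list(profile = profile, lib = lib, tissue = tissue,
                 clones = clones, expression = expr$expression,
                 target = expr$target, reads = reads[c("read_id", "payload",
                                                       "barcode_read")],
                 truth = reads$truth, truth_matrix = truth_matrix,
                 pooled = pooled, effects = effects, panel = panel,
                 params = list(grid_dims = grid_dims, n_sgrna = n_sgrna,
                               n_ntc = n_ntc, n_clones = n_clones,
                               clone_size_mean = clone_size_mean,
                               umi_mean = umi_mean,
                               reads_per_umi = reads_per_umi,
                               error_rate = error_rate,
                               ambient_rate = ambient_rate, effect = effect,
                               seed = seed)),
            class = "sim_scene")
}
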