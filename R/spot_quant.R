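# Spot x sgRNA quantification on the deterministic barcoding grid.
#
# Spot identity is the (A-index, B-index) channel pair, 1-based; the linear
# spot index is row-major by (x, y): i = (x - 1) * N_B + y.

.spot_index <- function(x, y, grid_dims) (x - 1L) * grid_dims[2L] + y

.spot_names <- function(grid_dims) {
  g <- expand.grid(y = seq_len(grid_dims[2L]), x = seq_len(grid_dims[1L]))
  paste0(g$x, "_", g$y)
}

#' Build the spot-by-sgRNA UMI count matrix
#'
#' Collapses deduplicated (spot, sgRNA, UMI) triples to per-(spot, sgRNA)
#' molecule counts. All grid spots are retained (zero rows stay implicit in
#' the sparse representation), so the matrix total always equals the number
#' of input triples.
#'
#' @param triples data.frame with columns `x, y, sgrna, umi` (deduplicated,
#'   e.g. from [dedup_umis()]).
#' @param grid_dims Integer `c(N_A, N_B)`.
#' @param lib [sgrna_library()] defining the sgRNA column order.
#' @param tissue Optional logical vector over spots (row-major by (x, y)) or
#'   data.frame of tissue spot coordinates; defaults to all spots.
#' @return A `spot_sgrna_matrix`: list with sparse `counts`
#'   (spots x sgRNAs, dgCMatrix), `grid_dims`, `sgrnas`, `tissue`.
#' @export
build_matrix <- function(triples, grid_dims, lib, tissue = NULL) {
  grid_dims <- as.integer(grid_dims)
  sgrnas <- lib$sgrna_name
  nspot <- prod(grid_dims)
  if (nrow(triples)) {
    if (any(triples$x < 1L | triples$x > grid_dims[1L] |
            triples$y < 1L | triples$y > grid_dims[2L])) {
      stop("triple references a spot outside the grid")
    }
    g <- match(triples$sgrna, sgrnas)
    if (anyNA(g)) stop("triple references an sgRNA absent from the library")
    i <- .spot_index(triples$x, triples$y, grid_dims)
    counts <- Matrix::sparseMatrix(i = i, j = g, x = 1,
                                   dims = c(nspot, length(sgrnas)))
  } else {
    counts <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                   dims = c(nspot, length(sgrnas)))
  }
  dimnames(counts) <- list(.spot_names(grid_dims), sgrnas)
  if (is.null(tissue)) {
    tissue <- rep(TRUE, nspot)
  } else if (is.data.frame(tissue)) {
    tv <- rep(FALSE, nspot)
    tv[.spot_index(tissue$x, tissue$y, grid_dims)] <- TRUE
    tissue <- tv
  }
  structure(list(counts = methods::as(counts, "CsparseMatrix"),
                 grid_dims = grid_dims, sgrnas = sgrnas, tissue = tissue),
            class = "spot_sgrna_matrix")
}

#' @export
print.spot_sgrna_matrix <- function(x, ...) {
  cat(sprintf("spot_sgrna_matrix: %dx%d grid, %d sgRNAs, %d UMIs in %d spots\n",
              x$grid_dims[1L], x$grid_dims[2L], length(x$sgrnas),
              sum(x$counts), sum(Matrix::rowSums(x$counts) > 0)))
  invisible(x)
}

#' Label spots by their sgRNA content
#'
#' Implements the spot assignment rule: a spot with no detected sgRNA is
#' `non_perturbed`; exactly one detected sgRNA is `unique`; with two or more,
#' the spot is `resolved` to the top sgRNA only when the top count is at least
#' `resolve_top_min` (default 10) and every other detected sgRNA has exactly
#' `resolve_other_exact` counts (default 1); anything else, including a tie
#' for the top count, is `ambiguous`.
#'
#' @param M A `spot_sgrna_matrix`.
#' @param resolve_top_min Minimum top-sgRNA count for resolution (default 10).
#' @param resolve_other_max Maximum count permitted for every non-top sgRNA;
#'   the default reading requires exactly 1 (`resolve_other_exact = TRUE`).
#' @param resolve_other_exact Require non-top counts to equal
#'   `resolve_other_max` exactly (strict reading) rather than at most.
#' @return A `spot_assignment` data.frame: `x, y, tissue, label, sgrna,
#'   n_umi`, with `label` in `non_perturbed/unique/resolved/ambiguous` and
#'   `sgrna` non-NA for unique/resolved spots.
#' @export
assign_spots <- function(M, resolve_top_min = 10L, resolve_other_max = 1L,
                         resolve_other_exact = TRUE) {
  cm <- M$counts
  nspot <- nrow(cm)
  tr <- Matrix::summary(cm)
  tr <- tr[tr$x > 0, , drop = FALSE]
  ndet <- tabulate(tr$i, nspot)
  # top count and its sgRNA per spot: sort by (spot, -count), take first
  o <- order(tr$i, -tr$x)
  first <- !duplicated(tr$i[o])
  top <- numeric(nspot)
  topj <- rep(NA_integer_, nspot)
  top[tr$i[o][first]] <- tr$x[o][first]
  topj[tr$i[o][first]] <- tr$j[o][first]
  n_top <- tabulate(tr$i[tr$x == top[tr$i]], nspot)
  ok_others <- if (resolve_other_exact) {
    n_eq <- tabulate(tr$i[tr$x == resolve_other_max], nspot)
    (n_eq - as.integer(top == resolve_other_max)) == ndet - 1L
  } else {
    n_le <- tabulate(tr$i[tr$x <= resolve_other_max], nspot)
    (n_le - as.integer(top <= resolve_other_max)) == ndet - 1L
  }
  label <- rep("ambiguous", nspot)
  label[ndet == 0L] <- "non_perturbed"
  label[ndet == 1L] <- "unique"
  resolved <- ndet >= 2L & n_top == 1L & top >= resolve_top_min & ok_others
  label[resolved] <- "resolved"
  sg <- rep(NA_character_, nspot)
  named <- label %in% c("unique", "resolved")
  sg[named] <- M$sgrnas[topj[named]]
  g <- expand.grid(y = seq_len(M$grid_dims[2L]), x = seq_len(M$grid_dims[1L]))
  out <- data.frame(x = g$x, y = g$y, tissue = M$tissue, label = label,
                    sgrna = sg, n_umi = Matrix::rowSums(cm),
                    stringsAsFactors = FALSE)
  class(out) <- c("spot_assignment", "data.frame")
  out
}

#' sgRNA detection area
#'
#' Number of spots in which an sgRNA is detected (>= 1 UMI). When the matrix
#' carries a spot pitch, the physical area (spots x pitch^2, in square
#' micrometers) is attached as attribute `physical_area`.
#'
#' @param M A `spot_sgrna_matrix`.
#' @param sgrna sgRNA name(s); default all.
#' @param pitch Optional spot pitch in micrometers.
#' @return Named integer vector of spot counts.
#' @export
sgrna_area <- function(M, sgrna = NULL, pitch = NULL) {
  if (is.null(sgrna)) sgrna <- M$sgrnas
  if (!all(sgrna %in% M$sgrnas)) {
    stop("unknown sgRNA: ", paste(setdiff(sgrna, M$sgrnas), collapse = ", "))
  }
  a <- Matrix::colSums(M$counts[, sgrna, drop = FALSE] > 0)
  a <- setNames(as.integer(a), sgrna)
  if (!is.null(pitch)) attr(a, "physical_area") <- a * pitch^2
  a
}

#' Define a named region of spots
#'
#' @param x,y Spot coordinates (1-based channel indices).
#' @param name Region name.
#' @param pitch Optional spot pitch (micrometers) for physical areas.
#' @return A `region_mask` data.frame.
#' @export
region_mask <- function(x, y, name = "region", pitch = NULL) {
  r <- data.frame(x = as.integer(x), y = as.integer(y))
  r <- unique(r)
  attr(r, "name") <- name
  attr(r, "pitch") <- pitch
  class(r) <- c("region_mask", "data.frame")
  r
}

#' Perturbation burden within a region
#'
#' The count and fraction of region spots carrying any detected sgRNA, i.e.
#' the sgRNA-bearing area of a tumor region.
#'
#' @param M A `spot_sgrna_matrix`.
#' @param region A [region_mask()] or data.frame with `x, y`.
#' @param pitch Spot pitch in micrometers (for `physical_area`; defaults to
#'   the region's own pitch attribute).
#' @return List: `spots_with_sgrna`, `fraction`, `physical_area` (NA without
#'   a pitch), `region_size`.
#' @export
perturbation_burden <- function(M, region, pitch = attr(region, "pitch")) {
  if (!nrow(region)) stop("empty region")
  if (any(region$x < 1L | region$x > M$grid_dims[1L] |
          region$y < 1L | region$y > M$grid_dims[2L])) {
    stop("region extends outside the grid")
  }
  idx <- .spot_index(region$x, region$y, M$grid_dims)
  with_sg <- sum(Matrix::rowSums(M$counts[idx, , drop = FALSE]) > 0)
  list(spots_with_sgrna = as.integer(with_sg),
       fraction = with_sg / nrow(region),
       physical_area = if (is.null(pitch)) NA_real_ else with_sg * pitch^2,
       region_size = nrow(region))
}

#' Spatial colocalization of an sgRNA pair
#'
#' Scores the overlap of two sgRNAs' detection spot sets, with a permutation
#' null that redraws both sets uniformly over tissue spots preserving set
#' sizes. `jaccard` is |S1 n S2| / |S1 u S2|; `neighborhood` is the fraction
#' of S1 spots with an S2 spot within Chebyshev radius `radius`. Because the
#' colocalization statistic is a methodological choice, both variants are
#' reconstructions and are labelled as such in the output.
#'
#' @param M A `spot_sgrna_matrix`.
#' @param g1,g2 sgRNA names.
#' @param mode `"jaccard"` or `"neighborhood"`.
#' @param radius Chebyshev radius for neighborhood mode (default 1).
#' @param n_perm Number of permutations (>= 99, default 999).
#' @param seed Integer seed for the permutation null.
#' @return List: `score`, `p`, `mode`, `n_perm`.
#' @export
colocalization <- function(M, g1, g2, mode = c("jaccard", "neighborhood"),
                           radius = 1L, n_perm = 999L, seed = 1L) {
  mode <- match.arg(mode)
  if (n_perm < 99L) stop("n_perm must be at least 99")
  det <- function(g) which(M$counts[, g] > 0)
  s1 <- det(g1); s2 <- det(g2)
  if (!length(s1) || !length(s2)) stop("both sgRNAs must be detected somewhere")
  grid_dims <- M$grid_dims
  coords <- function(i) cbind(x = (i - 1L) %/% grid_dims[2L] + 1L,
                              y = (i - 1L) %% grid_dims[2L] + 1L)
  score_fun <- function(a, b) {
    if (mode == "jaccard") {
      length(intersect(a, b)) / length(union(a, b))
    } else {
      ca <- coords(a); cb <- coords(b)
      hit <- vapply(seq_len(nrow(ca)), function(k) {
        any(pmax(abs(cb[, 1L] - ca[k, 1L]), abs(cb[, 2L] - ca[k, 2L])) <= radius)
      }, logical(1))
      mean(hit)
    }
  }
  obs <- score_fun(s1, s2)
  pool <- which(M$tissue)
  if (!length(pool)) pool <- seq_len(nrow(M$counts))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    score_fun(sample(pool, length(s1)), sample(pool, length(s2)))
  }, numeric(1))
  p <- (1 + sum(perm >= obs)) / (1 + n_perm)
  list(score = obs, p = p, mode = mode, n_perm = n_perm)
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
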