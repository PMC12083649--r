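# Expression container and normalization.

# coerce any matrix-like input to a general numeric CsparseMatrix without
# relying on base-matrix coercion methods (Matrix is imported, not attached)
.as_dgc <- function(x) {
  if (methods::is(x, "dgCMatrix")) return(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    nz <- which(x != 0, arr.ind = TRUE)
    return(Matrix::sparseMatrix(i = nz[, 1L], j = nz[, 2L],
                                x = as.numeric(x[nz]), dims = dim(x),
                                dimnames = dimnames(x)))
  }
  methods::as(methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix"),
              "dMatrix")
}

#' Construct a spot expression matrix
#'
#' @param counts Matrix-like (spots x genes) of raw non-negative integer
#'   counts; rownames are spot ids, colnames gene names.
#' @param x,y Spot coordinates (channel indices) aligned with rows.
#' @param feature_class Optional character vector per gene
#'   (`protein_coding`, `lncRNA`, `miRNA`, `tRNA`, `snoRNA`, `snRNA`,
#'   `rRNA`, `vault`, `other`); defaults to `protein_coding`.
#' @return An `expression_matrix`: list with `counts` (dgCMatrix), `spots`
#'   (data.frame x, y), `feature_class`, and normalization layers once
#'   [normalize_expression()] has run.
#' @export
expression_matrix <- function(counts, x, y, feature_class = NULL) {
  counts <- .as_dgc(counts)
  if (any(counts@x < 0)) stop("raw counts must be non-negative")
  if (is.null(colnames(counts))) stop("counts needs gene column names")
  if (is.null(feature_class)) {
    feature_class <- rep("protein_coding", ncol(counts))
  }
  stopifnot(length(x) == nrow(counts), length(y) == nrow(counts),
            length(feature_class) == ncol(counts))
  if (is.null(rownames(counts))) rownames(counts) <- paste0(x, "_", y)
  structure(list(counts = counts,
                 spots = data.frame(x = as.integer(x), y = as.integer(y)),
                 feature_class = setNames(feature_class, colnames(counts)),
                 lognorm = NULL, scaled = NULL, state = "raw"),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d spots x %d genes [%s]\n",
              nrow(x$counts), ncol(x$counts), x$state))
  invisible(x)
}

#' Normalize and scale an expression matrix
#'
#' Library-size normalization with log transform, then per-gene z-scaling:
#' `lognorm = ln(1 + 1e4 * c / libsize)` and `scaled` = per-gene z-score of
#' lognorm, clipped at +-10. Spots with zero total counts are dropped with a
#' warning. This deliberately simple normalization stands in the position a
#' variance-stabilizing transform would occupy; the layer is pluggable via
#' the `lognorm` slot.
#'
#' @param E An `expression_matrix`.
#' @param scale_factor Library-size scale factor (default 1e4).
#' @param clip Z-score clip bound (default 10).
#' @return The `expression_matrix` with `lognorm` and `scaled` layers
#'   (dense matrices) and `state = "scaled"`.
#' @export
normalize_expression <- function(E, scale_factor = 1e4, clip = 10) {
  stopifnot(inherits(E, "expression_matrix"))
  libsize <- Matrix::rowSums(E$counts)
  keep <- libsize > 0
  if (!all(keep)) {
    warning(sum(!keep), " spot(s) with zero total counts dropped")
    E$counts <- E$counts[keep, , drop = FALSE]
    E$spots <- E$spots[keep, , drop = FALSE]
    libsize <- libsize[keep]
  }
  ln <- as.matrix(E$counts / libsize * scale_factor)
  ln <- log1p(ln)
  mu <- colMeans(ln)
  sdv <- apply(ln, 2L, stats::sd)
  sdv[sdv == 0] <- 1  # constant genes scale to 0
  sc <- sweep(sweep(ln, 2L, mu, "-"), 2L, sdv, "/")
  sc[sc > clip] <- clip
  sc[sc < -clip] <- -clip
  E$lognorm <- ln
  E$scaled <- sc
  E$state <- "scaled"
  E
}
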