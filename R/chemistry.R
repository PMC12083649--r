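.valid_barcode_roles <- c("spatial-A", "spatial-B", "spatial-C", "spatial-D")

#' Construct a spatial barcode set
#'
#' A barcode set is one whitelist of equal-length DNA barcodes for a single
#' microfluidic barcoding axis. The 1-based position of an entry corresponds to
#' the microchannel it was flowed through, so entry `i` of the A set identifies
#' grid column `i` and entry `j` of the B set identifies grid row `j`.
#'
#' @param entries Character vector of DNA barcodes over A/C/G/T, all the same
#'   length (8 nt in the standard chemistry). Order is the channel order.
#' @param role One of `"spatial-A"`, `"spatial-B"`, `"spatial-C"`,
#'   `"spatial-D"`.
#' @return A `barcode_set` object: list with `role`, `entries`, `length` and
#'   `min_dist` (minimum pairwise Hamming distance, `NA` for one entry).
#' @export
barcode_set <- function(entries, role = "spatial-A") {
  role <- match.arg(role, .valid_barcode_roles)
  entries <- toupper(as.character(entries))
  if (length(entries) < 1L) stop("barcode set needs at least one entry")
  lens <- nchar(entries)
  if (length(unique(lens)) != 1L) {
    stop("RaggedBarcode: entries have unequal lengths")
  }
  if (any(grepl("[^ACGT]", entries))) {
    stop("InvalidBase: barcode entries must be over {A,C,G,T}")
  }
  if (anyDuplicated(entries)) {
    stop("DuplicateBarcode: duplicated barcode sequence in whitelist")
  }
  bs <- structure(
    list(role = role, entries = entries, length = lens[1L]),
    class = "barcode_set"
  )
  bs$min_dist <- if (length(entries) >= 2L) min_pairwise_distance(bs) else NA_integer_
  bs
}

#' @export
print.barcode_set <- function(x, ...) {
  cat(sprintf("barcode_set [%s]: %d entries x %d nt, min pairwise Hamming = %s\n",
              x$role, length(x$entries), x$length,
              ifelse(is.na(x$min_dist), "NA", x$min_dist)))
  invisible(x)
}

#' Load a barcode whitelist from a two-column TSV
#'
#' Expects columns `index` and `sequence`; indices must be contiguous from 1 so
#' that row order equals microchannel order.
#'
#' @param path Path to the TSV file.
#' @param role Barcode role, see [barcode_set()].
#' @return A `barcode_set`.
#' @export
load_whitelist <- function(path, role = "spatial-A") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("index", "sequence") %in% names(tab))) {
    stop("whitelist TSV must have columns 'index' and 'sequence'")
  }
  tab <- tab[order(tab$index), , drop = FALSE]
  if (!identical(as.integer(tab$index), seq_len(nrow(tab)))) {
    stop("whitelist indices must be contiguous from 1")
  }
  barcode_set(tab$sequence, role = role)
}

#' Write a barcode whitelist TSV
#'
#' Inverse of [load_whitelist()]; the round trip preserves content exactly.
#'
#' @param set A `barcode_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_whitelist <- function(set, path) {
  stopifnot(inherits(set, "barcode_set"))
  utils::write.table(
    data.frame(index = seq_along(set$entries), sequence = set$entries),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Minimum pairwise Hamming distance of a barcode set
#'
#' Exact brute force over all pairs. This bound decides whether
#' mismatch-tolerant matching is safe: correcting up to `m` substitutions is
#' unambiguous only when the minimum distance is at least `2*m + 1`.
#'
#' @param set A `barcode_set` with at least two entries.
#' @return Integer minimum Hamming distance.
#' @export
min_pairwise_distance <- function(set) {
  stopifnot(inherits(set, "barcode_set"))
  n <- length(set$entries)
  if (n < 2L) stop("need at least two entries to compute a pairwise distance")
  m <- .seq_char_matrix(set$entries)
  best <- set$length
  for (i in seq_len(n - 1L)) {
    d <- colSums(m[, i] != m[, (i + 1L):n, drop = FALSE])
    best <- min(best, d)
    if (best == 0L) break
  }
  as.integer(best)
}

# fixed-length DNA strings -> L x n character matrix (columns are sequences)
.seq_char_matrix <- function(seqs) {
  L <- nchar(seqs[1L])
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = L, ncol = length(seqs))
}

#' Load an sgRNA library table
#'
#' TSV with columns `sgrna_name`, `spacer`, `gene`, `is_ntc`. Spacers are
#' uppercased; names and spacers must be unique; every entry needs a target
#' gene unless it is flagged as a non-targeting control.
#'
#' @param path Path to the library TSV.
#' @return A `sgrna_library`: data.frame with the four columns, plus attribute
#'   `spacer_length` range.
#' @export
load_sgrna_library <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sgrna_name", "spacer", "gene", "is_ntc")
  if (!all(need %in% names(tab))) {
    stop("library TSV must have columns: ", paste(need, collapse = ", "))
  }
  sgrna_library(tab$sgrna_name, tab$spacer, tab$gene, as.logical(tab$is_ntc))
}

#' Construct an sgRNA library in code
#'
#' @param sgrna_name Unique sgRNA names.
#' @param spacer Spacer sequences (18-21 nt typical).
#' @param gene Target gene symbol (may be `""`/`NA` only for NTCs).
#' @param is_ntc Logical non-targeting-control flag.
#' @return A `sgrna_library` data.frame.
#' @export
sgrna_library <- function(sgrna_name, spacer, gene, is_ntc = FALSE) {
  spacer <- toupper(spacer)
  df <- data.frame(sgrna_name = as.character(sgrna_name),
                   spacer = spacer,
                   gene = as.character(gene),
                   is_ntc = rep_len(as.logical(is_ntc), length(sgrna_name)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sgrna_name)) stop("duplicate sgRNA names")
  if (anyDuplicated(df$spacer)) stop("duplicate spacer sequences")
  if (any(grepl("[^ACGT]", df$spacer))) stop("spacers must be over {A,C,G,T}")
  bad <- !df$is_ntc & (is.na(df$gene) | df$gene == "")
  if (any(bad)) stop("non-NTC entries must name a target gene")
  class(df) <- c("sgrna_library", "data.frame")
  df
}

#' Write an sgRNA library TSV
#' @param lib A `sgrna_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sgrna_library <- function(lib, path) {
  utils::write.table(as.data.frame(lib), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Declare one segment of a read layout
#'
#' @param name Segment name (unique within the layout).
#' @param kind One of `"anchor"` (fixed sequence, e.g. a ligation linker),
#'   `"barcode"`, `"umi"`, `"payload"`.
#' @param length Segment length in bases (payload: minimum length).
#' @param sequence For anchors: the expected sequence.
#' @param max_mismatches For anchors: substitutions tolerated when locating it.
#' @param barcode_role For barcodes: which whitelist the segment draws from.
#' @param min_length,max_length For UMI segments: accepted candidate lengths
#'   before truncation to `length`.
#' @return A `read_segment` list.
#' @export
read_segment <- function(name, kind, length = NULL, sequence = NULL,
                         max_mismatches = 1L, barcode_role = NULL,
                         min_length = NULL, max_length = NULL) {
  kind <- match.arg(kind, c("anchor", "barcode", "umi", "payload"))
  if (kind == "anchor") {
    stopifnot(!is.null(sequence))
    length <- nchar(sequence)
  }
  if (is.null(length)) stop("segment '", name, "' needs a length")
  structure(list(name = name, kind = kind, length = as.integer(length),
                 sequence = sequence, max_mismatches = as.integer(max_mismatches),
                 barcode_role = barcode_role,
                 min_length = min_length %||% length,
                 max_length = max_length %||% length),
            class = "read_segment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Declare a read layout
#'
#' An ordered 5'->3' description of one mate: which bases are spatial
#' barcodes, ligation-linker anchors, the UMI, and the payload. Segment offsets
#' are implied by the cumulative declared lengths; anchors may shift within a
#' small jitter window at extraction time.
#'
#' @param segments List of [read_segment()]s in 5'->3' order.
#' @param mate Which mate carries this structure (1 or 2).
#' @return A `read_layout` with precomputed expected offsets.
#' @export
read_layout <- function(segments, mate = 2L) {
  stopifnot(length(segments) >= 1L, mate %in% c(1L, 2L))
  kinds <- vapply(segments, `[[`, "", "kind")
  names <- vapply(segments, `[[`, "", "name")
  if (anyDuplicated(names)) stop("segment names must be unique")
  if (sum(kinds == "umi") > 1L) stop("a layout may declare at most one UMI segment")
  lens <- vapply(segments, `[[`, 0L, "length")
  starts <- cumsum(c(1L, lens[-length(lens)]))
  structure(list(segments = segments, mate = as.integer(mate),
                 starts = as.integer(starts),
                 fixed_prefix = sum(lens)),
            class = "read_layout")
}

#' Assemble a chemistry profile
#'
#' Binds barcode whitelists, read layouts and grid geometry for one of the two
#' capture chemistries: poly(A)-tailing capture (`"PAC"`, sgRNA reads share the
#' transcript A/B barcodes) or direct capture (`"DC"`, sgRNA reads carry their
#' own C/D barcodes).
#'
#' @param variant `"PAC"` or `"DC"`.
#' @param sgrna_layout [read_layout()] of the sgRNA barcode mate.
#' @param barcode_sets Named list of `barcode_set`s keyed by role
#'   (`"spatial-A"` etc.). PAC needs A/B; DC needs A/B/C/D.
#' @param grid_dims Integer c(N_A, N_B) grid dimensions.
#' @param spot_pitch Spot pitch in micrometers (default 50).
#' @param umi_length Expected UMI length (default 10).
#' @return A `chemistry_profile`.
#' @export
chemistry_profile <- function(variant = c("PAC", "DC"), sgrna_layout,
                              barcode_sets, grid_dims = c(50L, 50L),
                              spot_pitch = 50, umi_length = 10L) {
  variant <- match.arg(variant)
  structure(list(variant = variant, sgrna_layout = sgrna_layout,
                 barcode_sets = barcode_sets,
                 grid_dims = as.integer(grid_dims),
                 spot_pitch = spot_pitch, umi_length = as.integer(umi_length)),
            class = "chemistry_profile")
}

#' Validate a chemistry profile
#'
#' Report-only structural checks: required barcode sets present, layout
#' barcode segments sized like their whitelists, grid dimensions matching
#' whitelist sizes, UMI length sane, segments ordered without overlap (implied
#' by construction, re-checked here).
#'
#' @param profile A `chemistry_profile`.
#' @return Character vector of violations; `character(0)` means valid.
#' @export
validate_profile <- function(profile) {
  v <- character(0)
  need <- if (profile$variant == "DC") .valid_barcode_roles else .valid_barcode_roles[1:2]
  missing <- setdiff(need, names(profile$barcode_sets))
  if (length(missing)) {
    v <- c(v, paste0("missing barcode sets: ", paste(missing, collapse = ", ")))
  }
  # which sets address the sgRNA grid axes
  ax <- if (profile$variant == "DC") c("spatial-C", "spatial-D") else c("spatial-A", "spatial-B")
  for (k in seq_along(ax)) {
    bs <- profile$barcode_sets[[ax[k]]]
    if (!is.null(bs) && length(bs$entries) != profile$grid_dims[k]) {
      v <- c(v, sprintf("grid dimension %d (%d) does not match %s whitelist size (%d)",
                        k, profile$grid_dims[k], ax[k], length(bs$entries)))
    }
  }
  segs <- profile$sgrna_layout$segments
  n_umi <- sum(vapply(segs, `[[`, "", "kind") == "umi")
  if (n_umi != 1L) v <- c(v, "layout must declare exactly one UMI segment")
  for (s in segs) {
    if (s$kind == "barcode") {
      bs <- profile$barcode_sets[[s$barcode_role]]
      if (is.null(bs)) {
        v <- c(v, sprintf("barcode segment '%s' references absent set %s",
                          s$name, s$barcode_role))
      } else if (bs$length != s$length) {
        v <- c(v, sprintf("barcode segment '%s' length %d != whitelist length %d",
                          s$name, s$length, bs$length))
      }
    }
    if (s$kind == "umi" && s$length != profile$umi_length) {
      v <- c(v, sprintf("umi segment length %d != profile umi_length %d",
                        s$length, profile$umi_length))
    }
  }
  v
}

#' Standard sgRNA-mate layout for the direct-capture and poly(A) chemistries
#'
#' Barcode mate structure: `[barcode1 (8)] [linker1 (10)] [barcode2 (8)]
#' [linker2 (10)] [UMI (10)]`, mirroring the two-pass microfluidic barcoding
#' with 8-mer channel barcodes joined by 10-mer ligation linkers. Linker
#' sequences are configuration values.
#'
#' @param variant `"PAC"` (A/B barcodes) or `"DC"` (C/D barcodes).
#' @param linker1,linker2 Anchor (ligation linker) sequences, 10 nt.
#' @param barcode_length,umi_length Segment lengths.
#' @return A `read_layout` for mate 2.
#' @export
default_sgrna_layout <- function(variant = c("PAC", "DC"),
                                 linker1 = "GTGGCCGATG",
                                 linker2 = "ATCCACGTGC",
                                 barcode_length = 8L, umi_length = 10L) {
  variant <- match.arg(variant)
  roles <- if (variant == "DC") c("spatial-C", "spatial-D") else c("spatial-A", "spatial-B")
  read_layout(list(
    read_segment("barcode1", "barcode", length = barcode_length, barcode_role = roles[1]),
    read_segment("linker1", "anchor", sequence = linker1, max_mismatches = 1L),
    read_segment("barcode2", "barcode", length = barcode_length, barcode_role = roles[2]),
    read_segment("linker2", "anchor", sequence = linker2, max_mismatches = 1L),
    read_segment("umi", "umi", length = umi_length, min_length = umi_length,
                 max_length = umi_length + 2L)
  ), mate = 2L)
}
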