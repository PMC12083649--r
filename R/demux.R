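# Mismatch-tolerant demultiplexing of spatially barcoded sgRNA reads.
#
# All matching is substitution-only Hamming matching with unique-best-hit
# semantics: a query is assigned to the single whitelist entry within the
# mismatch budget; any tie at the minimal distance is rejected. This
# reproduces the -v/-m alignment semantics of short-read aligners
# deterministically and without indel handling.

# mismatch counts between equal-length strings `x` and one `target`;
# entries of wrong length get NA
.mismatch_counts <- function(x, target) {
  L <- nchar(target)
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x) & nchar(x) == L
  if (!any(ok)) return(out)
  tm <- strsplit(target, "", fixed = TRUE)[[1L]]
  m <- matrix(unlist(strsplit(x[ok], "", fixed = TRUE), use.names = FALSE),
              nrow = L)
  out[ok] <- as.integer(colSums(m != tm))
  out
}

# Vectorized unique-best-hit Hamming matcher: queries (all length L) against
# whitelist entries (length L). Returns 1-based index or NA (no hit within
# max_mm, or >=2 entries tied at the minimal distance).
.hamming_match <- function(queries, entries, max_mm) {
  n <- length(queries)
  idx <- match(queries, entries)        # exact hits first
  if (max_mm == 0L || !anyNA(idx)) return(idx)
  todo <- which(is.na(idx) & !is.na(queries) & nchar(queries) == nchar(entries[1L]))
  if (!length(todo)) return(idx)
  uq <- unique(queries[todo])
  L <- nchar(entries[1L])
  qm <- matrix(unlist(strsplit(uq, "", fixed = TRUE), use.names = FALSE), nrow = L)
  # distance of every unique query to every entry; whitelists are small
  best <- rep(L + 1L, length(uq)); best_i <- rep(NA_integer_, length(uq))
  tied <- logical(length(uq))
  for (j in seq_along(entries)) {
    ej <- strsplit(entries[j], "", fixed = TRUE)[[1L]]
    d <- colSums(qm != ej)
    lt <- d < best
    eq <- d == best
    tied[eq] <- TRUE
    tied[lt] <- FALSE
    best[lt] <- d[lt]
    best_i[lt] <- j
  }
  hit <- best <= max_mm & !tied
  res <- ifelse(hit, best_i, NA_integer_)
  idx[todo] <- res[match(queries[todo], uq)]
  idx
}

#' Match a barcode sequence against a whitelist
#'
#' Unique-best-hit Hamming matching: returns the 1-based index of the single
#' whitelist entry within `max_mm` substitutions of the query, or `NA` when no
#' entry qualifies or two or more entries tie at the minimal distance
#' (multi-match rejection).
#'
#' @param seq Character vector of queries, each the whitelist barcode length.
#' @param set A [barcode_set()].
#' @param max_mm Maximum substitutions (0-2; default 1 for 8-mers).
#' @return Integer vector of 1-based indices, `NA` for unmatched/ambiguous.
#' @export
match_barcode <- function(seq, set, max_mm = 1L) {
  stopifnot(inherits(set, "barcode_set"), max_mm %in% 0:2)
  if (any(!is.na(seq) & nchar(seq) != set$length)) {
    stop("query length does not match barcode length ", set$length)
  }
  .hamming_match(seq, set$entries, as.integer(max_mm))
}

#' Locate and match an sgRNA spacer in a payload read
#'
#' The spacer is delimited by the 3' scaffold flank: the flank is located at
#' every offset compatible with the library's spacer lengths (minimum
#' mismatches wins, earliest offset breaks ties), the prefix before it is the
#' spacer candidate, and the candidate is matched to the library spacers with
#' unique-best-hit Hamming semantics.
#'
#' @param payload Character vector of payload (cDNA mate) sequences.
#' @param lib A [sgrna_library()].
#' @param max_mm Maximum spacer substitutions (default 2 for 19-20 nt spacers).
#' @param flank Scaffold flank spec: list with `sequence` and `max_mismatches`.
#' @return Character vector of sgRNA names; `NA` where the flank is missing
#'   (`reason` attribute records `spacer_flank_missing`), the spacer is
#'   unmatched, or the best hit is ambiguous.
#' @export
match_spacer <- function(payload, lib, max_mm = 2L,
                         flank = list(sequence = "GTTTTAGAGCTAGAA",
                                      max_mismatches = 2L)) {
  stopifnot(inherits(lib, "sgrna_library"))
  sp_lens <- sort(unique(nchar(lib$spacer)))
  offsets <- seq(min(sp_lens), max(sp_lens))  # flank starts at spacer_len + 1
  n <- length(payload)
  best_mm <- rep(.Machine$integer.max, n)
  best_off <- rep(NA_integer_, n)
  for (off in offsets) {
    cand <- substring(payload, off + 1L, off + nchar(flank$sequence))
    mm <- .mismatch_counts(cand, flank$sequence)
    better <- !is.na(mm) & mm < best_mm
    best_mm[better] <- mm[better]
    best_off[better] <- off
  }
  found <- !is.na(best_off) & best_mm <= flank$max_mismatches
  out <- rep(NA_character_, n)
  reason <- ifelse(found, NA_character_, "spacer_flank_missing")
  for (L in sp_lens) {
    sel <- found & best_off == L
    if (!any(sel)) next
    entries <- lib$spacer[nchar(lib$spacer) == L]
    names_L <- lib$sgrna_name[nchar(lib$spacer) == L]
    cand <- substring(payload[sel], 1L, L)
    idx <- .hamming_match(cand, entries, as.integer(max_mm))
    out[sel] <- names_L[idx]
    reason[sel][is.na(idx)] <- "spacer_unmatched"
  }
  attr(out, "reason") <- reason
  out
}

#' Extract layout segments from barcode-mate reads
#'
#' Anchors (ligation linkers) are located within a positional jitter window
#' around their expected offset, allowing up to their declared substitution
#' budget; a found anchor shifts the expected offsets of all downstream
#' segments. Fixed-length barcode and UMI segments are then sliced relative to
#' the anchors.
#'
#' @param seqs Character vector of barcode-mate sequences.
#' @param layout A [read_layout()].
#' @param jitter Positional slack for anchor location, in nt (default 2).
#' @return A data.frame with one column per non-anchor segment plus `status`
#'   (`"ok"`, `"too_short"`, or `"anchor_not_found:<name>"`).
#' @export
extract_segments <- function(seqs, layout, jitter = 2L) {
  stopifnot(inherits(layout, "read_layout"))
  n <- length(seqs)
  shift <- integer(n)
  status <- rep("ok", n)
  too_short <- nchar(seqs) < layout$fixed_prefix
  status[too_short] <- "too_short"
  alive <- !too_short
  out <- list()
  deltas <- order(abs(seq(-jitter, jitter)))  # 0, -1, +1, ...
  delta_vals <- seq(-jitter, jitter)[deltas]
  for (k in seq_along(layout$segments)) {
    seg <- layout$segments[[k]]
    start <- layout$starts[k] + shift
    if (seg$kind == "anchor") {
      best_mm <- rep(.Machine$integer.max, n)
      best_d <- rep(NA_integer_, n)
      for (d in delta_vals) {
        s <- start + d
        ok <- alive & s >= 1L
        if (!any(ok)) next
        cand <- rep(NA_character_, n)
        cand[ok] <- substring(seqs[ok], s[ok], s[ok] + seg$length - 1L)
        cand[ok & nchar(cand) < seg$length] <- NA_character_
        mm <- .mismatch_counts(cand, seg$sequence)
        better <- !is.na(mm) & mm < best_mm
        best_mm[better] <- mm[better]
        best_d[better] <- d
      }
      hit <- alive & !is.na(best_d) & best_mm <= seg$max_mismatches
      miss <- alive & !hit
      status[miss] <- paste0("anchor_not_found:", seg$name)
      alive <- hit
      shift[hit] <- shift[hit] + best_d[hit]
    } else {
      vals <- rep(NA_character_, n)
      vals[alive] <- substring(seqs[alive], start[alive],
                               start[alive] + seg$length - 1L)
      short <- alive & nchar(vals) < seg$length & !is.na(vals)
      if (any(short)) {
        status[short] <- "too_short"
        alive[short] <- FALSE
        vals[short] <- NA_character_
      }
      out[[seg$name]] <- vals
    }
  }
  for (nm in names(out)) out[[nm]][status != "ok"] <- NA_character_
  res <- as.data.frame(out, stringsAsFactors = FALSE)
  res$status <- status
  res
}

#' Build a UMI whitelist from candidate strings
#'
#' Applies the whitelist-construction rules used for the raw data: candidates
#' must be 10-12 nt (`min_length`/`max_length`), are truncated to 10 nt
#' (`truncate_to`), and any candidate containing an N is rejected. Candidates
#' whose flank was not found should not be passed in (discard-untrimmed is the
#' caller's extraction step).
#'
#' @param candidates Character vector of flank-trimmed UMI candidates.
#' @param min_length,max_length Accepted candidate length window (default
#'   10-12).
#' @param truncate_to Final UMI length (default 10).
#' @param min_count Minimum observation count to retain a UMI (default 1).
#' @return A `umi_whitelist`: named integer vector of counts over distinct
#'   truncated UMIs.
#' @export
build_umi_whitelist <- function(candidates, min_length = 10L, max_length = 12L,
                                truncate_to = 10L, min_count = 1L) {
  if (!length(candidates)) {
    warning("no UMI candidates; returning empty whitelist")
    return(structure(integer(0), class = "umi_whitelist"))
  }
  keep <- nchar(candidates) >= min_length & nchar(candidates) <= max_length
  cand <- substring(candidates[keep], 1L, truncate_to)
  cand <- cand[!grepl("N", cand, fixed = TRUE)]
  if (!length(cand)) {
    warning("all UMI candidates rejected; returning empty whitelist")
    return(structure(integer(0), class = "umi_whitelist"))
  }
  counts <- table(cand)
  counts <- counts[counts >= min_count]
  structure(setNames(as.integer(counts), names(counts)), class = "umi_whitelist")
}

#' Demultiplex paired reads into (spot, sgRNA, UMI) records
#'
#' Stages are applied in fixed order and a read's drop reason is the first
#' failing stage: segment extraction (anchors/length), UMI whitelist lookup,
#' barcode axis 1, barcode axis 2, spacer matching on the payload mate. Every
#' input read yields exactly one record, so assigned + dropped = input.
#'
#' Mismatch correction of barcodes is gated on whitelist separation:
#' `max_mm_barcode` is lowered (with a warning) to `floor((min_dist - 1)/2)`
#' when a whitelist's minimum pairwise Hamming distance cannot support
#' unambiguous correction at the requested budget.
#'
#' @param read_id Character vector of read identifiers (shared by mates).
#' @param payload Mate-1 sequences (spacer + scaffold).
#' @param barcode_read Mate-2 sequences (barcodes + linkers + UMI).
#' @param profile A [chemistry_profile()].
#' @param lib A [sgrna_library()].
#' @param umi_whitelist Optional `umi_whitelist`; when supplied and
#'   `umi_filter = TRUE`, reads whose UMI is absent are dropped.
#' @param max_mm_barcode,max_mm_spacer Substitution budgets (defaults 1, 2).
#' @param umi_filter Drop reads with off-whitelist UMIs (default `TRUE` when a
#'   whitelist is given); set `FALSE` for pass-through.
#' @param spacer_flank Scaffold flank spec passed to [match_spacer()].
#' @param jitter Anchor jitter window (nt).
#' @return A `demux_result`: list with `records` (data.frame `read_id, x, y,
#'   sgrna, umi, status`) and `attrition` (named counts per status).
#' @export
demux_reads <- function(read_id, payload, barcode_read, profile, lib,
                        umi_whitelist = NULL, max_mm_barcode = 1L,
                        max_mm_spacer = 2L, umi_filter = !is.null(umi_whitelist),
                        spacer_flank = list(sequence = "GTTTTAGAGCTAGAA",
                                            max_mismatches = 2L),
                        jitter = 2L) {
  if (length(payload) != length(barcode_read)) {
    stop("mate files have unequal numbers of reads")
  }
  layout <- profile$sgrna_layout
  roles <- vapply(Filter(function(s) s$kind == "barcode", layout$segments),
                  `[[`, "", "barcode_role")
  set1 <- profile$barcode_sets[[roles[1L]]]
  set2 <- profile$barcode_sets[[roles[2L]]]

  eff_mm <- function(set, requested) {
    if (requested == 0L || is.na(set$min_dist)) return(as.integer(requested))
    safe <- (set$min_dist - 1L) %/% 2L
    if (requested > safe) {
      warning(sprintf(
        "%s whitelist min distance %d cannot support %d-mismatch correction; using %d",
        set$role, set$min_dist, requested, safe))
      return(safe)
    }
    as.integer(requested)
  }
  mm1 <- eff_mm(set1, max_mm_barcode)
  mm2 <- eff_mm(set2, max_mm_barcode)

  segs <- extract_segments(barcode_read, layout, jitter = jitter)
  n <- length(barcode_read)
  status <- ifelse(segs$status == "ok", "assigned", paste0("dropped:", segs$status))
  alive <- segs$status == "ok"

  umi <- segs$umi
  if (umi_filter && !is.null(umi_whitelist)) {
    bad <- alive & !(umi %in% names(umi_whitelist))
    status[bad] <- "dropped:umi_not_whitelisted"
    alive[bad] <- FALSE
  }

  x <- rep(NA_integer_, n); y <- rep(NA_integer_, n)
  x[alive] <- match_barcode(segs$barcode1[alive], set1, mm1)
  bad <- alive & is.na(x)
  status[bad] <- "dropped:barcode1"; alive[bad] <- FALSE
  y[alive] <- match_barcode(segs$barcode2[alive], set2, mm2)
  bad <- alive & is.na(y)
  status[bad] <- "dropped:barcode2"; alive[bad] <- FALSE

  sg <- rep(NA_character_, n)
  if (any(alive)) {
    hit <- match_spacer(payload[alive], lib, max_mm = max_mm_spacer,
                        flank = spacer_flank)
    reason <- attr(hit, "reason")
    sg[alive] <- as.character(hit)
    bad_local <- is.na(hit)
    idx <- which(alive)[bad_local]
    status[idx] <- paste0("dropped:", reason[bad_local])
    alive[idx] <- FALSE
  }
  drop_mask <- status != "assigned"
  x[drop_mask] <- NA_integer_; y[drop_mask] <- NA_integer_
  sg[drop_mask] <- NA_character_; umi[drop_mask] <- NA_character_

  records <- data.frame(read_id = read_id, x = x, y = y, sgrna = sg,
                        umi = umi, status = status, stringsAsFactors = FALSE)
  attrition <- c(table(status))
  structure(list(records = records,
                 attrition = setNames(as.integer(attrition), names(attrition)),
                 n_reads = n),
            class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  cat("demux_result:", x$n_reads, "reads\n")
  for (nm in names(x$attrition)) cat(sprintf("  %-32s %d\n", nm, x$attrition[[nm]]))
  invisible(x)
}

#' Demultiplex a FASTQ pair
#'
#' File-level wrapper around [demux_reads()]; gzip is handled transparently by
#' extension.
#'
#' @param fastq1,fastq2 Paths to the payload (mate 1) and barcode (mate 2)
#'   FASTQ files.
#' @inheritParams demux_reads
#' @param ... Further arguments to [demux_reads()].
#' @return A `demux_result`.
#' @export
demux_fastq <- function(fastq1, fastq2, profile, lib, ...) {
  r1 <- Biostrings::readDNAStringSet(fastq1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(fastq2, format = "fastq")
  if (length(r1) != length(r2)) stop("mate files have unequal numbers of reads")
  id1 <- sub("\\s.*$", "", names(r1))
  id2 <- sub("\\s.*$", "", names(r2))
  if (!identical(id1, id2)) stop("mate read IDs do not pair up")
  demux_reads(id1, as.character(r1), as.character(r2), profile, lib, ...)
}

#' Deduplicate assigned records to UMI triples
#'
#' Collapses assigned demultiplexed records to distinct (spot, sgRNA, UMI)
#' triples. Optional directional single-mismatch collapse merges, within each
#' (spot, sgRNA) group, a UMI into another UMI at Hamming distance 1 with at
#' least twice its read count (the more abundant UMI is taken as the true
#' molecule, the rarer as its sequencing-error satellite). Collapse is off by
#' default.
#'
#' @param records `demux_result` or its `records` data.frame.
#' @param collapse Enable directional 1-mismatch UMI collapse.
#' @return data.frame of distinct triples: `x, y, sgrna, umi`.
#' @export
dedup_umis <- function(records, collapse = FALSE) {
  if (inherits(records, "demux_result")) records <- records$records
  rec <- records[records$status == "assigned", c("x", "y", "sgrna", "umi")]
  if (!nrow(rec)) return(rec)
  if (!collapse) {
    out <- unique(rec)
    rownames(out) <- NULL
    return(out)
  }
  key <- paste(rec$x, rec$y, rec$sgrna, sep = "\r")
  pieces <- split(rec$umi, key)
  kept <- lapply(pieces, function(umis) {
    cnt <- sort(table(umis), decreasing = TRUE)
    us <- names(cnt)
    if (length(us) == 1L) return(us)
    alive <- rep(TRUE, length(us))
    for (i in seq_along(us)) {           # descending abundance
      if (!alive[i]) next
      for (j in seq_along(us)) {
        if (i == j || !alive[j]) next
        if (cnt[i] >= 2L * cnt[j] &&
            sum(strsplit(us[i], "")[[1L]] != strsplit(us[j], "")[[1L]]) == 1L) {
          alive[j] <- FALSE
        }
      }
    }
    us[alive]
  })
  meta <- do.call(rbind, strsplit(names(pieces), "\r", fixed = TRUE))
  reps <- lengths(kept)
  out <- data.frame(x = as.integer(rep(meta[, 1L], reps)),
                    y = as.integer(rep(meta[, 2L], reps)),
                    sgrna = rep(meta[, 3L], reps),
                    umi = unlist(kept, use.names = FALSE),
                    stringsAsFactors = FALSE)
  out <- out[order(out$x, out$y, out$sgrna, out$umi), ]
  rownames(out) <- NULL
  out
}
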