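# Segment extraction, matching, whitelist construction, demultiplexing,
# deduplication.

test_that("segments are recovered verbatim from well-formed reads", {
  prof <- tiny_profile()
  r <- assemble_read2(prof, 3, 5, "ACGTACGTAC")
  seg <- extract_segments(r, prof$sgrna_layout)
  expect_equal(seg$status, "ok")
  expect_equal(seg$barcode1, prof$barcode_sets[["spatial-A"]]$entries[3])
  expect_equal(seg$barcode2, prof$barcode_sets[["spatial-B"]]$entries[5])
  expect_equal(seg$umi, "ACGTACGTAC")
})

test_that("anchors tolerate declared mismatches and report missing anchors", {
  prof <- tiny_profile()
  r <- assemble_read2(prof, 1, 1, "TTTTTTTTTT")
  # one substitution inside linker1 (positions 9-18) is within max_mismatches=1
  r1 <- sub_base(r, 12)
  seg <- extract_segments(r1, prof$sgrna_layout)
  expect_equal(seg$status, "ok")
  expect_equal(seg$umi, "TTTTTTTTTT")
  # destroy linker2 (positions 27-36) beyond tolerance
  r2 <- r
  for (p in 27:33) r2 <- sub_base(r2, p)
  expect_equal(extract_segments(r2, prof$sgrna_layout)$status,
               "anchor_not_found:linker2")
  expect_equal(extract_segments("ACGT", prof$sgrna_layout)$status, "too_short")
})

test_that("UMI whitelist applies length, truncation and N rules", {
  wl <- build_umi_whitelist(c(rep("ACGTACGTAC", 3), "ACGTACGTACGT"))
  expect_equal(unclass(wl)[["ACGTACGTAC"]], 4L)
  expect_length(wl, 1L)
  # N-containing candidates are rejected (max-n 0)
  expect_false("ACGTNCGTAC" %in%
                 names(build_umi_whitelist(c("ACGTNCGTAC", "ACGTACGTAC"))))
  # below the 10 nt minimum
  expect_false("ACGTACGTA" %in%
                 names(build_umi_whitelist(c("ACGTACGTA", "ACGTACGTAC"))))
  expect_warning(build_umi_whitelist(character(0)), "empty")
})

test_that("barcode matching has unique-best-hit semantics", {
  bs <- barcode_set(c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG", "AACCGGTT"))
  expect_equal(match_barcode("CCCCCCCC", bs, 1L), 2L)
  expect_equal(match_barcode("CCCCCCCA", bs, 1L), 2L)     # 1 mm, unique
  expect_true(is.na(match_barcode("CCCCCCAA", bs, 1L)))   # 2 mm from best
  expect_error(match_barcode("ACGT", bs, 1L), "length")
  # tie at minimal distance is rejected
  bs2 <- barcode_set(c("AAAAAAAA", "AAAAAATT"))
  expect_true(is.na(match_barcode("AAAAAAAT", bs2, 1L)))
})

test_that("spacer matching trims at the scaffold flank and rejects ambiguity", {
  lib <- tiny_library()
  r1 <- assemble_read1(lib, lib$sgrna_name[2])
  expect_equal(as.character(match_spacer(r1, lib)), lib$sgrna_name[2])
  # two substitutions within default budget
  r1mm <- sub_base(sub_base(r1, 2), 5)
  expect_equal(as.character(match_spacer(r1mm, lib)), lib$sgrna_name[2])
  # flank destroyed -> reason spacer_flank_missing
  bad <- paste0(lib$spacer[1], strrep("A", 40))
  res <- match_spacer(bad, lib)
  expect_true(is.na(res[1]))
  expect_equal(attr(res, "reason")[1], "spacer_flank_missing")
  # equidistant query between two spacers at distance 2 is rejected
  libx <- sgrna_library(c("s1", "s2"),
                        c("AAAAAAAAAAAAAAAAAAAA", "AAAAAAAAAAAAAAAAAATT"),
                        c("G1", "G2"))
  q <- paste0("AAAAAAAAAAAAAAAAAAAT", "GTTTTAGAGCTAGAA", "CCCC")
  expect_true(is.na(match_spacer(q, libx)[1]))
})

test_that("demultiplexing recovers error-free reads exactly and accounts drops", {
  prof <- tiny_profile()
  lib <- tiny_library()
  set.seed(11)
  n <- 1000
  x <- sample(6, n, TRUE); y <- sample(6, n, TRUE)
  sg <- sample(lib$sgrna_name, n, TRUE)
  umi <- vapply(seq_len(n), function(i) paste(sample(c("A", "C", "G", "T"), 10,
                                                     TRUE), collapse = ""),
                character(1))
  r2 <- assemble_read2(prof, x, y, umi)
  r1 <- assemble_read1(lib, sg)
  dx <- demux_reads(sprintf("r%04d", 1:n), r1, r2, prof, lib)
  expect_true(all(dx$records$status == "assigned"))
  expect_equal(dx$records$x, x)
  expect_equal(dx$records$y, y)
  expect_equal(dx$records$sgrna, sg)
  expect_equal(dx$records$umi, umi)

  # scramble barcode-A segment beyond reach in exactly 10 reads
  r2b <- r2
  r2b[1:10] <- paste0(strrep("N", 8), substring(r2b[1:10], 9))
  dxb <- demux_reads(sprintf("r%04d", 1:n), r1, r2b, prof, lib)
  expect_equal(unname(dxb$attrition["dropped:barcode1"]), 10L)
  expect_equal(unname(dxb$attrition["assigned"]), n - 10L)
  # conservation: assigned + dropped = total
  expect_equal(sum(dxb$attrition), n)
  # determinism
  dxb2 <- demux_reads(sprintf("r%04d", 1:n), r1, r2b, prof, lib)
  expect_identical(dxb$records, dxb2$records)
  expect_error(demux_reads("a", "ACGT", c("ACGT", "ACGT"), prof, lib),
               "unequal")
})

test_that("demultiplexing agrees with a per-read brute-force oracle under errors", {
  prof <- tiny_profile()
  lib <- tiny_library()
  set.seed(13)
  n <- 400
  x <- sample(6, n, TRUE); y <- sample(6, n, TRUE)
  sg <- sample(lib$sgrna_name, n, TRUE)
  umi <- replicate(n, paste(sample(c("A", "C", "G", "T"), 10, TRUE),
                            collapse = ""))
  corrupt <- function(s, rate) {
    m <- strsplit(s, "")[[1L]]
    hit <- runif(length(m)) < rate
    m[hit] <- vapply(m[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                     character(1))
    paste(m, collapse = "")
  }
  r2 <- vapply(assemble_read2(prof, x, y, umi), corrupt, character(1), rate = 0.005)
  r1 <- vapply(assemble_read1(lib, sg), corrupt, character(1), rate = 0.005)
  dx <- demux_reads(seq_len(n), r1, r2, prof, lib)

  # oracle: exhaustive re-match of each read at fixed segment offsets
  ubh <- function(q, entries, mm) {
    d <- vapply(entries, hamming, 0L, a = q)
    i <- which(d == min(d))
    if (length(i) == 1L && d[i] <= mm) unname(i) else NA_integer_
  }
  for (i in seq_len(n)) {
    bc1 <- substring(r2[i], 1, 8); bc2 <- substring(r2[i], 19, 26)
    l1 <- substring(r2[i], 9, 18); l2 <- substring(r2[i], 27, 36)
    ok_anchor <- hamming(l1, "GTGGCCGATG") <= 1 && hamming(l2, "ATCCACGTGC") <= 1
    exp_x <- if (ok_anchor) ubh(bc1, prof$barcode_sets[["spatial-A"]]$entries, 1L) else NA
    exp_y <- if (ok_anchor && !is.na(exp_x))
      ubh(bc2, prof$barcode_sets[["spatial-B"]]$entries, 1L) else NA
    sp <- substring(r1[i], 1, 20)
    fl <- substring(r1[i], 21, 35)
    exp_sg <- if (ok_anchor && !is.na(exp_x) && !is.na(exp_y) &&
                  hamming(fl, "GTTTTAGAGCTAGAA") <= 2) {
      j <- ubh(sp, lib$spacer, 2L)
      if (is.na(j)) NA_character_ else lib$sgrna_name[j]
    } else NA_character_
    rec <- dx$records[i, ]
    if (!is.na(exp_sg)) {
      expect_equal(rec$status, "assigned")
      expect_equal(rec$x, exp_x); expect_equal(rec$y, exp_y)
      expect_equal(rec$sgrna, exp_sg)
    } else {
      expect_false(rec$status == "assigned")
    }
  }
})

test_that("raising the mismatch budget never lowers the assigned count", {
  prof <- tiny_profile()
  lib <- tiny_library()
  set.seed(17)
  n <- 300
  x <- sample(6, n, TRUE); y <- sample(6, n, TRUE)
  sg <- sample(lib$sgrna_name, n, TRUE)
  umi <- replicate(n, paste(sample(c("A", "C", "G", "T"), 10, TRUE),
                            collapse = ""))
  corrupt1 <- function(s) sub_base(s, sample(nchar(s), 1))
  r2 <- vapply(assemble_read2(prof, x, y, umi), corrupt1, character(1))
  r1 <- assemble_read1(lib, sg)
  n_assigned <- vapply(0:1, function(mm) {
    unname(demux_reads(seq_len(n), r1, r2, prof, lib,
                       max_mm_barcode = mm)$attrition["assigned"])
  }, integer(1))
  expect_true(n_assigned[2] >= n_assigned[1])
})

test_that("single-substitution corruptions are always corrected on separated sets", {
  bs <- random_barcode_set(8, min_dist = 4, seed = 5)
  expect_true(bs$min_dist >= 3)
  for (e in seq_along(bs$entries)) {
    for (pos in 1:8) {
      for (b in setdiff(c("A", "C", "G", "T"),
                        substring(bs$entries[e], pos, pos))) {
        q <- sub_base(bs$entries[e], pos, to = b)
        expect_equal(match_barcode(q, bs, 1L), e)
      }
    }
  }
})

test_that("mismatch correction is gated on whitelist separation", {
  prof <- tiny_profile()
  lib <- tiny_library()
  # replace A whitelist by a distance-1 set: correction must be disabled
  close_set <- barcode_set(c("AAAAAAAA", "AAAAAAAT", "CCCCCCCC", "CCCCCCCG",
                             "GGGGGGGG", "GGGGGGGT"), role = "spatial-A")
  prof$barcode_sets[["spatial-A"]] <- close_set
  r2 <- assemble_read2(prof, 1, 1, "ACGTACGTAC")
  r1 <- assemble_read1(lib, lib$sgrna_name[1])
  expect_warning(
    dx <- demux_reads("r1", r1, r2, prof, lib, max_mm_barcode = 1L),
    "cannot support")
  # exact read still assigned with effective max_mm 0
  expect_equal(dx$records$status, "assigned")
})

test_that("UMI deduplication collapses exact and directional duplicates", {
  rec <- data.frame(read_id = as.character(1:5), x = 1L, y = 1L,
                    sgrna = "sgA", umi = "AAAAAAAAAA", status = "assigned")
  expect_equal(nrow(dedup_umis(rec)), 1L)
  rec2 <- rec[1:2, ]; rec2$umi <- c("AAAAAAAAAA", "AAAAAAAAAT")
  expect_equal(nrow(dedup_umis(rec2)), 2L)
  # directional: 10 reads of u, 1 read of u' at distance 1 -> 1 molecule
  rec3 <- data.frame(read_id = as.character(1:11), x = 1L, y = 1L,
                     sgrna = "sgA",
                     umi = c(rep("AAAAAAAAAA", 10), "AAAAAAAAAT"),
                     status = "assigned")
  expect_equal(nrow(dedup_umis(rec3, collapse = TRUE)), 1L)
  expect_equal(dedup_umis(rec3, collapse = TRUE)$umi, "AAAAAAAAAA")
  # equal abundance is not collapsed (2x rule)
  rec4 <- data.frame(read_id = as.character(1:4), x = 1L, y = 1L,
                     sgrna = "sgA",
                     umi = rep(c("AAAAAAAAAA", "AAAAAAAAAT"), each = 2),
                     status = "assigned")
  expect_equal(nrow(dedup_umis(rec4, collapse = TRUE)), 2L)
})

test_that("FASTQ round-trip feeds the demultiplexer", {
  prof <- tiny_profile()
  lib <- tiny_library()
  set.seed(23)
  n <- 50
  x <- sample(6, n, TRUE); y <- sample(6, n, TRUE)
  sg <- sample(lib$sgrna_name, n, TRUE)
  umi <- replicate(n, paste(sample(c("A", "C", "G", "T"), 10, TRUE),
                            collapse = ""))
  f1 <- tempfile(fileext = ".fastq.gz"); f2 <- tempfile(fileext = ".fastq.gz")
  ids <- sprintf("read%03d", seq_len(n))
  write_fastq(assemble_read1(lib, sg), ids, f1)
  write_fastq(assemble_read2(prof, x, y, umi), ids, f2)
  dx <- demux_fastq(f1, f2, prof, lib)
  expect_true(all(dx$records$status == "assigned"))
  expect_equal(dx$records$sgrna, sg)
  expect_equal(dx$records$x, x)
})
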