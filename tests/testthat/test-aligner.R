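test_that("3' quality trimming strips low-quality tails only", {
  # Phred 30 = "?", Phred 2 = "#": the Q2 tail must go (threshold 5)
  r <- tibble::tibble(id = "r", bases = "ACGT", quals = "??##",
                      mate = NA_integer_)
  out <- trim_reads(r, align_params())
  expect_equal(out$bases, "AC")
  expect_equal(out$quals, "??")

  # all bases at or above the threshold: identity
  r2 <- reads_tbl("ACGTACGT")
  expect_identical(trim_reads(r2, align_params()), r2)

  # fully low-quality read trims to empty
  r3 <- tibble::tibble(id = "r", bases = "ACG", quals = "###",
                       mate = NA_integer_)
  expect_equal(trim_reads(r3, align_params())$bases, "")

  # a low-quality base shielded by a good 3' base survives
  r4 <- tibble::tibble(id = "r", bases = "ACGT", quals = "?#?#",
                       mate = NA_integer_)
  expect_equal(trim_reads(r4, align_params())$bases, "ACG")
})

test_that("adapter trimming removes the matching suffix first", {
  p <- align_params(adapter = "AGATCGGAAG", qual_trim_threshold = 0L)
  r <- reads_tbl("ACGTAGATCG")
  expect_equal(trim_reads(r, p)$bases, "ACGT")

  # no adapter match: unchanged
  r2 <- reads_tbl("ACGTACGTAC")
  expect_equal(trim_reads(r2, p)$bases, "ACGTACGTAC")

  # one mismatch allowed per 10 overlap bases
  r3 <- reads_tbl("ACGTAGATCGGAAX") # 10-base overlap, 1 mismatch at end
  expect_equal(trim_reads(r3, p)$bases, "ACGT")

  # overlap below 3 bases is never trimmed
  r4 <- reads_tbl("ACGTACGTAG")
  expect_equal(trim_reads(r4, p)$bases, "ACGTACGTAG")
})

test_that("read conversion replaces every C with T", {
  expect_equal(convert_reads_ct("TTCGA"), "TTTGA")
  expect_equal(convert_reads_ct("AAAA"), "AAAA")
  expect_equal(convert_reads_ct("CCCC"), "TTTT")
  tb <- reads_tbl("ACGC")
  expect_equal(convert_reads_ct(tb)$bases, "ATGT")
})

test_that("converted references are C-free on both strands", {
  cr <- build_converted_references(c(chr1 = "ACGT"))
  expect_equal(unname(cr$watson_ct), "ATGT")
  expect_equal(unname(cr$crick_ct), "ATGT") # revcomp(ACGT) = ACGT
  expect_equal(unname(build_converted_references(c(c = "AAAA"))$crick_ct),
               "TTTT")

  g <- random_genome(500, seed = 11)
  cr2 <- build_converted_references(g)
  expect_false(grepl("C", cr2$watson_ct))
  expect_false(grepl("C", cr2$crick_ct))
  expect_equal(nchar(cr2$watson_ct), nchar(cr2$crick_ct))
})

test_that("seed index lookups equal a naive substring scan", {
  set.seed(21)
  seqs <- c(s1 = random_genome(300, 1)[[1]], s2 = random_genome(200, 2)[[1]])
  idx <- seed_index(seqs, k = 8)
  for (i in 1:25) {
    q <- if (i <= 20) {
      s <- sample(names(seqs), 1)
      at <- sample.int(nchar(seqs[[s]]) - 7L, 1)
      substr(seqs[[s]], at, at + 7L)
    } else {
      paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = "")
    }
    got <- seed_lookup(idx, q)
    naive <- do.call(rbind, lapply(names(seqs), function(nm) {
      starts <- as.integer(
        gregexpr(q, seqs[[nm]], fixed = TRUE)[[1]]
      )
      starts <- starts[starts > 0]
      # gregexpr skips overlapping matches; rescan exhaustively
      n <- nchar(seqs[[nm]])
      starts <- which(vapply(seq_len(n - 7L), function(p) {
        substr(seqs[[nm]], p, p + 7L) == q
      }, logical(1)))
      if (length(starts) == 0) return(NULL)
      data.frame(seq = nm, pos = starts)
    }))
    if (is.null(naive)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(as.data.frame(got),
                   naive[order(naive$seq, naive$pos), ],
                   ignore_attr = TRUE)
    }
  }
})

test_that("align_reads reports exactly the naive-scan hit set", {
  g <- random_genome(1000, seed = 5)
  p <- align_params()

  # a read equal to a unique substring maps there with 0 mismatches
  read <- substr(chartr("C", "T", g[[1]]), 101, 140)
  hits <- align_reads(read, build_converted_references(g), p)
  ohits <- oracle_hits(g, read, p$max_mismatches)
  expect_equal(nrow(hits), nrow(ohits))
  expect_setequal(paste(hits$strand, hits$start, hits$mm),
                  paste(ohits$strand, ohits$start, ohits$mm))
  expect_true(any(hits$strand == "W" & hits$start == 101 & hits$mm == 0))

  # a read with >= 3 mismatches everywhere returns nothing
  set.seed(9)
  bad <- paste(sample(c("A", "G", "T"), 40, replace = TRUE), collapse = "")
  obad <- oracle_hits(g, bad, p$max_mismatches)
  if (nrow(obad) == 0) {
    expect_equal(nrow(align_reads(bad, build_converted_references(g), p)), 0)
  }

  # poly-T reads hit converted C-runs (Watson) and A-runs (Crick)
  g2 <- c(chr1 = paste0(strrep("G", 30), strrep("C", 30), strrep("A", 30),
                        strrep("G", 30)))
  polyt <- strrep("T", 25)
  h2 <- align_reads(polyt, build_converted_references(g2), align_params())
  expect_setequal(unique(h2$strand), c("W", "C"))
  o2 <- oracle_hits(g2, polyt, 2)
  expect_setequal(paste(h2$strand, h2$start, h2$mm),
                  paste(o2$strand, o2$start, o2$mm))
})

test_that("reads shorter than the seed are never aligned", {
  g <- random_genome(500, seed = 3)
  short <- substr(chartr("C", "T", g[[1]]), 10, 24) # 15 < 20
  expect_equal(nrow(align_reads(short, build_converted_references(g),
                                align_params())), 0)
})

test_that("single-end resolution keeps best-stratum unique hits only", {
  h <- tibble::tibble(read = 1L, strand = c("W", "C"), chrom = "chr1",
                      start = c(10L, 50L), mm = c(0L, 2L), len = 30L)
  r <- resolve_single(h)
  expect_equal(nrow(r$kept), 1)
  expect_equal(r$kept$strand, "W")

  # best stratum on both strands: discarded as ambiguous
  h2 <- dplyr::mutate(h, mm = c(0L, 0L))
  r2 <- resolve_single(h2)
  expect_equal(nrow(r2$kept), 0)
  expect_equal(r2$status$status, "both_strand")

  # two same-strand hits at the best stratum: non-unique
  h3 <- tibble::tibble(read = 1L, strand = "W", chrom = "chr1",
                       start = c(10L, 99L), mm = c(1L, 1L), len = 30L)
  r3 <- resolve_single(h3)
  expect_equal(nrow(r3$kept), 0)
  expect_equal(r3$status$status, "multi")
})

test_that("pair resolution enforces orientation and insert range", {
  p <- align_params() # insert 50..600
  mk <- function(start, mm = 0L, strand = "W", len = 75L) {
    tibble::tibble(read = 1L, strand = strand, chrom = "chr1",
                   start = start, mm = mm, len = len)
  }
  # unique proper pair, outer insert 300
  r <- resolve_pairs(mk(101L), mk(101L + 300L - 75L), p)
  expect_equal(nrow(r$kept), 1)
  expect_equal(r$kept$insert_size, 300L)

  # insert 700 exceeds the maximum
  r2 <- resolve_pairs(mk(101L), mk(101L + 700L - 75L), p)
  expect_equal(nrow(r2$kept), 0)

  # insert 40 below the minimum (overlapping almost fully is fine at >= 50)
  r3 <- resolve_pairs(mk(101L, len = 40L), mk(101L, len = 40L), p)
  expect_equal(nrow(r3$kept), 0)

  # wrong orientation on Watson (mate 2 left of mate 1)
  r4 <- resolve_pairs(mk(400L), mk(150L), p)
  expect_equal(nrow(r4$kept), 0)
})

test_that("duplicate removal keeps the best fragment per key", {
  rec <- function(id, start, q, insert = 100L) {
    tibble::tibble(read_id = id, chrom = "chr1", start = start, strand = "W",
                   mismatches = 0L, bases = "ACGT", quals = q, mate = 1L,
                   mate_start = start + 96L, insert_size = insert)
  }
  # three fragments with the same key, qual sums via string "I" (40) vs "5" (20)
  r <- dplyr::bind_rows(rec("b", 10L, "IIII"), rec("c", 10L, "5555"),
                        rec("a", 10L, "IIII"))
  kept <- remove_duplicates(r)
  expect_equal(unique(kept$read_id), "a") # max qual, tie -> smallest id

  # same start but different insert: both kept
  r2 <- dplyr::bind_rows(rec("x", 10L, "IIII", insert = 100L),
                         rec("y", 10L, "IIII", insert = 200L))
  expect_equal(sort(unique(remove_duplicates(r2)$read_id)), c("x", "y"))
})

test_that("full pipeline equals the naive oracle on random genomes (SE)", {
  for (seed in 1:4) {
    g <- random_genome(2000, seed = seed * 100)
    p <- align_params()
    bases <- draw_bs_reads(g, n = 30, read_len = 35, seed = seed)
    reads <- reads_tbl(bases)
    aln <- bs_align(reads, g, p)

    # oracle pipeline
    kept_o <- list()
    for (i in seq_along(bases)) {
      conv <- chartr("C", "T", bases[i])
      res <- oracle_resolve_single(oracle_hits(g, conv, p$max_mismatches))
      if (!is.null(res)) {
        kept_o[[length(kept_o) + 1L]] <- data.frame(
          read_id = reads$id[i], chrom = res$chrom, start = res$start,
          strand = res$strand, mm = res$mm
        )
      }
    }
    ko <- if (length(kept_o)) do.call(rbind, kept_o) else
      data.frame(read_id = character(0), chrom = character(0),
                 start = integer(0), strand = character(0), mm = integer(0))
    # oracle dedup (SE key: chrom, start, strand, read length)
    if (nrow(ko) > 0) {
      frags <- data.frame(id = ko$read_id, chrom = ko$chrom, start = ko$start,
                          strand = ko$strand, span = 35L,
                          qsum = (40 - 33) * 0 + 40 * 35)
      ko <- ko[ko$read_id %in% oracle_dedup_ids(frags), , drop = FALSE]
    }

    got <- aln$records[order(aln$records$read_id), ]
    ko <- ko[order(ko$read_id), ]
    expect_equal(got$read_id, ko$read_id)
    expect_equal(got$start, ko$start)
    expect_equal(got$strand, ko$strand)
    expect_equal(got$mismatches, ko$mm)
    expect_true(all(got$mismatches <= p$max_mismatches))
  }
})
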