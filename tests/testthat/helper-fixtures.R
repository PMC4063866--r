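# programmatic fixtures shared across test files

random_genome <- function(len, seed, gc = 0.5, name = "chr1") {
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  stats::setNames(
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = ""),
    name
  )
}

# reads tibble from plain sequences, constant quality
reads_tbl <- function(bases, q = "I", ids = NULL, mate = NA_integer_) {
  tibble::tibble(
    id = ids %||% sprintf("r%04d", seq_along(bases)),
    bases = bases,
    quals = strrep(q, nchar(bases)),
    mate = mate
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# bisulfite-style single-end reads drawn from a genome: fragment sampled,
# strand chosen, cytosines on the originating strand converted with prob
# `conv`, then `n_err` substitutions at random positions
draw_bs_reads <- function(genome, n, read_len, seed, conv = 1,
                          max_err = 2, frac_random = 0.1) {
  set.seed(seed)
  g <- genome[[1]]
  len <- nchar(g)
  bases <- character(n)
  for (i in seq_len(n)) {
    if (runif(1) < frac_random) {
      bases[i] <- paste(sample(c("A", "C", "G", "T"), read_len,
                               replace = TRUE), collapse = "")
      next
    }
    f <- sample.int(len - read_len + 1L, 1L)
    frag <- substr(g, f, f + read_len - 1L)
    if (runif(1) < 0.5) frag <- oracle_revcomp(frag)
    ch <- strsplit(frag, "", fixed = TRUE)[[1]]
    cs <- which(ch == "C")
    conv_hit <- cs[runif(length(cs)) < conv]
    ch[conv_hit] <- "T"
    n_err <- sample.int(max_err + 2L, 1L) - 1L # 0 .. max_err+1
    if (n_err > 0) {
      at <- sample.int(read_len, n_err)
      for (a in at) ch[a] <- sample(setdiff(c("A", "C", "G", "T"), ch[a]), 1)
    }
    bases[i] <- paste(ch, collapse = "")
  }
  bases
}

# a methylation calls tibble built directly from per-site levels
calls_from_levels <- function(pos, level, depth, seed,
                              chrom = "chr1", strand = "W",
                              context3 = "CGA", context_class = "CpG") {
  set.seed(seed)
  c_count <- stats::rbinom(length(pos), depth, level / 100)
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), strand = strand,
    context3 = context3, context_class = context_class,
    c_count = c_count, t_count = depth - c_count
  )
}

# two-sample replicate with one planted 1-kb differentially methylated
# block: 4-kb chromosome, CpG every 80 bp, depth 10, 80% everywhere in
# sample A, 80% outside / 20% inside the block in sample B
planted_dmr_replicate <- function(seed, chrom_len = 4000L,
                                  block = c(1501L, 2500L), spacing = 80L,
                                  depth = 10L, level_bg = 80,
                                  level_block = 20) {
  pos <- seq.int(spacing %/% 2, chrom_len, by = spacing)
  in_block <- pos >= block[1] & pos <= block[2]
  callsA <- calls_from_levels(pos, rep(level_bg, length(pos)), depth,
                              seed = seed)
  callsB <- calls_from_levels(pos,
                              ifelse(in_block, level_block, level_bg),
                              depth, seed = seed + 10000L)
  list(callsA = callsA, callsB = callsB, block = block)
}

# minimal bsm_alignment wrapper around hand-built records/stats
fake_alignment <- function(records, total = NULL, mapped = NULL,
                           unique_n = NULL, dup = 0L) {
  n <- length(unique(records$read_id))
  structure(list(
    records = records,
    stats = tibble::tibble(
      total_fragments = total %||% n, trimmed_discarded = 0L,
      mapped = mapped %||% n, unique = unique_n %||% n,
      both_strand_discarded = 0L, multi_discarded = 0L,
      duplicates_removed = dup
    ),
    paired = any(!is.na(records$mate))
  ), class = "bsm_alignment")
}
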