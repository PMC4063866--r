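# Independent naive-scan oracle for the aligner, written against the stated
# rules only (no shared code with the implementation beyond base R).

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# split converted strand references once per genome (the scan over every
# offset is repeated per read, so cache the character vectors)
oracle_cache <- function(genome) {
  lapply(genome, function(g) list(
    W = strsplit(chartr("C", "T", g), "", fixed = TRUE)[[1]],
    C = strsplit(chartr("C", "T", oracle_revcomp(g)), "", fixed = TRUE)[[1]]
  ))
}

# all placements of one converted read on both converted strands, by
# exhaustive Hamming scan; start is the Watson coordinate of the leftmost
# base; N never matches anything
oracle_hits <- function(genome, conv_read, max_mm,
                        cache = oracle_cache(genome)) {
  qc <- strsplit(conv_read, "", fixed = TRUE)[[1]]
  L <- length(qc)
  out <- list()
  for (ch in names(genome)) {
    n <- nchar(genome[[ch]])
    if (n < L) next
    for (strand in c("W", "C")) {
      rc <- cache[[ch]][[strand]]
      offs <- seq_len(n - L + 1L)
      refmat <- matrix(rc[outer(0:(L - 1L), offs, "+")], nrow = L)
      mm <- colSums(refmat != qc | refmat == "N" | qc == "N")
      hit <- which(mm <= max_mm)
      if (length(hit) == 0) next
      p <- offs[hit]
      start <- if (strand == "W") p else n - (p + L - 1L) + 1L
      out[[length(out) + 1L]] <- data.frame(
        strand = strand, chrom = ch, start = start, mm = mm[hit], len = L
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(strand = character(0), chrom = character(0),
                      start = integer(0), mm = integer(0), len = integer(0)))
  }
  do.call(rbind, out)
}

# single-end resolution rule, applied literally
oracle_resolve_single <- function(hits) {
  if (nrow(hits) == 0) return(NULL)
  best <- hits[hits$mm == min(hits$mm), , drop = FALSE]
  if (nrow(best) != 1) return(NULL)
  if (length(unique(best$strand)) != 1) return(NULL)
  best
}

# paired-end resolution rule, applied literally
oracle_resolve_pair <- function(h1, h2, insert_min, insert_max) {
  if (nrow(h1) == 0 || nrow(h2) == 0) return(NULL)
  cand <- merge(h1, h2, by = c("strand", "chrom"),
                suffixes = c("1", "2"))
  if (nrow(cand) == 0) return(NULL)
  e1 <- cand$start1 + cand$len1 - 1L
  e2 <- cand$start2 + cand$len2 - 1L
  ins <- pmax(e1, e2) - pmin(cand$start1, cand$start2) + 1L
  inward <- ifelse(cand$strand == "W", cand$start1 <= cand$start2,
                   cand$start2 <= cand$start1)
  ok <- inward & ins >= insert_min & ins <= insert_max
  cand <- cand[ok, , drop = FALSE]
  ins <- ins[ok]
  if (nrow(cand) == 0) return(NULL)
  tot <- cand$mm1 + cand$mm2
  at_min <- tot == min(tot)
  if (sum(at_min) != 1) return(NULL)
  if (length(unique(cand$strand[at_min])) != 1) return(NULL)
  cbind(cand[at_min, , drop = FALSE], insert_size = ins[at_min])
}

# duplicate rule: fragments sharing (chrom, leftmost start, strand,
# insert-or-length) keep the best quality sum, ties -> smallest id.
# `frags` has id, chrom, start, strand, span, qsum
oracle_dedup_ids <- function(frags) {
  frags <- frags[order(-frags$qsum, frags$id), , drop = FALSE]
  key <- paste(frags$chrom, frags$start, frags$strand, frags$span)
  frags$id[!duplicated(key)]
}
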