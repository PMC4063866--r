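#' Alignment parameters
#'
#' Defaults follow standard practice for directional MethylC-seq libraries:
#' at most 2 substitution mismatches, paired-end insert between 50 and 600
#' bases, 3'-end trimming of bases below Phred 5, and a 20-base exact seed
#' (reads shorter than the seed after trimming are discarded).
#'
#' @param max_mismatches Maximum substitutions per read (on the converted
#'   read versus the converted reference).
#' @param insert_min,insert_max Accepted outer insert size range for pairs.
#' @param qual_trim_threshold Phred threshold for 3' quality trimming.
#' @param adapter Optional adapter sequence to trim from 3' ends.
#' @param seed_len Exact-seed length; also the minimum usable read length.
#' @param trim5 Also quality-trim the 5' end (off by default; adapters and
#'   quality decay sit at the 3' end of Illumina reads).
#' @return A list of class `bsm_align_params`.
#' @export
align_params <- function(max_mismatches = 2L, insert_min = 50L,
                         insert_max = 600L, qual_trim_threshold = 5L,
                         adapter = NULL, seed_len = 20L, trim5 = FALSE) {
  stopifnot(max_mismatches >= 0, insert_min <= insert_max, seed_len >= 4)
  structure(
    list(max_mismatches = as.integer(max_mismatches),
         insert_min = as.integer(insert_min),
         insert_max = as.integer(insert_max),
         qual_trim_threshold = as.integer(qual_trim_threshold),
         adapter = adapter, seed_len = as.integer(seed_len),
         trim5 = isTRUE(trim5)),
    class = "bsm_align_params"
  )
}

# 3' trim of one read against the adapter: longest read suffix matching an
# adapter prefix, minimum overlap 3, at most 1 mismatch per 10 overlap bases
adapter_cut <- function(bases, adapter) {
  L <- nchar(bases)
  if (L < 3) return(L)
  rch <- strsplit(bases, "", fixed = TRUE)[[1]]
  ach <- strsplit(adapter, "", fixed = TRUE)[[1]]
  for (start in seq_len(L - 2)) {
    ov <- min(L - start + 1L, length(ach))
    if (ov < 3) break
    mism <- sum(rch[start:(start + ov - 1L)] != ach[seq_len(ov)])
    if (mism <= ov %/% 10) return(start - 1L)
  }
  L
}

#' Trim reads: adapter first, then low-quality 3' ends
#'
#' Adapter removal truncates at the start of the longest read suffix that
#' matches a prefix of the adapter (minimum overlap 3 bases, at most one
#' mismatch per 10 overlap bases).  Quality trimming then strips bases with
#' Phred below the threshold from the 3' end until a base at or above the
#' threshold is reached.  Reads may come back empty; [bs_align()] discards
#' reads shorter than the seed length and counts them in its stats.
#'
#' @param reads Reads tibble from [read_fastq()].
#' @param params [align_params()].
#' @return The reads tibble with trimmed `bases`/`quals`.
#' @export
trim_reads <- function(reads, params = align_params()) {
  bases <- reads$bases
  quals <- reads$quals
  if (!is.null(params$adapter)) {
    keep <- mapply(adapter_cut, bases, MoreArgs = list(adapter = params$adapter))
    bases <- substr(bases, 1L, keep)
    quals <- substr(quals, 1L, keep)
  }
  th <- params$qual_trim_threshold
  if (th > 0) {
    # strip trailing bases whose Phred+33 byte is below 33 + th
    pat <- sprintf("[\\x21-\\x%02X]+$", 32L + th)
    quals <- sub(pat, "", quals, perl = TRUE)
    if (params$trim5) {
      pat5 <- sprintf("^[\\x21-\\x%02X]+", 32L + th)
      drop5 <- nchar(quals)
      quals <- sub(pat5, "", quals, perl = TRUE)
      bases <- substr(bases, nchar(bases) - drop5 + 1L, nchar(bases))
    }
    bases <- substr(bases, 1L, nchar(quals))
  }
  reads$bases <- bases
  reads$quals <- quals
  reads
}

#' In-silico C-to-T conversion of read sequences
#'
#' @param x Character vector of read sequences (or a reads tibble, in which
#'   case `bases` is converted in place).
#' @return Same shape as the input with every C replaced by T.
#' @export
convert_reads_ct <- function(x) {
  if (is.data.frame(x)) {
    x$bases <- chartr("C", "T", x$bases)
    return(x)
  }
  chartr("C", "T", x)
}

#' Build the two C-depleted converted references
#'
#' The Watson reference has every C replaced by T; the Crick reference is
#' the reverse complement of Watson, again with every C replaced by T.
#'
#' @param genome Named character vector from [read_fasta()].
#' @return A list of class `bsm_convref` with `watson_ct`, `crick_ct`,
#'   `lengths` and the original `genome`.
#' @export
build_converted_references <- function(genome) {
  check_genome(genome)
  structure(
    list(watson_ct = chartr("C", "T", genome),
         crick_ct = chartr("C", "T", revcomp(genome)) |> setNames(names(genome)),
         lengths = setNames(nchar(genome), names(genome)),
         genome = genome),
    class = "bsm_convref"
  )
}

#' Exact-substring seed index
#'
#' A k-mer position table over a set of sequences: `seed_lookup()` returns
#' exactly the set of start positions where the query occurs, the contract
#' the aligner's candidate generation relies on.
#'
#' @param seqs Named character vector of sequences.
#' @param k Seed length.
#' @return An object of class `bsm_seed_index`.
#' @export
seed_index <- function(seqs, k) {
  stopifnot(k >= 1, all(nchar(seqs) >= 1))
  tab <- new.env(parent = emptyenv())
  for (nm in names(seqs)) {
    n <- nchar(seqs[[nm]])
    if (n < k) next
    kmers <- substring(seqs[[nm]], 1:(n - k + 1L), k:n)
    sp <- split(seq_len(n - k + 1L), kmers)
    for (km in names(sp)) {
      tab[[km]] <- rbind(tab[[km]],
                         cbind(seq = match(nm, names(seqs)), pos = sp[[km]]))
    }
  }
  structure(list(k = as.integer(k), seq_names = names(seqs), tab = tab),
            class = "bsm_seed_index")
}

#' @rdname seed_index
#' @param index A `bsm_seed_index`.
#' @param s Query string of length `k`.
#' @return For `seed_lookup()`: tibble of `seq` (sequence name) and `pos`
#'   (1-based start) of every occurrence.
#' @export
seed_lookup <- function(index, s) {
  stopifnot(nchar(s) == index$k)
  hit <- index$tab[[s]]
  if (is.null(hit)) {
    return(tibble::tibble(seq = character(0), pos = integer(0)))
  }
  tibble::tibble(seq = index$seq_names[hit[, "seq"]],
                 pos = as.integer(hit[, "pos"])) |>
    dplyr::arrange(.data$seq, .data$pos)
}

#' Align converted reads to both converted reference strands
#'
#' Returns all placements with at most `max_mismatches` substitutions (no
#' indels) on either converted strand.  Crick-strand placements are
#' translated back to the Watson coordinate of the read's leftmost base, so
#' all hits share one coordinate axis.  Reads shorter than the seed length
#' return no hits.
#'
#' @param converted Character vector of C-to-T converted read sequences.
#' @param convref [build_converted_references()] output.
#' @param params [align_params()].
#' @return Tibble with `read` (index into `converted`), `strand` (`W`/`C`),
#'   `chrom`, `start` (Watson 1-based leftmost), `mm`, `len`.
#' @export
align_reads <- function(converted, convref, params = align_params()) {
  nchr <- length(convref$watson_ct)
  refs <- c(unname(convref$watson_ct), unname(convref$crick_ct))
  lens <- nchar(converted)
  queries <- converted
  queries[lens < params$seed_len] <- "" # unmappable by contract
  hits <- cpp_align_batch(refs, queries, params$max_mismatches,
                          params$seed_len)
  strand <- ifelse(hits$ref <= nchr, "W", "C")
  ci <- ifelse(hits$ref <= nchr, hits$ref, hits$ref - nchr)
  clen <- unname(convref$lengths)[ci]
  rl <- lens[hits$read]
  start <- ifelse(strand == "W", hits$pos, clen - (hits$pos + rl - 1L) + 1L)
  tibble::tibble(read = hits$read, strand = strand,
                 chrom = names(convref$lengths)[ci],
                 start = as.integer(start), mm = hits$mm, len = rl)
}

#' Resolve single-end hits to unique alignments
#'
#' A read is kept iff, at the minimum mismatch count it attains, exactly one
#' placement exists and no placement at that minimum lies on the other
#' strand's reference (best-stratum uniqueness; reads whose best stratum
#' spans both strands are the "both-strand" discards).
#'
#' @param hits Hit tibble from [align_reads()] (any number of reads).
#' @return List with `kept` (one row per kept read) and `status` (one row
#'   per read that had any hit: `kept`, `multi` or `both_strand`).
#' @export
resolve_single <- function(hits) {
  if (nrow(hits) == 0) {
    return(list(kept = hits, status = tibble::tibble(read = integer(0),
                                                     status = character(0))))
  }
  best <- hits |>
    dplyr::group_by(.data$read) |>
    dplyr::filter(.data$mm == min(.data$mm)) |>
    dplyr::ungroup()
  status <- best |>
    dplyr::group_by(.data$read) |>
    dplyr::summarise(n = dplyr::n(), nstr = dplyr::n_distinct(.data$strand),
                     .groups = "drop") |>
    dplyr::mutate(status = dplyr::case_when(
      .data$nstr > 1 ~ "both_strand",
      .data$n > 1 ~ "multi",
      TRUE ~ "kept"
    ))
  kept <- best |>
    dplyr::inner_join(dplyr::filter(status, .data$status == "kept")["read"],
                      by = "read")
  list(kept = kept, status = status[c("read", "status")])
}

#' Resolve paired-end hits to unique proper pairs
#'
#' Candidate pairs place both mates on the same chromosome with the same
#' strand of origin, inward facing, with outer insert (rightmost end minus
#' leftmost start plus one) inside the configured range.  A pair is kept iff
#' exactly one candidate exists at the minimum total mismatch count and no
#' candidate at that minimum has the opposite strand of origin.
#'
#' @param hits1,hits2 Hit tibbles from [align_reads()] for mates 1 and 2,
#'   sharing the `read` (fragment) index.
#' @param params [align_params()].
#' @return List with `kept` (one row per kept fragment: `read`, `strand`,
#'   `chrom`, `start1`, `start2`, `mm1`, `mm2`, `len1`, `len2`,
#'   `insert_size`) and `status` as in [resolve_single()].
#' @export
resolve_pairs <- function(hits1, hits2, params = align_params()) {
  cand <- dplyr::inner_join(
    dplyr::rename(hits1, start1 = "start", mm1 = "mm", len1 = "len"),
    dplyr::rename(hits2, start2 = "start", mm2 = "mm", len2 = "len"),
    by = c("read", "strand", "chrom"),
    relationship = "many-to-many"
  ) |>
    dplyr::mutate(
      end1 = .data$start1 + .data$len1 - 1L,
      end2 = .data$start2 + .data$len2 - 1L,
      insert_size = pmax(.data$end1, .data$end2) -
        pmin(.data$start1, .data$start2) + 1L,
      mm = .data$mm1 + .data$mm2,
      inward = ifelse(.data$strand == "W",
                      .data$start1 <= .data$start2,
                      .data$start2 <= .data$start1)
    ) |>
    dplyr::filter(.data$inward,
                  .data$insert_size >= params$insert_min,
                  .data$insert_size <= params$insert_max)
  if (nrow(cand) == 0) {
    return(list(kept = cand[0, ], status = tibble::tibble(
      read = integer(0), status = character(0))))
  }
  best <- cand |>
    dplyr::group_by(.data$read) |>
    dplyr::filter(.data$mm == min(.data$mm)) |>
    dplyr::ungroup()
  status <- best |>
    dplyr::group_by(.data$read) |>
    dplyr::summarise(n = dplyr::n(), nstr = dplyr::n_distinct(.data$strand),
                     .groups = "drop") |>
    dplyr::mutate(status = dplyr::case_when(
      .data$nstr > 1 ~ "both_strand",
      .data$n > 1 ~ "multi",
      TRUE ~ "kept"
    ))
  kept <- best |>
    dplyr::inner_join(dplyr::filter(status, .data$status == "kept")["read"],
                      by = "read") |>
    dplyr::select("read", "strand", "chrom", "start1", "start2",
                  "mm1", "mm2", "len1", "len2", "insert_size")
  list(kept = kept, status = status[c("read", "status")])
}

#' Remove duplicate fragments
#'
#' Fragments sharing (chrom, leftmost start, strand of origin, insert size
#' for pairs / read length for single-end reads) collapse to one; the
#' retained fragment is the one with the greatest sum of base qualities,
#' ties broken by lexicographically smallest read id.
#'
#' @param records Alignment records tibble (per-mate rows).
#' @return The deduplicated records tibble.
#' @export
remove_duplicates <- function(records) {
  if (nrow(records) == 0) return(records)
  frag <- records |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(
      chrom = .data$chrom[1], strand = .data$strand[1],
      frag_start = min(.data$start),
      span = ifelse(is.na(.data$insert_size[1]),
                    nchar(.data$bases[1]), .data$insert_size[1]),
      qsum = sum(phred_sum(.data$quals)),
      .groups = "drop"
    )
  keep_ids <- frag |>
    dplyr::arrange(dplyr::desc(.data$qsum), .data$read_id) |>
    dplyr::distinct(.data$chrom, .data$frag_start, .data$strand, .data$span,
                    .keep_all = TRUE) |>
    dplyr::pull(.data$read_id)
  dplyr::filter(records, .data$read_id %in% keep_ids)
}

#' Align bisulfite reads end to end
#'
#' Runs the full alignment stage: 3' trimming, in-silico C-to-T conversion,
#' alignment of both mates to the two converted reference strands (read 2 of
#' a directional library is the base complement of the bisulfite strand, so
#' it is reverse-complemented before conversion), best-stratum uniqueness
#' and both-strand filtering, and fragment-level duplicate removal.  Kept
#' records carry the original (unconverted, trimmed) read bases.
#'
#' @param reads Reads tibble from [read_fastq()]; paired-end when the `mate`
#'   column holds 1/2, single-end otherwise.
#' @param genome Named character vector from [read_fasta()], or a
#'   pre-built [build_converted_references()] object.
#' @param params [align_params()].
#' @return An object of class `bsm_alignment`: a list with `records` (one
#'   row per kept read: `read_id`, `chrom`, `start`, `strand`,
#'   `mismatches`, `bases`, `quals`, `mate`, `mate_start`, `insert_size`),
#'   `stats` (fragment-level counts) and `params`.  Use [tidy()] /
#'   [glance()] to extract them.
#' @export
bs_align <- function(reads, genome, params = align_params()) {
  convref <- if (inherits(genome, "bsm_convref")) genome
             else build_converted_references(genome)
  paired <- !all(is.na(reads$mate))
  trimmed <- trim_reads(reads, params)

  if (paired) {
    r1 <- dplyr::filter(trimmed, .data$mate == 1L)
    r2 <- dplyr::filter(trimmed, .data$mate == 2L)
    if (nrow(r1) != nrow(r2) || !all(r1$id == r2$id)) {
      r2 <- r2[match(r1$id, r2$id), ]
      if (anyNA(r2$id)) stop("mates are not in lockstep", call. = FALSE)
    }
    total <- nrow(r1)
    long_enough <- nchar(r1$bases) >= params$seed_len &
      nchar(r2$bases) >= params$seed_len
    r1 <- r1[long_enough, ]; r2 <- r2[long_enough, ]
    trimmed_discarded <- total - nrow(r1)

    proc1 <- convert_reads_ct(r1$bases)
    proc2 <- convert_reads_ct(revcomp(r2$bases))
    hits1 <- align_reads(proc1, convref, params)
    hits2 <- align_reads(proc2, convref, params)
    res <- resolve_pairs(hits1, hits2, params)

    mapped <- nrow(res$status)
    both_strand <- sum(res$status$status == "both_strand")
    k <- res$kept
    records <- dplyr::bind_rows(
      tibble::tibble(
        read_id = r1$id[k$read], chrom = k$chrom, start = k$start1,
        strand = k$strand, mismatches = k$mm1, bases = r1$bases[k$read],
        quals = r1$quals[k$read], mate = 1L, mate_start = k$start2,
        insert_size = k$insert_size
      ),
      tibble::tibble(
        read_id = r2$id[k$read], chrom = k$chrom, start = k$start2,
        strand = k$strand, mismatches = k$mm2, bases = r2$bases[k$read],
        quals = r2$quals[k$read], mate = 2L, mate_start = k$start1,
        insert_size = k$insert_size
      )
    )
  } else {
    total <- nrow(trimmed)
    keep <- nchar(trimmed$bases) >= params$seed_len
    tr <- trimmed[keep, ]
    trimmed_discarded <- total - nrow(tr)

    hits <- align_reads(convert_reads_ct(tr$bases), convref, params)
    res <- resolve_single(hits)
    mapped <- nrow(res$status)
    both_strand <- sum(res$status$status == "both_strand")
    k <- res$kept
    records <- tibble::tibble(
      read_id = tr$id[k$read], chrom = k$chrom, start = k$start,
      strand = k$strand, mismatches = k$mm, bases = tr$bases[k$read],
      quals = tr$quals[k$read], mate = NA_integer_,
      mate_start = NA_integer_, insert_size = NA_integer_
    )
  }

  unique_n <- sum(res$status$status == "kept")
  deduped <- remove_duplicates(records)
  duplicates_removed <- unique_n -
    length(unique(deduped$read_id))

  stats <- tibble::tibble(
    total_fragments = total,
    trimmed_discarded = trimmed_discarded,
    mapped = mapped,
    unique = unique_n,
    both_strand_discarded = both_strand,
    multi_discarded = mapped - unique_n - both_strand,
    duplicates_removed = duplicates_removed
  )
  structure(list(records = deduped, stats = stats, params = params,
                 paired = paired),
            class = "bsm_alignment")
}

#' @export
print.bsm_alignment <- function(x, ...) {
  s <- x$stats
  cat("<bsm_alignment> ", if (x$paired) "paired-end" else "single-end", "\n",
      sep = "")
  cat(sprintf("  fragments: %d total, %d mapped, %d unique, %d kept after dedup\n",
              s$total_fragments, s$mapped, s$unique,
              length(unique(x$records$read_id))))
  invisible(x)
}

#' @rdname bs_align
#' @param x A `bsm_alignment`.
#' @param ... Unused.
#' @export
tidy.bsm_alignment <- function(x, ...) x$records

#' @rdname bs_align
#' @export
glance.bsm_alignment <- function(x, ...) {
  dplyr::mutate(
    x$stats,
    mappability = ifelse(.data$total_fragments > 0,
                         100 * .data$mapped / .data$total_fragments, NA_real_),
    dup_rate = ifelse(.data$mapped > 0,
                      100 * .data$duplicates_removed / .data$mapped, NA_real_)
  )
}
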