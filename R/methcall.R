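#' Per-cytosine C/T pileup
#'
#' Counts, for every reference cytosine covered by at least one kept read,
#' how often the read base (in the read's strand-of-origin orientation) was
#' C (methylated event) or T (unmethylated event).  Other read bases at a
#' cytosine site (sequencing error, variant) are ignored.  When the two
#' mates of a short fragment overlap a cytosine, the observation counts
#' once, taking the mate with the higher base quality (ties go to mate 1).
#'
#' Crick-strand cytosines are reported at the Watson coordinate of the
#' paired G, so both strands share one coordinate axis.
#'
#' @param records Alignment records tibble (from [bs_align()] via [tidy()],
#'   or [read_bsalign()]).
#' @param genome Named character vector from [read_fasta()].
#' @return Tibble with `chrom`, `pos`, `strand` (`W`/`C`), `c_count`,
#'   `t_count`, one row per covered cytosine.
#' @export
pileup <- function(records, genome) {
  check_genome(genome)
  chroms <- names(genome)
  lens <- setNames(nchar(genome), chroms)
  if (nrow(records) == 0) {
    return(tibble::tibble(chrom = character(0), pos = integer(0),
                          strand = character(0), c_count = integer(0),
                          t_count = integer(0)))
  }
  if (any(!records$chrom %in% chroms)) {
    stop("records refer to chromosomes absent from the genome", call. = FALSE)
  }
  nchr <- length(chroms)
  refs <- c(unname(genome), revcomp(unname(genome))) # Watson then Crick

  ci <- match(records$chrom, chroms)
  L <- nchar(records$bases)
  if (any(records$start < 1L) ||
      any(records$start + L - 1L > lens[records$chrom])) {
    stop("alignment record extends past chromosome end", call. = FALSE)
  }
  is_crick <- records$strand == "C"
  ref_id <- ifelse(is_crick, ci + nchr, ci)
  start_strand <- ifelse(is_crick,
                         lens[records$chrom] - (records$start + L - 1L) + 1L,
                         records$start)
  mate2 <- !is.na(records$mate) & records$mate == 2L
  bases <- records$bases
  quals <- records$quals
  if (any(mate2)) {
    bases[mate2] <- revcomp(bases[mate2])
    quals[mate2] <- reverse_string(quals[mate2])
  }
  frag_id <- match(records$read_id, unique(records$read_id))
  mate <- ifelse(is.na(records$mate), 1L, records$mate)

  res <- cpp_pileup(refs, as.integer(ref_id), as.integer(start_strand),
                    bases, quals, as.integer(frag_id), as.integer(mate))
  out_crick <- res$ref > nchr
  out_ci <- ifelse(out_crick, res$ref - nchr, res$ref)
  pos <- ifelse(out_crick, lens[out_ci] - res$pos + 1L, res$pos)
  tibble::tibble(
    chrom = chroms[out_ci],
    pos = as.integer(pos),
    strand = ifelse(out_crick, "C", "W"),
    c_count = res$c_count,
    t_count = res$t_count
  ) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$strand)
}

#' Trinucleotide context of a reference cytosine
#'
#' The context is the cytosine plus the next two bases read 5' to 3' on its
#' own strand (the Crick context is read off the reverse complement).
#' Positions within two bases of the chromosome end are padded with N; such
#' sites classify as CHH unless the CG dinucleotide is complete.  Class is a
#' pure function of the context: `CG.` is CpG, `C.G` is CHG, anything else
#' CHH (H = A, C or T).
#'
#' @param genome Named character vector from [read_fasta()].
#' @param chrom,pos,strand Vectors locating cytosines; `pos` uses the shared
#'   Watson coordinate axis (a Crick cytosine sits at the Watson G).
#' @return Tibble with `context3` and `context_class`.
#' @export
assign_context <- function(genome, chrom, pos, strand) {
  check_genome(genome)
  lens <- setNames(nchar(genome), names(genome))
  crick <- setNames(revcomp(genome), names(genome))
  p_strand <- ifelse(strand == "C", lens[chrom] - pos + 1L, pos)
  seqs <- ifelse(strand == "C", crick[chrom], genome[chrom])
  ctx <- substr(seqs, p_strand, p_strand + 2L)
  pad <- 3L - nchar(ctx)
  ctx <- paste0(ctx, strrep("N", pmax(pad, 0L)))
  if (any(substr(ctx, 1, 1) != "C")) {
    stop("assign_context called on a position that is not a cytosine",
         call. = FALSE)
  }
  cls <- ifelse(substr(ctx, 2, 2) == "G", "CpG",
                ifelse(substr(ctx, 3, 3) == "G", "CHG", "CHH"))
  tibble::tibble(context3 = unname(ctx), context_class = unname(cls))
}

#' Full methylation calling: pileup plus context annotation
#'
#' @param x A `bsm_alignment` from [bs_align()], or an alignment records
#'   tibble.
#' @param genome Named character vector from [read_fasta()].
#' @param min_depth Minimum total (C+T) depth for a site to be reported
#'   (default 1: every covered site).
#' @return Methylation calls tibble: `chrom`, `pos`, `strand`, `context3`,
#'   `context_class`, `c_count`, `t_count`.
#' @export
call_methylation <- function(x, genome, min_depth = 1L) {
  records <- if (inherits(x, "bsm_alignment")) x$records else x
  counts <- pileup(records, genome)
  counts <- dplyr::filter(counts,
                          .data$c_count + .data$t_count >= min_depth)
  if (nrow(counts) == 0) {
    return(tibble::tibble(chrom = character(0), pos = integer(0),
                          strand = character(0), context3 = character(0),
                          context_class = character(0), c_count = integer(0),
                          t_count = integer(0)))
  }
  ctx <- assign_context(genome, counts$chrom, counts$pos, counts$strand)
  dplyr::bind_cols(counts, ctx) |>
    dplyr::relocate("context3", "context_class", .after = "strand")
}

#' Pooled methylation density of a set of cytosines
#'
#' MD = 100 * sum(C_i) / sum(C_i + T_i) over the selected cytosines, the
#' pooled methylated fraction as a percentage.  With a single site this is
#' single-base-resolution MD.  Zero total depth yields a missing value, not
#' zero.
#'
#' @param calls Methylation calls tibble.
#' @param chrom,start,end Optional region filter (1-based inclusive).
#' @param strand Optional strand filter (`"W"` or `"C"`).
#' @param context Optional context-class filter (`"CpG"`, `"CHG"`, `"CHH"`).
#' @return One-row tibble with `md` (percent), `n_sites`, `depth`.
#' @export
methylation_density <- function(calls, chrom = NULL, start = NULL, end = NULL,
                                strand = NULL, context = NULL) {
  x <- calls
  if (!is.null(chrom)) x <- dplyr::filter(x, .data$chrom %in% !!chrom)
  if (!is.null(start)) x <- dplyr::filter(x, .data$pos >= !!start)
  if (!is.null(end)) x <- dplyr::filter(x, .data$pos <= !!end)
  if (!is.null(strand)) x <- dplyr::filter(x, .data$strand %in% !!strand)
  if (!is.null(context)) x <- dplyr::filter(x, .data$context_class %in% !!context)
  depth <- sum(x$c_count) + sum(x$t_count)
  tibble::tibble(
    md = if (depth > 0) 100 * sum(x$c_count) / depth else NA_real_,
    n_sites = nrow(x),
    depth = depth
  )
}

#' Bisulfite conversion rate from an unmethylated spike-in
#'
#' The spike chromosome (for example a lambda phage spike) is assumed fully
#' unmethylated, so every sequenced T at one of its cytosines reflects a
#' successful conversion: rate = 100 * sum(T) / sum(C + T) over all cytosine
#' positions of the spike.
#'
#' @param calls Methylation calls tibble.
#' @param spike_chrom Name of the spike chromosome; if absent from the
#'   calls, the rate is missing and the pipeline continues.
#' @return One-row tibble with `conversion_rate` (percent) and `depth`.
#' @export
conversion_rate <- function(calls, spike_chrom) {
  x <- dplyr::filter(calls, .data$chrom == spike_chrom)
  depth <- sum(x$c_count) + sum(x$t_count)
  tibble::tibble(
    conversion_rate = if (depth > 0) 100 * sum(x$t_count) / depth else NA_real_,
    depth = depth
  )
}
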