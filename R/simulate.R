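#' Simulation settings for bisulfite read pairs
#'
#' Defaults reproduce the lambda-scale alignment validation: a 48.5-kb
#' genome, 50,000 75-base paired-end reads with outer inserts uniform in
#' 75-600 bases, fully methylated CpGs, unmethylated CHG/CHH, complete
#' bisulfite conversion, and a 0.001 per-base substitution error rate.
#'
#' @param genome_len Genome length in bases.
#' @param gc GC fraction of the simulated genome.
#' @param n_pairs Number of read pairs.
#' @param read_len Read length in bases.
#' @param insert_min,insert_max Outer insert range; `insert_min` must be at
#'   least `read_len` (each mate is read fully off the fragment).
#' @param meth_cpg,meth_chg,meth_chh Methylation level (percent) assigned to
#'   every cytosine of that context class, on both strands.
#' @param error_rate Per-base substitution probability applied after
#'   conversion.
#' @param conversion_rate Percent of unmethylated cytosines converted.
#' @param qual_decay Phred points lost linearly from cycle 1 to the last
#'   cycle (0 = constant Q40).
#' @param seed RNG seed; every simulation is reproducible given the seed.
#' @return A list of class `bsm_sim_config`.
#' @export
sim_config <- function(genome_len = 48500L, gc = 0.5, n_pairs = 50000L,
                       read_len = 75L, insert_min = 75L, insert_max = 600L,
                       meth_cpg = 100, meth_chg = 0, meth_chh = 0,
                       error_rate = 0.001, conversion_rate = 100,
                       qual_decay = 0, seed = 1L) {
  stopifnot(gc >= 0, gc <= 1, error_rate >= 0, error_rate <= 1,
            conversion_rate >= 0, conversion_rate <= 100,
            meth_cpg >= 0, meth_cpg <= 100, meth_chg >= 0, meth_chg <= 100,
            meth_chh >= 0, meth_chh <= 100,
            insert_min <= insert_max, insert_min >= read_len,
            insert_max <= genome_len)
  structure(
    list(genome_len = as.integer(genome_len), gc = gc,
         n_pairs = as.integer(n_pairs), read_len = as.integer(read_len),
         insert_min = as.integer(insert_min),
         insert_max = as.integer(insert_max),
         meth_cpg = meth_cpg, meth_chg = meth_chg, meth_chh = meth_chh,
         error_rate = error_rate, conversion_rate = conversion_rate,
         qual_decay = qual_decay, seed = as.integer(seed)),
    class = "bsm_sim_config"
  )
}

#' Simulate a random genome
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(T) =
#' (1 - gc)/2; the result is reproducible for a fixed seed.
#'
#' @param config [sim_config()].
#' @return Named character vector with one chromosome, `simchr1`.
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
         G = config$gc / 2, T = (1 - config$gc) / 2)
  g <- paste(sample(names(p), config$genome_len, replace = TRUE, prob = p),
             collapse = "")
  c(simchr1 = g)
}

#' Assign a truth methylation level to every cytosine
#'
#' Every cytosine on both strands receives the level configured for its
#' context class.  Positions use the shared Watson axis (a Crick cytosine
#' sits at the Watson coordinate of its G), matching the convention of
#' [call_methylation()].
#'
#' @param genome Named character vector.
#' @param config [sim_config()].
#' @return Tibble with `chrom`, `pos`, `strand`, `context_class`, `level`
#'   (percent).
#' @export
simulate_methylome <- function(genome, config = sim_config()) {
  check_genome(genome)
  lv <- c(CpG = config$meth_cpg, CHG = config$meth_chg, CHH = config$meth_chh)
  per_chrom <- lapply(names(genome), function(ch) {
    seq_ <- genome[[ch]]
    len <- nchar(seq_)
    chars <- strsplit(seq_, "", fixed = TRUE)[[1]]
    wpos <- which(chars == "C")
    cpos <- len - which(chars == "G") + 1L # Crick coords of Crick cytosines
    pos <- c(wpos, len - cpos + 1L)
    strand <- rep(c("W", "C"), c(length(wpos), length(cpos)))
    if (length(pos) == 0) {
      return(tibble::tibble(chrom = character(0), pos = integer(0),
                            strand = character(0),
                            context_class = character(0),
                            level = numeric(0)))
    }
    ctx <- assign_context(genome, rep(ch, length(pos)), pos, strand)
    tibble::tibble(chrom = ch, pos = pos, strand = strand,
                   context_class = ctx$context_class,
                   level = unname(lv[ctx$context_class]))
  })
  dplyr::bind_rows(per_chrom) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$strand)
}

#' Simulate bisulfite paired-end reads with truth tracking
#'
#' Per fragment: start uniform along the genome, outer insert uniform in
#' `[insert_min, insert_max]`, strand of origin a fair coin.  Each cytosine
#' of the fragment molecule is methylated with its site's truth level;
#' unmethylated cytosines convert C to T with probability
#' `conversion_rate`; conversion outcomes are shared by overlapping mates of
#' the same fragment.  Sequencing errors are applied i.i.d. per sequenced
#' base after conversion.  Mate 2 is the base complement of the bisulfite
#' strand, read from the far end of the fragment.
#'
#' @param genome Named character vector (one chromosome or more).
#' @param methylome Tibble from [simulate_methylome()].
#' @param config [sim_config()].
#' @return List with `reads1`, `reads2` (tibbles as from [read_fastq()]) and
#'   `truth` (per pair: `id`, `chrom`, `strand`, `start1`, `start2`,
#'   `insert_size`).
#' @export
simulate_read_pairs <- function(genome, methylome, config = sim_config()) {
  check_genome(genome)
  set.seed(config$seed + 1L)
  rl <- config$read_len
  n <- config$n_pairs
  conv <- config$conversion_rate / 100

  # one chromosome sampled proportionally to length
  lens <- nchar(genome)
  chrom_i <- sample.int(length(genome), n, replace = TRUE, prob = lens)
  ins <- config$insert_min +
    (sample.int(config$insert_max - config$insert_min + 1L, n,
                replace = TRUE) - 1L)
  f <- vapply(seq_len(n), function(i) {
    sample.int(lens[chrom_i[i]] - ins[i] + 1L, 1L)
  }, integer(1))
  is_watson <- runif(n) < 0.5

  # per-strand conversion probability of a sequenced T (or A on the
  # Watson representation of a Crick fragment): (1 - level) * conversion
  out1 <- character(n); out2 <- character(n)
  for (ch in unique(chrom_i)) {
    sel <- which(chrom_i == ch)
    g <- genome[[ch]]
    len <- lens[ch]
    gchars <- strsplit(g, "", fixed = TRUE)[[1]]
    mt <- dplyr::filter(methylome, .data$chrom == names(genome)[ch])
    pt_w <- rep(NA_real_, len) # P(converted) for Watson cytosines
    pt_c <- rep(NA_real_, len) # same for Crick cytosines, by Watson coord
    w <- mt$strand == "W"
    pt_w[mt$pos[w]] <- (1 - mt$level[w] / 100) * conv
    pt_c[mt$pos[!w]] <- (1 - mt$level[!w] / 100) * conv

    fs <- f[sel]; is_ <- ins[sel]; ns <- length(sel)
    # sequenced molecule region: the two read windows (merged when they
    # overlap); conversion is decided once per molecule position
    short <- is_ <= 2L * rl
    seg1_start <- fs
    seg1_len <- ifelse(short, is_, rl)
    seg2_start <- fs + is_ - rl
    seg2_len <- ifelse(short, 0L, rl)
    flat_len <- seg1_len + seg2_len
    idx <- c(sequence(seg1_len, from = seg1_start),
             sequence(seg2_len, from = seg2_start))
    ford <- c(rep(seq_len(ns), seg1_len), rep(seq_len(ns), seg2_len))
    o <- order(ford, idx)
    idx <- idx[o]
    chars <- gchars[idx]
    frag_w <- rep(is_watson[sel], flat_len)

    # bisulfite conversion on the originating strand
    cw <- which(frag_w & chars == "C")
    cw <- cw[runif(length(cw)) < pt_w[idx[cw]]]
    chars[cw] <- "T"
    gc_ <- which(!frag_w & chars == "G")
    gc_ <- gc_[runif(length(gc_)) < pt_c[idx[gc_]]]
    chars[gc_] <- "A"

    # window extraction: first rl and last rl flat positions per fragment
    ends <- cumsum(flat_len)
    starts0 <- ends - flat_len # 0-based block starts
    i1 <- rep(starts0, each = rl) + rep(seq_len(rl), ns)
    i2 <- rep(ends - rl, each = rl) + rep(seq_len(rl), ns)
    w1 <- paste_blocks(chars[i1], rl, ns)
    w2rc <- revcomp(paste_blocks(chars[i2], rl, ns))
    sw <- is_watson[sel]
    out1[sel] <- ifelse(sw, w1, w2rc)
    out2[sel] <- ifelse(sw, w2rc, w1)
  }

  # sequencing errors, i.i.d. per sequenced base, after conversion
  if (config$error_rate > 0) {
    out1 <- add_errors(out1, config$error_rate)
    out2 <- add_errors(out2, config$error_rate)
  }

  qual <- sim_qual_string(rl, config$qual_decay)
  ids <- sprintf("sim%07d", seq_len(n))
  reads1 <- tibble::tibble(id = ids, bases = out1, quals = qual, mate = 1L)
  reads2 <- tibble::tibble(id = ids, bases = out2, quals = qual, mate = 2L)
  truth <- tibble::tibble(
    id = ids,
    chrom = names(genome)[chrom_i],
    strand = ifelse(is_watson, "W", "C"),
    start1 = as.integer(ifelse(is_watson, f, f + ins - rl)),
    start2 = as.integer(ifelse(is_watson, f + ins - rl, f)),
    insert_size = as.integer(ins)
  )
  list(reads1 = reads1, reads2 = reads2, truth = truth)
}

# substitute bases uniformly among the other three at rate `e`
add_errors <- function(reads, e) {
  rl <- nchar(reads)
  total <- sum(rl)
  hit <- which(runif(total) < e)
  if (length(hit) == 0) return(reads)
  stopifnot(length(unique(rl)) == 1) # constant read length by construction
  w <- rl[1]
  ri <- (hit - 1L) %/% w + 1L
  pi <- (hit - 1L) %% w + 1L
  for (j in seq_along(hit)) {
    cur <- substr(reads[ri[j]], pi[j], pi[j])
    alt <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    substr(reads[ri[j]], pi[j], pi[j]) <- alt
  }
  reads
}

sim_qual_string <- function(rl, decay) {
  q <- pmax(2L, round(40 - decay * (seq_len(rl) - 1) / max(rl - 1, 1)))
  intToUtf8(q + 33L)
}

#' Score an alignment against the simulation truth
#'
#' Mappability is the percentage of simulated pairs retained by the aligner;
#' accuracy the percentage of retained pairs whose chromosome, both start
#' coordinates and strand of origin match the truth.
#'
#' @param records Alignment records tibble (from [bs_align()]).
#' @param truth Truth tibble from [simulate_read_pairs()].
#' @return One-row tibble with `mappability`, `accuracy`, `n_simulated`,
#'   `n_kept`, `n_correct`.
#' @export
evaluate_alignment <- function(records, truth) {
  kept <- records |>
    dplyr::select("read_id", "chrom", "start", "strand", "mate") |>
    tidyr::pivot_wider(names_from = "mate", values_from = "start",
                       names_prefix = "aln_start") |>
    dplyr::filter(!is.na(.data$aln_start1), !is.na(.data$aln_start2))
  if (!all(kept$read_id %in% truth$id)) {
    stop("alignment records carry read ids absent from the truth table",
         call. = FALSE)
  }
  j <- dplyr::inner_join(kept, truth, by = c(read_id = "id"),
                         suffix = c("", "_true"))
  correct <- j$chrom == j$chrom_true & j$strand == j$strand_true &
    j$aln_start1 == j$start1 & j$aln_start2 == j$start2
  tibble::tibble(
    mappability = 100 * nrow(j) / nrow(truth),
    accuracy = if (nrow(j) > 0) 100 * sum(correct) / nrow(j) else NA_real_,
    n_simulated = nrow(truth),
    n_kept = nrow(j),
    n_correct = sum(correct)
  )
}

#' Compare recovered methylation densities with the simulated truth
#'
#' @param calls Methylation calls tibble from the simulated sample.
#' @param methylome Truth tibble from [simulate_methylome()].
#' @return Tibble per context class: `true_level`, `estimated_md` (pooled),
#'   `n_sites`, `depth`.
#' @export
evaluate_md_recovery <- function(calls, methylome) {
  j <- dplyr::inner_join(calls, methylome,
                         by = c("chrom", "pos", "strand"),
                         suffix = c("", "_true"))
  j |>
    dplyr::group_by(context_class = .data$context_class) |>
    dplyr::summarise(
      true_level = mean(.data$level),
      depth = sum(.data$c_count + .data$t_count),
      estimated_md = ifelse(.data$depth > 0,
                            100 * sum(.data$c_count) / .data$depth, NA_real_),
      n_sites = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select("context_class", "true_level", "estimated_md",
                  "n_sites", "depth")
}
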