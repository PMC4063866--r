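#' DMR detection parameters
#'
#' Defaults follow the four-stage sliding-window design: 500-base windows
#' slid in 100-base increments, at least 5 valid CpG sites per window with
#' at least 5 reads each in both samples, extension until the region exceeds
#' 1000 bases, merging of same-direction regions within 1000 bases whose
#' pooled MDs differ by less than 10 percentage points within each sample,
#' Mann-Whitney seed threshold p < 0.01, chi-square region threshold
#' p <= 0.01, and p > 0.25 for calling a region unchanged.
#'
#' @param w Window length (bases).
#' @param s Slide increment (bases).
#' @param m Minimum valid CpG sites per window, required in both samples.
#' @param n Minimum reads covering a CpG for it to be valid.
#' @param k Maximum extension length (bases); the next window is tested only
#'   while the current region is at most `k` long, so a pre-merge region can
#'   reach `k + w`.
#' @param p_seed Mann-Whitney two-sided threshold for seed significance.
#' @param p_region Chi-square threshold for emitted DMRs.
#' @param p_unchanged Mann-Whitney threshold above which a region is called
#'   unchanged.
#' @param merge_dist Maximum gap for merging adjacent regions (bases).
#' @param md_diff_merge Maximum pooled-MD difference (percentage points,
#'   within the same sample) for merging.
#' @param merge_strands Pool Watson and Crick CpG counts per dinucleotide
#'   before testing (off by default: strand-separate sites are used, as the
#'   calls are emitted per strand).
#' @return A list of class `bsm_dmr_params`.
#' @export
dmr_params <- function(w = 500L, s = 100L, m = 5L, n = 5L, k = 1000L,
                       p_seed = 0.01, p_region = 0.01, p_unchanged = 0.25,
                       merge_dist = 1000L, md_diff_merge = 10,
                       merge_strands = FALSE) {
  stopifnot(w > 0, s > 0, m > 0, n > 0, k > 0, merge_dist > 0,
            md_diff_merge > 0,
            p_seed > 0, p_seed < 1, p_region > 0, p_region < 1,
            p_unchanged > 0, p_unchanged < 1)
  structure(
    list(w = as.integer(w), s = as.integer(s), m = as.integer(m),
         n = as.integer(n), k = as.integer(k), p_seed = p_seed,
         p_region = p_region, p_unchanged = p_unchanged,
         merge_dist = as.integer(merge_dist), md_diff_merge = md_diff_merge,
         merge_strands = isTRUE(merge_strands)),
    class = "bsm_dmr_params"
  )
}

# CpG calls of one sample, optionally strand-pooled per dinucleotide
# (the Crick cytosine of a CpG sits at Watson coordinate of the Watson C + 1)
cpg_sites <- function(calls, merge_strands) {
  x <- dplyr::filter(calls, .data$context_class == "CpG")
  if (!merge_strands) {
    return(dplyr::select(x, "chrom", "pos", "strand", "c_count", "t_count"))
  }
  x |>
    dplyr::mutate(pos = ifelse(.data$strand == "C", .data$pos - 1L, .data$pos),
                  strand = "*") |>
    dplyr::group_by(.data$chrom, .data$pos, .data$strand) |>
    dplyr::summarise(c_count = sum(.data$c_count),
                     t_count = sum(.data$t_count), .groups = "drop")
}

# joined per-CpG table for one chromosome: positions valid in BOTH samples
joined_valid_cpgs <- function(callsA, callsB, params) {
  a <- cpg_sites(callsA, params$merge_strands) |>
    dplyr::filter(.data$c_count + .data$t_count >= params$n)
  b <- cpg_sites(callsB, params$merge_strands) |>
    dplyr::filter(.data$c_count + .data$t_count >= params$n)
  dplyr::inner_join(a, b, by = c("chrom", "pos", "strand"),
                    suffix = c("_a", "_b")) |>
    dplyr::mutate(
      md_a = 100 * .data$c_count_a / (.data$c_count_a + .data$t_count_a),
      md_b = 100 * .data$c_count_b / (.data$c_count_b + .data$t_count_b)
    ) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Valid CpG sites of an interval
#'
#' A CpG site is valid when it is covered by at least `n` reads in both
#' samples; the same position (and strand) must qualify in both.
#'
#' @param callsA,callsB Methylation calls tibbles of the two samples.
#' @param chrom,start,end Interval (1-based inclusive).
#' @param params [dmr_params()] (supplies `n` and strand handling).
#' @return Tibble of valid sites, ascending by position, with per-sample
#'   counts and single-site MDs (`md_a`, `md_b`).
#' @export
valid_cpgs <- function(callsA, callsB, chrom, start, end,
                       params = dmr_params()) {
  joined_valid_cpgs(callsA, callsB, params) |>
    dplyr::filter(.data$chrom == !!chrom, .data$pos >= start,
                  .data$pos <= end)
}

#' Mann-Whitney U test with midranks
#'
#' U is computed from midranks.  When the two groups total at most 20
#' observations the two-sided p-value is exact: from the Wilcoxon
#' distribution when there are no ties, and by full enumeration of the
#' choose(n1+n2, n1) group assignments of the midranks when there are (both
#' agree in the tie-free case).  Larger samples use a normal approximation
#' with tie correction and continuity correction.  If every value is
#' identical the p-value is 1.
#'
#' @param xs,ys Numeric vectors (per-CpG methylation densities of the two
#'   samples in DMR calling).
#' @return List with `u` and `p`.
#' @export
mann_whitney_u <- function(xs, ys) {
  n1 <- length(xs); n2 <- length(ys)
  stopifnot(n1 > 0, n2 > 0)
  all_v <- c(xs, ys)
  r <- rank(all_v) # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(all_v)
  has_ties <- any(ties > 1)
  N <- n1 + n2
  if (!has_ties && N <= 20) {
    p <- if (u > n1 * n2 / 2) {
      2 * (1 - pwilcox(u - 1, n1, n2))
    } else {
      2 * pwilcox(u, n1, n2)
    }
    p <- min(1, p)
  } else if (N <= 20) {
    # exact permutation distribution of U under ties (midranks)
    combs <- utils::combn(N, n1)
    us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
  } else {
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(list(u = u, p = 1))
    z <- (abs(u - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- min(1, 2 * pnorm(-z))
  }
  list(u = u, p = p)
}

#' Chi-square test on pooled region counts
#'
#' 2x2 test (1 df, no continuity correction) of the proportion of sequenced
#' methylated cytosines over total sequenced cytosines between the two
#' samples, on the table \[\[C1, T1\], \[C2, T2\]\].  A zero marginal gives
#' chi2 = 0, p = 1.
#'
#' @param c1,t1,c2,t2 Pooled C and T counts of the two samples.
#' @return List with `chi2` and `p`.
#' @export
chi_square_region <- function(c1, t1, c2, t2) {
  # double arithmetic: pooled genome-scale counts overflow integers
  c1 <- as.numeric(c1); t1 <- as.numeric(t1)
  c2 <- as.numeric(c2); t2 <- as.numeric(t2)
  n <- c1 + t1 + c2 + t2
  r1 <- c1 + t1; r2 <- c2 + t2; k1 <- c1 + c2; k2 <- t1 + t2
  if (r1 == 0 || r2 == 0 || k1 == 0 || k2 == 0) {
    return(list(chi2 = 0, p = 1))
  }
  chi2 <- n * (c1 * t2 - t1 * c2)^2 / (r1 * r2 * k1 * k2)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

# window summary on a pre-joined valid-CpG table of one chromosome
window_sites <- function(vt, start, end) {
  vt[vt$pos >= start & vt$pos <= end, , drop = FALSE]
}

pooled_mds <- function(sites) {
  ca <- sum(sites$c_count_a); ta <- sum(sites$t_count_a)
  cb <- sum(sites$c_count_b); tb <- sum(sites$t_count_b)
  list(c1 = ca, t1 = ta, c2 = cb, t2 = tb,
       md1 = if (ca + ta > 0) 100 * ca / (ca + ta) else NA_real_,
       md2 = if (cb + tb > 0) 100 * cb / (cb + tb) else NA_real_)
}

# seed test of one window: list(sig, p, dir) on the valid sites it holds
window_test <- function(vt, start, end, params) {
  sites <- window_sites(vt, start, end)
  if (nrow(sites) < params$m) return(list(sig = FALSE, p = NA_real_, dir = 0L))
  mw <- mann_whitney_u(sites$md_a, sites$md_b)
  pm <- pooled_mds(sites)
  dir <- sign(pm$md2 - pm$md1)
  list(sig = mw$p < params$p_seed && dir != 0, p = mw$p, dir = dir)
}

#' Find the next seed window
#'
#' Returns the leftmost window `[x, x + w - 1]` with `x >= from_pos` and
#' `x` on the slide grid (`x` congruent to `from_pos` modulo `s`) holding at
#' least `m` valid CpG sites, or `NULL` when the chromosome is exhausted.
#'
#' @param callsA,callsB Methylation calls tibbles.
#' @param chrom Chromosome name.
#' @param from_pos Grid origin (1-based).
#' @param params [dmr_params()].
#' @return List with `chrom`, `start`, `end`, the per-site table `sites`,
#'   and the Mann-Whitney `mw_p`; or `NULL`.
#' @export
find_next_seed <- function(callsA, callsB, chrom, from_pos,
                           params = dmr_params()) {
  vt <- joined_valid_cpgs(callsA, callsB, params)
  vt <- vt[vt$chrom == chrom, , drop = FALSE]
  seed_scan(vt, from_pos, params)
}

# scan implementation on a pre-joined single-chromosome table
seed_scan <- function(vt, from_pos, params) {
  if (nrow(vt) == 0) return(NULL)
  maxpos <- max(vt$pos)
  if (from_pos > maxpos) return(NULL)
  starts <- seq.int(from_pos, maxpos, by = params$s)
  cnt <- findInterval(starts + params$w - 1L, vt$pos) -
    findInterval(starts - 1L, vt$pos)
  hit <- which(cnt >= params$m)
  if (length(hit) == 0) return(NULL)
  x <- starts[hit[1]]
  sites <- window_sites(vt, x, x + params$w - 1L)
  mw <- mann_whitney_u(sites$md_a, sites$md_b)
  list(chrom = vt$chrom[1], start = x, end = x + params$w - 1L,
       sites = sites, mw_p = mw$p)
}

#' Extend a differentially methylated seed region downstream
#'
#' Greedy rightward extension by whole windows: while the current region is
#' no longer than `k` bases, the adjacent downstream `w`-base window is
#' tested; if it is itself a differentially methylated seed window with the
#' same direction it is merged, otherwise extension stops.
#'
#' @param seed A seed as returned by [find_next_seed()] that passed the
#'   Mann-Whitney test.
#' @param callsA,callsB Methylation calls tibbles.
#' @param params [dmr_params()].
#' @return List with `chrom`, `start`, `end`, `dir`, and `mw_p` (the worst
#'   constituent window p-value).
#' @export
extend_seed <- function(seed, callsA, callsB, params = dmr_params()) {
  vt <- joined_valid_cpgs(callsA, callsB, params)
  vt <- vt[vt$chrom == seed$chrom, , drop = FALSE]
  extend_scan(seed, vt, params)
}

extend_scan <- function(seed, vt, params) {
  sites <- window_sites(vt, seed$start, seed$end)
  pm <- pooled_mds(sites)
  dir <- sign(pm$md2 - pm$md1)
  cur_start <- seed$start
  cur_end <- seed$end
  worst_p <- seed$mw_p
  repeat {
    if (cur_end - cur_start + 1L > params$k) break
    nxt <- window_test(vt, cur_end + 1L, cur_end + params$w, params)
    if (!nxt$sig || nxt$dir != dir) break
    cur_end <- cur_end + params$w
    worst_p <- max(worst_p, nxt$p)
  }
  list(chrom = seed$chrom, start = cur_start, end = cur_end, dir = dir,
       mw_p = worst_p)
}

#' Merge adjacent differentially methylated regions
#'
#' Consecutive regions are merged, left to right and transitively, when the
#' gap between them is at most `merge_dist`, their directions agree, and the
#' pooled MDs of the two regions differ by less than `md_diff_merge`
#' percentage points within sample A and within sample B.  Valid CpGs lying
#' in the bridged gap join the pooled counts of the merged region.
#'
#' @param regions Tibble with `chrom`, `start`, `end`, `dir`, `mw_p`
#'   (sorted, non-overlapping).
#' @param callsA,callsB Methylation calls tibbles.
#' @param params [dmr_params()].
#' @return Tibble of the merged regions with pooled counts and MDs.
#' @export
merge_adjacent <- function(regions, callsA, callsB, params = dmr_params()) {
  vt_all <- joined_valid_cpgs(callsA, callsB, params)
  out <- lapply(split(regions, regions$chrom), function(rg) {
    vt <- vt_all[vt_all$chrom == rg$chrom[1], , drop = FALSE]
    merge_scan(rg, vt, params)
  })
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$chrom, .data$start)
}

merge_scan <- function(rg, vt, params) {
  rg <- dplyr::arrange(rg, .data$start)
  acc <- NULL
  done <- list()
  summarise_region <- function(start, end, dir, mw_p) {
    pm <- pooled_mds(window_sites(vt, start, end))
    c(list(chrom = rg$chrom[1], start = start, end = end,
           dir = dir, mw_p = mw_p), pm)
  }
  for (i in seq_len(nrow(rg))) {
    nxt <- summarise_region(rg$start[i], rg$end[i], rg$dir[i], rg$mw_p[i])
    if (is.null(acc)) { acc <- nxt; next }
    gap <- nxt$start - acc$end - 1L
    same_dir <- nxt$dir == acc$dir
    close_md <- !is.na(acc$md1) && !is.na(nxt$md1) &&
      abs(acc$md1 - nxt$md1) < params$md_diff_merge &&
      abs(acc$md2 - nxt$md2) < params$md_diff_merge
    if (gap <= params$merge_dist && same_dir && close_md) {
      acc <- summarise_region(acc$start, nxt$end, acc$dir,
                              max(acc$mw_p, nxt$mw_p))
    } else {
      done[[length(done) + 1L]] <- acc
      acc <- nxt
    }
  }
  if (!is.null(acc)) done[[length(done) + 1L]] <- acc
  dplyr::bind_rows(lapply(done, tibble::as_tibble))
}

#' Call differentially methylated regions between two samples
#'
#' Per chromosome: slide a `w`-base window in `s`-base steps to find seed
#' windows with at least `m` valid CpGs (depth >= `n` in both samples); test
#' each seed's per-CpG MDs with the Mann-Whitney U test; extend significant
#' seeds by whole windows of consistent direction; merge nearby regions with
#' similar methylation profiles; and test each merged region's pooled C/T
#' counts with a chi-square test.  Regions with chi-square p <= `p_region`
#' are emitted.  Direction is `hyper` when sample 2 (B) is more methylated
#' than sample 1 (A), `hypo` otherwise.
#'
#' @param callsA,callsB Methylation calls tibbles of samples 1 (A) and 2 (B).
#' @param params [dmr_params()].
#' @return An object of class `bsm_dmr_result`; [tidy()] returns the DMR
#'   tibble (`chrom`, `start`, `end`, `direction`, `md1`, `md2`, `n_cpgs`,
#'   `c1`, `t1`, `c2`, `t2`, `mw_p`, `chi2`, `chi2_p`), [glance()] a one-row
#'   summary.
#' @export
call_dmrs <- function(callsA, callsB, params = dmr_params()) {
  vt_all <- joined_valid_cpgs(callsA, callsB, params)
  chroms <- unique(vt_all$chrom)
  all_regions <- list()

  for (ch in chroms) {
    vt <- vt_all[vt_all$chrom == ch, , drop = FALSE]
    from <- 1L
    repeat {
      seed <- seed_scan(vt, from, params)
      if (is.null(seed)) break
      if (seed$mw_p < params$p_seed &&
          sign(with(pooled_mds(seed$sites), md2 - md1)) != 0) {
        region <- extend_scan(seed, vt, params)
        all_regions[[length(all_regions) + 1L]] <-
          tibble::tibble(chrom = ch, start = region$start, end = region$end,
                         dir = region$dir, mw_p = region$mw_p)
        from <- region$end + params$s
      } else {
        from <- seed$start + params$s
      }
    }
  }

  if (length(all_regions) == 0) {
    dmrs <- empty_dmr_tbl()
  } else {
    merged <- merge_adjacent(dplyr::bind_rows(all_regions),
                             callsA, callsB, params)
    dmrs <- merged |>
      dplyr::rowwise() |>
      dplyr::mutate(
        n_cpgs = nrow(window_sites(
          vt_all[vt_all$chrom == .data$chrom, , drop = FALSE],
          .data$start, .data$end)),
        chi2 = chi_square_region(.data$c1, .data$t1,
                                 .data$c2, .data$t2)$chi2,
        chi2_p = chi_square_region(.data$c1, .data$t1,
                                   .data$c2, .data$t2)$p
      ) |>
      dplyr::ungroup() |>
      dplyr::filter(.data$chi2_p <= params$p_region,
                    .data$md1 != .data$md2) |>
      dplyr::mutate(direction = ifelse(.data$md2 > .data$md1,
                                       "hyper", "hypo")) |>
      dplyr::select("chrom", "start", "end", "direction", "md1", "md2",
                    "n_cpgs", "c1", "t1", "c2", "t2", "mw_p", "chi2",
                    "chi2_p") |>
      dplyr::arrange(.data$chrom, .data$start)
  }

  structure(list(dmrs = dmrs, params = params), class = "bsm_dmr_result")
}

empty_dmr_tbl <- function() {
  tibble::tibble(
    chrom = character(0), start = integer(0), end = integer(0),
    direction = character(0), md1 = numeric(0), md2 = numeric(0),
    n_cpgs = integer(0), c1 = integer(0), t1 = integer(0),
    c2 = integer(0), t2 = integer(0), mw_p = numeric(0),
    chi2 = numeric(0), chi2_p = numeric(0)
  )
}

#' Classify a region as methylation-unchanged
#'
#' A region is unchanged when the Mann-Whitney two-sided p-value over its
#' valid CpG MDs exceeds `p_unchanged` (default 0.25).  Regions with fewer
#' than `m` valid CpGs return `NA`.
#'
#' @param callsA,callsB Methylation calls tibbles.
#' @param chrom,start,end The region.
#' @param params [dmr_params()].
#' @return `TRUE`, `FALSE`, or `NA` when the region is untestable.
#' @export
classify_unchanged <- function(callsA, callsB, chrom, start, end,
                               params = dmr_params()) {
  sites <- valid_cpgs(callsA, callsB, chrom, start, end, params)
  if (nrow(sites) < params$m) return(NA)
  mann_whitney_u(sites$md_a, sites$md_b)$p > params$p_unchanged
}

#' @export
print.bsm_dmr_result <- function(x, ...) {
  cat("<bsm_dmr_result> ", nrow(x$dmrs), " DMRs (",
      sum(x$dmrs$direction == "hyper"), " hyper, ",
      sum(x$dmrs$direction == "hypo"), " hypo)\n", sep = "")
  invisible(x)
}

#' @rdname call_dmrs
#' @param x A `bsm_dmr_result`.
#' @param ... Unused.
#' @export
tidy.bsm_dmr_result <- function(x, ...) x$dmrs

#' @rdname call_dmrs
#' @export
glance.bsm_dmr_result <- function(x, ...) {
  d <- x$dmrs
  tibble::tibble(
    n_dmrs = nrow(d),
    n_hyper = sum(d$direction == "hyper"),
    n_hypo = sum(d$direction == "hypo"),
    total_bases = sum(d$end - d$start + 1),
    median_length = if (nrow(d)) stats::median(d$end - d$start + 1) else NA_real_
  )
}

#' Export DMRs as BED6 for genome browsers
#'
#' @param dmrs DMR tibble from [tidy()] on a [call_dmrs()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  bed <- tibble::tibble(
    chrom = dmrs$chrom,
    start = dmrs$start - 1L, # BED is 0-based half-open
    end = dmrs$end,
    name = paste0(dmrs$direction, "_", seq_len(nrow(dmrs))),
    score = pmin(1000L, as.integer(round(-10 * log10(
      pmax(dmrs$chi2_p, 1e-100))))),
    strand = "."
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
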