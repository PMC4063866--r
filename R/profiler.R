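#' Genome-wide methylation profile in fixed windows
#'
#' Tiles each chromosome in non-overlapping windows (default 100 kb) from
#' position 1 and reports the pooled MD per window and strand, the unit of
#' the genome-wide scatter profile (Watson dots up, Crick triangles down in
#' [plot_window_profile()]).
#'
#' @param calls Methylation calls tibble.
#' @param window_len Window length in bases (default 100,000).
#' @param context Optional context-class filter, e.g. `"CpG"`.
#' @return Tibble with `chrom`, `window_start`, `strand`, `md`, `n_sites`,
#'   `depth`.
#' @export
fixed_window_profile <- function(calls, window_len = 100000L,
                                 context = NULL) {
  x <- calls
  if (!is.null(context)) x <- dplyr::filter(x, .data$context_class %in% !!context)
  x |>
    dplyr::mutate(window_start =
                    (.data$pos - 1L) %/% as.integer(window_len) *
                    as.integer(window_len) + 1L) |>
    dplyr::group_by(.data$chrom, .data$window_start, .data$strand) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      depth = sum(.data$c_count + .data$t_count),
      md = ifelse(.data$depth > 0, 100 * sum(.data$c_count) / .data$depth,
                  NA_real_),
      .groups = "drop"
    ) |>
    dplyr::select("chrom", "window_start", "strand", "md", "n_sites",
                  "depth") |>
    dplyr::arrange(.data$chrom, .data$window_start, .data$strand)
}

#' Methylation spectrum over the 16 trinucleotide contexts
#'
#' Pooled MD per context (CAA, CAC, ..., CTT) and, per context class, the
#' fractional methylated C: the proportion of sequenced methylated cytosines
#' in that class over all sequenced methylated cytosines.
#'
#' @param calls Methylation calls tibble.
#' @return List with `contexts` (16-row tibble: `context3`, `context_class`,
#'   `md`, `n_sites`, `depth`) and `class_fractions` (`context_class`,
#'   `methylated_c`, `fraction`; fractions missing when no methylated C was
#'   sequenced anywhere).
#' @export
context_spectrum <- function(calls) {
  all16 <- paste0("C", rep(c("A", "C", "G", "T"), each = 4),
                  rep(c("A", "C", "G", "T"), times = 4))
  cls16 <- ifelse(substr(all16, 2, 2) == "G", "CpG",
                  ifelse(substr(all16, 3, 3) == "G", "CHG", "CHH"))
  per_ctx <- calls |>
    dplyr::filter(.data$context3 %in% all16) |>
    dplyr::group_by(.data$context3) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      depth = sum(.data$c_count + .data$t_count),
      md = ifelse(.data$depth > 0,
                  100 * sum(.data$c_count) / .data$depth, NA_real_),
      .groups = "drop"
    )
  contexts <- tibble::tibble(context3 = all16, context_class = cls16) |>
    dplyr::left_join(per_ctx, by = "context3") |>
    dplyr::mutate(n_sites = tidyr::replace_na(.data$n_sites, 0L),
                  depth = tidyr::replace_na(.data$depth, 0L))

  total_mc <- sum(calls$c_count)
  class_fractions <- calls |>
    dplyr::group_by(.data$context_class) |>
    dplyr::summarise(methylated_c = sum(.data$c_count), .groups = "drop") |>
    dplyr::right_join(
      tibble::tibble(context_class = c("CpG", "CHG", "CHH")),
      by = "context_class"
    ) |>
    dplyr::mutate(
      methylated_c = tidyr::replace_na(.data$methylated_c, 0L),
      fraction = if (total_mc > 0) .data$methylated_c / total_mc
                 else NA_real_
    )
  list(contexts = contexts, class_fractions = class_fractions)
}

#' Methylation density of regions of interest
#'
#' Pooled MD per region; with `sites = TRUE` the per-cytosine table of the
#' regions is returned instead (box-plot-ready long format by label).
#' Regions sharing a label (e.g. all introns) still report one row each;
#' aggregate by `label` downstream if needed.
#'
#' @param calls Methylation calls tibble.
#' @param regions Regions tibble (`chrom`, `start`, `end`, `label`), e.g.
#'   from [read_bed_regions()].
#' @param sites Return the per-cytosine long table instead.
#' @param context Optional context-class filter.
#' @return Region-level tibble (`label`, `chrom`, `start`, `end`, `md`,
#'   `n_sites`, `depth`) or, with `sites = TRUE`, per-site rows with their
#'   region label and single-site MD.
#' @export
region_profile <- function(calls, regions, sites = FALSE, context = NULL) {
  x <- calls
  if (!is.null(context)) x <- dplyr::filter(x, .data$context_class %in% !!context)
  per_region <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    sub <- dplyr::filter(x, .data$chrom == r$chrom, .data$pos >= r$start,
                         .data$pos <= r$end)
    if (sites) {
      return(dplyr::mutate(
        sub, label = r$label,
        md = 100 * .data$c_count / (.data$c_count + .data$t_count)
      ))
    }
    depth <- sum(sub$c_count + sub$t_count)
    tibble::tibble(
      label = r$label, chrom = r$chrom, start = r$start, end = r$end,
      md = if (depth > 0) 100 * sum(sub$c_count) / depth else NA_real_,
      n_sites = nrow(sub), depth = depth
    )
  })
  dplyr::bind_rows(per_region)
}

#' Annotate DMRs with their closest gene and promoter overlap
#'
#' The transcription start site (TSS) of a `+` gene is its start, of a `-`
#' gene its end.  Each DMR gains the closest gene (distance from the DMR
#' interval to the TSS; ties broken by lexicographically smallest gene
#' name) and a `promoter` flag set when the DMR overlaps the 2-kb window
#' upstream of that gene's TSS.
#'
#' @param dmrs DMR tibble.
#' @param genes Genes tibble (`chrom`, `start`, `end`, `label`, `strand`)
#'   from [read_bed_regions()].
#' @param tss_window Upstream window size in bases (default 2000).
#' @return The DMR tibble with `gene`, `dist_tss`, `promoter` columns.
#' @export
annotate_dmrs <- function(dmrs, genes, tss_window = 2000L) {
  genes <- dplyr::mutate(
    genes,
    tss = ifelse(.data$strand == "-", .data$end, .data$start),
    prom_start = ifelse(.data$strand == "-", .data$tss + 1L,
                        .data$tss - as.integer(tss_window)),
    prom_end = ifelse(.data$strand == "-",
                      .data$tss + as.integer(tss_window), .data$tss - 1L)
  )
  ann <- lapply(seq_len(nrow(dmrs)), function(i) {
    d <- dmrs[i, ]
    g <- dplyr::filter(genes, .data$chrom == d$chrom)
    if (nrow(g) == 0) {
      return(tibble::tibble(gene = NA_character_, dist_tss = NA_integer_,
                            promoter = NA))
    }
    dist <- ifelse(g$tss < d$start, d$start - g$tss,
                   ifelse(g$tss > d$end, g$tss - d$end, 0L))
    best <- g[order(dist, g$label), ][1, ]
    bdist <- min(dist)
    tibble::tibble(
      gene = best$label,
      dist_tss = as.integer(bdist),
      promoter = d$start <= best$prom_end & d$end >= best$prom_start
    )
  })
  dplyr::bind_cols(dmrs, dplyr::bind_rows(ann))
}

#' Concordance between sequencing MDs and array beta values
#'
#' Watson and Crick CpG counts are pooled per CpG dinucleotide (keyed by the
#' Watson C position), sites with pooled depth below `min_depth` are
#' dropped, MD is rescaled to a fraction, and the Pearson correlation with
#' the array beta values over the joined loci is reported.
#'
#' @param calls Methylation calls tibble.
#' @param beta_table Tibble from [read_beta_table()] (`chrom`, `pos` of the
#'   Watson C of each array CpG, `beta` in \[0, 1\]).
#' @param min_depth Minimum pooled reads per locus (default 10).
#' @return List with `pearson_r`, `n_loci` and the joined `data` tibble
#'   (`chrom`, `pos`, `depth`, `md_fraction`, `beta`).  `pearson_r` is
#'   missing with fewer than 3 joined loci.
#' @export
correlate_with_array <- function(calls, beta_table, min_depth = 10L) {
  pooled <- calls |>
    dplyr::filter(.data$context_class == "CpG") |>
    dplyr::mutate(pos = ifelse(.data$strand == "C", .data$pos - 1L,
                               .data$pos)) |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(c_count = sum(.data$c_count),
                     t_count = sum(.data$t_count), .groups = "drop") |>
    dplyr::mutate(depth = .data$c_count + .data$t_count) |>
    dplyr::filter(.data$depth >= min_depth)
  joined <- dplyr::inner_join(pooled, beta_table, by = c("chrom", "pos")) |>
    dplyr::mutate(md_fraction = .data$c_count / .data$depth) |>
    dplyr::select("chrom", "pos", "depth", "md_fraction", "beta")
  r <- if (nrow(joined) >= 3) {
    cor(joined$md_fraction, joined$beta, method = "pearson")
  } else {
    NA_real_
  }
  list(pearson_r = r, n_loci = nrow(joined), data = joined)
}

#' Array-derived gold-standard region sets
#'
#' Mean beta per 500-bp window per sample (windows tiled from position 1;
#' windows lacking probes in either sample are dropped).  With
#' delta = mean(B) - mean(A): delta > 0.25 is hypermethylated, delta < -0.25
#' hypomethylated, |delta| <= 0.03 unchanged; anything between is
#' unassigned.
#'
#' @param betaA,betaB Beta tables of the two samples.
#' @param window Window length in bases (default 500).
#' @param diff_changed Mean-beta difference defining hyper/hypo (default
#'   0.25).
#' @param diff_unchanged Mean-beta difference bounding unchanged regions
#'   (default 0.03).
#' @return List of class `bsm_gold` with tibbles `hyper`, `hypo`,
#'   `unchanged` (`chrom`, `start`, `end`, `mean_a`, `mean_b`, `delta`).
#' @export
gold_standard_regions <- function(betaA, betaB, window = 500L,
                                  diff_changed = 0.25,
                                  diff_unchanged = 0.03) {
  win_means <- function(b) {
    b |>
      dplyr::mutate(start = (.data$pos - 1L) %/% as.integer(window) *
                      as.integer(window) + 1L) |>
      dplyr::group_by(.data$chrom, .data$start) |>
      dplyr::summarise(mean_beta = mean(.data$beta), .groups = "drop")
  }
  joined <- dplyr::inner_join(win_means(betaA), win_means(betaB),
                              by = c("chrom", "start"),
                              suffix = c("_a", "_b")) |>
    dplyr::mutate(
      end = .data$start + as.integer(window) - 1L,
      delta = .data$mean_beta_b - .data$mean_beta_a
    ) |>
    dplyr::select("chrom", "start", "end", mean_a = "mean_beta_a",
                  mean_b = "mean_beta_b", "delta")
  structure(
    list(
      hyper = dplyr::filter(joined, .data$delta > diff_changed),
      hypo = dplyr::filter(joined, .data$delta < -diff_changed),
      unchanged = dplyr::filter(joined, abs(.data$delta) <= diff_unchanged)
    ),
    class = "bsm_gold"
  )
}

# does any row of `query` overlap [start, end] on chrom by >= 1 bp?
overlaps_any <- function(chrom, start, end, query) {
  any(query$chrom == chrom & query$start <= end & query$end >= start)
}

#' Detection proportions against the gold standard
#'
#' For the hyper and hypo gold classes: the fraction of gold regions
#' overlapped (by at least 1 bp) by a DMR call of concordant direction.  For
#' the unchanged class: the fraction overlapped by a region of
#' `unchanged_regions` (regions classified unchanged via
#' [classify_unchanged()]).
#'
#' @param dmrs DMR tibble (with `direction`).
#' @param unchanged_regions Tibble of regions classified unchanged
#'   (`chrom`, `start`, `end`).
#' @param gold A `bsm_gold` from [gold_standard_regions()].
#' @return Tibble with `class`, `n_gold`, `n_detected`, `proportion`
#'   (missing for an empty gold class).
#' @export
evaluate_dmr_calls <- function(dmrs, unchanged_regions, gold) {
  one <- function(gold_tbl, query) {
    n <- nrow(gold_tbl)
    det <- if (n == 0) 0L else sum(vapply(
      seq_len(n),
      function(i) overlaps_any(gold_tbl$chrom[i], gold_tbl$start[i],
                               gold_tbl$end[i], query),
      logical(1)
    ))
    tibble::tibble(n_gold = n, n_detected = det,
                   proportion = if (n > 0) det / n else NA_real_)
  }
  dplyr::bind_rows(
    dplyr::mutate(one(gold$hyper,
                      dplyr::filter(dmrs, .data$direction == "hyper")),
                  class = "hyper"),
    dplyr::mutate(one(gold$hypo,
                      dplyr::filter(dmrs, .data$direction == "hypo")),
                  class = "hypo"),
    dplyr::mutate(one(gold$unchanged, unchanged_regions),
                  class = "unchanged")
  ) |>
    dplyr::relocate("class")
}
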