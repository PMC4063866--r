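#' Basic statistics of a bisulfite sequencing run
#'
#' Collects the summary reported for every sample: fragment counts and
#' filter losses, mappability (percent of fragments mapped), duplication
#' rate (percent of mapped fragments removed as duplicates), percent of
#' genomic cytosines (and CpG cytosines) covered by at least `min_cov`
#' reads, mean sequencing depth over cytosine sites, pooled MD per context
#' class, bisulfite conversion rate from an unmethylated spike-in when one
#' is configured, per-cycle base composition and the insert size
#' distribution.
#'
#' @param alignment A `bsm_alignment` from [bs_align()] (supplies the
#'   alignment stats and the kept records).
#' @param calls Methylation calls tibble from [call_methylation()].
#' @param genome Named character vector from [read_fasta()].
#' @param reads Optional raw reads tibble (pre-trimming) for the per-cycle
#'   base composition plot.
#' @param spike_chrom Optional name of the unmethylated spike chromosome.
#' @param min_cov Coverage threshold for "percent covered" (default 1).
#' @return A list of class `bsm_run_stats`.
#' @export
compute_run_stats <- function(alignment, calls, genome, reads = NULL,
                              spike_chrom = NULL, min_cov = 1L) {
  check_genome(genome)
  s <- alignment$stats

  # genome-wide cytosine site totals on both strands
  n_c_watson <- sum(stringr::str_count(genome, "C"))
  n_c_crick <- sum(stringr::str_count(genome, "G"))
  n_cyt <- n_c_watson + n_c_crick
  n_cpg <- 2L * sum(stringr::str_count(genome, "CG"))

  covered <- dplyr::filter(calls, .data$c_count + .data$t_count >= min_cov)
  covered_cpg <- dplyr::filter(covered, .data$context_class == "CpG")

  md_by_class <- calls |>
    dplyr::group_by(.data$context_class) |>
    dplyr::summarise(
      depth = sum(.data$c_count + .data$t_count),
      md = ifelse(.data$depth > 0,
                  100 * sum(.data$c_count) / .data$depth, NA_real_),
      .groups = "drop"
    )

  conv <- if (!is.null(spike_chrom)) {
    conversion_rate(calls, spike_chrom)$conversion_rate
  } else {
    NA_real_
  }

  structure(list(
    total_fragments = s$total_fragments,
    trimmed_discarded = s$trimmed_discarded,
    mapped = s$mapped,
    unique = s$unique,
    both_strand_discarded = s$both_strand_discarded,
    duplicates_removed = s$duplicates_removed,
    mappability = ifelse(s$total_fragments > 0,
                         100 * s$mapped / s$total_fragments, NA_real_),
    dup_rate = ifelse(s$mapped > 0,
                      100 * s$duplicates_removed / s$mapped, NA_real_),
    pct_cytosines_covered = ifelse(n_cyt > 0,
                                   100 * nrow(covered) / n_cyt, NA_real_),
    pct_cpg_covered = ifelse(n_cpg > 0,
                             100 * nrow(covered_cpg) / n_cpg, NA_real_),
    mean_depth = ifelse(n_cyt > 0,
                        sum(calls$c_count + calls$t_count) / n_cyt, NA_real_),
    md_by_class = md_by_class,
    conversion_rate = conv,
    per_cycle_base_freq = if (!is.null(reads)) per_cycle_composition(reads)
                          else NULL,
    insert_histogram = insert_size_distribution(alignment$records)
  ), class = "bsm_run_stats")
}

#' @export
print.bsm_run_stats <- function(x, ...) {
  cat("<bsm_run_stats>\n")
  cat(sprintf("  fragments: %d, mappability %.2f%%, dup rate %.2f%%\n",
              x$total_fragments, x$mappability, x$dup_rate))
  cat(sprintf("  cytosines covered: %.2f%% (CpG: %.2f%%), mean depth %.2fx\n",
              x$pct_cytosines_covered, x$pct_cpg_covered, x$mean_depth))
  invisible(x)
}

#' Base composition per sequencing cycle
#'
#' Fraction of A/C/G/T among non-N bases at each cycle.  In bisulfite data a
#' high T and low C fraction is expected; deviation flags incomplete
#' conversion or sequencing problems.
#'
#' @param reads Reads tibble.
#' @return Tibble with `cycle`, `fA`, `fC`, `fG`, `fT` (each cycle's
#'   fractions sum to 1).
#' @export
per_cycle_composition <- function(reads) {
  stopifnot(nrow(reads) > 0)
  chars <- strsplit(reads$bases, "", fixed = TRUE)
  flat <- unlist(chars, use.names = FALSE)
  cyc <- sequence(lengths(chars))
  keep <- flat != "N"
  tab <- table(cycle = cyc[keep],
               base = factor(flat[keep], levels = c("A", "C", "G", "T")))
  tot <- rowSums(tab)
  tibble::tibble(
    cycle = as.integer(rownames(tab)),
    fA = unname(tab[, "A"] / tot), fC = unname(tab[, "C"] / tot),
    fG = unname(tab[, "G"] / tot), fT = unname(tab[, "T"] / tot)
  )
}

#' Insert size distribution of kept pairs
#'
#' @param records Alignment records tibble; single-end data yields an empty
#'   histogram with a warning.
#' @return Tibble with `insert_size` and `count` (fragments, not reads).
#' @export
insert_size_distribution <- function(records) {
  frag <- records |>
    dplyr::filter(!is.na(.data$insert_size)) |>
    dplyr::distinct(.data$read_id, .data$insert_size)
  if (nrow(frag) == 0) {
    if (nrow(records) > 0) {
      warning("no paired records: insert size histogram is empty",
              call. = FALSE)
    }
    return(tibble::tibble(insert_size = integer(0), count = integer(0)))
  }
  frag |>
    dplyr::count(.data$insert_size, name = "count") |>
    dplyr::arrange(.data$insert_size)
}

# embed a ggplot as a base64 PNG <img> tag
plot_to_img <- function(p, width = 640, height = 400) {
  f <- tempfile(fileext = ".png")
  on.exit(unlink(f), add = TRUE)
  grDevices::png(f, width = width, height = height, res = 96)
  print(p)
  grDevices::dev.off()
  b64 <- jsonlite::base64_enc(readBin(f, "raw", file.info(f)$size))
  sprintf('<img src="data:image/png;base64,%s" width="%d" height="%d"/>',
          gsub("\n", "", b64), width, height)
}

fmt_stat <- function(x, digits = 2) {
  if (is.null(x) || length(x) == 0 || is.na(x)) "n/a"
  else format(round(x, digits), nsmall = 0, big.mark = ",")
}

#' Render the QC report as a self-contained HTML file
#'
#' One page holding the basic-statistics table, the per-cycle base
#' composition plot and the insert size plot (both embedded as base64 PNG),
#' with intra-page navigation links.  Missing statistics render as "n/a";
#' an empty insert histogram omits the plot and renders a note.
#'
#' @param stats A `bsm_run_stats` from [compute_run_stats()].
#' @param out_path Output HTML path.
#' @param title Report title.
#' @return `out_path`, invisibly.
#' @export
render_html <- function(stats, out_path, title = "Bisulfite sequencing QC") {
  rows <- c(
    "Total fragments" = fmt_stat(stats$total_fragments, 0),
    "Discarded by trimming" = fmt_stat(stats$trimmed_discarded, 0),
    "Mapped fragments" = fmt_stat(stats$mapped, 0),
    "Uniquely aligned" = fmt_stat(stats$unique, 0),
    "Both-strand discarded" = fmt_stat(stats$both_strand_discarded, 0),
    "Duplicates removed" = fmt_stat(stats$duplicates_removed, 0),
    "Mappability (%)" = fmt_stat(stats$mappability),
    "Duplication rate (%)" = fmt_stat(stats$dup_rate),
    "Cytosines covered (%)" = fmt_stat(stats$pct_cytosines_covered),
    "CpG cytosines covered (%)" = fmt_stat(stats$pct_cpg_covered),
    "Mean depth (fold)" = fmt_stat(stats$mean_depth),
    "Bisulfite conversion rate (%)" = fmt_stat(stats$conversion_rate)
  )
  md_rows <- stats$md_by_class
  md_html <- paste0(
    sprintf("<tr><td>MD %s (%%)</td><td>%s</td></tr>",
            md_rows$context_class, vapply(md_rows$md, fmt_stat, "")),
    collapse = "\n"
  )
  table_html <- paste0(
    sprintf("<tr><td>%s</td><td>%s</td></tr>", names(rows), rows),
    collapse = "\n"
  )

  cycle_html <- if (!is.null(stats$per_cycle_base_freq)) {
    plot_to_img(plot_cycle_composition(stats$per_cycle_base_freq))
  } else {
    "<p>Per-cycle base composition unavailable (raw reads not supplied).</p>"
  }
  insert_html <- if (nrow(stats$insert_histogram) > 0) {
    plot_to_img(plot_insert_sizes(stats$insert_histogram))
  } else {
    "<p>No paired-end insert sizes available.</p>"
  }

  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset='utf-8'><title>", title,
    "</title>\n<style>body{font-family:sans-serif;max-width:60em;margin:auto}",
    "table{border-collapse:collapse}td{border:1px solid #999;padding:4px 8px}",
    "</style></head>\n<body>\n<h1>", title, "</h1>\n",
    "<p><a href='#stats'>Basic statistics</a> | ",
    "<a href='#cycles'>Base composition</a> | ",
    "<a href='#inserts'>Insert sizes</a></p>\n",
    "<h2 id='stats'>Basic statistics</h2>\n<table>\n", table_html, "\n",
    md_html, "\n</table>\n",
    "<h2 id='cycles'>Base composition per cycle</h2>\n", cycle_html, "\n",
    "<h2 id='inserts'>Insert size distribution</h2>\n", insert_html, "\n",
    "</body></html>\n"
  )
  writeLines(html, out_path)
  invisible(out_path)
}
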