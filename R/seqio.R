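#' Read a reference genome from FASTA
#'
#' Sequences are uppercased on read; only the alphabet A, C, G, T, N is
#' accepted.  The returned vector holds the Watson strand; the Crick strand
#' is its reverse complement.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of chromosome sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(ss) == 0) stop("no sequences in ", path, call. = FALSE)
  nm <- sub("\\s.*$", "", names(ss))
  if (any(!nzchar(nm))) stop("empty sequence name in ", path, call. = FALSE)
  if (anyDuplicated(nm)) {
    stop("duplicate sequence name in ", path, ": ",
         nm[duplicated(nm)][1], call. = FALSE)
  }
  g <- toupper(as.character(ss))
  names(g) <- nm
  check_genome(g)
  g
}

#' Read bisulfite sequencing reads from FASTQ
#'
#' Quality scores are Phred+33 encoded and kept as the encoded string in the
#' `quals` column (use [phred_scores()] to decode).  When `path2` is given,
#' the two files are read in lockstep and reads are tagged `mate = 1` / `2`.
#'
#' @param path FASTQ file (read 1 for paired-end data).
#' @param path2 Optional FASTQ file with the second mates.
#' @return A tibble with columns `id`, `bases`, `quals`, `mate`.
#' @export
read_fastq <- function(path, path2 = NULL) {
  one <- function(p, mate) {
    # Biostrings warns about dropping (empty) metadata columns on every read
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(p, quality.scoring = "phred"),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    n_lines <- length(readLines(p))
    if (n_lines %% 4L != 0L || n_lines %/% 4L != length(x)) {
      stop("truncated or malformed 4-line FASTQ record in ", p, call. = FALSE)
    }
    tibble::tibble(
      id = as.character(names(x)),
      bases = unname(as.character(x)),
      quals = unname(as.character(Biostrings::quality(x))),
      mate = mate
    )
  }
  if (is.null(path2)) return(one(path, NA_integer_))
  r1 <- one(path, 1L)
  r2 <- one(path2, 2L)
  if (nrow(r1) != nrow(r2)) {
    stop("paired FASTQ files differ in record count", call. = FALSE)
  }
  dplyr::bind_rows(r1, r2)
}

#' Decode Phred+33 quality strings
#'
#' @param quals Character vector of encoded quality strings.
#' @return A list of integer vectors of per-base Phred scores.
#' @export
phred_scores <- function(quals) lapply(quals, phred_decode)

#' Write reads to FASTQ
#'
#' Writes plain 4-line records (`@id`, bases, `+`, Phred+33 qualities), so a
#' [read_fastq()] / `write_fastq()` round trip is byte-identical for
#' well-formed input.
#'
#' @param reads Tibble as returned by [read_fastq()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$bases) == nchar(reads$quals)))
  out <- as.vector(rbind(paste0("@", reads$id), reads$bases, "+", reads$quals))
  writeLines(out, path)
  invisible(path)
}

#' Write alignment records to a `.bsalign` file
#'
#' Tab-separated with one line per aligned read: `read_id`, `chrom`, `start`
#' (1-based leftmost Watson coordinate), `strand_of_origin` (`W`/`C`),
#' `mismatches`, `original_bases`, `quals`, `mate_start`, `insert_size`.
#' Mate-tagged reads get a `/1` or `/2` suffix on `read_id`.  Rows are
#' ordered by (chrom, start, read_id); missing fields are written as `.`.
#'
#' @param records Alignment records tibble (see [bs_align()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bsalign <- function(records, path) {
  out <- records |>
    dplyr::mutate(
      read_id = ifelse(is.na(.data$mate), .data$read_id,
                       paste0(.data$read_id, "/", .data$mate))
    ) |>
    dplyr::select(
      read_id = "read_id", chrom = "chrom", start = "start",
      strand_of_origin = "strand", mismatches = "mismatches",
      original_bases = "bases", quals = "quals",
      mate_start = "mate_start", insert_size = "insert_size"
    ) |>
    dplyr::arrange(.data$chrom, .data$start, .data$read_id)
  readr::write_tsv(out, path, na = ".")
  invisible(path)
}

#' Read a `.bsalign` file back into alignment records
#'
#' @param path Path written by [write_bsalign()].
#' @return Alignment records tibble.
#' @export
read_bsalign <- function(path) {
  x <- readr::read_tsv(
    path, na = ".",
    col_types = readr::cols(
      read_id = readr::col_character(), chrom = readr::col_character(),
      start = readr::col_integer(), strand_of_origin = readr::col_character(),
      mismatches = readr::col_integer(),
      original_bases = readr::col_character(), quals = readr::col_character(),
      mate_start = readr::col_integer(), insert_size = readr::col_integer()
    )
  )
  has_mate <- grepl("/[12]$", x$read_id)
  tibble::tibble(
    read_id = ifelse(has_mate, sub("/[12]$", "", x$read_id), x$read_id),
    chrom = x$chrom, start = x$start, strand = x$strand_of_origin,
    mismatches = x$mismatches, bases = x$original_bases, quals = x$quals,
    mate = ifelse(has_mate,
                  as.integer(sub("^.*/", "", x$read_id)), NA_integer_),
    mate_start = x$mate_start, insert_size = x$insert_size
  )
}

#' Write per-cytosine methylation calls, one file per strand
#'
#' Both files are always written (possibly with zero data rows), each a TSV
#' with columns `chrom`, `pos`, `context3`, `context_class`, `c_count`,
#' `t_count`, sorted by chromosome and position.  Crick-strand cytosines are
#' reported at the Watson coordinate of the paired G, so both files share
#' one 1-based coordinate axis.
#'
#' @param calls Methylation calls tibble (see [call_methylation()]).
#' @param path_watson,path_crick Output paths for the two strands.
#' @return The two paths, invisibly.
#' @export
write_methcalls <- function(calls, path_watson, path_crick) {
  one <- function(str, path) {
    calls |>
      dplyr::filter(.data$strand == str) |>
      dplyr::select("chrom", "pos", "context3", "context_class",
                    "c_count", "t_count") |>
      dplyr::arrange(.data$chrom, .data$pos) |>
      readr::write_tsv(path)
  }
  one("W", path_watson)
  one("C", path_crick)
  invisible(c(path_watson, path_crick))
}

#' Read per-strand methylation call files
#'
#' @param path_watson,path_crick Paths written by [write_methcalls()].
#' @return Calls tibble with a `strand` column (`W`/`C`).
#' @export
read_methcalls <- function(path_watson, path_crick) {
  ct <- readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    context3 = readr::col_character(), context_class = readr::col_character(),
    c_count = readr::col_integer(), t_count = readr::col_integer()
  )
  w <- readr::read_tsv(path_watson, col_types = ct)
  c_ <- readr::read_tsv(path_crick, col_types = ct)
  dplyr::bind_rows(
    dplyr::mutate(w, strand = "W"),
    dplyr::mutate(c_, strand = "C")
  ) |>
    dplyr::relocate("strand", .after = "pos")
}

#' Read gene or region annotations from BED
#'
#' Accepts 3- or 6-column BED (0-based half-open) and converts to 1-based
#' inclusive coordinates.  Column 6, when present, supplies the strand used
#' for transcription start site determination.
#'
#' @param path BED file path.
#' @return Tibble with `chrom`, `start`, `end`, `label`, `strand`.
#' @export
read_bed_regions <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm)) nm <- rep(NA_character_, length(gr))
  lab <- ifelse(
    is.na(nm) | !nzchar(nm),
    paste0(as.character(GenomicRanges::seqnames(gr)), ":",
           GenomicRanges::start(gr), "-", GenomicRanges::end(gr)),
    nm
  )
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    label = lab,
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Read a methylation-array beta-value table
#'
#' Expects a TSV with columns `chrom`, `pos` (1-based CpG position) and
#' `beta` (fraction in \[0, 1\]).
#'
#' @param path TSV path.
#' @return Tibble with the three validated columns.
#' @export
read_beta_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    beta = readr::col_double()
  ))
  if (any(x$beta < 0 | x$beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(x[c("chrom", "pos")])) {
    stop("duplicate (chrom, pos) in beta table", call. = FALSE)
  }
  x
}
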