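# shared internal helpers

# reverse complement for plain character vectors
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# decoded Phred+33 scores for one quality string
phred_decode <- function(q) utf8ToInt(q) - 33L

# sum of Phred scores per quality string (vectorised)
phred_sum <- function(quals) {
  vapply(quals, function(q) sum(utf8ToInt(q)) - 33L * nchar(q), numeric(1),
         USE.NAMES = FALSE)
}

reverse_string <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# assemble strings from a flat character vector holding `n` blocks of
# constant width `w` (block-major order)
paste_blocks <- function(chars, w, n) {
  if (n == 0) return(character(0))
  m <- matrix(chars, nrow = w)
  do.call(paste0, lapply(seq_len(w), function(r) m[r, ]))
}

check_genome <- function(genome) {
  if (!is.character(genome) || is.null(names(genome)) ||
      any(!nzchar(names(genome)))) {
    stop("`genome` must be a named character vector of chromosome sequences",
         call. = FALSE)
  }
  if (anyDuplicated(names(genome))) {
    stop("duplicate chromosome names in genome", call. = FALSE)
  }
  if (any(nchar(genome) == 0)) stop("empty chromosome sequence", call. = FALSE)
  if (any(grepl("[^ACGTN]", genome))) {
    stop("genome sequences may only contain A, C, G, T, N", call. = FALSE)
  }
  invisible(genome)
}
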