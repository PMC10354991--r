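# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement nucleotide strings
#'
#' Vectorised over a character vector; `N` is preserved.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of the same length.
#' @export
dna_revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- character(length(x))
  ok <- !is.na(x) & nzchar(x)
  if (any(ok)) {
    out[ok] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[ok]))
    )
  }
  out[!ok] <- x[!ok]
  out
}

# Strip mate suffixes ("/1", "/2") and space-delimited comments so R1/R2 ids
# from different FASTQ dialects compare equal.
normalize_read_id <- function(id) {
  id <- sub("[ \t].*$", "", id)
  sub("/[12]$", "", id)
}

# Seeded random DNA strings; one string per element of `len`.
random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  len <- rep_len(len, n)
  vapply(
    len,
    function(l) paste(sample(DNA_BASES, l, replace = TRUE), collapse = ""),
    character(1)
  )
}

# Positionwise identity of `seqs` prefixes against a fixed reference segment.
# Bases beyond the end of a short read count as mismatches (denominator is
# always nchar(ref)). Returns a numeric vector in [0, 1].
prefix_identity <- function(seqs, ref) {
  L <- nchar(ref)
  n <- length(seqs)
  if (n == 0) return(numeric(0))
  win <- substr(seqs, 1L, L)
  # pad short reads so the char matrix is rectangular
  pad <- L - nchar(win)
  if (any(pad > 0)) {
    win[pad > 0] <- paste0(win[pad > 0], strrep(".", pad[pad > 0]))
  }
  mat <- matrix(unlist(strsplit(win, "", fixed = TRUE), use.names = FALSE),
                nrow = L)
  refc <- strsplit(ref, "", fixed = TRUE)[[1]]
  colSums(mat == refc) / L
}

new_tbl <- function(...) tibble::tibble(...)

`%||%` <- rlang::`%||%`
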