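# File I/O for the formats the pipeline touches: paired FASTQ, the
# association CSV, BED interval files, FASTA genomes, and SAM (read-only,
# see ingest_sam() in alignfilter.R).

#' Read a pair of FASTQ files into a tibble of read pairs
#'
#' Files are read in lock-step: record i of `r1_path` is paired with record i
#' of `r2_path`, and their ids must agree after mate-suffix normalisation
#' (trailing `/1`, `/2` and space-delimited comments are stripped). Gzipped
#' input is transparent.
#'
#' @param r1_path,r2_path Paths to the R1 and R2 FASTQ files.
#' @return A tibble with columns `id`, `r1_seq`, `r1_qual`, `r2_seq`,
#'   `r2_qual`; zero rows for empty files.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  r1 <- read_fastq_one(r1_path)
  r2 <- read_fastq_one(r2_path)
  if (nrow(r1) != nrow(r2)) {
    stop(sprintf(
      "FASTQ pairing error: %s has %d records but %s has %d",
      r1_path, nrow(r1), r2_path, nrow(r2)
    ), call. = FALSE)
  }
  id1 <- normalize_read_id(r1$id)
  id2 <- normalize_read_id(r2$id)
  bad <- which(id1 != id2)
  if (length(bad) > 0) {
    stop(sprintf(
      "FASTQ pairing error at record %d: R1 id '%s' does not match R2 id '%s'",
      bad[1], r1$id[bad[1]], r2$id[bad[1]]
    ), call. = FALSE)
  }
  new_tbl(
    id = id1,
    r1_seq = r1$seq, r1_qual = r1$qual,
    r2_seq = r2$seq, r2_qual = r2$qual
  )
}

read_fastq_one <- function(path) {
  if (!file.exists(path)) {
    stop("FASTQ file not found: ", path, call. = FALSE)
  }
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      stop(sprintf("malformed FASTQ in %s: %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  if (length(x) == 0) {
    return(new_tbl(id = character(0), seq = character(0), qual = character(0)))
  }
  new_tbl(
    id = unname(names(x)),
    seq = unname(as.character(x)),
    qual = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' Write a tibble of read pairs to two FASTQ files
#'
#' Inverse of [read_fastq_pairs()]; round-trips sequences and qualities
#' byte-exactly. Paths ending in `.gz` are gzip-compressed.
#'
#' @param pairs Tibble with `id`, `r1_seq`, `r1_qual`, `r2_seq`, `r2_qual`.
#' @param r1_path,r2_path Output paths.
#' @return Invisibly, `c(r1_path, r2_path)`.
#' @export
write_fastq_pairs <- function(pairs, r1_path, r2_path) {
  write_fastq_one(pairs$id, pairs$r1_seq, pairs$r1_qual, r1_path)
  write_fastq_one(pairs$id, pairs$r2_seq, pairs$r2_qual, r2_path)
  invisible(c(r1_path, r2_path))
}

write_fastq_one <- function(id, seq, qual, path) {
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- id
  q <- Biostrings::BStringSet(qual)
  Biostrings::writeXStringSet(
    x, path, format = "fastq", qualities = q,
    compress = grepl("\\.gz$", path)
  )
}

#' Parse the sample association file
#'
#' The association CSV declares one sample per row with its LTR-side and
#' LC-side barcodes and the transduction group (`group_id`, the field used to
#' mark independent sample groups between which shared sites are treated as
#' collisions). Extra columns are preserved untouched.
#'
#' @param csv_path Path to a CSV with at least `sample_id`, `ltr_barcode`,
#'   `lc_barcode`, `group_id` columns.
#' @return A tibble, one row per sample.
#' @export
parse_association <- function(csv_path) {
  tbl <- readr::read_csv(csv_path, show_col_types = FALSE,
                         progress = FALSE)
  required <- c("sample_id", "ltr_barcode", "lc_barcode", "group_id")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop("association file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tbl$ltr_barcode <- toupper(tbl$ltr_barcode)
  tbl$lc_barcode <- toupper(tbl$lc_barcode)
  if (any(is.na(tbl$group_id) | !nzchar(as.character(tbl$group_id)))) {
    stop("association file has empty group_id values", call. = FALSE)
  }
  key <- paste(tbl$ltr_barcode, tbl$lc_barcode)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate barcode pair in association file: ", dup, call. = FALSE)
  }
  if (anyDuplicated(tbl$sample_id)) {
    stop("duplicate sample_id in association file", call. = FALSE)
  }
  tibble::as_tibble(tbl)
}

#' Load a BED file as a role-tagged interval table
#'
#' Intervals are 0-based half-open, as in BED. The `role` tag records what the
#' track is used for downstream (`repeat` regions for the MAPQ gate, `gene`
#' annotation, or a `vector_mask`).
#'
#' @param bed_path Path to a BED3+ file.
#' @param role One of `"repeat"`, `"gene"`, `"vector_mask"`.
#' @return A tibble with columns `chrom`, `start`, `end`, `label`, `role`,
#'   sorted within chromosome.
#' @export
load_intervals <- function(bed_path, role = c("repeat", "gene", "vector_mask")) {
  role <- match.arg(role)
  gr <- tryCatch(
    rtracklayer::import(bed_path, format = "BED"),
    error = function(e) {
      stop(sprintf("malformed BED in %s: %s", bed_path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  if (length(gr) == 0) {
    return(new_tbl(chrom = character(0), start = integer(0),
                   end = integer(0), label = character(0),
                   role = character(0)))
  }
  label <- if (!is.null(gr$name)) as.character(gr$name) else
    paste0(role, "_", seq_along(gr))
  label[is.na(label)] <- paste0(role, "_", which(is.na(label)))
  out <- new_tbl(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to 0-based half-open
    end = GenomicRanges::end(gr),
    label = label,
    role = role
  )
  dplyr::arrange(out, .data$chrom, .data$start, .data$end)
}

# TRUE for each (chrom, start0, end0) query span that overlaps any interval.
spans_overlap_intervals <- function(chrom, start0, end0, intervals) {
  n <- length(chrom)
  if (n == 0 || nrow(intervals) == 0) return(rep(FALSE, n))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
  s <- GenomicRanges::GRanges(
    intervals$chrom, IRanges::IRanges(intervals$start + 1L, intervals$end)
  )
  IRanges::overlapsAny(q, s)
}

#' Read a reference genome FASTA
#' @param fasta_path Path to a (optionally gzipped) FASTA file.
#' @return A named `DNAStringSet`, one entry per chromosome.
#' @export
read_genome <- function(fasta_path) {
  g <- Biostrings::readDNAStringSet(fasta_path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g))) {
    stop("duplicate chromosome names in ", fasta_path, call. = FALSE)
  }
  g
}

#' Write a reference genome FASTA
#' @param genome A named `DNAStringSet`.
#' @param fasta_path Output path.
#' @return Invisibly, `fasta_path`.
#' @export
write_genome <- function(genome, fasta_path) {
  Biostrings::writeXStringSet(genome, fasta_path,
                              compress = grepl("\\.gz$", fasta_path))
  invisible(fasta_path)
}
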