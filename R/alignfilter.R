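# Mapping of trimmed genomic pairs and the post-alignment filters:
# MAPQ/repeat gating, the 3 nt junction check, filter60, and reduction of
# concordant pairs to junction events.

#' Map reads with the built-in exact-seed mapper
#'
#' A deliberately simple, deterministic mapper for desk-scale genomes: exact
#' 31-mer seeds are looked up at a ladder of read offsets (so reads whose 5'
#' end is mutated still map via a downstream seed), each seed hit is extended
#' ungapped over the full read on both strands, and the best locus is
#' reported with MAPQ 60 when the seed hit a single locus, MAPQ 0 when it hit
#' several (multi-mapping), or dropped when no extension reaches
#' `min_identity`. External aligners are supported instead via
#' [ingest_sam()]; the pipeline never shells out.
#'
#' @param reads Tibble with `read_id` and `seq` columns (additional columns
#'   such as `sample_id`, `group_id`, `umi` are carried through).
#' @param genome Named `DNAStringSet` reference.
#' @param seed_len Exact-seed length (default 31).
#' @param seed_offsets 1-based read offsets at which seeds are tried, in
#'   order; a read uses the first offset that yields any hit.
#' @param min_identity Minimum fraction of matching bases over the extended
#'   (reference-overlapping) span.
#' @return A tibble of alignment records: `read_id`, `chrom`, `strand`,
#'   `start`/`end` (0-based half-open reference span), `mapq`, `matches`,
#'   `genomic_match_len`, `clip5`/`clip3` (query bases falling off the
#'   contig), `m_first`/`m_last` (contiguous reference-consuming run lengths
#'   at each end; equal to the span here since extension is ungapped),
#'   `query_fwd` (query in reference orientation), carried-through columns.
#'   Unmapped reads are absent; their count is attached as attribute
#'   `n_unmapped`.
#' @export
builtin_map <- function(reads, genome, seed_len = 31L,
                        seed_offsets = c(1L, 33L, 65L, 97L, 129L),
                        min_identity = 0.75) {
  stopifnot(is.data.frame(reads), all(c("read_id", "seq") %in% names(reads)))
  n <- nrow(reads)
  chrom_chars <- stats::setNames(as.character(genome), names(genome))
  chrom_lens <- stats::setNames(Biostrings::width(genome), names(genome))

  seqs <- toupper(reads$seq)
  rc <- dna_revcomp(seqs)
  unresolved <- rep(TRUE, n)
  hits_all <- vector("list", length(seed_offsets))

  for (k in seq_along(seed_offsets)) {
    o <- seed_offsets[k]
    idx <- which(unresolved & nchar(seqs) >= o + seed_len - 1L)
    if (length(idx) == 0) next
    # the offset ladder is measured on the READ for both strands, so a read
    # whose 5' end is damaged still maps via a downstream window either way
    fwd_seed <- substr(seqs[idx], o, o + seed_len - 1L)
    rev_seed <- dna_revcomp(fwd_seed)
    seeds <- c(fwd_seed, rev_seed)
    valid <- !grepl("[^ACGT]", seeds)
    if (!any(valid)) next
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds[valid]))
    vmap <- which(valid)  # position in `seeds` per pdict entry

    rows <- list()
    for (ch in names(chrom_chars)) {
      m <- Biostrings::matchPDict(pd, genome[[ch]])
      cnt <- S4Vectors::elementNROWS(m)
      if (sum(cnt) == 0) next
      j <- rep.int(seq_along(m), cnt)          # pdict entry per hit
      pos0 <- unlist(IRanges::start(m), use.names = FALSE) - 1L  # 0-based
      sidx <- vmap[j]                           # index in `seeds`
      is_rev <- sidx > length(idx)
      ridx <- idx[ifelse(is_rev, sidx - length(idx), sidx)]
      len <- nchar(seqs)[ridx]
      # + strand: seed sits o-1 bases into the read;
      # - strand: the seed is the revcomp of read[o .. o+k-1], which sits
      #   len - o - k + 1 bases into the reference-oriented query
      start <- ifelse(is_rev,
                      pos0 - (len - (o - 1L) - seed_len),
                      pos0 - (o - 1L))
      rows[[ch]] <- new_tbl(
        read = ridx,
        chrom = ch,
        strand = ifelse(is_rev, "-", "+"),
        start = as.integer(start)
      )
    }
    if (length(rows) == 0) next
    h <- dplyr::distinct(dplyr::bind_rows(rows))
    unresolved[unique(h$read)] <- FALSE
    hits_all[[k]] <- h
  }

  hits <- dplyr::bind_rows(hits_all)
  if (nrow(hits) == 0) {
    out <- empty_alignments(reads)
    attr(out, "n_unmapped") <- n
    return(out)
  }

  # ungapped extension of every candidate locus
  len <- nchar(seqs)[hits$read]
  clen <- chrom_lens[hits$chrom]
  clip5 <- pmax(0L, -hits$start)
  ref_start <- hits$start + clip5               # 0-based, clipped
  ref_end <- pmin(hits$start + len, clen)
  clip3 <- (hits$start + len) - ref_end
  span <- ref_end - ref_start
  qf <- ifelse(hits$strand == "+", seqs[hits$read], rc[hits$read])
  qcmp <- substr(qf, clip5 + 1L, clip5 + span)
  refseq <- substring(chrom_chars[hits$chrom], ref_start + 1L, ref_end)
  matches <- mapply(function(a, b) sum(charToRaw(a) == charToRaw(b)),
                    qcmp, refseq, USE.NAMES = FALSE)

  cand <- new_tbl(
    read = hits$read, chrom = hits$chrom, strand = hits$strand,
    start = as.integer(ref_start), end = as.integer(ref_end),
    clip5 = as.integer(clip5), clip3 = as.integer(clip3),
    genomic_match_len = as.integer(span),
    matches = as.integer(matches),
    identity = matches / pmax(span, 1L),
    query_fwd = qf
  )
  n_loci <- dplyr::count(cand, .data$read, name = "n_loci")
  cand <- dplyr::left_join(cand, n_loci, by = "read")
  best <- cand |>
    dplyr::filter(.data$identity >= min_identity) |>
    dplyr::arrange(.data$read, dplyr::desc(.data$matches),
                   .data$chrom, .data$start, .data$strand) |>
    dplyr::distinct(.data$read, .keep_all = TRUE) |>
    dplyr::mutate(mapq = ifelse(.data$n_loci > 1L, 0L, 60L))

  out <- dplyr::bind_cols(
    reads[best$read, setdiff(names(reads), "seq"), drop = FALSE],
    dplyr::select(best, "chrom", "strand", "start", "end", "mapq",
                  "matches", "genomic_match_len", "clip5", "clip3",
                  "query_fwd")
  )
  out$m_first <- out$genomic_match_len
  out$m_last <- out$genomic_match_len
  attr(out, "n_unmapped") <- n - nrow(out)
  out
}

empty_alignments <- function(reads = NULL) {
  base <- if (!is.null(reads)) {
    reads[0, setdiff(names(reads), "seq"), drop = FALSE]
  } else {
    new_tbl(read_id = character(0))
  }
  dplyr::bind_cols(base, new_tbl(
    chrom = character(0), strand = character(0),
    start = integer(0), end = integer(0), mapq = integer(0),
    matches = integer(0), genomic_match_len = integer(0),
    clip5 = integer(0), clip3 = integer(0), query_fwd = character(0),
    m_first = integer(0), m_last = integer(0)
  ))
}

#' Ingest primary alignments from a SAM file
#'
#' Reads a SAM produced by an external aligner on the trimmed per-sample
#' FASTQ pairs ([write_trimmed_fastq()]). Secondary and supplementary
#' records are skipped; CIGARs are parsed into the 0-based half-open
#' reference span, the total reference-consuming query length, terminal
#' clip lengths, and the terminal match-run lengths needed by the junction
#' check. UMIs are recovered from the `_UMI:<seq>` read-id suffix.
#'
#' @param sam_path Path to a SAM (or BAM) file.
#' @param sample_id Optional sample id to stamp on every record.
#' @param group_id Optional group id.
#' @return An alignment tibble in the same layout as [builtin_map()], plus
#'   `is_r1` (from the SAM flag) and `umi`.
#' @export
ingest_sam <- function(sam_path, sample_id = NA_character_,
                       group_id = NA_character_) {
  bam <- sam_path
  if (grepl("\\.sam$", sam_path, ignore.case = TRUE)) {
    bam <- tryCatch(
      Rsamtools::asBam(sam_path,
                       destination = tempfile(fileext = ""),
                       overwrite = TRUE, indexDestination = FALSE),
      error = function(e) {
        stop(sprintf("malformed SAM in %s: %s", sam_path,
                     conditionMessage(e)), call. = FALSE)
      }
    )
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq", "seq"),
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE,
      isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE
    )
  )
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  if (length(ga) == 0) {
    out <- empty_alignments()
    out$is_r1 <- logical(0)
    out$umi <- character(0)
    out$sample_id <- character(0)
    out$group_id <- character(0)
    return(out)
  }
  mc <- S4Vectors::mcols(ga)
  cig <- GenomicAlignments::cigar(ga)
  ops <- GenomicAlignments::explodeCigarOps(cig)
  opl <- GenomicAlignments::explodeCigarOpLengths(cig)
  match_len <- vapply(seq_along(ops), function(i) {
    sum(opl[[i]][ops[[i]] %in% c("M", "=", "X")])
  }, integer(1))
  end_run <- function(o, l, from_start) {
    if (!from_start) { o <- rev(o); l <- rev(l) }
    keep <- !(o %in% c("S", "H"))
    o <- o[keep]; l <- l[keep]
    # first reference-consuming run length (0 when alignment starts with I)
    if (length(o) == 0 || !(o[1] %in% c("M", "=", "X"))) 0L else l[1]
  }
  clip_len <- function(o, l, from_start) {
    if (!from_start) { o <- rev(o); l <- rev(l) }
    k <- 0L
    for (i in seq_along(o)) {
      if (o[i] %in% c("S", "H")) k <- k + l[i] else break
    }
    k
  }
  clip5 <- mapply(clip_len, ops, opl, MoreArgs = list(from_start = TRUE))
  clip3 <- mapply(clip_len, ops, opl, MoreArgs = list(from_start = FALSE))
  m_first <- mapply(end_run, ops, opl, MoreArgs = list(from_start = TRUE))
  m_last <- mapply(end_run, ops, opl, MoreArgs = list(from_start = FALSE))

  qname <- mc$qname
  umi <- stringr::str_match(qname, "_UMI:([ACGTN]+)")[, 2]
  new_tbl(
    read_id = normalize_read_id(sub("_UMI:[ACGTN]+", "", qname)),
    sample_id = sample_id,
    group_id = group_id,
    umi = umi,
    is_r1 = bitwAnd(mc$flag, 64L) > 0L | bitwAnd(mc$flag, 1L) == 0L,
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    strand = as.character(GenomicAlignments::strand(ga)),
    start = GenomicAlignments::start(ga) - 1L,
    end = GenomicAlignments::end(ga),
    mapq = as.integer(mc$mapq),
    matches = NA_integer_,
    genomic_match_len = match_len,
    clip5 = as.integer(clip5),
    clip3 = as.integer(clip3),
    query_fwd = as.character(mc$seq),
    m_first = as.integer(m_first),
    m_last = as.integer(m_last)
  )
}

ops_is_clip <- function(o) o %in% c("S", "H")

#' MAPQ/repeat filter
#'
#' Alignments outside annotated repeat regions always pass; alignments
#' overlapping a repeat pass only with `mapq >= mapq_min` (high mapping
#' quality rescues repeat hits). `mode = "global"` instead applies the MAPQ
#' threshold to every alignment.
#'
#' @param alns Alignment tibble.
#' @param repeats Repeat intervals from [load_intervals()], or `NULL`.
#' @param mapq_min MAPQ threshold (default 12; set 0 to disable).
#' @param mode `"repeat_only"` (default) or `"global"`.
#' @return The rows of `alns` that pass.
#' @export
mapq_repeat_filter <- function(alns, repeats = NULL, mapq_min = 12L,
                               mode = c("repeat_only", "global")) {
  mode <- match.arg(mode)
  if (nrow(alns) == 0) return(alns)
  if (mode == "global") {
    return(alns[alns$mapq >= mapq_min, , drop = FALSE])
  }
  if (is.null(repeats) || nrow(repeats) == 0) return(alns)
  in_rep <- spans_overlap_intervals(alns$chrom, alns$start, alns$end, repeats)
  alns[!in_rep | alns$mapq >= mapq_min, , drop = FALSE]
}

#' Junction 3 nt perfect-match check
#'
#' The three query bases at the LTR-proximal end of an R1 alignment (the
#' alignment start for `+` reads, the end for `-` reads) must be
#' reference-consuming (no clip at that end) and match the reference
#' perfectly; otherwise the vector-genome junction is not trusted.
#'
#' @param alns R1 alignment tibble.
#' @param genome Named `DNAStringSet` reference.
#' @return Logical vector, one per alignment.
#' @export
junction_3nt_check <- function(alns, genome) {
  n <- nrow(alns)
  if (n == 0) return(logical(0))
  chrom_chars <- stats::setNames(as.character(genome), names(genome))
  plus <- alns$strand == "+"
  qlen <- nchar(alns$query_fwd)
  # query bases at the junction-proximal end, in reference orientation
  qb <- ifelse(plus,
               substr(alns$query_fwd, alns$clip5 + 1L, alns$clip5 + 3L),
               substr(alns$query_fwd, qlen - alns$clip3 - 2L,
                      qlen - alns$clip3))
  rb <- ifelse(plus,
               substring(chrom_chars[alns$chrom], alns$start + 1L,
                         alns$start + 3L),
               substring(chrom_chars[alns$chrom], alns$end - 2L, alns$end))
  clip_ok <- ifelse(plus, alns$clip5 == 0L, alns$clip3 == 0L)
  run_ok <- ifelse(plus, alns$m_first >= 3L, alns$m_last >= 3L)
  clip_ok & run_ok & !is.na(qb) & qb == rb
}

#' At-least-60 bp genomic match filter
#'
#' @param genomic_match_len Integer vector of reference-consuming query
#'   lengths.
#' @param min_len Threshold (default 60).
#' @return Logical vector.
#' @export
filter60 <- function(genomic_match_len, min_len = 60L) {
  genomic_match_len >= min_len
}

#' Reduce mapped R1/R2 mates to junction events
#'
#' Mates are joined by read id and must map to the same chromosome in
#' opposite orientation. The junction position is the LTR-proximal end of
#' R1 (1-based); the fragment length is the distance from the junction to
#' the shear site, i.e. the outer end of the R2 alignment. UMI and sample
#' information are propagated from R1.
#'
#' @param aln_r1,aln_r2 Alignment tibbles for R1 and R2 reads.
#' @return A tibble of junction events: `read_id`, `sample_id`, `group_id`,
#'   `chrom`, `strand`, `junction_pos` (1-based), `fragment_len`, `umi`,
#'   `match_len_r1`, `mapq_r1`. Drop reasons are tabulated in attribute
#'   `drops`.
#' @export
to_junction_events <- function(aln_r1, aln_r2) {
  keep_r1 <- c("read_id", intersect(c("sample_id", "group_id", "umi"),
                                    names(aln_r1)),
               "chrom", "strand", "start", "end", "genomic_match_len", "mapq")
  r1 <- dplyr::select(aln_r1, dplyr::all_of(keep_r1))
  r2 <- dplyr::select(aln_r2, "read_id", r2_chrom = "chrom",
                      r2_strand = "strand", r2_start = "start",
                      r2_end = "end")
  j <- dplyr::inner_join(r1, r2, by = "read_id")
  n_unpaired <- nrow(aln_r1) - nrow(j)

  same_chrom <- j$chrom == j$r2_chrom
  opposite <- j$strand != j$r2_strand
  plus <- j$strand == "+"
  junction <- ifelse(plus, j$start + 1L, j$end)
  frag <- ifelse(plus, j$r2_end - j$start, j$end - j$r2_start)
  ok <- same_chrom & opposite & frag > 0L

  drops <- c(
    unpaired = n_unpaired,
    discordant_chrom = sum(!same_chrom),
    discordant_orientation = sum(same_chrom & !opposite),
    nonpositive_fragment = sum(same_chrom & opposite & frag <= 0L)
  )

  out <- j[ok, , drop = FALSE]
  out <- dplyr::mutate(
    out,
    junction_pos = as.integer(junction[ok]),
    fragment_len = as.integer(frag[ok]),
    match_len_r1 = .data$genomic_match_len,
    mapq_r1 = .data$mapq
  )
  out <- dplyr::select(
    out, dplyr::any_of(c("read_id", "sample_id", "group_id", "chrom",
                         "strand", "junction_pos", "fragment_len", "umi",
                         "match_len_r1", "mapq_r1"))
  )
  attr(out, "drops") <- drops
  out
}
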