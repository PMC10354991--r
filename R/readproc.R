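# Oligo-structure parsing: turn raw read pairs into demultiplexed, trimmed
# genomic pairs with validated anchored UMIs. Rejections are first-fail and
# stage-ordered so the funnel is auditable:
#   too_short -> unassigned -> ltr_fail -> lc_fail -> anchor_fail

REJECTION_STAGES <- c("too_short", "id_mismatch", "unassigned",
                      "ltr_fail", "lc_fail", "anchor_fail")

#' Strip the random prefix from reads
#'
#' Removes the first `n` bases (the random stretch the fusion primers add for
#' cluster recognition) from sequence and quality alike.
#'
#' @param seq,qual Character vectors of sequences and qualities.
#' @param n Number of bases to strip.
#' @return A tibble with `seq`, `qual`, and logical `too_short` marking reads
#'   of length `<= n` (which are left unstripped).
#' @export
strip_random_prefix <- function(seq, qual = NULL, n) {
  stopifnot(n >= 0)
  too_short <- nchar(seq) <= n
  out_seq <- ifelse(too_short, seq, substr(seq, n + 1L, nchar(seq)))
  out_qual <- if (is.null(qual)) NA_character_ else
    ifelse(too_short, qual, substr(qual, n + 1L, nchar(qual)))
  new_tbl(seq = out_seq, qual = out_qual, too_short = too_short)
}

#' Match a fixed oligo segment against read prefixes
#'
#' Identity is the number of matching bases divided by the full segment
#' length, so a read that truncates the segment is penalised. A fast
#' substitution-only check at the expected offset handles the overwhelming
#' majority of reads; when it falls in an intermediate band (possible
#' insertion/deletion shifting the segment) a semi-global
#' `pairwiseAlignment` -- segment global, read ends free, unit
#' match/mismatch scoring -- is used instead, and the identity of the
#' score-optimal alignment is reported.
#'
#' @param seqs Character vector of read (sub)sequences whose start is where
#'   the segment is expected.
#' @param ref_seq The segment to match (e.g. the LTR).
#' @param min_identity Acceptance threshold; defaults to the design's 0.90.
#' @param fallback_band Fast-path identities in `[fallback_band, min_identity)`
#'   trigger the alignment fallback; lower values are rejected outright.
#' @return A tibble with `matched`, `identity`, `match_end` (1-based position
#'   in the read just past the matched segment; `NA` when unmatched).
#' @export
match_segment <- function(seqs, ref_seq, min_identity = 0.90,
                          fallback_band = 0.5) {
  L <- nchar(ref_seq)
  stopifnot(L > 0)
  n <- length(seqs)
  if (n == 0) {
    return(new_tbl(matched = logical(0), identity = numeric(0),
                   match_end = integer(0)))
  }
  identity <- prefix_identity(seqs, ref_seq)
  match_end <- rep(L, n)
  retry <- which(identity < min_identity & identity >= fallback_band &
                   nchar(seqs) > 0)
  if (length(retry) > 0) {
    aln <- align_segment(seqs[retry], ref_seq)
    better <- aln$identity > identity[retry]
    identity[retry][better] <- aln$identity[better]
    match_end[retry][better] <- aln$match_end[better]
  }
  matched <- identity >= min_identity
  new_tbl(
    matched = matched,
    identity = identity,
    match_end = ifelse(matched, as.integer(match_end), NA_integer_)
  )
}

# Semi-global alignment fallback: segment aligned end-to-end, read ends free.
align_segment <- function(seqs, ref_seq) {
  L <- nchar(ref_seq)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(seqs),
    subject = Biostrings::DNAString(ref_seq),
    type = "local-global",
    substitutionMatrix = sm,
    gapOpening = 0, gapExtension = 2  # linear gap cost, 2 per base
  )
  new_tbl(
    identity = Biostrings::nmatch(aln) / L,
    match_end = IRanges::end(Biostrings::pattern(aln))
  )
}

#' Demultiplex read pairs by independent LTR and LC barcodes
#'
#' The R1 barcode window must match a sample's `ltr_barcode` and the R2
#' window that same sample's `lc_barcode`; mixed matches (LTR of one sample,
#' LC of another) are unassigned. Matching is exact by default -- the
#' conservative reading of the protocol -- with an optional per-barcode
#' mismatch tolerance.
#'
#' @param bc_r1,bc_r2 Character vectors: the barcode windows cut from the
#'   prefix-stripped R1 and R2 reads.
#' @param samples Association tibble from [parse_association()].
#' @param max_mismatch Allowed mismatches per barcode (default 0). With
#'   tolerance, a window is assigned only when exactly one sample's barcode
#'   is within range.
#' @return Character vector of `sample_id`, `NA` where unassigned.
#' @export
demultiplex <- function(bc_r1, bc_r2, samples, max_mismatch = 0L) {
  n <- length(bc_r1)
  if (n == 0) return(character(0))
  if (max_mismatch == 0) {
    key <- paste(bc_r1, bc_r2)
    lut <- stats::setNames(samples$sample_id,
                           paste(samples$ltr_barcode, samples$lc_barcode))
    return(unname(lut[key]))
  }
  assign_one <- function(obs, ref) {
    d <- vapply(ref, function(r) {
      sum(strsplit(obs, "")[[1]] != strsplit(r, "")[[1]])
    }, integer(1))
    hit <- which(d <= max_mismatch)
    if (length(hit) == 1) hit else NA_integer_
  }
  i1 <- vapply(bc_r1, assign_one, integer(1), ref = samples$ltr_barcode)
  i2 <- vapply(bc_r2, assign_one, integer(1), ref = samples$lc_barcode)
  unname(ifelse(!is.na(i1) & !is.na(i2) & i1 == i2,
                samples$sample_id[i1], NA_character_))
}

#' Extract anchored UMIs from the post-LC1 portion of R2
#'
#' Scans each sequence for exact occurrences of the design anchor. Secondary
#' anchor hits can arise by chance in the downstream genomic sequence, so the
#' anchor locus is fixed batch-wide as the modal hit position, which is
#' checked against the expected offset (`umi_flank_len`); a read is accepted
#' only if it carries a perfect anchor at that locus. Any mismatch in the
#' anchor at the expected position -- or an anchor shifted by an indel in the
#' UMI region -- rejects the read (`anchor_fail`).
#'
#' @param seqs Character vector starting immediately after the LC1 match.
#' @param design An [oligo_design()].
#' @return A tibble with `umi` (18 nt by default; `NA` on failure) and
#'   logical `anchor_fail`. The batch-modal anchor position is attached as
#'   attribute `anchor_locus`.
#' @export
extract_umi <- function(seqs, design = oligo_design()) {
  flank <- design$umi_flank_len
  anchor <- design$anchor_seq
  alen <- nchar(anchor)
  ulen <- umi_length(design)
  expected <- flank + 1L  # 1-based anchor start within the UMI window
  n <- length(seqs)
  if (n == 0) {
    out <- new_tbl(umi = character(0), anchor_fail = logical(0))
    attr(out, "anchor_locus") <- expected
    return(out)
  }
  # modal exact-hit position across the batch (first hit per read suffices
  # for the mode; scan a window generous enough to see shifted anchors)
  scan_to <- ulen + nchar(design$lc2_seq)
  first_hit <- as.integer(regexpr(anchor, substr(seqs, 1L, scan_to + alen),
                                  fixed = TRUE))
  hits <- first_hit[first_hit > 0]
  locus <- if (length(hits) > 0) {
    as.integer(names(sort(table(hits), decreasing = TRUE))[1])
  } else {
    expected
  }
  at_expected <- substr(seqs, expected, expected + alen - 1L) == anchor
  ok <- locus == expected & at_expected & nchar(seqs) >= ulen
  out <- new_tbl(
    umi = ifelse(ok, substr(seqs, 1L, ulen), NA_character_),
    anchor_fail = !ok
  )
  attr(out, "anchor_locus") <- locus
  out
}

#' Process raw read pairs through the full oligo-parsing funnel
#'
#' Composition of the per-stage operations, applied batch-wise:
#' random-prefix strip, independent dual-barcode demultiplexing, LTR
#' match/trim on R1, LC1 match on R2, anchored-UMI extraction, LC2
#' match/trim. Every input pair appears exactly once in the output, either
#' as a survivor (`rejection` is `NA`) or with the first failing stage's
#' reason code.
#'
#' @param pairs Tibble from [read_fastq_pairs()] (columns `id`, `r1_seq`,
#'   `r1_qual`, `r2_seq`, `r2_qual`; an optional `r2_id` is checked against
#'   `id` after mate normalisation).
#' @param samples Association tibble ([parse_association()]).
#' @param design An [oligo_design()].
#' @param max_mismatch Barcode mismatch tolerance for [demultiplex()].
#' @return The input tibble with columns `sample_id`, `group_id`,
#'   `genomic_r1`, `genomic_r1_qual`, `genomic_r2`, `genomic_r2_qual`,
#'   `umi`, and `rejection` added. Survivor genomic segments are non-empty.
#' @seealso [rejection_funnel()] for the stage -> count report.
#' @export
process_reads <- function(pairs, samples, design = oligo_design(),
                          max_mismatch = 0L) {
  n <- nrow(pairs)
  rejection <- rep(NA_character_, n)
  sample_id <- rep(NA_character_, n)
  genomic_r1 <- rep(NA_character_, n)
  genomic_r1_qual <- rep(NA_character_, n)
  genomic_r2 <- rep(NA_character_, n)
  genomic_r2_qual <- rep(NA_character_, n)
  umi <- rep(NA_character_, n)

  pre <- design$random_prefix_len
  bl <- design$barcode_len
  ulen <- umi_length(design)

  # minimum length to hold the full anatomy plus >= 1 genomic base
  min_r1 <- pre + bl + nchar(design$ltr_seq) + 1L
  min_r2 <- pre + bl + nchar(design$lc1_seq) + ulen + nchar(design$lc2_seq) + 1L
  too_short <- nchar(pairs$r1_seq) < min_r1 | nchar(pairs$r2_seq) < min_r2
  rejection[too_short] <- "too_short"

  if ("r2_id" %in% names(pairs)) {
    mism <- is.na(rejection) &
      normalize_read_id(pairs$id) != normalize_read_id(pairs$r2_id)
    rejection[mism] <- "id_mismatch"
  }

  live <- which(is.na(rejection))
  if (length(live) > 0) {
    r1 <- substr(pairs$r1_seq[live], pre + 1L, nchar(pairs$r1_seq[live]))
    q1 <- substr(pairs$r1_qual[live], pre + 1L, nchar(pairs$r1_qual[live]))
    r2 <- substr(pairs$r2_seq[live], pre + 1L, nchar(pairs$r2_seq[live]))
    q2 <- substr(pairs$r2_qual[live], pre + 1L, nchar(pairs$r2_qual[live]))

    sid <- demultiplex(substr(r1, 1L, bl), substr(r2, 1L, bl),
                       samples, max_mismatch)
    rejection[live[is.na(sid)]] <- "unassigned"
    sample_id[live] <- sid

    keep <- !is.na(sid)
    idx <- live[keep]
    if (length(idx) > 0) {
      r1k <- substr(r1[keep], bl + 1L, nchar(r1[keep]))
      q1k <- substr(q1[keep], bl + 1L, nchar(q1[keep]))
      m_ltr <- match_segment(r1k, design$ltr_seq, design$min_identity)
      rejection[idx[!m_ltr$matched]] <- "ltr_fail"

      keep2 <- m_ltr$matched
      idx2 <- idx[keep2]
      if (length(idx2) > 0) {
        g1 <- substr(r1k[keep2], m_ltr$match_end[keep2] + 1L,
                     nchar(r1k[keep2]))
        g1q <- substr(q1k[keep2], m_ltr$match_end[keep2] + 1L,
                      nchar(q1k[keep2]))

        r2k <- substr(r2[keep][keep2], bl + 1L, nchar(r2[keep][keep2]))
        q2k <- substr(q2[keep][keep2], bl + 1L, nchar(q2[keep][keep2]))
        m_lc1 <- match_segment(r2k, design$lc1_seq, design$min_identity)
        rejection[idx2[!m_lc1$matched]] <- "lc_fail"

        keep3 <- m_lc1$matched
        idx3 <- idx2[keep3]
        if (length(idx3) > 0) {
          post_lc1 <- substr(r2k[keep3], m_lc1$match_end[keep3] + 1L,
                             nchar(r2k[keep3]))
          post_lc1_q <- substr(q2k[keep3], m_lc1$match_end[keep3] + 1L,
                               nchar(q2k[keep3]))
          u <- extract_umi(post_lc1, design)
          rejection[idx3[u$anchor_fail]] <- "anchor_fail"

          keep4 <- !u$anchor_fail
          idx4 <- idx3[keep4]
          if (length(idx4) > 0) {
            umi[idx4] <- u$umi[keep4]
            # re-index the R1 genomic segments into idx4-space
            g1_4 <- g1[keep3][keep4]
            g1q_4 <- g1q[keep3][keep4]
            post_umi <- substr(post_lc1[keep4], ulen + 1L,
                               nchar(post_lc1[keep4]))
            post_umi_q <- substr(post_lc1_q[keep4], ulen + 1L,
                                 nchar(post_lc1_q[keep4]))
            m_lc2 <- match_segment(post_umi, design$lc2_seq,
                                   design$min_identity)
            bad_lc2 <- !m_lc2$matched
            rejection[idx4[bad_lc2]] <- "lc_fail"

            ok <- which(!bad_lc2)
            if (length(ok) > 0) {
              g2 <- substr(post_umi[ok], m_lc2$match_end[ok] + 1L,
                           nchar(post_umi[ok]))
              g2q <- substr(post_umi_q[ok], m_lc2$match_end[ok] + 1L,
                            nchar(post_umi_q[ok]))
              empty <- !nzchar(g2) | !nzchar(g1_4[ok])
              rejection[idx4[ok][empty]] <- "too_short"
              fin <- ok[!empty]
              genomic_r1[idx4[fin]] <- g1_4[fin]
              genomic_r1_qual[idx4[fin]] <- g1q_4[fin]
              genomic_r2[idx4[fin]] <- g2[!empty]
              genomic_r2_qual[idx4[fin]] <- g2q[!empty]
            }
          }
        }
      }
    }
  }

  out <- dplyr::mutate(
    pairs,
    sample_id = sample_id,
    genomic_r1 = genomic_r1, genomic_r1_qual = genomic_r1_qual,
    genomic_r2 = genomic_r2, genomic_r2_qual = genomic_r2_qual,
    umi = umi,
    rejection = rejection
  )
  # survivors must be demultiplexed; clear sample on rejected rows for clarity
  out$sample_id[!is.na(out$rejection)] <- NA_character_
  out <- dplyr::left_join(
    out,
    dplyr::select(samples, "sample_id", "group_id"),
    by = "sample_id"
  )
  out
}

#' Stage-by-stage rejection funnel of a processed batch
#'
#' @param processed Output of [process_reads()].
#' @return A tibble with `stage` (ordered: input, each rejection reason,
#'   survivors) and `n`; the reason counts plus survivors sum to the input.
#' @export
rejection_funnel <- function(processed) {
  counts <- table(factor(processed$rejection, levels = REJECTION_STAGES))
  new_tbl(
    stage = c("input", REJECTION_STAGES, "survivors"),
    n = c(nrow(processed), as.integer(counts),
          sum(is.na(processed$rejection)))
  )
}

#' Write per-sample trimmed FASTQ pairs
#'
#' Survivors of [process_reads()] are written as one FASTQ pair per sample,
#' with the UMI carried in the read id as `<id>_UMI:<seq>` so downstream
#' alignment preserves it.
#'
#' @param processed Output of [process_reads()].
#' @param dir Output directory (created if needed).
#' @param gzip Compress outputs.
#' @return A tibble with `sample_id`, `r1_path`, `r2_path`, `n_pairs`.
#' @export
write_trimmed_fastq <- function(processed, dir, gzip = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  surv <- dplyr::filter(processed, is.na(.data$rejection))
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  res <- lapply(split(surv, surv$sample_id), function(s) {
    r1 <- file.path(dir, paste0(s$sample_id[1], "_R1", ext))
    r2 <- file.path(dir, paste0(s$sample_id[1], "_R2", ext))
    ids <- paste0(s$id, "_UMI:", s$umi)
    write_fastq_one(ids, s$genomic_r1, s$genomic_r1_qual, r1)
    write_fastq_one(ids, s$genomic_r2, s$genomic_r2_qual, r2)
    new_tbl(sample_id = s$sample_id[1], r1_path = r1, r2_path = r2,
            n_pairs = nrow(s))
  })
  dplyr::bind_rows(res)
}
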