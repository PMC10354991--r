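#' Oligo design of a linker-mediated PCR integration-site library
#'
#' Describes the fixed anatomy of the paired reads this pipeline parses.
#' R1 reads are laid out as
#' `random prefix (12 nt) + sample barcode (8 nt) + LTR (32 nt) + genomic DNA`,
#' and R2 reads as
#' `random prefix (12 nt) + sample barcode (8 nt) + LC1 (29 nt) + UMI (18 nt) +
#' LC2 (20 nt) + genomic DNA`.
#' The UMI itself is two random flanks of `umi_flank_len` nt around a fixed
#' anchor (default `GTAAGG`); a sequencing error anywhere in the anchor is
#' grounds for discarding the read, on the assumption the error may extend
#' into the random flanks and distort UMI diversity.
#'
#' The default LTR/LC sequences are a working lentiviral-style design; all
#' segments are configurable for other vector platforms.
#'
#' @param random_prefix_len Random bases ahead of the barcode on both reads.
#' @param barcode_len Sample barcode length (nt), on both reads.
#' @param ltr_seq Vector LTR segment expected on R1; its 3' end abuts the
#'   vector-genome junction.
#' @param lc1_seq Linker-cassette segment upstream of the UMI on R2.
#' @param anchor_seq Fixed anchor inside the UMI; must match perfectly.
#' @param umi_flank_len Length of each random UMI flank.
#' @param lc2_seq Linker-cassette segment between UMI and genomic DNA on R2.
#' @param min_identity Minimum fraction of matching bases for the LTR and LC
#'   segment checks (computed over the full segment length).
#' @return An object of class `oligo_design`.
#' @examples
#' d <- oligo_design()
#' umi_space_size(d) # 16777216 possible UMIs
#' @export
oligo_design <- function(random_prefix_len = 12L,
                         barcode_len = 8L,
                         ltr_seq = "ACCCTTTTAGTCAGTGTGGAAAATCTCTAGCA",
                         lc1_seq = "AGTGGCACAGCAGTTAGGACTCGATCCTA",
                         anchor_seq = "GTAAGG",
                         umi_flank_len = 6L,
                         lc2_seq = "CTAGAGGATCCTTGAACGCT",
                         min_identity = 0.90) {
  stopifnot(
    random_prefix_len >= 0, barcode_len > 0,
    nchar(ltr_seq) > 0, nchar(lc1_seq) > 0, nchar(lc2_seq) > 0,
    nchar(anchor_seq) > 0, umi_flank_len > 0,
    min_identity > 0, min_identity <= 1
  )
  d <- structure(
    list(
      random_prefix_len = as.integer(random_prefix_len),
      barcode_len = as.integer(barcode_len),
      ltr_seq = toupper(ltr_seq),
      lc1_seq = toupper(lc1_seq),
      anchor_seq = toupper(anchor_seq),
      umi_flank_len = as.integer(umi_flank_len),
      lc2_seq = toupper(lc2_seq),
      min_identity = min_identity
    ),
    class = "oligo_design"
  )
  d
}

#' @export
print.oligo_design <- function(x, ...) {
  cat("<oligo_design>\n")
  cat(sprintf("  R1: random(%d) + barcode(%d) + LTR(%d) + genomic\n",
              x$random_prefix_len, x$barcode_len, nchar(x$ltr_seq)))
  cat(sprintf("  R2: random(%d) + barcode(%d) + LC1(%d) + UMI(%d) + LC2(%d) + genomic\n",
              x$random_prefix_len, x$barcode_len, nchar(x$lc1_seq),
              umi_length(x), nchar(x$lc2_seq)))
  cat(sprintf("  UMI: %dnt flank + anchor %s + %dnt flank; min identity %.2f\n",
              x$umi_flank_len, x$anchor_seq, x$umi_flank_len, x$min_identity))
  invisible(x)
}

#' Total UMI length implied by a design
#' @param design An [oligo_design()].
#' @return Integer, `2 * umi_flank_len + nchar(anchor_seq)` (18 by default).
#' @export
umi_length <- function(design) {
  2L * design$umi_flank_len + nchar(design$anchor_seq)
}

#' Number of distinct UMIs a design can produce
#'
#' Only the two random flanks vary, so the space is `4^(2 * umi_flank_len)`
#' (16,777,216 for the default 6 nt flanks).
#'
#' @param design An [oligo_design()].
#' @return A double (the space exceeds integer range for flanks > 7 nt).
#' @export
umi_space_size <- function(design) {
  4^(2 * design$umi_flank_len)
}

# 0-based offset of the first genomic base on R1 / R2 for a clean read.
genomic_offset_r1 <- function(design) {
  design$random_prefix_len + design$barcode_len + nchar(design$ltr_seq)
}
genomic_offset_r2 <- function(design) {
  design$random_prefix_len + design$barcode_len + nchar(design$lc1_seq) +
    umi_length(design) + nchar(design$lc2_seq)
}

#' Fold change equivalent to a log2 fold-change cutoff
#'
#' Differential-expression practice calls genes at `|log2 FC| >= 1.5`, i.e. a
#' fold change of `2^1.5 = 2.83`. Integration-site read counts across the
#' genome follow a similarly overdispersed (negative-binomial-like)
#' distribution, which motivates a fold-change rule for resolving cross-group
#' collisions; the default in [resolve_collisions()] is a deliberately more
#' conservative 10.
#'
#' @param log2fc Log2 fold-change cutoff (default 1.5).
#' @return The equivalent linear fold change.
#' @examples
#' round(collision_fold_reference(), 2) # 2.83
#' @export
collision_fold_reference <- function(log2fc = 1.5) {
  2^log2fc
}
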