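# Independent brute-force oracles and small fixture builders used across
# the test files. These deliberately share no code with the implementation.

oracle_bases <- c("A", "C", "G", "T")

random_seq <- function(len) {
  paste(sample(oracle_bases, len, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# Substitute the bases of `seq` at 1-based positions `at` with different
# bases (deterministic: next base in the alphabet).
substitute_at <- function(seq, at) {
  b <- strsplit(seq, "")[[1]]
  nxt <- c(A = "C", C = "G", G = "T", T = "A")
  b[at] <- nxt[b[at]]
  paste(b, collapse = "")
}

# Exhaustive semi-global alignment oracle: score-optimal alignment of the
# full `ref` against any region of `read` (free read ends), unit
# match/mismatch scoring and a linear gap cost of 2 per gap base (the same
# scoring the implementation uses). Returns the number of matched bases of
# the score-optimal alignment and its end position in the read.
oracle_semiglobal <- function(read, ref, gap = 2) {
  r <- strsplit(read, "")[[1]]
  q <- strsplit(ref, "")[[1]]
  n <- length(r); m <- length(q)
  # dp[i+1, j+1]: best (score, matches) aligning ref[1..j] ending at read i
  score <- matrix(-Inf, n + 1, m + 1)
  matches <- matrix(0L, n + 1, m + 1)
  score[, 1] <- 0  # free start in read; ref fully consumed column-wise
  for (j in 1:m) {
    score[1, j + 1] <- score[1, j] - gap  # ref base gapped before read
    for (i in 1:n) {
      cand_score <- c(
        score[i, j] + if (r[i] == q[j]) 1 else -1,  # (mis)match
        score[i, j + 1] - gap,                      # gap: consume read base
        score[i + 1, j] - gap                       # gap: skip ref base
      )
      cand_match <- c(matches[i, j] + (r[i] == q[j]),
                      matches[i, j + 1], matches[i + 1, j])
      best <- max(cand_score)
      score[i + 1, j + 1] <- best
      # among score-optimal paths, report the one with most matches
      matches[i + 1, j + 1] <- max(cand_match[cand_score == best])
    }
  }
  # free read end: best score over all read end positions at full ref
  i_best <- which.max(score[, m + 1])
  list(matches = matches[i_best, m + 1], match_end = i_best - 1L,
       score = max(score[, m + 1]))
}

# Brute-force mapper: scan every position on both strands of every
# chromosome, count ungapped matches of the full read, return the best
# locus/loci.
oracle_map <- function(read, genome_chars) {
  len <- nchar(read)
  rc <- revcomp_chr(read)
  best <- NULL
  for (ch in names(genome_chars)) {
    chr <- genome_chars[[ch]]
    L <- nchar(chr)
    if (L < len) next
    starts <- 1:(L - len + 1)
    wins <- substring(chr, starts, starts + len - 1)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") read else rc
      mm <- vapply(wins, function(w) {
        sum(charToRaw(w) == charToRaw(q))
      }, integer(1), USE.NAMES = FALSE)
      cand <- data.frame(chrom = ch, strand = strand, start0 = starts - 1L,
                         matches = mm)
      best <- rbind(best, cand)
    }
  }
  best[order(-best$matches, best$chrom, best$start0, best$strand), ]
}

# Brute-force interval membership: does 1-based position p fall in any
# 0-based half-open interval on its chromosome?
oracle_in_interval <- function(chrom, pos1, intervals) {
  any(intervals$chrom == chrom &
        intervals$start < pos1 & pos1 <= intervals$end)
}

# Brute-force symmetric Procrustes for 2-column matrices: grid over the
# rotation angle (with and without reflection), optimal scaling in closed
# form, on centred unit-Frobenius configurations.
oracle_procrustes_2col <- function(X, Y, n_grid = 200000) {
  norm_cfg <- function(M) {
    M <- scale(M, center = TRUE, scale = FALSE)
    M / sqrt(sum(M^2))
  }
  Xn <- norm_cfg(X); Yn <- norm_cfg(Y)
  best <- Inf
  for (refl in c(1, -1)) {
    Yr <- Yn %*% diag(c(1, refl))
    for (th in seq(0, 2 * pi, length.out = n_grid)) {
      R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
      ip <- sum(Xn * (Yr %*% R))
      ss <- 1 - max(ip, 0)^2  # optimal scale c = <Xn, YnR>
      if (ss < best) best <- ss
    }
  }
  best
}

# A tiny association table with two samples in two groups.
two_sample_association <- function() {
  tibble::tibble(
    sample_id = c("S1", "S2"),
    ltr_barcode = c("ACGTACGT", "GGTTCCAA"),
    lc_barcode = c("TGCATGCA", "CCAAGGTT"),
    group_id = c("G1", "G2")
  )
}

# Hand-built junction events for merge/quantify tests.
events_tbl <- function(pos, reads_per_pos = 1L, chrom = "chr1",
                       strand = "+", sample_id = "S1", group_id = "G1",
                       umi = NULL, fragment_len = NULL) {
  pos <- rep(pos, rep_len(reads_per_pos, length(pos)))
  n <- length(pos)
  tibble::tibble(
    read_id = paste0("r", seq_len(n)),
    sample_id = sample_id,
    group_id = group_id,
    chrom = chrom,
    strand = strand,
    junction_pos = as.integer(pos),
    fragment_len = if (is.null(fragment_len))
      as.integer(200 + seq_len(n)) else as.integer(fragment_len),
    umi = if (is.null(umi)) paste0("UMI", seq_len(n)) else umi,
    match_len_r1 = 100L,
    mapq_r1 = 60L
  )
}
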