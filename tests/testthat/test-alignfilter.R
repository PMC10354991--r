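make_test_genome <- function(seed = 101, lens = c(gA = 12000, gB = 10000),
                             dup = FALSE) {
  withr::with_seed(seed, {
    chroms <- vapply(lens, function(l) random_seq(l), character(1))
  })
  if (dup) {
    # plant an exact 2 kb duplication across the two chromosomes
    seg <- substr(chroms[[1]], 3001, 5000)
    chroms[[2]] <- paste0(substr(chroms[[2]], 1, 4000), seg,
                          substr(chroms[[2]], 6001, nchar(chroms[[2]])))
  }
  Biostrings::DNAStringSet(chroms)
}

test_that("built-in mapper places unique substrings on both strands", {
  g <- make_test_genome()
  chr <- as.character(g[["gA"]])
  read_plus <- substr(chr, 2001, 2100)
  read_minus <- revcomp_chr(substr(chr, 5001, 5100))
  aln <- builtin_map(
    tibble::tibble(read_id = c("p", "m"),
                   seq = c(read_plus, read_minus)), g
  )
  expect_identical(aln$chrom, c("gA", "gA"))
  expect_identical(aln$strand, c("+", "-"))
  expect_identical(aln$start, c(2000L, 5000L))
  expect_identical(aln$end, c(2100L, 5100L))
  expect_identical(aln$mapq, c(60L, 60L))
  expect_identical(aln$genomic_match_len, c(100L, 100L))
})

test_that("reads from a duplicated segment map with MAPQ 0", {
  g <- make_test_genome(dup = TRUE)
  read <- substr(as.character(g[["gA"]]), 3501, 3600)  # inside duplication
  aln <- builtin_map(tibble::tibble(read_id = "d", seq = read), g)
  expect_identical(aln$mapq, 0L)
  expect_identical(aln$chrom, "gA")  # deterministic first-locus tie-break
  expect_identical(aln$start, 3500L)
})

test_that("built-in mapper agrees with the brute-force all-positions scan", {
  g <- make_test_genome(seed = 57, lens = c(gA = 9000, gB = 7000) * 2)
  gc <- setNames(as.character(g), names(g))
  withr::with_seed(77, {
    reads <- lapply(1:25, function(i) {
      ch <- sample(names(gc), 1)
      st <- sample(nchar(gc[[ch]]) - 120, 1)
      seq <- substr(gc[[ch]], st, st + 99)
      if (i %% 3 == 0) seq <- revcomp_chr(seq)
      if (i %% 4 == 0) seq <- substitute_at(seq, sample(60:99, 5))
      if (i %% 7 == 0) seq <- random_seq(100)  # unmappable
      seq
    })
  })
  reads_tbl <- tibble::tibble(read_id = paste0("q", seq_along(reads)),
                              seq = unlist(reads))
  aln <- builtin_map(reads_tbl, g)
  for (i in seq_len(nrow(reads_tbl))) {
    want <- oracle_map(reads_tbl$seq[i], gc)
    got <- aln[aln$read_id == reads_tbl$read_id[i], ]
    if (nrow(got) == 0) {
      # unmapped: no locus reaches the extension identity floor
      expect_lt(want$matches[1] / 100, 0.75)
    } else {
      expect_identical(got$chrom, want$chrom[1])
      expect_identical(got$start, want$start0[1])
      expect_identical(got$strand, want$strand[1])
      expect_identical(got$matches, want$matches[1])
    }
  }
})

test_that("SAM ingest parses CIGAR spans and skips non-primary records", {
  d <- withr::local_tempdir()
  sam <- file.path(d, "toy.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:gA\tLN:12000",
    paste("r1_UMI:ACGTACGTAAGGTTGGCC", 0, "gA", 500, 60, "100M", "*", 0, 0,
          strrep("A", 100), strrep("I", 100), sep = "\t"),
    paste("r2", 16, "gA", 700, 37, "20S80M", "*", 0, 0,
          strrep("C", 100), strrep("I", 100), sep = "\t"),
    paste("r3", 2048, "gA", 900, 60, "50M50S", "*", 0, 0,
          strrep("G", 100), strrep("I", 100), sep = "\t"),  # supplementary
    paste("r4", 256, "gA", 950, 60, "100M", "*", 0, 0,
          "*", "*", sep = "\t")                             # secondary
  ), sam)
  aln <- ingest_sam(sam)
  expect_identical(nrow(aln), 2L)

  a1 <- aln[aln$read_id == "r1", ]
  expect_identical(a1$start, 499L)
  expect_identical(a1$end, 599L)
  expect_identical(a1$genomic_match_len, 100L)
  expect_identical(a1$umi, "ACGTACGTAAGGTTGGCC")
  expect_true(a1$is_r1)

  a2 <- aln[aln$read_id == "r2", ]
  expect_identical(a2$genomic_match_len, 80L)
  expect_identical(a2$clip5, 20L)
  expect_identical(a2$strand, "-")
})

test_that("MAPQ gate applies only to repeat-overlapping alignments", {
  repeats <- tibble::tibble(chrom = "gA", start = 1000L, end = 2000L,
                            label = "rpt", role = "repeat")
  alns <- tibble::tibble(
    read_id = c("free_lowq", "rep_highq", "rep_lowq"),
    chrom = "gA",
    start = c(5000L, 1500L, 1200L),
    end = c(5100L, 1600L, 1300L),
    mapq = c(0L, 60L, 0L)
  )
  kept <- mapq_repeat_filter(alns, repeats, mapq_min = 12)
  expect_setequal(kept$read_id, c("free_lowq", "rep_highq"))

  # global mode gates everything
  kept_g <- mapq_repeat_filter(alns, repeats, mapq_min = 12,
                               mode = "global")
  expect_identical(kept_g$read_id, "rep_highq")

  # no repeat annotation: identity
  expect_identical(nrow(mapq_repeat_filter(alns, NULL, 12)), 3L)
})

test_that("junction check demands 3 perfect reference-consuming bases", {
  g <- make_test_genome()
  chr <- as.character(g[["gA"]])
  base <- tibble::tibble(
    read_id = "x", chrom = "gA", strand = "+",
    start = 4000L, end = 4100L, clip5 = 0L, clip3 = 0L,
    m_first = 100L, m_last = 100L,
    query_fwd = substr(chr, 4001, 4100)
  )
  expect_true(junction_3nt_check(base, g))

  sub2 <- base
  sub2$query_fwd <- substitute_at(sub2$query_fwd, 2)
  expect_false(junction_3nt_check(sub2, g))

  # substitution beyond the first 3 bases does not affect the junction
  sub9 <- base
  sub9$query_fwd <- substitute_at(sub9$query_fwd, 9)
  expect_true(junction_3nt_check(sub9, g))

  clip <- base
  clip$clip5 <- 1L
  expect_false(junction_3nt_check(clip, g))

  # minus strand: the junction end is the reference END of the span
  minus <- base
  minus$strand <- "-"
  expect_true(junction_3nt_check(minus, g))
  minus_bad <- minus
  minus_bad$query_fwd <- substitute_at(minus_bad$query_fwd, 99)
  expect_false(junction_3nt_check(minus_bad, g))
  minus_clip <- minus
  minus_clip$clip3 <- 2L
  expect_false(junction_3nt_check(minus_clip, g))
})

test_that("filter60 is a >= 60 bp boundary", {
  expect_identical(filter60(c(59L, 60L, 250L)), c(FALSE, TRUE, TRUE))
})

test_that("junction events encode the junction/shear-site geometry", {
  r1 <- tibble::tibble(
    read_id = c("a", "b", "c"),
    sample_id = "S1", group_id = "G1", umi = "U",
    chrom = c("gA", "gA", "gA"),
    strand = c("+", "-", "+"),
    start = c(1000L, 2000L, 3000L),
    end = c(1250L, 2250L, 3250L),
    genomic_match_len = 250L, mapq = 60L
  )
  r2 <- tibble::tibble(
    read_id = c("a", "b", "c"),
    chrom = c("gA", "gA", "gB"),  # c: discordant chromosome
    strand = c("-", "+", "-"),
    start = c(1730L, 1400L, 3700L),
    end = c(1980L, 1650L, 3950L)
  )
  ev <- to_junction_events(r1, r2)
  expect_identical(nrow(ev), 2L)

  a <- ev[ev$read_id == "a", ]
  expect_identical(a$junction_pos, 1001L)
  expect_identical(a$strand, "+")
  expect_identical(a$fragment_len, 980L)

  b <- ev[ev$read_id == "b", ]
  expect_identical(b$junction_pos, 2250L)
  expect_identical(b$strand, "-")
  expect_identical(b$fragment_len, 850L)

  expect_identical(attr(ev, "drops")[["discordant_chrom"]], 1L)
})

test_that("noise-free simulation reproduces truth junctions and fragments", {
  sim <- simulate_library(seed = 3, n_sites = 3, alloc = c(12, 8, 6))
  res <- call_sites(sim$library, sim$association, sim$genome)
  ev <- res$events
  truth_pos <- setNames(sim$truth$pos, sim$truth$site_id)
  truth_strand <- setNames(sim$truth$strand, sim$truth$site_id)
  m <- match(ev$read_id, sim$read_map$id)
  expect_false(anyNA(m))
  sid <- sim$read_map$site_id[m]
  expect_identical(ev$junction_pos, unname(truth_pos[sid]))
  expect_identical(ev$strand, unname(truth_strand[sid]))
  expect_identical(ev$fragment_len, sim$read_map$fragment_len[m])
  expect_identical(ev$umi, sim$read_map$umi[m])
  # funnel conservation: events out <= pairs in, with every drop accounted
  expect_lte(nrow(ev), nrow(sim$library))
})
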