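design <- oligo_design()

test_that("random-prefix stripping removes n bases or flags short reads", {
  r <- strip_random_prefix(strrep("A", 250), strrep("I", 250), 12)
  expect_identical(nchar(r$seq), 238L)
  expect_identical(nchar(r$qual), 238L)
  expect_false(r$too_short)

  r0 <- strip_random_prefix("ACGT", "IIII", 0)
  expect_identical(r0$seq, "ACGT")

  rs <- strip_random_prefix(strrep("A", 10), strrep("I", 10), 12)
  expect_true(rs$too_short)
})

test_that("segment identity is matches over full segment length", {
  ltr <- design$ltr_seq  # 32 nt
  tail <- random_seq_fixed <- withr::with_seed(7, random_seq(80))

  exact <- match_segment(paste0(ltr, tail), ltr)
  expect_true(exact$matched)
  expect_equal(exact$identity, 1.0)
  expect_identical(exact$match_end, 32L)

  # 3 substitutions: 29/32 = 0.906 >= 0.9 -> matched
  m3 <- match_segment(paste0(substitute_at(ltr, c(5, 15, 25)), tail), ltr)
  expect_true(m3$matched)
  expect_equal(m3$identity, 29 / 32)

  # 4 substitutions: 0.875 < 0.9 -> not matched
  m4 <- match_segment(paste0(substitute_at(ltr, c(5, 10, 15, 25)), tail),
                      ltr)
  expect_false(m4$matched)
  expect_equal(m4$identity, 28 / 32)

  # truncated segment: missing bases count against the identity
  mtr <- match_segment(substr(ltr, 1, 20), ltr)
  expect_equal(mtr$identity, 20 / 32)
  expect_false(mtr$matched)
})

test_that("semi-global fallback agrees with the exhaustive DP oracle", {
  withr::with_seed(23, {
    ref <- random_seq(20)
    for (rep in 1:30) {
      read <- paste0(ref, random_seq(30))
      b <- strsplit(read, "")[[1]]
      # random edit: substitution, deletion or insertion inside the segment
      mode <- sample(c("sub", "del", "ins"), 1)
      at <- sample(2:15, 1)
      if (mode == "sub") {
        read <- substitute_at(read, at)
      } else if (mode == "del") {
        read <- paste(b[-at], collapse = "")
      } else {
        read <- paste(c(b[1:at], sample(oracle_bases, 1),
                        b[(at + 1):length(b)]), collapse = "")
      }
      got <- match_segment(read, ref, min_identity = 0.99,
                           fallback_band = 0)
      want <- oracle_semiglobal(read, ref)
      expect_equal(got$identity, want$matches / nchar(ref),
                   info = paste(mode, "edit at", at))
    }
  })
})

test_that("match identity is invariant under alphabet complementation", {
  withr::with_seed(41, {
    for (rep in 1:10) {
      ref <- random_seq(24)
      read <- substitute_at(paste0(ref, random_seq(40)),
                            sample(1:24, sample(0:5, 1)))
      a <- match_segment(read, ref, min_identity = 0.99, fallback_band = 0)
      b <- match_segment(chartr("ACGT", "TGCA", read),
                         chartr("ACGT", "TGCA", ref),
                         min_identity = 0.99, fallback_band = 0)
      expect_equal(a$identity, b$identity)
    }
  })
})

test_that("demultiplexing requires both barcodes from the same sample", {
  samples <- two_sample_association()
  expect_identical(
    demultiplex("ACGTACGT", "TGCATGCA", samples), "S1"
  )
  expect_identical(
    demultiplex("ACGTACGT", "AAAAAAAA", samples), NA_character_
  )
  # LTR barcode of S1 with LC barcode of S2: unassigned
  expect_identical(
    demultiplex("ACGTACGT", "CCAAGGTT", samples), NA_character_
  )
  # optional mismatch tolerance assigns near-misses uniquely
  expect_identical(
    demultiplex("ACGTACGA", "TGCATGCA", samples, max_mismatch = 1), "S1"
  )
})

test_that("anchored UMI extraction demands a perfect anchor at its locus", {
  ok <- extract_umi(paste0("ACGTAC", "GTAAGG", "TTGGCC",
                           design$lc2_seq, "ACGTACGT"), design)
  expect_identical(ok$umi, "ACGTACGTAAGGTTGGCC")
  expect_false(ok$anchor_fail)

  bad <- extract_umi(paste0("ACGTAC", "GTAAGC", "TTGGCC",
                            design$lc2_seq), design)
  expect_true(bad$anchor_fail)

  # a chance anchor occurrence downstream does not displace the expected
  # locus: the batch-modal position is the designed offset
  batch <- c(
    paste0("ACGTAC", "GTAAGG", "TTGGCC", design$lc2_seq, "GTAAGGAAA"),
    paste0("CCCAAA", "GTAAGG", "GGGTTT", design$lc2_seq, "ACGTACGTA"),
    paste0("TTTCCC", "GTAAGG", "AAAGGG", design$lc2_seq, "ACGTACGTA")
  )
  got <- extract_umi(batch, design)
  expect_false(any(got$anchor_fail))
  expect_identical(got$umi[1], "ACGTACGTAAGGTTGGCC")
  expect_identical(attr(got, "anchor_locus"), 7L)
})

test_that("a wrapped clean pair is recovered exactly at the design offsets", {
  samples <- two_sample_association()
  withr::with_seed(13, {
    gpairs <- tibble::tibble(
      id = c("p1", "p2"),
      genomic_r1 = c(random_seq(198), random_seq(198)),
      genomic_r2 = c(random_seq(163), random_seq(163)),
      umi = c(paste0("AAATTT", design$anchor_seq, "CCGGCC"),
              paste0("GGGCCC", design$anchor_seq, "TTAATT"))
    )
  })
  wrapped <- sim_wrap_oligo(gpairs, design, samples$ltr_barcode[1],
                            samples$lc_barcode[1], seed = 2)
  # genomic payloads sit at the documented raw offsets: 52 on R1, 87 on R2
  expect_identical(substr(wrapped$r1_seq, 53, nchar(wrapped$r1_seq)),
                   gpairs$genomic_r1)
  expect_identical(substr(wrapped$r2_seq, 88, nchar(wrapped$r2_seq)),
                   gpairs$genomic_r2)

  proc <- process_reads(
    dplyr::select(wrapped, "id", "r1_seq", "r1_qual", "r2_seq", "r2_qual"),
    samples, design
  )
  expect_true(all(is.na(proc$rejection)))
  expect_identical(proc$sample_id, c("S1", "S1"))
  expect_identical(proc$genomic_r1, gpairs$genomic_r1)
  expect_identical(proc$genomic_r2, gpairs$genomic_r2)
  expect_identical(proc$umi, gpairs$umi)
})

test_that("processing is first-fail with conserved counts", {
  samples <- two_sample_association()
  withr::with_seed(17, {
    base <- tibble::tibble(
      id = "ok",
      genomic_r1 = random_seq(150), genomic_r2 = random_seq(150),
      umi = paste0("ACACAC", design$anchor_seq, "GTGTGT")
    )
  })
  clean <- sim_wrap_oligo(base, design, samples$ltr_barcode[1],
                          samples$lc_barcode[1], seed = 3)

  # degrade copies of the clean read at successive stages
  ltr_bad <- clean
  ltr_bad$id <- "ltr_bad"
  pre <- design$random_prefix_len + design$barcode_len
  ltr_bad$r1_seq <- paste0(
    substr(ltr_bad$r1_seq, 1, pre),
    substitute_at(substr(ltr_bad$r1_seq, pre + 1, pre + 32),
                  c(2, 9, 16, 23)),  # identity 0.875 < 0.9
    substr(ltr_bad$r1_seq, pre + 33, nchar(ltr_bad$r1_seq))
  )

  anchor_bad <- clean
  anchor_bad$id <- "anchor_bad"
  a_at <- pre + nchar(design$lc1_seq) + design$umi_flank_len + 1
  anchor_bad$r2_seq <- paste0(
    substr(anchor_bad$r2_seq, 1, a_at - 1),
    "GTAAGC",
    substr(anchor_bad$r2_seq, a_at + 6, nchar(anchor_bad$r2_seq))
  )

  unassigned <- clean
  unassigned$id <- "unassigned"
  unassigned$r1_seq <- paste0(substr(unassigned$r1_seq, 1, 12), "AAAAAAAA",
                              substr(unassigned$r1_seq, 21,
                                     nchar(unassigned$r1_seq)))

  short <- tibble::tibble(
    id = "short", r1_seq = strrep("A", 40), r1_qual = strrep("I", 40),
    r2_seq = strrep("A", 40), r2_qual = strrep("I", 40)
  )

  cols <- c("id", "r1_seq", "r1_qual", "r2_seq", "r2_qual")
  batch <- dplyr::bind_rows(
    dplyr::select(clean, dplyr::all_of(cols)),
    dplyr::select(ltr_bad, dplyr::all_of(cols)),
    dplyr::select(anchor_bad, dplyr::all_of(cols)),
    dplyr::select(unassigned, dplyr::all_of(cols)),
    short
  )
  proc <- process_reads(batch, samples, design)
  got <- setNames(proc$rejection, proc$id)
  expect_identical(got[["ltr_bad"]], "ltr_fail")
  expect_identical(got[["anchor_bad"]], "anchor_fail")
  expect_identical(got[["unassigned"]], "unassigned")
  expect_identical(got[["short"]], "too_short")
  expect_true(is.na(got[["ok"]]))

  funnel <- rejection_funnel(proc)
  n_in <- funnel$n[funnel$stage == "input"]
  expect_identical(
    sum(funnel$n[!funnel$stage %in% c("input", "survivors")]) +
      funnel$n[funnel$stage == "survivors"],
    n_in
  )
})

test_that("zero-noise simulator output survives 100% with UMI bijection", {
  sim <- simulate_library(seed = 19, n_sites = 2, alloc = c(15, 10))
  proc <- process_reads(sim$library, sim$association, sim$design)
  expect_true(all(is.na(proc$rejection)))
  m <- match(proc$id, sim$read_map$id)
  expect_false(anyNA(m))
  expect_identical(proc$umi, sim$read_map$umi[m])
})
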