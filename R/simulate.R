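# Ground-truthed library simulator. Emulates the wet-lab read anatomy end to
# end: sonication fragment lengths, oligo wrapping (prefix + barcode + LTR on
# R1; prefix + barcode + LC1 + UMI + LC2 on R2), targeted junction mutations,
# random background reads, PCR duplication, and UMI pools of controlled
# entropy. Everything is reproducible from (config, seed).

#' Generate a seeded synthetic reference genome
#'
#' Random uniform-composition chromosomes standing in for a real reference
#' at desk scale. An exact duplicated segment can be planted to emulate
#' repetitive regions and multi-mapping.
#'
#' @param lengths Named integer vector of chromosome lengths (>= 10 kb each).
#' @param seed Integer seed.
#' @param duplication Optional list
#'   `list(from = chrom, from_start = pos, to = chrom, to_start = pos,
#'   len = n)` (1-based): copies `len` bases so the two segments are
#'   identical.
#' @return A named `DNAStringSet`.
#' @export
sim_genome <- function(lengths = c(chrA = 120000L, chrB = 80000L),
                       seed = 1L, duplication = NULL) {
  if (length(lengths) == 0) stop("need at least one chromosome", call. = FALSE)
  stopifnot(all(lengths >= 10000))
  if (is.null(names(lengths))) {
    names(lengths) <- paste0("chr", seq_along(lengths))
  }
  chroms <- withr::with_seed(seed, {
    vapply(lengths, function(l) {
      paste(sample(DNA_BASES, l, replace = TRUE), collapse = "")
    }, character(1))
  })
  if (!is.null(duplication)) {
    d <- duplication
    seg <- substr(chroms[[d$from]], d$from_start, d$from_start + d$len - 1L)
    target <- chroms[[d$to]]
    chroms[[d$to]] <- paste0(
      substr(target, 1L, d$to_start - 1L), seg,
      substr(target, d$to_start + d$len, nchar(target))
    )
  }
  Biostrings::DNAStringSet(chroms)
}

#' Draw ground-truth integration sites
#'
#' Site counts are allocated to chromosomes proportionally to their lengths
#' (largest-remainder rounding); positions are uniform with a minimum
#' pairwise distance and an edge margin wide enough for the longest
#' sonication fragment; strands are fair coin flips. Alternatively, pass
#' explicit `sites` to pin positions (e.g. inside a duplicated segment).
#'
#' @param genome Named `DNAStringSet`.
#' @param n_sites Number of sites.
#' @param seed Integer seed.
#' @param alloc Read pairs per site (recycled; default 100 each).
#' @param min_dist Minimum pairwise distance between sites on a chromosome.
#' @param margin Distance kept from both contig edges (>= maximum fragment
#'   length so every fragment fits).
#' @param sites Optional tibble with `chrom`, `pos` (1-based junction),
#'   `strand` to use instead of random placement.
#' @return Truth tibble: `site_id`, `chrom`, `strand`, `pos`, `alloc`,
#'   `expected_pct` (summing to 100).
#' @export
sim_truth_sites <- function(genome, n_sites = 1L, seed = 1L, alloc = 100L,
                            min_dist = 1000L, margin = 3100L, sites = NULL) {
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  if (is.null(sites)) {
    stopifnot(n_sites >= 1)
    counts <- allocate_proportional(lens, n_sites)
    capacity <- pmax(0, (lens - 2 * margin) %/% min_dist + 1)
    if (any(counts > capacity)) {
      stop("n_sites exceeds capacity at the requested minimum distance",
           call. = FALSE)
    }
    sites <- withr::with_seed(seed, {
      dplyr::bind_rows(lapply(names(counts), function(ch) {
        k <- counts[[ch]]
        if (k == 0) return(NULL)
        lo <- margin + 1L
        hi <- lens[[ch]] - margin
        pos <- integer(0)
        tries <- 0L
        while (length(pos) < k) {
          cand <- sample.int(hi - lo + 1L, 1L) + lo - 1L
          if (all(abs(cand - pos) >= min_dist)) pos <- c(pos, cand)
          tries <- tries + 1L
          if (tries > 1000L * k) {
            stop("could not place sites at the requested minimum distance",
                 call. = FALSE)
          }
        }
        new_tbl(chrom = ch, pos = sort(pos),
                strand = sample(c("+", "-"), k, replace = TRUE))
      }))
    })
  } else {
    sites <- tibble::as_tibble(sites)
    stopifnot(all(c("chrom", "pos", "strand") %in% names(sites)))
    n_sites <- nrow(sites)
  }
  alloc <- rep_len(as.integer(alloc), n_sites)
  dplyr::mutate(
    sites,
    site_id = paste0("IS", seq_len(n_sites)),
    alloc = alloc,
    expected_pct = 100 * alloc / sum(alloc),
    .before = 1
  )
}

# Largest-remainder apportionment of n among weights.
allocate_proportional <- function(weights, n) {
  q <- n * weights / sum(weights)
  base <- floor(q)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(q - base, weights, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

#' Synthesize genomic read pairs from truth sites
#'
#' Per read pair, a sonication fragment length is drawn from a truncated
#' Normal and the fragment is laid from the junction into the genome on the
#' strand-appropriate side. R1 is the first `read_len` bases from the
#' junction end; R2 is the reverse complement of the last `read_len` bases
#' (the shear end).
#'
#' @param truth Tibble from [sim_truth_sites()].
#' @param genome Named `DNAStringSet`.
#' @param seed Integer seed.
#' @param read_len Read length (default 250).
#' @param frag_mean,frag_sd Fragment-length Normal parameters (default
#'   1000 and 300).
#' @param frag_max Upper truncation (default 3000); the lower truncation is
#'   `read_len`.
#' @return Tibble of genomic pairs: `id`, `site_id`, `genomic_r1`,
#'   `genomic_r2`, `fragment_len`.
#' @export
sim_pairs <- function(truth, genome, seed = 1L, read_len = 250L,
                      frag_mean = 1000, frag_sd = 300, frag_max = 3000L) {
  chrom_chars <- stats::setNames(as.character(genome), names(genome))
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(nrow(truth)), function(i) {
      s <- truth[i, ]
      n <- s$alloc
      frag <- integer(0)
      while (length(frag) < n) {
        draw <- round(stats::rnorm(n, frag_mean, frag_sd))
        frag <- c(frag, draw[draw >= read_len & draw <= frag_max])
      }
      frag <- frag[seq_len(n)]
      chr <- chrom_chars[[s$chrom]]
      if (s$strand == "+") {
        r1 <- substring(chr, s$pos, s$pos + read_len - 1L)
        r2 <- dna_revcomp(substring(chr, s$pos + frag - read_len,
                                    s$pos + frag - 1L))
      } else {
        r1 <- dna_revcomp(substring(chr, s$pos - read_len + 1L, s$pos))
        r2 <- substring(chr, s$pos - frag + 1L, s$pos - frag + read_len)
      }
      new_tbl(
        id = sprintf("SIM%s_%d", s$site_id, seq_len(n)),
        site_id = s$site_id,
        genomic_r1 = r1, genomic_r2 = r2,
        fragment_len = as.integer(frag)
      )
    }))
  })
}

#' Build a UMI pool of chosen size or entropy
#'
#' The pool is a weighted set of distinct UMIs (random flanks around the
#' fixed anchor). Uniform weights give entropy `log2(size)` bits; with an
#' `entropy_target`, weights are tilted geometrically until the realized
#' entropy is within 0.01 bits of the target.
#'
#' @param size Number of distinct UMIs (<= `umi_space_size(design)`).
#' @param entropy_target Optional target Shannon entropy in bits
#'   (< `log2(size)`).
#' @param seed Integer seed.
#' @param design An [oligo_design()].
#' @return Tibble with `umi` and `weight` (summing to 1); realized entropy
#'   in attribute `entropy`.
#' @export
sim_umi_pool <- function(size, entropy_target = NULL, seed = 1L,
                         design = oligo_design()) {
  space <- umi_space_size(design)
  stopifnot(size >= 1, size <= space)
  idx <- withr::with_seed(seed, sample(space, size))
  umi <- encode_umi(idx - 1, design)
  if (is.null(entropy_target)) {
    w <- rep(1 / size, size)
  } else {
    if (entropy_target >= log2(size) || entropy_target < 0) {
      stop("entropy_target must be in [0, log2(size))", call. = FALSE)
    }
    ent_of <- function(lr) {  # geometric weights r^i on log scale
      lw <- lr * (seq_len(size) - 1)
      lw <- lw - max(lw)
      w <- exp(lw) / sum(exp(lw))
      w <- w[w > 0]
      -sum(w * log2(w))
    }
    lr <- stats::uniroot(function(x) ent_of(x) - entropy_target,
                         c(-20, -1e-9), tol = 1e-12)$root
    lw <- lr * (seq_len(size) - 1)
    lw <- lw - max(lw)
    w <- exp(lw) / sum(exp(lw))
    realized <- -sum(w * log2(w))
    if (abs(realized - entropy_target) > 0.01) {
      stop("could not reach target entropy within 0.01 bits", call. = FALSE)
    }
  }
  out <- new_tbl(umi = umi, weight = w)
  attr(out, "entropy") <- -sum(w * log2(w))
  out
}

# Map 0-based indices to UMI strings: index in base 4 spells the two flanks.
encode_umi <- function(idx0, design = oligo_design()) {
  flank_total <- 2L * design$umi_flank_len
  mat <- matrix("", nrow = length(idx0), ncol = flank_total)
  x <- idx0
  for (p in flank_total:1) {
    mat[, p] <- DNA_BASES[(x %% 4) + 1]
    x <- x %/% 4
  }
  flanks <- apply(mat, 1, paste, collapse = "")
  paste0(substr(flanks, 1L, design$umi_flank_len), design$anchor_seq,
         substr(flanks, design$umi_flank_len + 1L, flank_total))
}

#' Draw UMIs for a set of read pairs
#'
#' @param n Number of UMIs to draw.
#' @param pool Optional pool from [sim_umi_pool()]; `NULL` draws uniformly
#'   from the full UMI space (maximum diversity).
#' @param seed Integer seed.
#' @param design An [oligo_design()].
#' @return Character vector of UMIs.
#' @export
sim_draw_umis <- function(n, pool = NULL, seed = 1L,
                          design = oligo_design()) {
  withr::with_seed(seed, {
    if (is.null(pool)) {
      encode_umi(sample(umi_space_size(design), n, replace = TRUE) - 1,
                 design)
    } else {
      sample(pool$umi, n, replace = TRUE, prob = pool$weight)
    }
  })
}

#' Inject junction-proximal mutations into a fraction of pairs
#'
#' A seeded choice of `round(fraction * n)` pairs receives per-base
#' substitutions in the first `region_len` genomic bases of R1, at a
#' per-read rate drawn uniformly from `rate_range`; the three
#' junction-proximal bases are always altered, so mutated reads fail the
#' downstream junction check by construction.
#'
#' @param pairs Genomic pairs from [sim_pairs()].
#' @param fraction Fraction of pairs to mutate.
#' @param region_len Mutated window length (default 50).
#' @param rate_range Per-read mutation-rate range (default the
#'   0.4651163-0.9230769 band).
#' @param seed Integer seed.
#' @return `pairs` with mutated `genomic_r1` and a logical `mutated` column.
#' @export
sim_mutate <- function(pairs, fraction = 0.10, region_len = 50L,
                       rate_range = c(0.4651163, 0.9230769), seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  n <- nrow(pairs)
  pairs$mutated <- FALSE
  k <- round(fraction * n)
  if (k == 0) return(pairs)
  withr::with_seed(seed, {
    pick <- sample.int(n, k)
    rates <- stats::runif(k, rate_range[1], rate_range[2])
    for (j in seq_along(pick)) {
      i <- pick[j]
      seq <- pairs$genomic_r1[i]
      m <- min(region_len, nchar(seq))
      bases <- strsplit(substr(seq, 1, m), "")[[1]]
      hit <- stats::runif(m) < rates[j]
      hit[1:3] <- TRUE  # junction-proximal bases always altered
      bases[hit] <- vapply(bases[hit], function(b) {
        sample(setdiff(DNA_BASES, b), 1)
      }, character(1))
      pairs$genomic_r1[i] <- paste0(paste(bases, collapse = ""),
                                    substr(seq, m + 1, nchar(seq)))
    }
    pairs$mutated[pick] <- TRUE
  })
  pairs
}

#' PCR-duplicate a library
#'
#' Each pair is replicated `k` times with `k` uniform on `1..pcr_max_dup`.
#' Duplicates share the UMI and fragment length of their template but get
#' fresh read ids (and fresh random prefixes at wrapping time).
#'
#' @param pairs Genomic pairs (with `umi` already drawn).
#' @param pcr_max_dup Maximum duplication factor (>= 1; 1 is the identity).
#' @param seed Integer seed.
#' @return The amplified pairs tibble.
#' @export
sim_amplify_pcr <- function(pairs, pcr_max_dup = 1L, seed = 1L) {
  stopifnot(pcr_max_dup >= 1)
  if (pcr_max_dup == 1 || nrow(pairs) == 0) return(pairs)
  withr::with_seed(seed, {
    k <- sample.int(pcr_max_dup, nrow(pairs), replace = TRUE)
    out <- pairs[rep(seq_len(nrow(pairs)), k), , drop = FALSE]
    dup_no <- sequence(k)
    out$id <- ifelse(dup_no == 1, out$id,
                     paste0(out$id, ".dup", dup_no - 1L))
    tibble::as_tibble(out)
  })
}

#' Wrap genomic pairs in the full oligo structure
#'
#' Produces raw reads as sequenced: R1 = random prefix + LTR barcode + LTR +
#' genomic R1; R2 = random prefix + LC barcode + LC1 + UMI + LC2 + genomic
#' R2. Qualities are constant high.
#'
#' @param pairs Genomic pairs with a `umi` column.
#' @param design An [oligo_design()].
#' @param ltr_barcode,lc_barcode Sample barcodes.
#' @param seed Integer seed (for the random prefixes).
#' @return Tibble with `id`, `r1_seq`, `r1_qual`, `r2_seq`, `r2_qual` plus
#'   the provenance columns of `pairs`.
#' @export
sim_wrap_oligo <- function(pairs, design = oligo_design(),
                           ltr_barcode, lc_barcode, seed = 1L) {
  stopifnot("umi" %in% names(pairs))
  flank <- design$umi_flank_len
  anchor_at <- substr(pairs$umi, flank + 1L, flank + nchar(design$anchor_seq))
  if (any(anchor_at != design$anchor_seq | nchar(pairs$umi) !=
          umi_length(design))) {
    stop("malformed UMI: anchor missing at the expected offset",
         call. = FALSE)
  }
  n <- nrow(pairs)
  pre <- withr::with_seed(seed, {
    list(p1 = random_dna(n, design$random_prefix_len),
         p2 = random_dna(n, design$random_prefix_len))
  })
  r1 <- paste0(pre$p1, ltr_barcode, design$ltr_seq, pairs$genomic_r1)
  r2 <- paste0(pre$p2, lc_barcode, design$lc1_seq, pairs$umi,
               design$lc2_seq, pairs$genomic_r2)
  dplyr::mutate(
    pairs,
    r1_seq = r1, r1_qual = strrep("I", nchar(r1)),
    r2_seq = r2, r2_qual = strrep("I", nchar(r2))
  )
}

#' Generate random background read pairs
#'
#' Random sequence with no oligo structure (no LTR, no linker), emulating
#' off-target genomic noise; such pairs are rejected at the LTR gate and
#' must never produce a site.
#'
#' @param n Number of background pairs.
#' @param read_len Read length.
#' @param seed Integer seed.
#' @return Tibble in the raw-library layout (`id`, `r1_seq`, ...), with
#'   `site_id = NA`.
#' @export
sim_background <- function(n, read_len = 250L, seed = 1L) {
  if (n == 0) {
    return(new_tbl(id = character(0), site_id = character(0),
                   r1_seq = character(0), r1_qual = character(0),
                   r2_seq = character(0), r2_qual = character(0)))
  }
  withr::with_seed(seed, {
    new_tbl(
      id = sprintf("BG_%d", seq_len(n)),
      site_id = NA_character_,
      r1_seq = random_dna(n, read_len),
      r1_qual = strrep("I", read_len),
      r2_seq = random_dna(n, read_len),
      r2_qual = strrep("I", read_len)
    )
  })
}

#' Simulate a complete ground-truthed library
#'
#' Orchestrates the simulator: genome, truth sites, sonication pairs,
#' optional junction mutations, UMI draws, optional PCR duplication, oligo
#' wrapping, and background noise. All randomness derives from `seed`.
#'
#' @param seed Master seed.
#' @param genome_lengths Named chromosome lengths for [sim_genome()].
#' @param duplication Optional duplicated-segment spec for [sim_genome()].
#' @param n_sites,alloc,sites Site layout (see [sim_truth_sites()]).
#' @param design An [oligo_design()].
#' @param samples Association tibble; the library is wrapped with the FIRST
#'   sample's barcodes (one sample per simulated library).
#' @param read_len,frag_mean,frag_sd,frag_max Read/fragment geometry.
#' @param mutate_fraction,mutate_region_len,mutate_rate_range Junction
#'   mutation controls (fraction 0 disables).
#' @param umi_pool Optional [sim_umi_pool()]; `NULL` = maximal diversity.
#' @param pcr_max_dup PCR duplication cap (1 disables).
#' @param n_background Random background pairs to interleave.
#' @param out_dir Optional directory; when given, writes `R1.fastq.gz` /
#'   `R2.fastq.gz`, `truth.tsv`, `association.csv`, `genome.fa` and returns
#'   the paths in the result.
#' @return List with `library` (raw read-pair tibble), `truth`,
#'   `read_map` (read id to true site), `association`, `genome`, `design`,
#'   and `paths` when written.
#' @export
simulate_library <- function(seed = 1L,
                             genome_lengths = c(chrA = 120000L,
                                                chrB = 80000L),
                             duplication = NULL,
                             n_sites = 1L, alloc = 100L, sites = NULL,
                             design = oligo_design(),
                             samples = default_association(),
                             read_len = 250L, frag_mean = 1000,
                             frag_sd = 300, frag_max = 3000L,
                             mutate_fraction = 0, mutate_region_len = 50L,
                             mutate_rate_range = c(0.4651163, 0.9230769),
                             umi_pool = NULL, pcr_max_dup = 1L,
                             n_background = 0L, out_dir = NULL) {
  genome <- sim_genome(genome_lengths, seed = seed,
                       duplication = duplication)
  truth <- sim_truth_sites(genome, n_sites = n_sites, seed = seed + 1L,
                           alloc = alloc, margin = frag_max + 100L,
                           sites = sites)
  pairs <- sim_pairs(truth, genome, seed = seed + 2L, read_len = read_len,
                     frag_mean = frag_mean, frag_sd = frag_sd,
                     frag_max = frag_max)
  if (mutate_fraction > 0) {
    pairs <- sim_mutate(pairs, fraction = mutate_fraction,
                        region_len = mutate_region_len,
                        rate_range = mutate_rate_range, seed = seed + 3L)
  } else {
    pairs$mutated <- FALSE
  }
  pairs$umi <- sim_draw_umis(nrow(pairs), pool = umi_pool, seed = seed + 4L,
                             design = design)
  pairs <- sim_amplify_pcr(pairs, pcr_max_dup = pcr_max_dup,
                           seed = seed + 5L)
  wrapped <- sim_wrap_oligo(pairs, design = design,
                            ltr_barcode = samples$ltr_barcode[1],
                            lc_barcode = samples$lc_barcode[1],
                            seed = seed + 6L)
  bg <- sim_background(n_background, read_len = read_len, seed = seed + 7L)
  lib_cols <- c("id", "site_id", "r1_seq", "r1_qual", "r2_seq", "r2_qual")
  library_tbl <- dplyr::bind_rows(
    dplyr::select(wrapped, dplyr::all_of(lib_cols)),
    dplyr::select(bg, dplyr::all_of(lib_cols))
  )
  read_map <- dplyr::select(wrapped, "id", "site_id", "fragment_len",
                            "umi", dplyr::any_of("mutated"))
  out <- list(
    library = library_tbl,
    truth = truth,
    read_map = read_map,
    association = samples,
    genome = genome,
    design = design
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      r1 = file.path(out_dir, "R1.fastq.gz"),
      r2 = file.path(out_dir, "R2.fastq.gz"),
      truth = file.path(out_dir, "truth.tsv"),
      association = file.path(out_dir, "association.csv"),
      genome = file.path(out_dir, "genome.fa")
    )
    write_fastq_pairs(library_tbl, paths$r1, paths$r2)
    readr::write_tsv(truth, paths$truth, progress = FALSE)
    readr::write_csv(samples, paths$association, progress = FALSE)
    write_genome(genome, paths$genome)
    out$paths <- paths
  }
  out
}

#' Default single-sample association table for simulations
#' @return A one-row association tibble.
#' @export
default_association <- function() {
  new_tbl(
    sample_id = "S1",
    ltr_barcode = "ACGTACGT",
    lc_barcode = "TGCATGCA",
    group_id = "G1"
  )
}

#' Pinned simulation scenarios
#'
#' One-call versions of the six in-silico study designs used to validate the
#' caller: a clean single-site library of 2,924 pairs; the same with 10%
#' junction-mutated pairs; with random background added; a five-site design
#' (3,006 pairs to a dominant site, 251 to each of four minor sites, two of
#' them inside an exact 5 kb duplicated segment) with background; and
#' many-site designs (100 or 1000 sites) for PR/ROC evaluation.
#'
#' @param name Preset name (see Details).
#' @param seed Master seed.
#' @param n_background Background pairs for the `*-bg` presets (default
#'   100,000; the full-scale 17,274,461 of a MiSeq run is configurable but
#'   far beyond desk scale).
#' @param ... Overrides passed on to [simulate_library()].
#' @details
#' * `"single-clean"`: 1 site, 2,924 clean pairs.
#' * `"single-mutated"`: adds 10% junction mutations.
#' * `"single-mutated-bg"`: adds random background pairs.
#' * `"five-site-bg"`: 5 sites (3,006 + 4 x 251) on a genome with a
#'   duplicated segment, plus background.
#' * `"hundred-site"` / `"thousand-site"`: 100 / 1000 sites, equal
#'   allocations, on a genome scaled to hold them.
#' @return The [simulate_library()] result.
#' @export
simulate_preset <- function(name = c("single-clean", "single-mutated",
                                     "single-mutated-bg", "five-site-bg",
                                     "hundred-site", "thousand-site"),
                            seed = 1L, n_background = 100000L, ...) {
  name <- match.arg(name)
  args <- switch(
    name,
    "single-clean" = list(n_sites = 1L, alloc = 2924L),
    "single-mutated" = list(n_sites = 1L, alloc = 2924L,
                            mutate_fraction = 0.10),
    "single-mutated-bg" = list(n_sites = 1L, alloc = 2924L,
                               mutate_fraction = 0.10,
                               n_background = n_background),
    "five-site-bg" = list(
      duplication = list(from = "chrA", from_start = 20001L, to = "chrB",
                         to_start = 30001L, len = 5000L),
      sites = new_tbl(
        chrom = c("chrA", "chrA", "chrB", "chrA", "chrA"),
        pos = c(70001L, 90001L, 60001L, 22001L, 24501L),
        strand = c("+", "-", "+", "+", "-")
      ),
      alloc = c(3006L, 251L, 251L, 251L, 251L),
      n_background = n_background
    ),
    "hundred-site" = list(
      genome_lengths = c(chrA = 400000L, chrB = 300000L),
      n_sites = 100L, alloc = 30L
    ),
    "thousand-site" = list(
      genome_lengths = c(chrA = 4000000L, chrB = 3000000L),
      n_sites = 1000L, alloc = 10L
    )
  )
  do.call(simulate_library, utils::modifyList(args, c(list(seed = seed),
                                                      list(...))))
}
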