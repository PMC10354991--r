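# Site calling: greedy 7 bp merging of junction events, abundance
# quantification, cross-group collision resolution, vector masking, and
# nearest-gene annotation.

#' Merge junction events into integration sites within a window
#'
#' Greedy peak-absorb: the unmerged position with the highest total read
#' abundance (ties broken toward the lowest coordinate) becomes a site peak
#' and absorbs every unmerged position within `window` bp of it on the same
#' chromosome and strand; tallies sum. Iterates until no positions remain,
#' so output peaks on one (chrom, strand) are pairwise more than `window`
#' apart and re-merging is a no-op.
#'
#' @param events Junction-event tibble ([to_junction_events()]); one row per
#'   read.
#' @param window Merge window in bp (default 7).
#' @return The events tibble with `site_id` and `peak_pos` columns added.
#' @export
merge_within_window <- function(events, window = 7L) {
  stopifnot(window >= 0)
  if (nrow(events) == 0) {
    return(dplyr::mutate(events, site_id = character(0),
                         peak_pos = integer(0)))
  }
  assign_group <- function(pos) {
    tal <- dplyr::count(new_tbl(pos = pos), .data$pos, name = "ab")
    tal <- dplyr::arrange(tal, dplyr::desc(.data$ab), .data$pos)
    peak_of <- rep(NA_integer_, nrow(tal))
    taken <- rep(FALSE, nrow(tal))
    for (i in seq_len(nrow(tal))) {
      if (taken[i]) next
      absorb <- !taken & abs(tal$pos - tal$pos[i]) <= window
      peak_of[absorb] <- tal$pos[i]
      taken[absorb] <- TRUE
    }
    peak_of[match(pos, tal$pos)]
  }
  events |>
    dplyr::group_by(.data$chrom, .data$strand) |>
    dplyr::mutate(peak_pos = assign_group(.data$junction_pos)) |>
    dplyr::ungroup() |>
    dplyr::mutate(site_id = paste0(.data$chrom, ":", .data$strand, ":",
                                   .data$peak_pos))
}

#' Summarise merged events per site
#'
#' @param merged Output of [merge_within_window()].
#' @return One row per site: `site_id`, `chrom`, `strand`, `peak_pos`,
#'   `n_positions` (absorbed junction positions), `n_reads`, `n_umis`,
#'   `n_fragments` (distinct fragment lengths pooled over samples).
#' @export
site_summary <- function(merged) {
  merged |>
    dplyr::group_by(.data$site_id, .data$chrom, .data$strand,
                    .data$peak_pos) |>
    dplyr::summarise(
      n_positions = dplyr::n_distinct(.data$junction_pos),
      n_reads = dplyr::n(),
      n_umis = dplyr::n_distinct(.data$umi),
      n_fragments = dplyr::n_distinct(.data$fragment_len),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$peak_pos)
}

#' Quantify site abundance per sample
#'
#' Four readouts of clonal abundance:
#' * `reads` - raw read count (inflated by PCR duplication);
#' * `umi` - distinct UMIs, optionally collapsed at Hamming distance 1;
#' * `fragment` - distinct sonication fragment lengths (shear-site
#'   diversity); lengths never pool across samples;
#' * `fragment_mle` - the per-site progenitor estimate from the
#'   fragment-length maximum-likelihood model ([estimate_theta_mle()]),
#'   fitted per sample across its sites.
#'
#' @param merged Output of [merge_within_window()].
#' @param method One of `"reads"`, `"umi"`, `"fragment"`, `"fragment_mle"`.
#' @param umi_collapse `"exact"` (default) or `"hamming1"` directional
#'   collapse for the UMI readout.
#' @return A tidy abundance table: `site_id`, `chrom`, `strand`, `peak_pos`,
#'   `sample_id`, `group_id`, `abundance`, `rel_pct` (relative abundance,
#'   summing to 100 within each sample). Class `abundance_tbl`; the method is
#'   recorded in attribute `method`.
#' @export
quantify <- function(merged, method = c("reads", "umi", "fragment",
                                        "fragment_mle"),
                     umi_collapse = c("exact", "hamming1")) {
  method <- match.arg(method)
  umi_collapse <- match.arg(umi_collapse)
  key <- c("site_id", "chrom", "strand", "peak_pos", "sample_id", "group_id")
  grouped <- dplyr::group_by(merged, dplyr::across(dplyr::all_of(key)))
  ab <- switch(
    method,
    reads = dplyr::summarise(grouped, abundance = dplyr::n(),
                             .groups = "drop"),
    umi = dplyr::summarise(
      grouped,
      abundance = count_umis(.data$umi, umi_collapse),
      .groups = "drop"
    ),
    fragment = dplyr::summarise(
      grouped, abundance = dplyr::n_distinct(.data$fragment_len),
      .groups = "drop"
    ),
    fragment_mle = quantify_mle(merged, key)
  )
  ab <- ab |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(rel_pct = 100 * .data$abundance / sum(.data$abundance)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$peak_pos, .data$sample_id)
  structure(ab, method = method,
            class = c("abundance_tbl", class(ab)))
}

count_umis <- function(umi, collapse) {
  if (collapse == "exact") return(dplyr::n_distinct(umi))
  length(collapse_umis_directional(umi))
}

# Directional Hamming-1 collapse: a UMI is absorbed by a more abundant
# neighbour when count_big >= 2 * count_small - 1 (sequencing-error model:
# errors fork low-count satellites off true UMIs).
collapse_umis_directional <- function(umi) {
  cnt <- sort(table(umi), decreasing = TRUE)
  seqs <- names(cnt)
  if (length(seqs) <= 1) return(seqs)
  keep <- rep(TRUE, length(seqs))
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  for (i in seq_along(seqs)[-1]) {
    for (j in seq_len(i - 1)) {
      if (!keep[j]) next
      if (sum(mat[i, ] != mat[j, ]) == 1 &&
          cnt[j] >= 2 * cnt[i] - 1) {
        keep[i] <- FALSE
        break
      }
    }
  }
  seqs[keep]
}

quantify_mle <- function(merged, key) {
  per_sample <- split(merged, merged$sample_id)
  out <- lapply(per_sample, function(s) {
    prof <- dplyr::distinct(s, .data$site_id, .data$fragment_len)
    if (dplyr::n_distinct(prof$fragment_len) < 2) {
      # degenerate: a single pooled length cannot identify phi; theta = d
      est <- dplyr::count(prof, .data$site_id, name = "theta")
      meta <- dplyr::distinct(
        s, dplyr::across(dplyr::all_of(setdiff(key, "sample_id"))),
        .data$sample_id
      )
      return(dplyr::left_join(meta,
                              dplyr::rename(est, abundance = "theta"),
                              by = "site_id"))
    }
    fit <- estimate_theta_mle(split(prof$fragment_len, prof$site_id))
    est <- tidy(fit)
    meta <- dplyr::distinct(
      s, dplyr::across(dplyr::all_of(setdiff(key, "sample_id"))),
      .data$sample_id
    )
    dplyr::left_join(meta, dplyr::select(est, "site_id", abundance = "theta"),
                     by = "site_id")
  })
  dplyr::bind_rows(out)
}

#' Resolve cross-group collisions with the tenfold abundance rule
#'
#' Sites shared between independent transduction groups are sequencing-run
#' contaminations or coincidences. Each group's normalized abundance at the
#' site (site abundance over the group's total abundance) is compared: the
#' site is reassigned to the group whose normalized abundance is at least
#' `fold` times every other group's, or discarded from all groups when no
#' group dominates. Because sites are merged globally before this step,
#' cross-group identity within the merge window is already site identity.
#'
#' @param ab Abundance table from [quantify()].
#' @param fold Dominance threshold (default 10; see
#'   [collision_fold_reference()] for the fold-change rationale).
#' @param normalize `"group_total"` (default) or `"none"` (raw abundances).
#' @return A list: `table` (the filtered abundance table) and `collisions`
#'   (one row per collision with the winning group or `NA` when discarded).
#' @export
resolve_collisions <- function(ab, fold = 10, normalize = c("group_total",
                                                            "none")) {
  normalize <- match.arg(normalize)
  stopifnot(fold > 1)
  grp <- ab |>
    dplyr::group_by(.data$site_id, .data$group_id) |>
    dplyr::summarise(g_ab = sum(.data$abundance), .groups = "drop")
  if (normalize == "group_total") {
    grp <- grp |>
      dplyr::group_by(.data$group_id) |>
      dplyr::mutate(norm = .data$g_ab / sum(.data$g_ab)) |>
      dplyr::ungroup()
  } else {
    grp <- dplyr::mutate(grp, norm = .data$g_ab)
  }
  grp <- dplyr::filter(grp, .data$norm > 0)

  shared <- grp |>
    dplyr::group_by(.data$site_id) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::arrange(dplyr::desc(.data$norm), .by_group = TRUE) |>
    dplyr::summarise(
      n_groups = dplyr::n(),
      top_group = dplyr::first(.data$group_id),
      top_norm = dplyr::first(.data$norm),
      runner_up_norm = dplyr::nth(.data$norm, 2),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      winner = ifelse(.data$top_norm >= fold * .data$runner_up_norm,
                      .data$top_group, NA_character_),
      outcome = ifelse(is.na(.data$winner), "discarded", "reassigned")
    )

  keep <- rep(TRUE, nrow(ab))
  if (nrow(shared) > 0) {
    m <- match(ab$site_id, shared$site_id)
    coll <- !is.na(m)
    keep[coll] <- !is.na(shared$winner[m[coll]]) &
      ab$group_id[coll] == shared$winner[m[coll]]
  }
  table <- ab[keep, , drop = FALSE]
  attr(table, "method") <- attr(ab, "method")
  list(table = table, collisions = shared)
}

#' Mask sites on the vector sequence
#'
#' Removes sites called on vector contigs (reads internal to the vector, not
#' vector-genome junctions) and, optionally, sites whose peak falls inside a
#' mask interval.
#'
#' @param ab Abundance table (or any tibble with `chrom` and `peak_pos`).
#' @param vector_chroms Character vector of vector contig names.
#' @param mask Optional `vector_mask` intervals from [load_intervals()];
#'   a site is removed iff its `peak_pos` lies inside an interval.
#' @return The filtered table; the number of removed rows is attached as
#'   attribute `n_masked`.
#' @export
vector_mask <- function(ab, vector_chroms = NULL, mask = NULL) {
  drop <- rep(FALSE, nrow(ab))
  if (!is.null(vector_chroms)) {
    drop <- drop | ab$chrom %in% vector_chroms
  }
  if (!is.null(mask) && nrow(mask) > 0) {
    # peak inside the 0-based half-open interval
    drop <- drop | spans_overlap_intervals(ab$chrom, ab$peak_pos - 1L,
                                           ab$peak_pos, mask)
  }
  out <- ab[!drop, , drop = FALSE]
  attr(out, "method") <- attr(ab, "method")
  attr(out, "n_masked") <- sum(drop)
  out
}

#' Annotate sites with the nearest gene
#'
#' Distance is 0 when the peak lies inside a gene interval; ties are broken
#' toward the lexicographically smallest gene label. Sites on chromosomes
#' without genes are annotated `NA`.
#'
#' @param ab Abundance table (any tibble with `chrom` and `peak_pos`).
#' @param genes Gene intervals from [load_intervals()].
#' @return `ab` with `gene` and `gene_distance` columns added.
#' @export
annotate_nearest_gene <- function(ab, genes) {
  if (is.null(genes) || nrow(genes) == 0) {
    return(dplyr::mutate(ab, gene = NA_character_,
                         gene_distance = NA_integer_))
  }
  sites <- dplyr::distinct(ab, .data$chrom, .data$peak_pos)
  hits <- sites |>
    dplyr::inner_join(
      dplyr::select(genes, "chrom", g_start = "start", g_end = "end",
                    "label"),
      by = "chrom", relationship = "many-to-many"
    ) |>
    dplyr::mutate(
      gene_distance = pmax(0L, .data$g_start + 1L - .data$peak_pos,
                           .data$peak_pos - .data$g_end)
    ) |>
    dplyr::group_by(.data$chrom, .data$peak_pos) |>
    dplyr::arrange(.data$gene_distance, .data$label, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("chrom", "peak_pos", gene = "label", "gene_distance")
  out <- dplyr::left_join(ab, hits, by = c("chrom", "peak_pos"))
  attr(out, "method") <- attr(ab, "method")
  out
}

#' Write the final collision table
#'
#' One row per site with its annotation and one abundance column per sample;
#' the quantification method is recorded in a `method` column. This wide TSV
#' is the pipeline's final output.
#'
#' @param ab Abundance table, ideally after [resolve_collisions()] and
#'   [annotate_nearest_gene()].
#' @param path Output TSV path.
#' @return Invisibly, the wide tibble that was written.
#' @export
write_collision_table <- function(ab, path) {
  wide <- collision_table_wide(ab)
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(wide)
}

collision_table_wide <- function(ab) {
  method <- attr(ab, "method") %||% "reads"
  keep <- intersect(c("chrom", "peak_pos", "strand", "gene"), names(ab))
  wide <- ab |>
    dplyr::select(dplyr::all_of(keep), "sample_id", "abundance") |>
    tidyr::pivot_wider(names_from = "sample_id",
                       values_from = "abundance", values_fill = 0)
  names(wide)[names(wide) == "peak_pos"] <- "position"
  dplyr::mutate(wide, method = method)
}

#' Read a collision table written by [write_collision_table()]
#' @param path TSV path.
#' @return The wide tibble (sites x annotation + per-sample abundances).
#' @export
read_collision_table <- function(path) {
  readr::read_tsv(
    path, progress = FALSE,
    col_types = readr::cols(chrom = "c", strand = "c", gene = "c",
                            method = "c", .default = readr::col_guess())
  )
}
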