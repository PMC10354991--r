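# End-to-end orchestration: the in-memory core used by simulations and
# tests, plus a checkpointed, file-based pipeline whose stages are skipped
# on re-run when their content hashes are unchanged.

#' Pipeline configuration
#'
#' @param r1,r2 Raw FASTQ paths.
#' @param association Association CSV path.
#' @param genome Reference FASTA path.
#' @param repeats,genes Optional BED paths (repeat regions, gene
#'   annotation).
#' @param vector_chroms Optional vector contig names to mask.
#' @param sam_r1,sam_r2 Optional pre-aligned SAM paths (external aligner);
#'   when given, the built-in mapper is skipped.
#' @param method Quantification method (see [quantify()]).
#' @param window Site-merge window (default 7 bp).
#' @param collision_fold Collision dominance threshold (default 10).
#' @param mapq_min,mapq_mode MAPQ gate (default 12, repeat-overlapping
#'   alignments only; see [mapq_repeat_filter()]).
#' @param filter_class `"filterNo"`, `"filter60"`, or `"both"` (default).
#' @param workdir Working directory for checkpoints and outputs.
#' @param design An [oligo_design()].
#' @param max_mismatch Barcode mismatch tolerance.
#' @param min_map_identity Built-in mapper extension identity.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(r1, r2, association, genome,
                            repeats = NULL, genes = NULL,
                            vector_chroms = NULL,
                            sam_r1 = NULL, sam_r2 = NULL,
                            method = "reads", window = 7L,
                            collision_fold = 10, mapq_min = 12L,
                            mapq_mode = "repeat_only",
                            filter_class = "both",
                            workdir = tempfile("iscallr_run_"),
                            design = oligo_design(),
                            max_mismatch = 0L,
                            min_map_identity = 0.75) {
  stopifnot(
    method %in% c("reads", "umi", "fragment", "fragment_mle"),
    window >= 0, collision_fold > 1,
    filter_class %in% c("filterNo", "filter60", "both")
  )
  structure(
    list(r1 = r1, r2 = r2, association = association, genome = genome,
         repeats = repeats, genes = genes, vector_chroms = vector_chroms,
         sam_r1 = sam_r1, sam_r2 = sam_r2,
         method = method, window = as.integer(window),
         collision_fold = collision_fold, mapq_min = as.integer(mapq_min),
         mapq_mode = mapq_mode, filter_class = filter_class,
         workdir = workdir, design = design,
         max_mismatch = as.integer(max_mismatch),
         min_map_identity = min_map_identity),
    class = "pipeline_config"
  )
}

#' Call integration sites in memory
#'
#' The pipeline core on in-memory objects: oligo parsing, mapping (built-in
#' mapper), MAPQ/repeat gate, junction check, event reduction, merging,
#' quantification, collision resolution, vector masking and annotation.
#'
#' @param pairs Raw read-pair tibble ([read_fastq_pairs()] or
#'   `simulate_library()$library`).
#' @param samples Association tibble.
#' @param genome Named `DNAStringSet`.
#' @param design An [oligo_design()].
#' @param method,window,collision_fold,mapq_min,mapq_mode,filter_class,
#'   repeats,genes,vector_chroms,max_mismatch,min_map_identity
#'   As in [pipeline_config()].
#' @return A list: `funnel`, `align_stats`, `events` (both-class junction
#'   events), `tables` (named list of collision-resolved, annotated
#'   abundance tables per filter class), `collisions`.
#' @export
call_sites <- function(pairs, samples, genome, design = oligo_design(),
                       method = "reads", window = 7L, collision_fold = 10,
                       mapq_min = 12L, mapq_mode = "repeat_only",
                       filter_class = "both", repeats = NULL, genes = NULL,
                       vector_chroms = NULL, max_mismatch = 0L,
                       min_map_identity = 0.75) {
  processed <- process_reads(pairs, samples, design = design,
                             max_mismatch = max_mismatch)
  funnel <- rejection_funnel(processed)
  surv <- dplyr::filter(processed, is.na(.data$rejection))

  r1_reads <- new_tbl(read_id = surv$id, sample_id = surv$sample_id,
                      group_id = surv$group_id, umi = surv$umi,
                      seq = surv$genomic_r1)
  r2_reads <- new_tbl(read_id = surv$id, seq = surv$genomic_r2)
  aln_r1 <- builtin_map(r1_reads, genome, min_identity = min_map_identity)
  aln_r2 <- builtin_map(r2_reads, genome, min_identity = min_map_identity)

  aln_r1 <- mapq_repeat_filter(aln_r1, repeats = repeats,
                               mapq_min = mapq_min, mode = mapq_mode)
  junction_ok <- junction_3nt_check(aln_r1, genome)
  align_stats <- new_tbl(
    stat = c("pairs_in", "r1_mapped", "r2_mapped", "r1_post_mapq",
             "r1_junction_ok"),
    n = c(nrow(surv),
          nrow(surv) - (attr(aln_r1, "n_unmapped") %||% NA_integer_),
          nrow(surv) - (attr(aln_r2, "n_unmapped") %||% NA_integer_),
          nrow(aln_r1), sum(junction_ok))
  )
  aln_r1 <- aln_r1[junction_ok, , drop = FALSE]

  events <- to_junction_events(aln_r1, aln_r2)
  out_tables <- list()
  collisions <- list()
  classes <- if (filter_class == "both") c("filterNo", "filter60") else
    filter_class
  for (cl in classes) {
    ev <- if (cl == "filter60") {
      events[filter60(events$match_len_r1), , drop = FALSE]
    } else {
      events
    }
    if (nrow(ev) == 0) {
      out_tables[[cl]] <- NULL
      next
    }
    merged <- merge_within_window(ev, window = window)
    ab <- quantify(merged, method = method)
    res <- resolve_collisions(ab, fold = collision_fold)
    tab <- vector_mask(res$table, vector_chroms = vector_chroms)
    tab <- annotate_nearest_gene(tab, genes)
    attr(tab, "method") <- method
    out_tables[[cl]] <- tab
    collisions[[cl]] <- res$collisions
  }
  list(funnel = funnel, align_stats = align_stats, events = events,
       tables = out_tables, collisions = collisions)
}

#' Run the checkpointed pipeline on files
#'
#' Executes read processing, alignment, event reduction and site calling,
#' writing each stage's output under `config$workdir`. Stages are
#' checkpointed by content hash (input file digests plus the parameters the
#' stage consumes): an immediate re-run performs no stage work, and editing
#' an input invalidates only that stage and its descendants.
#'
#' @param config A [pipeline_config()].
#' @return A list: `tables` (per filter class), `funnel`, `collisions`,
#'   `paths` (output files), `stages_run` (which stages executed this
#'   call).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c(config$r1, config$r2, config$association, config$genome,
              config$repeats, config$genes, config$sam_r1, config$sam_r2)) {
    if (!is.null(f) && !file.exists(f)) {
      stop("input file not found: ", f, call. = FALSE)
    }
  }
  wd <- config$workdir
  dir.create(wd, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(wd, "checkpoints.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else {
    list()
  }
  stages_run <- character(0)
  samples <- parse_association(config$association)
  genome <- read_genome(config$genome)
  repeats <- if (!is.null(config$repeats))
    load_intervals(config$repeats, "repeat") else NULL
  genes <- if (!is.null(config$genes))
    load_intervals(config$genes, "gene") else NULL

  # --- stage 1: read processing -------------------------------------------
  h1 <- rlang::hash(list(
    "readproc",
    unname(tools::md5sum(c(config$r1, config$r2, config$association))),
    config$design, config$max_mismatch
  ))
  trimmed_path <- file.path(wd, "trimmed.tsv")
  funnel_path <- file.path(wd, "funnel.tsv")
  if (!checkpoint_ok(manifest, "readproc", h1, c(trimmed_path,
                                                 funnel_path))) {
    stages_run <- c(stages_run, "readproc")
    pairs <- read_fastq_pairs(config$r1, config$r2)
    processed <- process_reads(pairs, samples, design = config$design,
                               max_mismatch = config$max_mismatch)
    readr::write_tsv(
      dplyr::select(processed, "id", "sample_id", "group_id",
                    "genomic_r1", "genomic_r2", "umi", "rejection"),
      trimmed_path, progress = FALSE
    )
    readr::write_tsv(rejection_funnel(processed), funnel_path,
                     progress = FALSE)
    manifest <- checkpoint_set(manifest, "readproc", h1,
                               c(trimmed_path, funnel_path))
    checkpoint_write(manifest, manifest_path)
  }
  trimmed <- readr::read_tsv(
    trimmed_path, progress = FALSE,
    col_types = readr::cols(
      id = "c", sample_id = "c", group_id = "c", genomic_r1 = "c",
      genomic_r2 = "c", umi = "c", rejection = "c"
    )
  )
  funnel <- readr::read_tsv(funnel_path, show_col_types = FALSE,
                            progress = FALSE)

  # --- stage 2: alignment --------------------------------------------------
  use_sam <- !is.null(config$sam_r1)
  h2 <- rlang::hash(list(
    "align", h1, unname(tools::md5sum(config$genome)),
    use_sam,
    if (use_sam) unname(tools::md5sum(c(config$sam_r1, config$sam_r2))),
    config$min_map_identity
  ))
  aln1_path <- file.path(wd, "alignments_r1.tsv")
  aln2_path <- file.path(wd, "alignments_r2.tsv")
  if (!checkpoint_ok(manifest, "align", h2, c(aln1_path, aln2_path))) {
    stages_run <- c(stages_run, "align")
    surv <- dplyr::filter(trimmed, is.na(.data$rejection))
    if (use_sam) {
      if (!is.null(config$sam_r2)) {
        aln_r1 <- ingest_sam(config$sam_r1)
        aln_r2 <- ingest_sam(config$sam_r2)
      } else {
        all_alns <- ingest_sam(config$sam_r1)
        aln_r1 <- dplyr::filter(all_alns, .data$is_r1)
        aln_r2 <- dplyr::filter(all_alns, !.data$is_r1)
      }
      meta <- dplyr::select(surv, read_id = "id", "sample_id", "group_id",
                            meta_umi = "umi")
      aln_r1 <- dplyr::inner_join(
        dplyr::select(aln_r1, -dplyr::any_of(c("sample_id", "group_id"))),
        meta, by = "read_id"
      )
      aln_r1$umi <- dplyr::coalesce(aln_r1$umi, aln_r1$meta_umi)
      aln_r1$meta_umi <- NULL
    } else {
      aln_r1 <- builtin_map(
        new_tbl(read_id = surv$id, sample_id = surv$sample_id,
                group_id = surv$group_id, umi = surv$umi,
                seq = surv$genomic_r1),
        genome, min_identity = config$min_map_identity
      )
      aln_r2 <- builtin_map(
        new_tbl(read_id = surv$id, seq = surv$genomic_r2),
        genome, min_identity = config$min_map_identity
      )
    }
    readr::write_tsv(aln_r1, aln1_path, progress = FALSE)
    readr::write_tsv(aln_r2, aln2_path, progress = FALSE)
    manifest <- checkpoint_set(manifest, "align", h2,
                               c(aln1_path, aln2_path))
    checkpoint_write(manifest, manifest_path)
  }
  aln_r1 <- read_aln_tsv(aln1_path)
  aln_r2 <- read_aln_tsv(aln2_path)

  # --- stage 3: events -----------------------------------------------------
  h3 <- rlang::hash(list(
    "events", h2,
    if (!is.null(config$repeats)) unname(tools::md5sum(config$repeats)),
    config$mapq_min, config$mapq_mode
  ))
  events_path <- file.path(wd, "events.tsv")
  if (!checkpoint_ok(manifest, "events", h3, events_path)) {
    stages_run <- c(stages_run, "events")
    a1 <- mapq_repeat_filter(aln_r1, repeats = repeats,
                             mapq_min = config$mapq_min,
                             mode = config$mapq_mode)
    a1 <- a1[junction_3nt_check(a1, genome), , drop = FALSE]
    events <- to_junction_events(a1, aln_r2)
    readr::write_tsv(events, events_path, progress = FALSE)
    manifest <- checkpoint_set(manifest, "events", h3, events_path)
    checkpoint_write(manifest, manifest_path)
  }
  events <- readr::read_tsv(
    events_path, progress = FALSE,
    col_types = readr::cols(read_id = "c", sample_id = "c",
                            group_id = "c", chrom = "c", strand = "c",
                            umi = "c", .default = "i")
  )

  # --- stage 4: sites ------------------------------------------------------
  h4 <- rlang::hash(list(
    "sites", h3, config$window, config$method, config$collision_fold,
    config$filter_class, config$vector_chroms,
    if (!is.null(config$genes)) unname(tools::md5sum(config$genes))
  ))
  classes <- if (config$filter_class == "both") c("filterNo", "filter60")
  else config$filter_class
  table_paths <- stats::setNames(
    file.path(wd, sprintf("%s_%s_CollisionTable.txt", config$method,
                          classes)),
    classes
  )
  if (!checkpoint_ok(manifest, "sites", h4, table_paths)) {
    stages_run <- c(stages_run, "sites")
    for (cl in classes) {
      ev <- if (cl == "filter60") {
        events[filter60(events$match_len_r1), , drop = FALSE]
      } else {
        events
      }
      merged <- merge_within_window(ev, window = config$window)
      ab <- quantify(merged, method = config$method)
      res <- resolve_collisions(ab, fold = config$collision_fold)
      tab <- vector_mask(res$table, vector_chroms = config$vector_chroms)
      tab <- annotate_nearest_gene(tab, genes)
      attr(tab, "method") <- config$method
      write_collision_table(tab, table_paths[[cl]])
      readr::write_tsv(res$collisions,
                       file.path(wd, paste0("collisions_", cl, ".tsv")),
                       progress = FALSE)
    }
    manifest <- checkpoint_set(manifest, "sites", h4, table_paths)
    checkpoint_write(manifest, manifest_path)
  }
  tables <- lapply(table_paths, read_collision_table)
  collisions <- lapply(classes, function(cl) {
    readr::read_tsv(file.path(wd, paste0("collisions_", cl, ".tsv")),
                    show_col_types = FALSE, progress = FALSE)
  })
  names(collisions) <- classes

  list(
    tables = tables, funnel = funnel, collisions = collisions,
    paths = list(trimmed = trimmed_path, events = events_path,
                 tables = table_paths, manifest = manifest_path),
    stages_run = stages_run
  )
}

# TSV reader that types the known character columns present in the header.
read_aln_tsv <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  chr_cols <- intersect(c("read_id", "sample_id", "group_id", "umi",
                          "chrom", "strand", "query_fwd"), hdr)
  ct <- do.call(readr::cols,
                c(stats::setNames(as.list(rep("c", length(chr_cols))),
                                  chr_cols),
                  list(.default = readr::col_guess())))
  readr::read_tsv(path, progress = FALSE, col_types = ct)
}

checkpoint_ok <- function(manifest, stage, hash, outputs) {
  st <- manifest[[stage]]
  !is.null(st) && identical(st$hash, hash) &&
    all(file.exists(unlist(outputs)))
}

checkpoint_set <- function(manifest, stage, hash, outputs) {
  manifest[[stage]] <- list(hash = hash,
                            outputs = as.list(unname(unlist(outputs))),
                            time = format(Sys.time(), tz = "UTC"))
  manifest
}

checkpoint_write <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
}

#' Sweep the site-merge window
#'
#' Re-merges the same junction events at a range of windows and counts the
#' resulting sites -- the sensitivity analysis behind the choice of the
#' 7 bp default: counts fall as jittered positions are absorbed and then
#' plateau once all local noise is merged.
#'
#' @param events Junction-event tibble.
#' @param windows Integer vector of windows to test (default 0:10).
#' @return Tibble with `window`, `n_sites`.
#' @export
sweep_window <- function(events, windows = 0:10) {
  dplyr::bind_rows(lapply(windows, function(w) {
    merged <- merge_within_window(events, window = w)
    new_tbl(window = w,
            n_sites = dplyr::n_distinct(merged$site_id))
  }))
}
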