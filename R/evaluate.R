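# Comparison statistics: MSE against expected abundance, precision-recall /
# ROC against ground truth, UMI entropy with a bootstrap uniformity test,
# and Procrustes distance between abundance matrices with a subsampled null.

#' Mean squared error between observed and expected relative abundances
#'
#' Computed on the percentage scale, matching the magnitudes of per-sample
#' abundance tables.
#'
#' @param observed_pct,expected_pct Numeric vectors of equal length (values
#'   in `[0, 100]`).
#' @return The mean of squared differences.
#' @export
mse <- function(observed_pct, expected_pct) {
  if (length(observed_pct) != length(expected_pct)) {
    stop("observed and expected vectors must have equal length",
         call. = FALSE)
  }
  mean((observed_pct - expected_pct)^2)
}

#' Shannon entropy of a UMI tally (bits)
#'
#' `H(X) = -sum p(x) log2 p(x)` over the occurrence probabilities of the
#' observed UMIs. Bounded by `log2(n_unique)`, with equality iff uniform.
#'
#' @param counts Named (or bare) vector of per-UMI occurrence counts, or a
#'   character vector of raw UMI observations.
#' @return Entropy in bits.
#' @export
umi_entropy <- function(counts) {
  if (is.character(counts)) counts <- table(counts)
  counts <- as.numeric(counts)
  counts <- counts[counts > 0]
  if (length(counts) == 0) {
    stop("empty UMI tally: entropy undefined", call. = FALSE)
  }
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Bootstrap test of UMI-distribution uniformity
#'
#' Draws `B` uniform resamples (each of size `total count x
#' size_multiplier`) from the set of unique UMIs, forming the uniform null:
#' the mean per-UMI bootstrap frequency is the reference distribution and
#' the per-resample entropies its entropy null. A two-sample
#' Kolmogorov-Smirnov test compares the observed per-UMI count distribution
#' with the pooled bootstrap counts (pooling keeps the null sample's
#' multinomial spread; comparing against the bootstrap MEAN would shrink
#' the reference spread by sqrt(B) and reject even when the null is true).
#'
#' @param counts Named vector of per-UMI counts (>= 2 unique UMIs), or a
#'   character vector of raw UMI observations.
#' @param B Number of bootstrap resamples (default 100).
#' @param seed Integer seed.
#' @param size_multiplier Resample-size multiplier (the x10 adjustment used
#'   when the unique set is close to the total count).
#' @return A list: `observed_entropy`, `bootstrap_entropies` (length `B`),
#'   `reference` (tibble of mean bootstrap counts per UMI), `ks` (the
#'   `htest`), `p_value`.
#' @export
bootstrap_uniformity <- function(counts, B = 100L, seed = 1L,
                                 size_multiplier = 1) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (is.character(counts)) counts <- table(counts)
  counts <- counts[counts > 0]
  u <- length(counts)
  if (u < 2) stop("need >= 2 unique UMIs", call. = FALSE)
  umis <- names(counts) %||% as.character(seq_len(u))
  size <- round(sum(counts) * size_multiplier)
  boot <- withr::with_seed(seed, {
    replicate(B, tabulate(sample.int(u, size, replace = TRUE), nbins = u))
  })
  ref <- rowMeans(boot)
  ent <- apply(boot, 2, umi_entropy)
  ks <- suppressWarnings(stats::ks.test(as.numeric(counts),
                                        as.numeric(boot)))
  list(
    observed_entropy = umi_entropy(counts),
    bootstrap_entropies = ent,
    reference = new_tbl(umi = umis, mean_count = ref),
    ks = ks,
    p_value = ks$p.value
  )
}

#' Precision-recall and ROC curves for called sites against truth
#'
#' A called site is a true positive when it lies within `window` bp of a
#' truth site on the same chromosome and strand (the same identity window
#' the caller uses for merging). Sweeping an abundance threshold over the
#' calls yields the curves; areas are trapezoidal. Recall is measured
#' against the full truth set; with no called sites the report is degenerate
#' with recall 0.
#'
#' @param calls Tibble with `chrom`, `strand`, `pos`, `score` (abundance).
#' @param truth Tibble with `chrom`, `strand`, `pos`.
#' @param window Site-identity window (default 7).
#' @return A list: `points` (threshold sweep with `precision`, `recall`,
#'   `fpr`, `tpr`), `aupr`, `auroc`, `n_truth`, `n_calls`.
#' @export
pr_roc <- function(calls, truth, window = 7L) {
  stopifnot(nrow(truth) > 0)
  if (nrow(calls) == 0) {
    return(list(
      points = new_tbl(threshold = numeric(0), precision = numeric(0),
                       recall = numeric(0), fpr = numeric(0),
                       tpr = numeric(0)),
      aupr = 0, auroc = NA_real_, n_truth = nrow(truth), n_calls = 0
    ))
  }
  truth_key <- paste(truth$chrom, truth$strand)
  call_match <- vapply(seq_len(nrow(calls)), function(i) {
    hit <- which(truth_key == paste(calls$chrom[i], calls$strand[i]) &
                   abs(truth$pos - calls$pos[i]) <= window)
    if (length(hit) > 0) hit[1] else NA_integer_
  }, integer(1))

  th <- sort(unique(calls$score), decreasing = TRUE)
  pts <- dplyr::bind_rows(lapply(th, function(t) {
    pos <- calls$score >= t
    tp_calls <- sum(pos & !is.na(call_match))
    fp_calls <- sum(pos & is.na(call_match))
    truth_hit <- length(unique(stats::na.omit(call_match[pos])))
    n_neg <- sum(is.na(call_match))
    new_tbl(
      threshold = t,
      precision = if (tp_calls + fp_calls > 0)
        tp_calls / (tp_calls + fp_calls) else NA_real_,
      recall = truth_hit / nrow(truth),
      tpr = truth_hit / nrow(truth),
      fpr = if (n_neg > 0) fp_calls / n_neg else 0
    )
  }))
  aupr <- trapezoid_area(c(0, pts$recall), c(pts$precision[1],
                                             pts$precision))
  auroc <- if (all(pts$fpr == 0)) {
    # no false calls at any threshold: perfect ranking iff full recall
    if (max(pts$tpr) == 1) 1 else max(pts$tpr)
  } else {
    trapezoid_area(c(0, pts$fpr, 1), c(0, pts$tpr, max(pts$tpr)))
  }
  list(points = pts, aupr = aupr, auroc = auroc,
       n_truth = nrow(truth), n_calls = nrow(calls))
}

trapezoid_area <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Procrustes distance between two abundance matrices
#'
#' Symmetric Procrustes: both matrices are centred and unit-scaled, `Y` is
#' optimally rotated onto `X`, and the distance is the sum of squared
#' residuals. Zero iff the configurations match up to translation, scaling
#' and rotation.
#'
#' @param X,Y Numeric matrices of identical shape (sites x samples,
#'   >= 2 rows).
#' @param scale Use the symmetric (scaled) form (default); `FALSE` skips
#'   the scaling normalisation.
#' @return The Procrustes sum of squares (`ss`).
#' @export
procrustes_distance <- function(X, Y, scale = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y))) {
    stop("X and Y must have the same shape", call. = FALSE)
  }
  stopifnot(nrow(X) >= 2)
  p <- vegan::procrustes(X, Y, symmetric = scale)
  p$ss
}

#' Subsampled null for a Procrustes distance
#'
#' Draws `n_sub` random row subsets (with replacement, applied jointly to
#' both matrices), computes each subset's Procrustes distance, and reports
#' the fraction of null distances at or below the observed one.
#'
#' @param X,Y Numeric matrices of identical shape.
#' @param n_sub Number of subsamples (default 500).
#' @param seed Integer seed.
#' @param scale Passed to [procrustes_distance()].
#' @return A list: `observed`, `null` (length `n_sub`), `frac_leq`.
#' @export
procrustes_null <- function(X, Y, n_sub = 500L, seed = 1L, scale = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  obs <- procrustes_distance(X, Y, scale = scale)
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_sub), function(i) {
      idx <- sample.int(nrow(X), nrow(X), replace = TRUE)
      if (length(unique(idx)) < 2) idx <- seq_len(nrow(X))
      procrustes_distance(X[idx, , drop = FALSE], Y[idx, , drop = FALSE],
                          scale = scale)
    }, numeric(1))
  })
  list(observed = obs, null = null, frac_leq = mean(null <= obs))
}

#' Evaluate a pipeline run against simulator ground truth
#'
#' Matches called sites to truth within the merge window and reports the
#' per-sample MSE between observed and expected relative abundance
#' (unrecovered truth sites count as observed 0), the PR/ROC summary, and
#' site tallies.
#'
#' @param ab Abundance table from [quantify()] (optionally collision-
#'   resolved).
#' @param truth Truth tibble from the simulator (`chrom`, `pos`, `strand`,
#'   `expected_pct`).
#' @param window Site-identity window (default 7).
#' @return A list of class `eval_report`: `per_sample` (tibble with `mse`),
#'   `pr` (the [pr_roc()] result), `n_truth`, `n_called`,
#'   `matched` (truth-to-call site map).
#' @export
evaluate_run <- function(ab, truth, window = 7L) {
  sites <- dplyr::distinct(ab, .data$site_id, .data$chrom, .data$strand,
                           .data$peak_pos)
  match_site <- function(chrom, strand, pos) {
    hit <- which(sites$chrom == chrom & sites$strand == strand &
                   abs(sites$peak_pos - pos) <= window)
    if (length(hit) > 0) sites$site_id[hit[1]] else NA_character_
  }
  truth$matched_site <- mapply(match_site, truth$chrom, truth$strand,
                               truth$pos)
  per_sample <- ab |>
    dplyr::distinct(.data$sample_id) |>
    dplyr::mutate(mse = vapply(.data$sample_id, function(s) {
      obs <- ab[ab$sample_id == s, ]
      o <- obs$rel_pct[match(truth$matched_site, obs$site_id)]
      o[is.na(o)] <- 0
      mse(o, truth$expected_pct)
    }, numeric(1), USE.NAMES = FALSE))
  scores <- ab |>
    dplyr::group_by(.data$site_id, .data$chrom, .data$strand,
                    .data$peak_pos) |>
    dplyr::summarise(score = sum(.data$abundance), .groups = "drop")
  pr <- pr_roc(
    dplyr::select(scores, "chrom", "strand", pos = "peak_pos", "score"),
    dplyr::select(truth, "chrom", "strand", "pos"),
    window = window
  )
  structure(
    list(per_sample = per_sample, pr = pr, n_truth = nrow(truth),
         n_called = nrow(sites),
         matched = dplyr::select(truth, "site_id", "chrom", "strand",
                                 "pos", "matched_site")),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d truth site(s), %d called; AUROC %.3f, AUPR %.3f\n",
              x$n_truth, x$n_called, x$pr$auroc, x$pr$aupr))
  print(x$per_sample)
  invisible(x)
}

#' Write an evaluation report as TSV + JSON
#'
#' @param report An `eval_report` from [evaluate_run()].
#' @param path_prefix Output prefix; writes `<prefix>_per_sample.tsv` and
#'   `<prefix>_summary.json`.
#' @return Invisibly, the two paths.
#' @export
write_eval_report <- function(report, path_prefix) {
  tsv <- paste0(path_prefix, "_per_sample.tsv")
  js <- paste0(path_prefix, "_summary.json")
  readr::write_tsv(report$per_sample, tsv, progress = FALSE)
  jsonlite::write_json(
    list(
      n_truth = report$n_truth,
      n_called = report$n_called,
      auroc = report$pr$auroc,
      aupr = report$pr$aupr,
      mse = stats::setNames(as.list(report$per_sample$mse),
                            report$per_sample$sample_id)
    ),
    js, auto_unbox = TRUE, digits = NA
  )
  invisible(c(tsv, js))
}
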