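#' Marker selection thresholds
#'
#' The three filters that make a gene a cluster-restricted marker: a minimum
#' fold-change increase in the target population, a cap on the detection
#' fraction across all non-target cells pooled, and a cap on the detection
#' fraction within any single non-target cluster. All comparisons are strict
#' (`>` for fold change, `<` for detection caps).
#'
#' @param min_fold_change ratio, > 1.
#' @param max_global_detection fraction in (0,1): cap over all other cells.
#' @param max_cluster_detection fraction in (0,1): cap within any other
#'   individual cluster.
#' @return object of class `selection_thresholds`.
#' @export
selection_thresholds <- function(min_fold_change, max_global_detection,
                                 max_cluster_detection) {
  if (!(min_fold_change > 1)) stop("min_fold_change must be > 1")
  for (v in c(max_global_detection, max_cluster_detection)) {
    if (!(v > 0 && v < 1)) stop("detection caps must lie in (0,1)")
  }
  structure(list(min_fold_change = min_fold_change,
                 max_global_detection = max_global_detection,
                 max_cluster_detection = max_cluster_detection),
            class = "selection_thresholds")
}

#' @export
print.selection_thresholds <- function(x, ...) {
  cat(sprintf("<selection_thresholds> FC > %g, global detection < %g, per-cluster detection < %g\n",
              x$min_fold_change, x$max_global_detection, x$max_cluster_detection))
  invisible(x)
}

#' Threshold grid for marker selection
#'
#' Defaults are the published grid: fold change in {1.5, 1.75, 2}, global
#' detection cap in {5%, 10%, 15%}, per-cluster detection cap in
#' {20%, 30%, 40%} — 27 combinations.
#'
#' @param fold_change_values,global_detection_values,cluster_detection_values
#'   non-empty, strictly increasing numeric vectors of valid threshold
#'   values.
#' @return object of class `selection_grid`.
#' @export
selection_grid <- function(fold_change_values = c(1.5, 1.75, 2),
                           global_detection_values = c(0.05, 0.10, 0.15),
                           cluster_detection_values = c(0.20, 0.30, 0.40)) {
  check_sorted <- function(v, what) {
    if (!length(v)) stop(what, " must be non-empty")
    if (is.unsorted(v, strictly = TRUE)) stop(what, " must be strictly increasing")
  }
  check_sorted(fold_change_values, "fold_change_values")
  check_sorted(global_detection_values, "global_detection_values")
  check_sorted(cluster_detection_values, "cluster_detection_values")
  if (any(fold_change_values <= 1)) stop("fold_change_values must all exceed 1")
  if (any(global_detection_values <= 0 | global_detection_values >= 1) ||
      any(cluster_detection_values <= 0 | cluster_detection_values >= 1)) {
    stop("detection values must lie in (0,1)")
  }
  structure(list(fold_change_values = fold_change_values,
                 global_detection_values = global_detection_values,
                 cluster_detection_values = cluster_detection_values),
            class = "selection_grid")
}

#' Enumerate all threshold combinations of a grid
#'
#' Cartesian product in deterministic order: fold change outermost, global
#' detection next, per-cluster detection innermost.
#'
#' @param g a [selection_grid()].
#' @return list of [selection_thresholds()], length = product of the three
#'   list lengths.
#' @export
enumerate_grid <- function(g) {
  out <- list()
  for (fc in g$fold_change_values) {
    for (gd in g$global_detection_values) {
      for (cd in g$cluster_detection_values) {
        out[[length(out) + 1L]] <- selection_thresholds(fc, gd, cd)
      }
    }
  }
  out
}

#' Per-gene detection fraction in a subset of observations
#'
#' Detection = nonzero raw count, the standard single-cell convention for
#' "expressed in".
#'
#' @param m a [count_matrix()] (raw counts).
#' @param obs_subset observation ids or column indices; non-empty.
#' @return named numeric vector, fraction in \[0,1\] per gene.
#' @export
detection_fraction <- function(m, obs_subset) {
  if (!length(obs_subset)) stop("obs_subset must be non-empty")
  vals <- cm_values(m)
  if (is.character(obs_subset)) {
    missing_ids <- setdiff(obs_subset, colnames(vals))
    if (length(missing_ids)) stop("unknown observation id(s): ", paste(missing_ids, collapse = ", "))
  }
  rowMeans(vals[, obs_subset, drop = FALSE] > 0)
}

#' Per-gene marker statistics for a target population
#'
#' Computes, for every gene, the mean linear library-size-normalized
#' expression in the target population and in all other cells, their
#' pseudocounted ratio (fold change), detection fractions in the target, in
#' all other cells pooled, and the maximum within any single non-target
#' cluster, and a BH-adjusted two-sided Wilcoxon rank-sum q-value
#' (target vs rest, on normalized expression) used as a differential-
#' expression prefilter.
#'
#' @param m a raw [count_matrix()].
#' @param ann a [cluster_annotation()] matching `m`; the target population
#'   must be a non-empty strict subset and at least one non-target cluster
#'   must exist.
#' @param pseudocount added to both means before taking the ratio
#'   (default 0.01).
#' @param de_test compute the rank-sum q-values (default TRUE). Turning this
#'   off leaves `de_qvalue` as `NA`, and [apply_thresholds()] then skips the
#'   DE condition.
#' @param min_detect detection screen of the DE prefilter: only genes
#'   detected in at least this fraction of the target population or of the
#'   pooled other cells are tested (default 0.10, the standard single-cell
#'   marker-testing convention); untested genes get `de_qvalue = NA` and are
#'   dropped by [apply_thresholds()] whenever the prefilter is active. A
#'   gene detected in a few percent of its own population cannot be a
#'   marker, and its fold-change estimate is sampling noise.
#' @return a `marker_stats` data.frame, one row per gene, with columns
#'   `mean_target`, `mean_rest`, `fold_change`, `detect_target`,
#'   `detect_global_other`, `detect_max_other_cluster`, `de_qvalue`.
#' @export
compute_marker_stats <- function(m, ann, pseudocount = 0.01, de_test = TRUE,
                                 min_detect = 0.10) {
  check_annotation_matches(m, ann)
  tgt <- is_target_obs(ann)
  if (!any(tgt)) stop("target population is empty")
  if (all(tgt)) stop("target population covers every observation; nothing to contrast")
  other_clusters <- setdiff(unique(ann$cluster_labels), ann$target_clusters)
  if (!length(other_clusters)) stop("annotation has no non-target cluster")

  counts <- cm_values(m)
  norm <- cm_values(normalize_linear(m))

  mean_target <- rowMeans(norm[, tgt, drop = FALSE])
  mean_rest <- rowMeans(norm[, !tgt, drop = FALSE])
  fold_change <- (mean_target + pseudocount) / (mean_rest + pseudocount)

  detect_target <- rowMeans(counts[, tgt, drop = FALSE] > 0)
  detect_global_other <- rowMeans(counts[, !tgt, drop = FALSE] > 0)
  per_cluster <- vapply(other_clusters, function(cl) {
    rowMeans(counts[, ann$cluster_labels == cl, drop = FALSE] > 0)
  }, numeric(nrow(counts)))
  detect_max_other_cluster <- if (length(other_clusters) == 1L) {
    as.numeric(per_cluster)
  } else {
    apply(per_cluster, 1L, max)
  }

  de_qvalue <- rep(NA_real_, nrow(counts))
  if (de_test) {
    tested <- detect_target >= min_detect | detect_global_other >= min_detect
    if (any(tested)) {
      p <- rank_sum_pvalues(norm[tested, , drop = FALSE], which(tgt))
      de_qvalue[tested] <- stats::p.adjust(p, method = "BH")
    }
  }

  structure(data.frame(gene = rownames(counts),
                       mean_target = mean_target, mean_rest = mean_rest,
                       fold_change = fold_change,
                       detect_target = detect_target,
                       detect_global_other = detect_global_other,
                       detect_max_other_cluster = detect_max_other_cluster,
                       de_qvalue = de_qvalue,
                       row.names = rownames(counts), stringsAsFactors = FALSE),
            class = c("marker_stats", "data.frame"))
}

# Row-wise two-sided Wilcoxon rank-sum p-values (normal approximation with
# tie-corrected variance and continuity correction), group 1 = columns idx1.
# Matches stats::wilcox.test(exact = FALSE, correct = TRUE).
rank_sum_pvalues <- function(x, idx1) {
  n <- ncol(x)
  n1 <- length(idx1)
  n2 <- n - n1
  stats_row <- function(v) {
    r <- rank(v)
    nt <- table_counts(v)
    c(sum(r[idx1]), sum(nt^3 - nt))
  }
  srt <- t(apply(x, 1L, stats_row))
  U <- srt[, 1L] - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - srt[, 2L] / (n * (n - 1)))
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  p[sigma2 <= 0] <- 1          # constant rows: no evidence either way
  pmin(p, 1)
}

# run lengths of equal values (tie sizes) without the cost of table()
table_counts <- function(v) {
  rle(sort(v, method = "radix"))$lengths
}

#' Filter marker statistics through selection thresholds
#'
#' Keeps genes with `de_qvalue < de_alpha` (skipped when q-values are absent
#' or `de_alpha` is `NULL`), `fold_change > min_fold_change`,
#' `detect_global_other < max_global_detection` and
#' `detect_max_other_cluster < max_cluster_detection` — all strict.
#' The result is ordered by decreasing fold change.
#'
#' @param stats a `marker_stats` table from [compute_marker_stats()].
#' @param t a [selection_thresholds()].
#' @param de_alpha q-value cutoff for the DE prefilter (default 0.05);
#'   `NULL` disables it.
#' @return character vector of gene ids (possibly empty), ordered by
#'   descending fold change.
#' @export
apply_thresholds <- function(stats, t, de_alpha = 0.05) {
  keep <- stats$fold_change > t$min_fold_change &
    stats$detect_global_other < t$max_global_detection &
    stats$detect_max_other_cluster < t$max_cluster_detection
  if (!is.null(de_alpha) && !all(is.na(stats$de_qvalue))) {
    keep <- keep & !is.na(stats$de_qvalue) & stats$de_qvalue < de_alpha
  }
  sel <- stats[keep, , drop = FALSE]
  sel$gene[order(-sel$fold_change, sel$gene)]
}

#' Candidate gene lists over a threshold grid
#'
#' Runs [apply_thresholds()] at every grid point.
#'
#' @param stats a `marker_stats` table.
#' @param grid a [selection_grid()].
#' @param de_alpha passed to [apply_thresholds()].
#' @param min_size minimum gene-list size for a candidate to be usable
#'   (default 10).
#' @return list of candidates; each has `thresholds`, `genes`,
#'   `passed_min_size` and (after [select_signature()]) `validation_auc`.
#' @export
derive_candidates <- function(stats, grid = selection_grid(), de_alpha = 0.05,
                              min_size = 10L) {
  lapply(enumerate_grid(grid), function(t) {
    genes <- apply_thresholds(stats, t, de_alpha = de_alpha)
    list(thresholds = t, genes = genes,
         passed_min_size = length(genes) >= min_size,
         validation_auc = NA_real_)
  })
}

#' Select the best candidate signature by validation ROC
#'
#' Discards candidates smaller than `min_size`, scores each remaining
#' candidate on an independent validation dataset ([score_signature()] on
#' the genes present there), computes the AUC of the score as a classifier
#' of the validation labels, and returns the candidate with maximal AUC.
#' Ties break toward the smaller gene list, then lexicographic gene order —
#' a deterministic rule so reruns reproduce the same signature.
#'
#' @param candidates list from [derive_candidates()].
#' @param validation_counts a [count_matrix()] for the validation dataset;
#'   raw counts are log-normalized internally with the single-cell
#'   convention.
#' @param validation_labels logical/0-1 vector, one per validation
#'   observation; `TRUE`/1 marks the target cell type. Both classes must be
#'   present.
#' @param min_size minimum candidate size (default 10).
#' @param name,species passed to the returned [gene_signature()].
#' @return a [gene_signature()] whose provenance records the winning
#'   thresholds and validation AUC, with the evaluated candidate list
#'   attached as attribute `candidates`.
#' @export
select_signature <- function(candidates, validation_counts, validation_labels,
                             min_size = 10L, name = "signature",
                             species = c("mouse", "human")) {
  species <- match.arg(species)
  if (cm_layer(validation_counts) == "raw_counts") {
    validation_counts <- log_normalize(validation_counts, mode = "sc_library_size")
  }
  labels <- as.logical(validation_labels)
  if (length(unique(labels)) < 2L) stop("validation labels must contain both classes")

  eligible <- which(vapply(candidates, function(cand) length(cand$genes) >= min_size,
                           logical(1L)))
  if (!length(eligible)) {
    stop("no candidate gene list reaches the minimum size of ", min_size,
         " genes; relax the selection grid or lower min_size")
  }
  for (i in eligible) {
    sc <- suppressWarnings(
      score_signature(validation_counts,
                      gene_signature(name, candidates[[i]]$genes, species = species))
    )
    candidates[[i]]$validation_auc <- auc(sc$score, labels)
    candidates[[i]]$passed_min_size <- TRUE
  }

  keys <- vapply(eligible, function(i) {
    cand <- candidates[[i]]
    sprintf("%.15f|%09d|%s", 1 - cand$validation_auc, length(cand$genes),
            paste(cand$genes, collapse = "|"))
  }, character(1L))
  best <- candidates[[eligible[order(keys)[1L]]]]

  sig <- gene_signature(name, best$genes, species = species,
                        provenance = list(thresholds = best$thresholds,
                                          validation_auc = best$validation_auc,
                                          min_size = min_size))
  attr(sig, "candidates") <- candidates
  sig
}

#' Derive a cell-type signature end to end
#'
#' Convenience wrapper: marker statistics on the derivation dataset, grid
#' search, minimum-size rule, and ROC-based selection on the validation
#' dataset.
#'
#' @param counts raw derivation [count_matrix()].
#' @param ann [cluster_annotation()] for the derivation dataset.
#' @param validation_counts,validation_labels independent validation dataset
#'   and binary target-population labels.
#' @param grid a [selection_grid()] (default: the published 27-point grid).
#' @param de_alpha,pseudocount,min_size,name,species see the underlying
#'   functions.
#' @param fixed_thresholds optional [selection_thresholds()]: skip the grid
#'   search and ROC selection and apply one fixed threshold combination
#'   (used when a signature inherits thresholds optimized for another cell
#'   type).
#' @return a [gene_signature()]; see [select_signature()].
#' @export
derive_signature <- function(counts, ann, validation_counts = NULL,
                             validation_labels = NULL, grid = selection_grid(),
                             de_alpha = 0.05, pseudocount = 0.01, min_size = 10L,
                             name = "signature", species = c("mouse", "human"),
                             fixed_thresholds = NULL) {
  species <- match.arg(species)
  stats <- compute_marker_stats(counts, ann, pseudocount = pseudocount)
  if (!is.null(fixed_thresholds)) {
    genes <- apply_thresholds(stats, fixed_thresholds, de_alpha = de_alpha)
    if (length(genes) < min_size) {
      stop("fixed thresholds yield only ", length(genes), " genes (min_size ", min_size, ")")
    }
    return(gene_signature(name, genes, species = species,
                          provenance = list(thresholds = fixed_thresholds,
                                            mode = "fixed")))
  }
  if (is.null(validation_counts) || is.null(validation_labels)) {
    stop("grid-search derivation needs a validation dataset and labels")
  }
  candidates <- derive_candidates(stats, grid, de_alpha = de_alpha, min_size = min_size)
  select_signature(candidates, validation_counts, validation_labels,
                   min_size = min_size, name = name, species = species)
}

#' Candidate report as a data.frame
#'
#' @param sig a signature returned by [select_signature()] or
#'   [derive_signature()], or a candidate list.
#' @return data.frame with one row per grid point: the three thresholds,
#'   list size, min-size flag and validation AUC (NA when not evaluated).
#' @export
candidate_report <- function(sig) {
  cands <- if (inherits(sig, "gene_signature")) attr(sig, "candidates") else sig
  if (is.null(cands)) stop("no candidate list attached")
  do.call(rbind, lapply(cands, function(cand) {
    data.frame(min_fold_change = cand$thresholds$min_fold_change,
               max_global_detection = cand$thresholds$max_global_detection,
               max_cluster_detection = cand$thresholds$max_cluster_detection,
               n_genes = length(cand$genes),
               passed_min_size = cand$passed_min_size,
               validation_auc = cand$validation_auc)
  }))
}
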