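#' Run the full synthetic-data pipeline
#'
#' One-shot orchestration of the stages: simulate a clustered single-cell
#' derivation dataset and an independent validation dataset sharing the
#' same planted markers; derive a signature by threshold grid search with
#' ROC-based selection; evaluate it on the validation cells; simulate a
#' bulk cohort whose disease groups carry an elevated satellite fraction
#' plus a paired pseudo-histology readout; score and center the signature
#' in the bulk cohort; compare groups; and test the score-histology
#' association against the random-gene-set resampling null. All randomness
#' derives deterministically from `seed` via per-stage child seeds, so the
#' same call reproduces identical outputs.
#'
#' @param seed global seed (integer).
#' @param outdir optional directory; when given, writes `signature.gmt`,
#'   `candidates.tsv`, `scores.tsv`, `roc.tsv`, `tests.tsv`, `assoc.json`
#'   and `provenance.json`.
#' @param config named list of overrides. Recognized keys:
#'   `sc` (arguments to [sim_config()] for the derivation dataset),
#'   `validation_cells` (cells per cluster in the validation dataset),
#'   `grid` (a [selection_grid()]), `min_size`, `de_alpha`,
#'   `bulk_n_per_group`, `bulk_library_size`, `bulk_nb_size`,
#'   `marker_boost`, `n_resamples`. Unknown keys are rejected.
#' @return list with `signature`, `candidates`, `roc`, `scores`,
#'   `group_tests`, `association`, `bulk_truth`, `provenance`.
#' @export
run_pipeline <- function(seed = 1L, outdir = NULL, config = list()) {
  allowed <- c("sc", "validation_cells", "grid", "min_size", "de_alpha",
               "bulk_n_per_group", "bulk_library_size", "bulk_nb_size",
               "marker_boost", "n_resamples")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg_get <- function(key, default) if (key %in% names(config)) config[[key]] else default

  # -- stage 1: derivation + validation single-cell datasets ---------------
  sc_args <- cfg_get("sc", list())
  sc_args$seed <- child_seed(seed, 1L)
  derivation <- generate_single_cell(do.call(sim_config, sc_args))

  val_args <- sc_args
  val_args$cells_per_cluster <- cfg_get("validation_cells", 250L)
  val_args$seed <- child_seed(seed, 2L)
  # validation shares the planted marker genes of the derivation dataset
  dcfg <- do.call(sim_config, sc_args)
  val_args$markers <- lapply(dcfg$markers, function(spec) {
    spec$genes <- derivation$truth[[spec$target_cluster]]
    spec
  })
  validation <- generate_single_cell(do.call(sim_config, val_args))
  val_labels <- is_target_obs(validation$annotation)

  # -- stage 2: derive the signature ---------------------------------------
  signature <- derive_signature(
    derivation$counts, derivation$annotation,
    validation_counts = validation$counts, validation_labels = val_labels,
    grid = cfg_get("grid", selection_grid()),
    de_alpha = cfg_get("de_alpha", 0.05),
    min_size = cfg_get("min_size", 10L),
    name = "derived_satellite", species = "mouse")

  # -- stage 3: evaluate on the validation cells ---------------------------
  val_log <- log_normalize(validation$counts, mode = "sc_library_size")
  val_scores <- score_signature(val_log, signature)
  roc <- roc_curve(val_scores$score, val_labels)

  # -- stage 4: bulk cohort with pseudo-histology --------------------------
  gene_ids <- rownames(cm_values(derivation$counts))
  profiles <- with_seed(child_seed(seed, 3L), {
    base <- stats::rlnorm(length(gene_ids), 1, 1)
    pr <- matrix(base, nrow = length(gene_ids), ncol = 4L,
                 dimnames = list(gene_ids, c("satellite", "myoblast", "myonuclear", "other")))
    pr[signature$genes, "satellite"] <- pr[signature$genes, "satellite"] *
      cfg_get("marker_boost", 50)
    pr
  })
  groups <- list(
    control        = c(satellite = 0.015, myoblast = 0.010, myonuclear = 0.500, other = 0.475),
    disease_mild   = c(satellite = 0.030, myoblast = 0.020, myonuclear = 0.460, other = 0.490),
    disease_severe = c(satellite = 0.045, myoblast = 0.040, myonuclear = 0.400, other = 0.515))
  bulk <- generate_bulk_cohort(bulk_sim_config(
    profiles, group_proportions = groups,
    n_per_group = cfg_get("bulk_n_per_group", 8L),
    library_size = cfg_get("bulk_library_size", 1e5),
    nb_size = cfg_get("bulk_nb_size", 20),
    seed = child_seed(seed, 4L)))

  # -- stage 5: score, center, compare -------------------------------------
  bulk_log <- log_normalize(bulk$counts, mode = "bulk_median_of_ratios")
  human_sig <- gene_signature(signature$name, signature$genes, species = "human",
                              provenance = signature$provenance)
  st <- score_signature(bulk_log, human_sig)
  ctrl_ids <- bulk$metadata$sample_id[bulk$metadata$group == "control"]
  st <- center_scores(st, ctrl_ids)
  scores <- data.frame(sample_id = st$obs_id, group = bulk$metadata$group,
                       signature = human_sig$name, centered_score = st$score,
                       coverage = attr(st, "coverage"), stringsAsFactors = FALSE)
  group_tests <- group_compare(st$score, bulk$metadata$group, design = "multi_group")

  # -- stage 6: association vs histology -----------------------------------
  assoc <- resampling_null(bulk_log, human_sig, bulk$histology,
                           n_resamples = cfg_get("n_resamples", 1000L),
                           seed = child_seed(seed, 5L))

  provenance <- list(package_version = as.character(utils::packageVersion("myosig")),
                     seed = seed, config = config,
                     child_seeds = vapply(1:5, function(k) child_seed(seed, k), integer(1L)))

  result <- list(signature = signature, candidates = candidate_report(signature),
                 roc = roc, scores = scores, group_tests = group_tests,
                 association = assoc, bulk_truth = bulk$truth,
                 provenance = provenance)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_signature_gmt(signature, file.path(outdir, "signature.gmt"))
    utils::write.table(result$candidates, file.path(outdir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(scores, file.path(outdir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cbind(roc_points(roc), auc = roc$auc),
                       file.path(outdir, "roc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(group_tests, file.path(outdir, "tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(observed_rho = assoc$observed_rho, empirical_p = assoc$empirical_p,
           n_resamples = assoc$n_resamples, seed = assoc$seed,
           alternative = assoc$alternative,
           gene_universe_size = assoc$gene_universe_size),
      file.path(outdir, "assoc.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(provenance, file.path(outdir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  result
}
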