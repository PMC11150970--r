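#' Negative-binomial mean implied by a detection fraction
#'
#' Inverts the NB zero probability `P[X = 0] = (r/(r+mu))^r`: the mean at
#' which a gene with dispersion `size` is detected (count > 0) in a given
#' fraction of cells. Used to calibrate planted markers analytically rather
#' than by trial and error.
#'
#' @param detection target detection fraction in (0,1).
#' @param size NB size (inverse-dispersion) parameter.
#' @return the NB mean.
#' @export
nb_mean_for_detection <- function(detection, size) {
  if (any(detection <= 0 | detection >= 1)) stop("detection must lie in (0,1)")
  size * ((1 - detection)^(-1 / size) - 1)
}

#' Planted-marker specification
#'
#' @param target_cluster cluster label carrying the markers.
#' @param n_markers number of marker genes.
#' @param fold_change minimum target/background mean ratio, > 1.
#' @param target_detection desired detection fraction in the target cluster.
#' @param max_background_detection desired detection fraction everywhere
#'   else; must be below `target_detection`.
#' @param genes optional explicit gene ids to use as markers (so a
#'   derivation and a validation simulation can share the same planted
#'   truth); default: sampled from the unassigned gene pool.
#' @return list of class `marker_spec`.
#' @export
marker_spec <- function(target_cluster, n_markers, fold_change,
                        target_detection, max_background_detection,
                        genes = NULL) {
  if (!(fold_change > 1)) stop("fold_change must exceed 1")
  if (target_detection <= max_background_detection) {
    stop("infeasible marker spec: target_detection (", target_detection,
         ") must exceed max_background_detection (", max_background_detection, ")")
  }
  structure(list(target_cluster = as.character(target_cluster),
                 n_markers = as.integer(n_markers), fold_change = fold_change,
                 target_detection = target_detection,
                 max_background_detection = max_background_detection,
                 genes = genes),
            class = "marker_spec")
}

#' Single-cell simulation configuration
#'
#' Defaults give a desk-scale stand-in for a clustered muscle atlas:
#' 4 clusters x 500 cells x 2000 genes, NB counts with lognormal baseline
#' means, and one planted satellite-like marker set in cluster `C1`
#' (12 markers, fold change 4, detection 0.8 in target vs 0.02 elsewhere —
#' a clear-separation regime).
#'
#' @param n_clusters,cells_per_cluster,n_genes dimensions.
#' @param baseline_log_mean,baseline_log_sd lognormal location/scale of the
#'   per-gene baseline NB means.
#' @param nb_dispersion NB size parameter (smaller = more overdispersed).
#' @param markers list of [marker_spec()]s (may be empty).
#' @param seed RNG seed; identical config + seed reproduce the dataset.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 4L, cells_per_cluster = 500L, n_genes = 2000L,
                       baseline_log_mean = -2, baseline_log_sd = 1.2,
                       nb_dispersion = 0.5,
                       markers = list(marker_spec("C1", 12L, 4, 0.8, 0.02)),
                       seed = 1L) {
  if (n_clusters < 1L || cells_per_cluster < 1L || n_genes < 1L) {
    stop("cluster, cell and gene counts must be positive")
  }
  structure(list(n_clusters = as.integer(n_clusters),
                 cells_per_cluster = as.integer(cells_per_cluster),
                 n_genes = as.integer(n_genes),
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 nb_dispersion = nb_dispersion,
                 markers = markers, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate clustered single-cell counts with planted markers
#'
#' Draws NB counts with per-gene lognormal baseline means shared across
#' clusters. Each planted marker gene gets a background mean calibrated
#' analytically to its background detection fraction and a target-cluster
#' mean equal to the larger of (fold change x background mean) and the mean
#' implied by the target detection fraction — so realized detection
#' fractions land on spec and the realized fold change is at least the
#' planted one.
#'
#' @param cfg a [sim_config()].
#' @return list with `counts` (raw [count_matrix()]), `annotation`
#'   ([cluster_annotation()] whose target clusters are those carrying
#'   markers, or the first cluster when none do) and `truth` (named list:
#'   target cluster -> planted marker gene ids).
#' @export
generate_single_cell <- function(cfg) {
  k <- cfg$n_clusters
  nc <- cfg$cells_per_cluster
  ng <- cfg$n_genes
  r <- cfg$nb_dispersion
  clusters <- paste0("C", seq_len(k))
  gene_ids <- sprintf("g%04d", seq_len(ng))
  cell_ids <- sprintf("cell%05d", seq_len(k * nc))
  cell_cluster <- rep(clusters, each = nc)

  with_seed(cfg$seed, {
    base_mu <- stats::rlnorm(ng, cfg$baseline_log_mean, cfg$baseline_log_sd)
    mu <- matrix(base_mu, nrow = ng, ncol = k, dimnames = list(gene_ids, clusters))

    assigned <- character(0)
    truth <- list()
    for (spec in cfg$markers) {
      if (!spec$target_cluster %in% clusters) {
        stop("marker target cluster ", spec$target_cluster, " not in simulation")
      }
      if (is.null(spec$genes)) {
        pool <- setdiff(gene_ids, assigned)
        genes <- sample(pool, spec$n_markers)
      } else {
        genes <- as.character(spec$genes)
        if (!all(genes %in% gene_ids)) stop("explicit marker genes outside gene universe")
      }
      assigned <- c(assigned, genes)
      mu_bg <- nb_mean_for_detection(spec$max_background_detection, r)
      mu_tg <- max(spec$fold_change * mu_bg,
                   nb_mean_for_detection(spec$target_detection, r))
      mu[genes, ] <- mu_bg
      mu[genes, spec$target_cluster] <- mu_tg
      truth[[spec$target_cluster]] <- c(truth[[spec$target_cluster]], genes)
    }

    counts <- matrix(0L, nrow = ng, ncol = k * nc,
                     dimnames = list(gene_ids, cell_ids))
    for (j in seq_len(k)) {
      cols <- which(cell_cluster == clusters[j])
      counts[, cols] <- stats::rnbinom(ng * length(cols), size = r, mu = mu[, j])
    }

    target <- if (length(truth)) names(truth) else clusters[1L]
    list(counts = count_matrix(counts, layer = "raw_counts"),
         annotation = cluster_annotation(cell_ids, cell_cluster, target),
         truth = truth)
  })
}

#' Bulk-cohort simulation configuration
#'
#' Bulk samples are proportion-weighted mixtures of cell-type expression
#' profiles, scaled to a library size and read out with NB noise. Groups
#' carry their own cell-type proportion vectors (each summing to 1); a
#' paired pseudo-histology readout (e.g. PAX7+ cells per fiber) is linked
#' linearly to the satellite fraction with Gaussian noise, floored at zero.
#'
#' @param profiles genes x cell-types matrix of expected expression (row
#'   names = gene ids, column names = type names, one of which is
#'   `satellite_type`).
#' @param group_proportions named list: group -> named proportion vector
#'   over the profile columns, each summing to 1 (tolerance 1e-9). Ignored
#'   when `sample_proportions` is given.
#' @param n_per_group samples per group (scalar or per-group vector).
#' @param sample_proportions optional cell-types x samples matrix of
#'   per-sample proportions (for gradient designs); column names become
#'   sample ids.
#' @param library_size expected total counts per sample.
#' @param nb_size NB size parameter of the count noise (larger = less
#'   noisy).
#' @param histology_slope,histology_noise_sd linear link from satellite
#'   fraction to the histology readout.
#' @param satellite_type profile column treated as the satellite-cell type.
#' @param paired assign pair ids across groups (requires equal group
#'   sizes).
#' @param timecourse optional data.frame with a `time` column and one
#'   column per cell type: one group per timepoint with that proportion
#'   vector (overrides `group_proportions`).
#' @param seed RNG seed.
#' @return list of class `bulk_sim_config`.
#' @export
bulk_sim_config <- function(profiles, group_proportions = NULL, n_per_group = 8L,
                            sample_proportions = NULL, library_size = 1e5,
                            nb_size = 20, histology_slope = 4,
                            histology_noise_sd = 0.005,
                            satellite_type = "satellite", paired = FALSE,
                            timecourse = NULL, seed = 1L) {
  if (is.null(colnames(profiles)) || is.null(rownames(profiles))) {
    stop("profiles needs gene rownames and cell-type colnames")
  }
  types <- colnames(profiles)
  if (!satellite_type %in% types) stop("satellite_type '", satellite_type, "' not a profile column")
  if (!is.null(timecourse)) {
    if (!"time" %in% names(timecourse)) stop("timecourse needs a 'time' column")
    miss <- setdiff(types, names(timecourse))
    if (length(miss)) stop("timecourse missing cell-type column(s): ", paste(miss, collapse = ", "))
    group_proportions <- lapply(seq_len(nrow(timecourse)), function(i) {
      unlist(timecourse[i, types])
    })
    names(group_proportions) <- paste0("t", timecourse$time, "h")
  }
  if (is.null(sample_proportions)) {
    if (is.null(group_proportions)) stop("need group_proportions, timecourse or sample_proportions")
    for (g in names(group_proportions)) {
      pr <- group_proportions[[g]]
      if (!all(types %in% names(pr))) stop("group '", g, "' proportions must name every cell type")
      pr <- pr[types]
      if (any(pr < 0)) stop("negative proportion in group '", g, "'")
      if (abs(sum(pr) - 1) > 1e-9) {
        stop("proportions of group '", g, "' sum to ", sum(pr), ", not 1")
      }
      group_proportions[[g]] <- pr
    }
  } else {
    if (!identical(rownames(sample_proportions), types)) {
      stop("sample_proportions rows must match profile cell types")
    }
    bad <- abs(colSums(sample_proportions) - 1) > 1e-9
    if (any(bad)) stop("sample proportion column(s) not summing to 1: ",
                       paste(colnames(sample_proportions)[bad], collapse = ", "))
  }
  structure(list(profiles = profiles, group_proportions = group_proportions,
                 n_per_group = n_per_group, sample_proportions = sample_proportions,
                 library_size = library_size, nb_size = nb_size,
                 histology_slope = histology_slope,
                 histology_noise_sd = histology_noise_sd,
                 satellite_type = satellite_type, paired = paired,
                 timecourse = timecourse, seed = as.integer(seed)),
            class = "bulk_sim_config")
}

#' Simulate a bulk RNA-seq cohort as cell-type mixtures
#'
#' @param cfg a [bulk_sim_config()].
#' @return list with `counts` (raw [count_matrix()]), `metadata`
#'   (data.frame: `sample_id`, `group`, optional `pair_id`, optional
#'   `time`), `histology` (named numeric vector, the pseudo-histology
#'   readout per sample) and `truth` (cell-types x samples proportion
#'   matrix).
#' @export
generate_bulk_cohort <- function(cfg) {
  profiles <- cfg$profiles
  types <- colnames(profiles)

  if (!is.null(cfg$sample_proportions)) {
    props <- cfg$sample_proportions
    if (is.null(colnames(props))) colnames(props) <- sprintf("s%03d", seq_len(ncol(props)))
    meta <- data.frame(sample_id = colnames(props), group = "gradient",
                       stringsAsFactors = FALSE)
  } else {
    groups <- names(cfg$group_proportions)
    n_per <- rep(cfg$n_per_group, length.out = length(groups))
    meta <- data.frame(
      sample_id = unlist(lapply(seq_along(groups), function(i) {
        sprintf("%s_s%02d", groups[i], seq_len(n_per[i]))
      })),
      group = rep(groups, n_per), stringsAsFactors = FALSE)
    props <- vapply(seq_len(nrow(meta)), function(i) {
      cfg$group_proportions[[meta$group[i]]]
    }, numeric(length(types)))
    rownames(props) <- types
    colnames(props) <- meta$sample_id
    if (cfg$paired) {
      if (length(unique(n_per)) != 1L) stop("paired design requires equal group sizes")
      meta$pair_id <- rep(sprintf("p%02d", seq_len(n_per[1L])), length(groups))
    }
    if (!is.null(cfg$timecourse)) {
      meta$time <- cfg$timecourse$time[match(meta$group, paste0("t", cfg$timecourse$time, "h"))]
    }
  }

  with_seed(cfg$seed, {
    expected <- profiles %*% props                       # genes x samples
    mu <- sweep(expected, 2L, colSums(expected), "/") * cfg$library_size
    counts <- matrix(stats::rnbinom(length(mu), size = cfg$nb_size, mu = mu),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    sat_frac <- props[cfg$satellite_type, ]
    histology <- pmax(0, cfg$histology_slope * sat_frac +
                        stats::rnorm(length(sat_frac), 0, cfg$histology_noise_sd))
    names(histology) <- colnames(props)
    list(counts = count_matrix(counts, layer = "raw_counts"),
         metadata = meta, histology = histology, truth = props)
  })
}

#' Default cell-type expression profiles with planted signatures
#'
#' Builds genes x 4 profiles (`satellite`, `myoblast`, `myonuclear`,
#' `other`) over a synthetic gene universe: every type shares a lognormal
#' baseline, and each myogenic type overexpresses its own disjoint planted
#' gene set by `marker_boost`.
#'
#' @param n_genes gene universe size (default 1000).
#' @param n_markers markers per myogenic type (default 10, the satellite
#'   signature size).
#' @param marker_boost expression multiplier for a type's own markers
#'   (default 50 — cluster-restricted expression).
#' @param seed RNG seed for baselines and marker placement.
#' @return list with `profiles` (matrix) and `signatures` (named list of
#'   [gene_signature()]s, one per myogenic type).
#' @export
bulk_profiles <- function(n_genes = 1000L, n_markers = 10L, marker_boost = 50,
                          seed = 99L) {
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  types <- c("satellite", "myoblast", "myonuclear", "other")
  with_seed(seed, {
    base <- stats::rlnorm(n_genes, 1, 1)
    profiles <- matrix(base, nrow = n_genes, ncol = length(types),
                       dimnames = list(gene_ids, types))
    pool <- sample(gene_ids, 3L * n_markers)
    sets <- split(pool, rep(types[1:3], each = n_markers))[types[1:3]]
    for (ty in names(sets)) {
      profiles[sets[[ty]], ty] <- profiles[sets[[ty]], ty] * marker_boost
    }
    sigs <- lapply(names(sets), function(ty) {
      gene_signature(paste0(ty, "_planted"), sort(sets[[ty]]), species = "human")
    })
    names(sigs) <- names(sets)
    list(profiles = profiles, signatures = sigs)
  })
}

#' Default post-injury proportion trajectory
#'
#' Qualitative regeneration dynamics over timepoints 0-48 h: the satellite
#' fraction dips by 8 h, the myoblast/myocyte fraction rises from 16 h, and
#' the myonuclear fraction dips around 20 h and recovers by 48 h.
#'
#' @return data.frame with columns `time`, `satellite`, `myoblast`,
#'   `myonuclear`, `other`.
#' @export
injury_timecourse <- function() {
  tc <- data.frame(
    time       = c(0,     4,     8,     12,    16,    20,    24,    48),
    satellite  = c(0.040, 0.030, 0.015, 0.012, 0.010, 0.010, 0.012, 0.020),
    myoblast   = c(0.010, 0.010, 0.012, 0.020, 0.040, 0.060, 0.070, 0.080),
    myonuclear = c(0.500, 0.490, 0.470, 0.450, 0.420, 0.350, 0.400, 0.480))
  tc$other <- 1 - tc$satellite - tc$myoblast - tc$myonuclear
  tc
}

#' Satellite-fraction gradient design
#'
#' Per-sample proportions with the satellite fraction spanning a range
#' (default 0.5%-10%, evenly spaced) and the remaining mass split between
#' the other types in fixed ratio — the design used to check that signature
#' scores track the underlying cell-type fraction.
#'
#' @param types cell-type names (satellite first).
#' @param n_samples number of samples (default 24).
#' @param satellite_range range of satellite fractions.
#' @return cell-types x samples proportion matrix.
#' @export
satellite_gradient <- function(types = c("satellite", "myoblast", "myonuclear", "other"),
                               n_samples = 24L, satellite_range = c(0.005, 0.10)) {
  sat <- seq(satellite_range[1L], satellite_range[2L], length.out = n_samples)
  rest_w <- c(0.02, 0.50, 0.48)   # myoblast / myonuclear / other split
  props <- rbind(sat, outer(rest_w / sum(rest_w), 1 - sat))
  rownames(props) <- types
  colnames(props) <- sprintf("s%03d", seq_len(n_samples))
  props
}
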