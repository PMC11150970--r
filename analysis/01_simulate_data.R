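#!/usr/bin/env Rscript
# Stage 1: simulate every dataset the downstream analyses consume.
#
# Emulated designs:
#   - a clustered single-cell "derivation atlas" (4 clusters x 500 cells,
#     2000 genes) with 12 satellite-like markers planted in cluster C1
#     (fold change 4, detection 0.8 in-target vs 0.02 elsewhere);
#   - an independent validation dataset sharing the same planted markers;
#   - a bulk case/control cohort whose disease groups carry elevated
#     satellite/myoblast fractions, with a paired pseudo-histology readout
#     (PAX7+ cells per fiber) linked to the true satellite fraction;
#   - a post-injury time course of shifting cell-type proportions.

suppressMessages(library(myosig))

seed <- 20240508L
outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

## single-cell derivation + validation -------------------------------------
derivation <- generate_single_cell(sim_config(seed = seed))
validation <- generate_single_cell(sim_config(
  cells_per_cluster = 250L, seed = seed + 1L,
  markers = list(marker_spec("C1", 12L, 4, 0.8, 0.02,
                             genes = derivation$truth$C1))))

for (nm in c("derivation", "validation")) {
  ds <- get(nm)
  write_count_matrix(ds$counts, file.path(outdir, paste0(nm, "_mtx")),
                     format = "mtx_dir")
  write.table(data.frame(cell_id = ds$annotation$obs_ids,
                         cluster = ds$annotation$cluster_labels),
              file.path(outdir, paste0(nm, "_clusters.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
writeLines(derivation$truth$C1, file.path(outdir, "planted_markers.txt"))

## bulk cohort with pseudo-histology ----------------------------------------
pb <- bulk_profiles(n_genes = 1000L, n_markers = 10L, seed = seed + 2L)
groups <- list(
  control        = c(satellite = 0.015, myoblast = 0.010, myonuclear = 0.500, other = 0.475),
  disease_mild   = c(satellite = 0.030, myoblast = 0.020, myonuclear = 0.460, other = 0.490),
  disease_severe = c(satellite = 0.045, myoblast = 0.040, myonuclear = 0.400, other = 0.515))
cohort <- generate_bulk_cohort(bulk_sim_config(pb$profiles,
                                               group_proportions = groups,
                                               n_per_group = 8L, seed = seed + 3L))
write_count_matrix(cohort$counts, file.path(outdir, "bulk_counts.tsv"), "tsv")
meta <- cohort$metadata
meta$external_measure <- cohort$histology[meta$sample_id]
write.csv(meta, file.path(outdir, "bulk_metadata.csv"), row.names = FALSE)
write.table(cohort$truth, file.path(outdir, "bulk_true_proportions.tsv"),
            sep = "\t", quote = FALSE, col.names = NA)
write_signature_gmt(pb$signatures, file.path(outdir, "bulk_planted_signatures.gmt"))

## post-injury time course ----------------------------------------------------
tc <- generate_bulk_cohort(bulk_sim_config(pb$profiles,
                                           timecourse = injury_timecourse(),
                                           n_per_group = 4L, seed = seed + 4L))
write_count_matrix(tc$counts, file.path(outdir, "timecourse_counts.tsv"), "tsv")
write.csv(tc$metadata, file.path(outdir, "timecourse_metadata.csv"), row.names = FALSE)

cat("Simulated datasets written under", outdir, "\n")
cat(sprintf(" derivation: %d genes x %d cells, %d planted markers in C1\n",
            nrow(derivation$counts), ncol(derivation$counts),
            length(derivation$truth$C1)))
cat(sprintf(" validation: %d cells; bulk cohort: %d samples in 3 groups; time course: %d samples over %d timepoints\n",
            ncol(validation$counts), nrow(meta), nrow(tc$metadata),
            nrow(injury_timecourse())))
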