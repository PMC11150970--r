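test_that("detection fraction counts nonzero cells", {
  m <- count_matrix(matrix(c(0, 2, 0,   0, 0, 0,   1, 1, 1), nrow = 3, byrow = TRUE,
                           dimnames = list(c("gA", "gB", "gC"), c("c1", "c2", "c3"))),
                    layer = "raw_counts")
  d <- detection_fraction(m, c("c1", "c2", "c3"))
  expect_equal(unname(d), c(1 / 3, 0, 1))
  expect_error(detection_fraction(m, character(0)), "non-empty")

  sparse <- random_counts(50, 200, lambda = 0.3, seed = 5)
  sub <- sample(colnames(sparse), 80)
  oracle <- apply(cm_values(sparse)[, sub], 1, function(v) sum(v > 0) / length(v))
  expect_equal(detection_fraction(sparse, sub), oracle)
})

test_that("marker statistics match an independent per-gene recomputation", {
  fix <- planted_small()
  st <- compute_marker_stats(fix$counts, fix$annotation, pseudocount = 0.01)

  counts <- cm_values(fix$counts)
  norm <- sweep(counts, 2, colSums(counts), "/") * 1e4
  tgt <- fix$annotation$cluster_labels == "C1"
  clusters <- fix$annotation$cluster_labels
  # brute-force per-gene loop over every field
  for (g in sample(rownames(counts), 15)) {
    expect_equal(st[g, "mean_target"], mean(norm[g, tgt]))
    expect_equal(st[g, "mean_rest"], mean(norm[g, !tgt]))
    expect_equal(st[g, "fold_change"],
                 (mean(norm[g, tgt]) + 0.01) / (mean(norm[g, !tgt]) + 0.01))
    expect_equal(st[g, "detect_target"], mean(counts[g, tgt] > 0))
    expect_equal(st[g, "detect_global_other"], mean(counts[g, !tgt] > 0))
    expect_equal(st[g, "detect_max_other_cluster"],
                 max(mean(counts[g, clusters == "C2"] > 0),
                     mean(counts[g, clusters == "C3"] > 0)))
  }
  # planted marker leads the fold changes and is confidently DE
  expect_equal(rownames(st)[which.max(st$fold_change)], fix$marker)
  expect_lt(st[fix$marker, "de_qvalue"], 0.01)

  # q-values agree with stats::wilcox.test + BH over the tested genes
  tested <- !is.na(st$de_qvalue)
  p_ref <- vapply(rownames(counts)[tested], function(g) {
    suppressWarnings(stats::wilcox.test(norm[g, tgt], norm[g, !tgt],
                                        exact = FALSE, correct = TRUE)$p.value)
  }, numeric(1))
  expect_equal(st$de_qvalue[tested], unname(p.adjust(p_ref, "BH")), tolerance = 1e-10)
})

test_that("global other-cell detection lies between the per-cluster extremes", {
  fix <- planted_small(seed = 7)
  st <- compute_marker_stats(fix$counts, fix$annotation)
  counts <- cm_values(fix$counts)
  cl <- fix$annotation$cluster_labels
  per <- sapply(c("C2", "C3"), function(k) rowMeans(counts[, cl == k] > 0))
  expect_true(all(st$detect_global_other >= apply(per, 1, min) - 1e-12))
  expect_true(all(st$detect_global_other <= apply(per, 1, max) + 1e-12))
})

test_that("degenerate annotations are rejected", {
  m <- random_counts(10, 9, seed = 3)
  ann1 <- cluster_annotation(colnames(m), rep("C1", 9), "C1")
  expect_error(compute_marker_stats(m, ann1), "every observation|non-target")
  ann2 <- cluster_annotation(rev(colnames(m)), rep(c("C1", "C2", "C3"), 3), "C1")
  expect_error(compute_marker_stats(m, ann2), "match")
})

test_that("fold change behaves at the trivial anchors", {
  # target mean 3, rest mean 1, pseudocount 0 -> fold change 3
  vals <- matrix(c(3, 3, 1, 1, 1, 1), nrow = 1,
                 dimnames = list("gA", paste0("c", 1:6)))
  m <- count_matrix(rbind(vals, gB = 10), layer = "raw_counts")
  ann <- cluster_annotation(paste0("c", 1:6), rep(c("T", "R"), c(2, 4)), "T")
  st <- compute_marker_stats(m, ann, pseudocount = 0, de_test = FALSE)
  norm_fc <- st["gA", "fold_change"]
  counts <- cm_values(m)
  norm <- sweep(counts, 2, colSums(counts), "/") * 1e4
  expect_equal(norm_fc, mean(norm["gA", 1:2]) / mean(norm["gA", 3:6]))

  # identical distributions -> fold change near 1, q-value near 1
  set.seed(8)
  base <- matrix(rpois(40 * 60, 5), nrow = 40,
                 dimnames = list(sprintf("g%02d", 1:40), sprintf("c%02d", 1:60)))
  m2 <- count_matrix(base, layer = "raw_counts")
  ann2 <- cluster_annotation(colnames(base), rep(c("A", "B", "C"), each = 20), "A")
  st2 <- compute_marker_stats(m2, ann2)
  expect_true(all(abs(st2$fold_change - 1) < 0.35))
  expect_gt(median(st2$de_qvalue), 0.5)
})

test_that("threshold filtering equals the brute-force predicate, with strict boundaries", {
  th <- selection_thresholds(1.5, 0.10, 0.30)
  mk <- function(fc, glob, clus, q = 0.001) {
    structure(data.frame(gene = "g", mean_target = 1, mean_rest = 1,
                         fold_change = fc, detect_target = 0.9,
                         detect_global_other = glob,
                         detect_max_other_cluster = clus, de_qvalue = q,
                         row.names = "g"),
              class = c("marker_stats", "data.frame"))
  }
  expect_equal(apply_thresholds(mk(2.0, 0.05, 0.10), th), "g")
  expect_equal(apply_thresholds(mk(1.4, 0.05, 0.10), th), character(0))
  expect_equal(apply_thresholds(mk(1.5, 0.05, 0.10), th), character(0))  # strict >
  expect_equal(apply_thresholds(mk(2.0, 0.10, 0.10), th), character(0))  # strict <
  expect_equal(apply_thresholds(mk(2.0, 0.05, 0.30), th), character(0))  # strict <
  expect_equal(apply_thresholds(mk(2.0, 0.05, 0.10, q = 0.2), th), character(0))
  expect_equal(apply_thresholds(mk(2.0, 0.05, 0.10, q = 0.2), th, de_alpha = NULL), "g")

  # 200 random genes against direct predicate evaluation
  set.seed(17)
  n <- 200
  st <- structure(data.frame(
    gene = sprintf("g%03d", 1:n), mean_target = runif(n), mean_rest = runif(n),
    fold_change = runif(n, 0.5, 3), detect_target = runif(n),
    detect_global_other = runif(n, 0, 0.3),
    detect_max_other_cluster = runif(n, 0, 0.6),
    de_qvalue = runif(n, 0, 0.2), row.names = sprintf("g%03d", 1:n)),
    class = c("marker_stats", "data.frame"))
  got <- apply_thresholds(st, th, de_alpha = 0.05)
  want <- st$gene[st$de_qvalue < 0.05 & st$fold_change > 1.5 &
                    st$detect_global_other < 0.10 & st$detect_max_other_cluster < 0.30]
  expect_setequal(got, want)
  expect_equal(got, got[order(-st[got, "fold_change"], got)])  # descending FC order
})

test_that("grid enumeration is the Cartesian product in deterministic order", {
  g <- enumerate_grid(selection_grid())
  expect_length(g, 27)
  expect_length(enumerate_grid(selection_grid(2, 0.1, 0.3)), 1)
  expect_length(enumerate_grid(selection_grid(c(1.5, 2), c(0.05, 0.1, 0.15), 0.3)), 6)
  # fold change outermost, cluster detection innermost
  fc <- vapply(g, `[[`, numeric(1), "min_fold_change")
  cd <- vapply(g, `[[`, numeric(1), "max_cluster_detection")
  expect_equal(fc, rep(c(1.5, 1.75, 2), each = 9))
  expect_equal(cd, rep(c(0.2, 0.3, 0.4), 9))
})

test_that("tightening any single threshold never grows the selected set", {
  fix <- planted_small(seed = 19, n_genes = 120, marker_boost = 3)
  st <- compute_marker_stats(fix$counts, fix$annotation)
  grid <- selection_grid()
  sel <- lapply(enumerate_grid(grid), function(t) apply_thresholds(st, t))
  idx <- function(i_fc, i_gd, i_cd) (i_fc - 1) * 9 + (i_gd - 1) * 3 + i_cd
  for (i_fc in 1:3) for (i_gd in 1:3) for (i_cd in 1:3) {
    here <- sel[[idx(i_fc, i_gd, i_cd)]]
    if (i_fc < 3) expect_true(all(sel[[idx(i_fc + 1, i_gd, i_cd)]] %in% here))
    if (i_gd > 1) expect_true(all(sel[[idx(i_fc, i_gd - 1, i_cd)]] %in% here))
    if (i_cd > 1) expect_true(all(sel[[idx(i_fc, i_gd, i_cd - 1)]] %in% here))
  }
})

test_that("ROC selection prefers the best-discriminating list above the size floor", {
  set.seed(23)
  # validation matrix where geneshigh separate classes perfectly and genesbad do not
  n <- 40
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  good <- sprintf("good%02d", 1:12)
  ok <- sprintf("ok%02d", 1:12)
  noise <- sprintf("ns%02d", 1:20)
  vals <- rbind(
    matrix(rpois(12 * n, ifelse(rep(labels, each = 12), 30, 1)), nrow = 12,
           dimnames = list(good, NULL)),
    matrix(rpois(12 * n, ifelse(rep(labels, each = 12), 8, 4)), nrow = 12,
           dimnames = list(ok, NULL)),
    matrix(rpois(20 * n, 5), nrow = 20, dimnames = list(noise, NULL)))
  colnames(vals) <- sprintf("c%02d", 1:n)
  vm <- count_matrix(vals, layer = "raw_counts")

  cand <- function(genes, fc = 2) list(thresholds = selection_thresholds(fc, 0.1, 0.3),
                                       genes = genes, passed_min_size = NA,
                                       validation_auc = NA_real_)
  # two candidates: the sharper list wins
  sig <- select_signature(list(cand(ok), cand(good)), vm, labels, min_size = 10)
  expect_setequal(sig$genes, good)

  # a 9-gene list with perfect AUC loses to a 12-gene list at min_size 10
  sig2 <- select_signature(list(cand(good[1:9]), cand(ok)), vm, labels, min_size = 10)
  expect_setequal(sig2$genes, ok)

  # permutation invariance of candidate order
  cands <- list(cand(ok), cand(good), cand(c(good[1:6], ok[1:6])))
  sig_a <- select_signature(cands, vm, labels, min_size = 10)
  sig_b <- select_signature(rev(cands), vm, labels, min_size = 10)
  expect_equal(sig_a$genes, sig_b$genes)

  # nothing above the floor -> actionable error
  expect_error(select_signature(list(cand(good[1:3])), vm, labels, min_size = 10),
               "relax")
})

test_that("derivation recovers planted markers exactly in a clear-separation regime", {
  cfg <- sim_config(n_clusters = 3, cells_per_cluster = 150, n_genes = 500,
                    markers = list(marker_spec("C1", 12, 4, 0.8, 0.02)), seed = 29)
  sim <- generate_single_cell(cfg)
  val <- generate_single_cell(sim_config(
    n_clusters = 3, cells_per_cluster = 100, n_genes = 500,
    markers = list(marker_spec("C1", 12, 4, 0.8, 0.02, genes = sim$truth$C1)),
    seed = 30))
  sig <- derive_signature(sim$counts, sim$annotation,
                          validation_counts = val$counts,
                          validation_labels = is_target_obs(val$annotation))
  expect_setequal(sig$genes, sim$truth$C1)
  expect_gt(sig$provenance$validation_auc, 0.99)
  rep <- candidate_report(sig)
  expect_equal(nrow(rep), 27)
})

test_that("fixed-threshold mode skips the grid search", {
  cfg <- sim_config(n_clusters = 3, cells_per_cluster = 120, n_genes = 400,
                    markers = list(marker_spec("C1", 11, 4, 0.8, 0.02)), seed = 31)
  sim <- generate_single_cell(cfg)
  sig <- derive_signature(sim$counts, sim$annotation,
                          fixed_thresholds = selection_thresholds(1.5, 0.10, 0.30))
  expect_setequal(sig$genes, sim$truth$C1)
  expect_equal(sig$provenance$mode, "fixed")
})
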