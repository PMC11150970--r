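# Small fixture builders used across test files.

# random integer count matrix with unique gene/observation names
random_counts <- function(n_genes, n_obs, lambda = 2, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_obs, lambda), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_obs))))
  count_matrix(m, layer = "raw_counts")
}

# log-normalized matrix with explicit values (for scoring arithmetic tests)
log_matrix <- function(values) {
  count_matrix(values, layer = "log_normalized")
}

# a 3-cluster raw matrix with one planted marker in cluster C1
planted_small <- function(seed = 42, n_genes = 60, cells_per_cluster = 40,
                          marker_boost = 6) {
  set.seed(seed)
  clusters <- rep(c("C1", "C2", "C3"), each = cells_per_cluster)
  mu <- rlnorm(n_genes, 0, 0.6)
  m <- matrix(rnbinom(n_genes * length(clusters), size = 2, mu = mu),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("c%03d", seq_along(clusters))))
  marker <- "g001"
  m[marker, clusters == "C1"] <- rnbinom(cells_per_cluster, size = 2,
                                         mu = mu[1] * marker_boost)
  list(counts = count_matrix(m, layer = "raw_counts"),
       annotation = cluster_annotation(colnames(m), clusters, "C1"),
       marker = marker)
}

# brute-force tie-aware AUC over all positive/negative pairs
pairwise_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
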