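#' Spearman rank correlation
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties).
#' The two-sided p-value uses the t approximation for n > 10; for n <= 7 it
#' is exact (full enumeration of permutations of one argument); for
#' 8 <= n <= 10 it is a seeded Monte-Carlo permutation estimate.
#'
#' @param x,y paired numeric vectors, n >= 4, neither constant.
#' @param n_mc Monte-Carlo draws for 8 <= n <= 10 (default 10000).
#' @return list with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_cor <- function(x, y, n_mc = 10000L) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (anyNA(x) || anyNA(y)) stop("missing values in input")
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("constant input vector: Spearman correlation undefined")
  }
  rho <- stats::cor(rx, ry)
  if (n > 10L) {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  } else if (n <= 7L) {
    perms <- permutations_of(n)
    rho_null <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    p <- with_seed(n, {
      rho_null <- replicate(n_mc, stats::cor(rx, sample(ry)))
      (1 + sum(abs(rho_null) >= abs(rho) - 1e-12)) / (1 + n_mc)
    })
    method <- "Monte-Carlo permutation"
  }
  list(rho = rho, p_value = min(p, 1), n = n, method = method)
}

# all permutations of 1..n as rows (n <= 7 keeps this small)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

#' Random-gene-set resampling null for a score-phenotype correlation
#'
#' Tests whether a curated signature's correlation with an external
#' per-sample measurement (e.g. PAX7+ cells per fiber) out-performs
#' size-matched random gene sets. Each resample draws `sig_size` genes
#' uniformly without replacement from the gene universe, scores them
#' (sum of log-normalized expression) and records the Spearman rho with the
#' external measure. The empirical p is `(1 + #{null >= observed}) /
#' (1 + n_resamples)` — never exactly zero, and equal to `1/(n+1)` exactly
#' when the observed correlation beats every draw (so 1000 resamples with no
#' exceedance reads "p < 0.001").
#'
#' @param m a log-normalized [count_matrix()].
#' @param signature the curated [gene_signature()] whose observed
#'   correlation is tested.
#' @param external numeric vector, one value per observation of `m` (same
#'   order).
#' @param sig_size random-set size; defaults to the number of signature
#'   genes present in the matrix.
#' @param n_resamples number of random sets (default 1000).
#' @param seed RNG seed for the resampling stream.
#' @param universe candidate gene ids; default = genes with nonzero count in
#'   at least one sample (a constant all-zero score has no rank
#'   correlation).
#' @param alternative `"greater"` (default; one-sided on rho, matching a
#'   claimed positive association) or `"two_sided"` (compares |rho|).
#' @return object of class `resampling_result`: list with `observed_rho`,
#'   `null_rhos`, `n_resamples`, `empirical_p`, `seed`,
#'   `gene_universe_size`, `alternative`, `sig_size`.
#' @export
resampling_null <- function(m, signature, external, sig_size = NULL,
                            n_resamples = 1000L, seed = 1L, universe = NULL,
                            alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (cm_layer(m) != "log_normalized") stop("resampling_null expects a log_normalized matrix")
  vals <- cm_values(m)
  if (length(external) != ncol(vals)) stop("external measure length must match observations")
  if (is.null(universe)) universe <- rownames(vals)[rowSums(vals) > 0]
  universe <- intersect(universe, rownames(vals))

  obs_table <- score_signature(m, signature)
  if (is.null(sig_size)) sig_size <- length(attr(obs_table, "genes_used"))
  if (length(universe) < sig_size) {
    stop("gene universe (", length(universe), ") smaller than sig_size (", sig_size, ")")
  }
  observed <- spearman_cor(obs_table$score, external)$rho

  r_ext <- rank(external)
  null_rhos <- with_seed(seed, vapply(seq_len(n_resamples), function(i) {
    genes <- sample(universe, sig_size)
    stats::cor(rank(colSums(vals[genes, , drop = FALSE])), r_ext)
  }, numeric(1L)))

  exceed <- if (alternative == "greater") {
    sum(null_rhos >= observed)
  } else {
    sum(abs(null_rhos) >= abs(observed))
  }
  structure(list(observed_rho = observed, null_rhos = null_rhos,
                 n_resamples = as.integer(n_resamples),
                 empirical_p = (1 + exceed) / (1 + n_resamples),
                 seed = as.integer(seed),
                 gene_universe_size = length(universe),
                 alternative = alternative, sig_size = as.integer(sig_size)),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("<resampling_result> observed rho = %.3f vs %d random %d-gene sets; empirical p = %.4g (%s)\n",
              x$observed_rho, x$n_resamples, x$sig_size, x$empirical_p, x$alternative))
  invisible(x)
}

#' Group comparison of signature scores
#'
#' Dispatches the comparison designs used in practice: two groups ->
#' Wilcoxon (signed-rank when paired, rank-sum otherwise); three or more
#' groups -> one-way ANOVA with Tukey's post-hoc when normality holds,
#' Kruskal-Wallis with Dunn's post-hoc otherwise. When `normality_ok` is not
#' supplied it is decided by per-group Shapiro-Wilk at alpha = 0.05.
#'
#' @param scores numeric vector (e.g. centered signature scores).
#' @param groups factor/character vector of group labels, same length.
#' @param design `"two_group_unpaired"`, `"two_group_paired"` or
#'   `"multi_group"`.
#' @param pair_ids required for the paired design: pair identifier per
#'   observation; every pair must appear exactly once in each group.
#' @param normality_ok logical; overrides the Shapiro-Wilk gate for the
#'   multi-group design.
#' @return data.frame with one row per comparison: `comparison`, `test`,
#'   `statistic`, `p_value`, `stars`.
#' @export
group_compare <- function(scores, groups,
                          design = c("two_group_unpaired", "two_group_paired", "multi_group"),
                          pair_ids = NULL, normality_ok = NULL) {
  design <- match.arg(design)
  groups <- as.character(groups)
  if (length(scores) != length(groups)) stop("scores and groups differ in length")
  lv <- unique(groups)
  if (any(table(groups) < 2L)) stop("every group needs at least 2 observations")

  if (design %in% c("two_group_unpaired", "two_group_paired")) {
    if (length(lv) != 2L) stop("two-group design requires exactly 2 groups, got ", length(lv))
    x <- scores[groups == lv[1L]]
    y <- scores[groups == lv[2L]]
    if (design == "two_group_paired") {
      if (is.null(pair_ids)) stop("paired design requires pair_ids")
      p1 <- pair_ids[groups == lv[1L]]
      p2 <- pair_ids[groups == lv[2L]]
      unmatched <- c(setdiff(p1, p2), setdiff(p2, p1))
      if (length(unmatched) || length(p1) != length(p2)) {
        stop("incomplete pairs: ", paste(unique(unmatched), collapse = ", "))
      }
      y <- y[match(p1, p2)]
      ht <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
      test <- "Wilcoxon signed-rank (paired)"
    } else {
      ht <- suppressWarnings(stats::wilcox.test(x, y))
      test <- "Wilcoxon rank-sum"
    }
    out <- data.frame(comparison = paste(lv[1L], "vs", lv[2L]), test = test,
                      statistic = unname(ht$statistic), p_value = ht$p.value,
                      stringsAsFactors = FALSE)
  } else {
    if (length(lv) < 3L) stop("multi_group design requires >= 3 groups")
    if (is.null(normality_ok)) {
      sw <- vapply(lv, function(g) {
        v <- scores[groups == g]
        if (length(v) < 3L || stats::sd(v) == 0) return(0)  # too small/degenerate: treat as non-normal
        stats::shapiro.test(v)$p.value
      }, numeric(1L))
      normality_ok <- all(sw > 0.05)
    }
    gf <- factor(groups, levels = lv)
    if (normality_ok) {
      fit <- stats::aov(scores ~ gf)
      tk <- stats::TukeyHSD(fit)$gf
      out <- data.frame(comparison = sub("-", " vs ", rownames(tk), fixed = TRUE),
                        test = "ANOVA + Tukey HSD",
                        statistic = tk[, "diff"], p_value = tk[, "p adj"],
                        stringsAsFactors = FALSE)
    } else {
      out <- dunn_posthoc(scores, gf)
    }
    rownames(out) <- NULL
  }
  out$stars <- as.character(p_stars(out$p_value))
  out
}

# Dunn's post-hoc z-tests on Kruskal-Wallis ranks with tie correction;
# two-sided unadjusted p per pairwise comparison.
dunn_posthoc <- function(scores, gf) {
  N <- length(scores)
  r <- rank(scores)
  nt <- table_counts(scores)
  tie_term <- sum(nt^3 - nt) / (12 * (N - 1))
  mean_rank <- tapply(r, gf, mean)
  n_g <- tapply(r, gf, length)
  lv <- levels(gf)
  combs <- utils::combn(lv, 2L)
  rows <- apply(combs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_g[[i]] + 1 / n_g[[j]]))
    z <- (mean_rank[[i]] - mean_rank[[j]]) / se
    data.frame(comparison = paste(j, "vs", i), test = "Kruskal-Wallis + Dunn",
               statistic = z, p_value = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
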