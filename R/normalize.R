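#' Median-of-ratios size factors
#'
#' Per-sample size factor as the median, over usable genes, of the ratio
#' count / geometric-mean reference. The reference for each sample is the
#' geometric mean of the \emph{other} samples' counts (leave-one-out), so
#' multiplying one sample's counts by a constant multiplies its size factor
#' by exactly that constant and leaves its normalized values exactly
#' unchanged — the all-sample pseudo-reference of the classical estimator
#' only has this covariance asymptotically, because the reference itself
#' absorbs a share of the scaling. The two references agree closely on
#' real-size cohorts.
#'
#' A gene is usable for a sample when it is nonzero in that sample and in
#' every other sample (finite leave-one-out geometric mean).
#'
#' @param counts raw integer count matrix, genes x samples (>= 2 samples).
#' @return numeric vector of size factors, one per sample.
#' @export
size_factors_median_ratio <- function(counts) {
  n <- ncol(counts)
  if (n < 2L) stop("median-of-ratios needs at least 2 samples")
  lc <- log(counts)                       # -Inf where count is zero
  zero <- counts == 0
  lc_fin <- ifelse(zero, 0, lc)
  row_sum <- rowSums(lc_fin)
  n_zero <- rowSums(zero)
  vapply(seq_len(n), function(j) {
    # leave-one-out log geometric mean, finite iff no zero among the others
    others_ok <- (n_zero - zero[, j]) == 0
    usable <- others_ok & counts[, j] > 0
    if (!any(usable)) {
      stop("sample '", colnames(counts)[j], "' shares no all-nonzero gene with ",
           "the rest; median-of-ratios undefined — consider sc_library_size mode")
    }
    log_ref <- (row_sum[usable] - lc_fin[usable, j]) / (n - 1)
    stats::median(exp(lc[usable, j] - log_ref))
  }, numeric(1L))
}

#' Log-normalize a raw count matrix
#'
#' Two conventions:
#' \describe{
#'   \item{`bulk_median_of_ratios`}{median-of-ratios size factors (see
#'     [size_factors_median_ratio()]), then `log2(count / size_factor + 1)`.
#'     Invariant to rescaling any one sample's counts.}
#'   \item{`sc_library_size`}{per-cell library-size scaling to 10,000
#'     counts, then `ln(x + 1)` — the standard single-cell convention.}
#' }
#'
#' @param m a [count_matrix()] with layer `raw_counts`.
#' @param mode `"bulk_median_of_ratios"` or `"sc_library_size"`.
#' @param log_base logarithm base for bulk mode (default 2). Scores built on
#'   these values are compared within a dataset, so the base is a convention,
#'   not a result.
#' @return a [count_matrix()] with layer `log_normalized`.
#' @export
log_normalize <- function(m, mode = c("bulk_median_of_ratios", "sc_library_size"),
                          log_base = 2) {
  mode <- match.arg(mode)
  if (cm_layer(m) != "raw_counts") stop("log_normalize expects a raw_counts matrix")
  counts <- cm_values(m)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  if (mode == "bulk_median_of_ratios") {
    sf <- size_factors_median_ratio(counts)
    out <- log(sweep(counts, 2L, sf, "/") + 1) / log(log_base)
  } else {
    out <- log1p(sweep(counts, 2L, lib, "/") * 1e4)
  }
  count_matrix(out, layer = "log_normalized")
}

#' Linear library-size-normalized expression
#'
#' Counts scaled per observation to 10,000 total — the linear-scale
#' counterpart of `sc_library_size` log normalization; used for marker
#' fold-change computation.
#'
#' @param m a [count_matrix()] with layer `raw_counts`.
#' @return a [count_matrix()] with layer `normalized`.
#' @export
normalize_linear <- function(m) {
  if (cm_layer(m) != "raw_counts") stop("normalize_linear expects a raw_counts matrix")
  counts <- cm_values(m)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("observation(s) with zero total counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  count_matrix(sweep(counts, 2L, lib, "/") * 1e4, layer = "normalized")
}
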