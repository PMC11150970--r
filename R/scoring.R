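#' Score a gene signature per observation
#'
#' The signature score of an observation is the plain sum of its
#' log-normalized expression over the signature genes present in the matrix.
#' Genes absent from the matrix are excluded from the signature for the
#' analysis; the retained fraction is recorded as coverage and a warning is
#' emitted when it falls below `coverage_warn` (default 0.75). Scores are
#' sums, not means, so signature size sets the scale — compare scores only
#' within a dataset, ideally after [center_scores()].
#'
#' @param m a [count_matrix()] with layer `log_normalized`.
#' @param sig a [gene_signature()].
#' @param coverage_warn warn when the fraction of signature genes found in
#'   the matrix is below this value.
#' @return a `score_table`: data.frame with columns `obs_id` and `score`,
#'   plus attributes `signature`, `coverage`, `genes_used`.
#' @export
score_signature <- function(m, sig, coverage_warn = 0.75) {
  if (cm_layer(m) != "log_normalized") {
    stop("score_signature expects a log_normalized matrix; run log_normalize() first")
  }
  vals <- cm_values(m)
  present <- sig$genes[sig$genes %in% rownames(vals)]
  if (!length(present)) {
    stop("none of the ", length(sig$genes), " genes of signature '", sig$name,
         "' are present in the matrix")
  }
  coverage <- length(present) / length(sig$genes)
  if (coverage < coverage_warn) {
    warning(sprintf("signature '%s': only %d/%d genes present (coverage %.2f < %.2f)",
                    sig$name, length(present), length(sig$genes), coverage, coverage_warn))
  }
  score <- colSums(vals[present, , drop = FALSE])
  out <- data.frame(obs_id = colnames(vals), score = unname(score),
                    stringsAsFactors = FALSE)
  structure(out, signature = sig$name, coverage = coverage, genes_used = present,
            centering = NULL, class = c("score_table", "data.frame"))
}

#' Center signature scores on a control group
#'
#' Subtracts the arithmetic mean of the control observations' scores from
#' every score, so controls average exactly zero and case scores read as
#' differences from the control average.
#'
#' @param s a `score_table` from [score_signature()].
#' @param control_ids observation ids forming the control/reference group;
#'   must all be present in `s`.
#' @return a `score_table` with centered `score` and a `centering` attribute
#'   recording the control ids and subtracted mean.
#' @export
center_scores <- function(s, control_ids) {
  control_ids <- as.character(control_ids)
  if (!length(control_ids)) stop("control_ids must be non-empty")
  missing_ids <- setdiff(control_ids, s$obs_id)
  if (length(missing_ids)) {
    stop("control id(s) not found in score table: ", paste(missing_ids, collapse = ", "))
  }
  ctrl_mean <- mean(s$score[s$obs_id %in% control_ids])
  s$score <- s$score - ctrl_mean
  attr(s, "centering") <- list(control_ids = control_ids, subtracted_mean = ctrl_mean)
  s
}

#' Score several signatures into one long table
#'
#' @param m a log-normalized [count_matrix()].
#' @param signatures list of [gene_signature()] objects.
#' @param control_ids optional control ids; when given, a `centered_score`
#'   column is added per signature.
#' @param coverage_warn passed to [score_signature()].
#' @return data.frame with columns `sample_id`, `signature`, `score`,
#'   `centered_score` (if centered), `coverage`.
#' @export
score_signatures <- function(m, signatures, control_ids = NULL, coverage_warn = 0.75) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  rows <- lapply(signatures, function(sig) {
    st <- score_signature(m, sig, coverage_warn = coverage_warn)
    out <- data.frame(sample_id = st$obs_id, signature = sig$name,
                      score = st$score, coverage = attr(st, "coverage"),
                      stringsAsFactors = FALSE)
    if (!is.null(control_ids)) {
      out$centered_score <- center_scores(st, control_ids)$score
    }
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
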