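#' Expression count matrix
#'
#' The universal expression container of the package: a genes x observations
#' matrix of non-negative values with unique gene and observation identifiers
#' and a layer tag recording what the values are (raw integer counts,
#' linear normalized expression, or log-normalized expression).
#'
#' @param values numeric matrix (base or \pkg{Matrix} sparse), genes as rows,
#'   observations as columns, with unique non-empty rownames (gene ids) and
#'   colnames (observation ids).
#' @param layer one of `"raw_counts"`, `"normalized"`, `"log_normalized"`.
#'   The raw layer must contain integer values only.
#'
#' @return An object of class `count_matrix`: the matrix itself with a
#'   `layer` attribute.
#' @export
count_matrix <- function(values, layer = c("raw_counts", "normalized", "log_normalized")) {
  layer <- match.arg(layer)
  if (!(is.matrix(values) || methods::is(values, "Matrix"))) {
    stop("`values` must be a matrix (base or Matrix)")
  }
  gid <- rownames(values)
  oid <- colnames(values)
  if (is.null(gid) || is.null(oid)) stop("`values` must have rownames (gene ids) and colnames (observation ids)")
  dup_g <- unique(gid[duplicated(gid)])
  if (length(dup_g)) stop("duplicate gene ids: ", paste(utils::head(dup_g, 5L), collapse = ", "))
  dup_o <- unique(oid[duplicated(oid)])
  if (length(dup_o)) stop("duplicate observation ids: ", paste(utils::head(dup_o, 5L), collapse = ", "))
  v <- if (methods::is(values, "Matrix")) values@x else values
  if (anyNA(v) || !is.numeric(v)) stop("values must be numeric and non-missing")
  if (any(v < 0)) {
    bad <- which(as.matrix(values) < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative entry at gene '%s', observation '%s'", gid[bad[1L]], oid[bad[2L]]))
  }
  if (layer == "raw_counts" && any(v != floor(v))) {
    bad <- which(as.matrix(values) != floor(as.matrix(values)), arr.ind = TRUE)[1L, ]
    stop(sprintf("raw_counts layer requires integers; non-integer at gene '%s', observation '%s'",
                 gid[bad[1L]], oid[bad[2L]]))
  }
  structure(values, layer = layer, class = c("count_matrix", class(values)))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d observations, layer = %s\n",
              nrow(x), ncol(x), cm_layer(x)))
  invisible(x)
}

#' Layer tag of a count matrix
#' @param m a `count_matrix`.
#' @return `"raw_counts"`, `"normalized"` or `"log_normalized"`.
#' @export
cm_layer <- function(m) attr(m, "layer")

#' Underlying numeric matrix of a count matrix
#'
#' Strips the class so that plain matrix algebra applies; sparse input is
#' densified.
#' @param m a `count_matrix`.
#' @return base numeric matrix.
#' @export
cm_values <- function(m) {
  cls <- class(m)
  attr(m, "layer") <- NULL
  class(m) <- setdiff(cls, "count_matrix")
  as.matrix(m)
}

#' Cluster annotation for a count matrix
#'
#' Maps each observation (cell) to a cluster label and designates which
#' clusters form the target population of interest (e.g. the satellite-cell
#' pseudotime bins of a myogenic atlas).
#'
#' @param obs_ids character vector of observation ids, matching a
#'   `count_matrix` column order.
#' @param cluster_labels character vector, one label per observation.
#' @param target_clusters character vector of labels defining the target
#'   population; must be a non-empty subset of the observed labels.
#' @return An object of class `cluster_annotation`.
#' @export
cluster_annotation <- function(obs_ids, cluster_labels, target_clusters) {
  obs_ids <- as.character(obs_ids)
  cluster_labels <- as.character(cluster_labels)
  target_clusters <- as.character(target_clusters)
  if (length(obs_ids) != length(cluster_labels)) stop("obs_ids and cluster_labels differ in length")
  if (anyDuplicated(obs_ids)) stop("duplicate observation ids in annotation")
  if (!length(target_clusters)) stop("target_clusters must be non-empty")
  missing_cl <- setdiff(target_clusters, unique(cluster_labels))
  if (length(missing_cl)) {
    stop("target cluster(s) not observed: ", paste(missing_cl, collapse = ", "))
  }
  structure(list(obs_ids = obs_ids, cluster_labels = cluster_labels,
                 target_clusters = target_clusters),
            class = "cluster_annotation")
}

#' @export
print.cluster_annotation <- function(x, ...) {
  cat(sprintf("<cluster_annotation> %d observations, %d clusters, target: %s\n",
              length(x$obs_ids), length(unique(x$cluster_labels)),
              paste(x$target_clusters, collapse = ", ")))
  invisible(x)
}

#' Target-population membership of each observation
#'
#' @param ann a [cluster_annotation()].
#' @return logical vector, `TRUE` where the observation's cluster is one of
#'   the target clusters.
#' @export
is_target_obs <- function(ann) ann$cluster_labels %in% ann$target_clusters

check_annotation_matches <- function(m, ann) {
  if (!identical(colnames(m), ann$obs_ids)) {
    stop("annotation obs_ids do not match count matrix columns (same ids, same order required)")
  }
  invisible(TRUE)
}
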