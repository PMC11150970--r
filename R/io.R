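#' Read a count matrix from disk
#'
#' Two dialects are supported: a dense TSV (genes as rows, first column the
#' gene id, header row of observation ids) and a MatrixMarket directory
#' (`matrix.mtx` in coordinate format with `genes.tsv` / `barcodes.tsv`
#' sidecars whose order defines the matrix order).
#'
#' @param path file (TSV) or directory (MTX) path.
#' @param format `"tsv"` or `"mtx_dir"`.
#' @return a [count_matrix()] with layer `raw_counts`, input ordering
#'   preserved.
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx_dir")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    gid <- as.character(df[[1L]])
    vals <- df[, -1L, drop = FALSE]
    non_num <- !vapply(vals, is.numeric, logical(1L))
    if (any(non_num)) {
      j <- which(non_num)[1L]
      i <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1L]
      stop(sprintf("non-numeric entry at gene '%s', observation '%s' in %s",
                   gid[if (is.na(i)) 1L else i], colnames(vals)[j], path))
    }
    m <- as.matrix(vals)
    rownames(m) <- gid
    count_matrix(m, layer = "raw_counts")
  } else {
    mtx <- file.path(path, "matrix.mtx")
    genes_f <- file.path(path, "genes.tsv")
    barcodes_f <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, genes_f, barcodes_f)) {
      if (!file.exists(f)) stop("missing file: ", f)
    }
    m <- as.matrix(Matrix::readMM(mtx))
    genes <- utils::read.delim(genes_f, header = FALSE, stringsAsFactors = FALSE)[[1L]]
    barcodes <- utils::read.delim(barcodes_f, header = FALSE, stringsAsFactors = FALSE)[[1L]]
    if (nrow(m) != length(genes) || ncol(m) != length(barcodes)) {
      stop(sprintf("MTX shape %dx%d does not match sidecars (%d genes, %d barcodes)",
                   nrow(m), ncol(m), length(genes), length(barcodes)))
    }
    rownames(m) <- genes
    colnames(m) <- barcodes
    count_matrix(m, layer = "raw_counts")
  }
}

#' Write a count matrix to disk
#'
#' @param m a [count_matrix()].
#' @param path target TSV file or MTX directory (created if absent).
#' @param format `"tsv"` or `"mtx_dir"`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path, format = c("tsv", "mtx_dir")) {
  format <- match.arg(format)
  vals <- cm_values(m)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(vals), vals, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(vals, sparse = TRUE), file.path(path, "matrix.mtx"))
    writeLines(rownames(vals), file.path(path, "genes.tsv"))
    writeLines(colnames(vals), file.path(path, "barcodes.tsv"))
  }
  invisible(path)
}

#' Read gene signatures from a GMT file
#'
#' Standard GMT: one set per line, `name TAB description TAB gene TAB gene ...`.
#'
#' @param path GMT file.
#' @param species species tag to attach to each signature.
#' @return named list of [gene_signature()] objects.
#' @export
read_signature_gmt <- function(path, species = c("human", "mouse")) {
  species <- match.arg(species)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sigs <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    fields <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has %d field(s); need name, description and >=1 gene",
                   k, length(fields)))
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    dup <- unique(genes[duplicated(genes)])
    if (length(dup)) {
      stop(sprintf("GMT line %d ('%s') has duplicate genes: %s",
                   k, fields[1L], paste(dup, collapse = ", ")))
    }
    sigs[[k]] <- gene_signature(fields[1L], genes, species = species,
                                provenance = list(description = fields[2L]))
  }
  names(sigs) <- vapply(sigs, `[[`, character(1L), "name")
  sigs
}

#' Write gene signatures to a GMT file
#'
#' @param signatures a [gene_signature()] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_signature_gmt <- function(signatures, path) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  lines <- vapply(signatures, function(s) {
    desc <- s$provenance$description
    if (is.null(desc) || !nzchar(desc)) desc <- "na"
    paste(c(s$name, desc, s$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Published myogenic cell-type signatures
#'
#' Loads the packaged satellite cell (10 genes), myoblast/myocyte (25 genes)
#' and myonuclear type I/IIa/IIx (66 genes) signatures, as human gene
#' symbols.
#'
#' @return named list of three [gene_signature()] objects:
#'   `satellite_cell`, `myoblast_myocyte`, `myonuclear`.
#' @export
muscle_signatures <- function() {
  path <- system.file("extdata", "muscle_signatures.gmt", package = "myosig",
                      mustWork = TRUE)
  read_signature_gmt(path, species = "human")
}

#' Read sample metadata
#'
#' CSV with columns `sample_id`, `group` and optionally `pair_id` and
#' `external_measure`.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in ", path)
  df
}
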