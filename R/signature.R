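#' Gene signature
#'
#' A named, ordered list of unique gene symbols with species and optional
#' selection-parameter provenance (the thresholds that produced it and a
#' source-dataset tag).
#'
#' @param name non-empty signature name.
#' @param genes character vector of unique, non-empty gene symbols.
#' @param species `"human"` or `"mouse"`.
#' @param provenance optional list, e.g. `list(thresholds = <selection_thresholds>,
#'   source = "derivation-atlas")`.
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes, species = c("human", "mouse"), provenance = NULL) {
  species <- match.arg(species)
  genes <- as.character(genes)
  if (!nzchar(name)) stop("signature name must be non-empty")
  if (!length(genes)) stop("signature gene list must be non-empty")
  if (any(!nzchar(genes))) stop("empty gene symbol in signature '", name, "'")
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) stop("duplicate genes in signature '", name, "': ", paste(dup, collapse = ", "))
  structure(list(name = name, genes = genes, species = species, provenance = provenance),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s (%s, %d genes): %s%s\n",
              x$name, x$species, length(x$genes),
              paste(utils::head(x$genes, 6L), collapse = ", "),
              if (length(x$genes) > 6L) ", ..." else ""))
  invisible(x)
}

#' Map a signature across species via an ortholog table
#'
#' Translates every symbol of a signature through a one-to-one ortholog
#' table, dropping symbols without a counterpart in the target species.
#' The mapped symbols keep the original order; the mapped and dropped lists
#' partition the input exactly.
#'
#' @param sig a [gene_signature()].
#' @param table ortholog table: a named character vector
#'   (source symbol -> target symbol) or a two-column data frame
#'   (source, target). `NA`/empty targets count as unmapped.
#' @param target_species species of the mapped signature; must differ from
#'   `sig$species`.
#' @return list with elements `signature` (mapped [gene_signature()]) and
#'   `dropped` (character vector of unmapped input symbols).
#' @export
map_orthologs <- function(sig, table, target_species = c("human", "mouse")) {
  target_species <- match.arg(target_species)
  if (identical(sig$species, target_species)) {
    stop("signature is already in species '", target_species, "'")
  }
  map <- as_ortholog_map(table)
  tgt <- unname(map[sig$genes])
  mapped <- !is.na(tgt) & nzchar(tgt)
  dropped <- sig$genes[!mapped]
  out_genes <- tgt[mapped]
  if (!length(out_genes)) {
    stop("no gene of signature '", sig$name, "' has an ortholog in ", target_species,
         "; signature unusable in target species")
  }
  if (anyDuplicated(out_genes)) {
    dup <- unique(out_genes[duplicated(out_genes)])
    warning("ortholog mapping collapsed several source genes onto: ",
            paste(dup, collapse = ", "), "; keeping first occurrence")
    keep <- !duplicated(out_genes)
    dropped <- c(dropped, sig$genes[mapped][!keep])
    out_genes <- out_genes[keep]
  }
  prov <- c(sig$provenance, list(mapped_from = sig$species, n_dropped = length(dropped)))
  list(signature = gene_signature(sig$name, out_genes, species = target_species,
                                  provenance = prov),
       dropped = dropped)
}

as_ortholog_map <- function(table) {
  if (is.data.frame(table)) {
    if (ncol(table) < 2L) stop("ortholog table needs two columns (source, target)")
    map <- as.character(table[[2L]])
    names(map) <- as.character(table[[1L]])
  } else if (is.character(table)) {
    if (is.null(names(table))) stop("ortholog vector must be named by source symbol")
    map <- table
  } else {
    stop("unsupported ortholog table type")
  }
  if (anyDuplicated(names(map))) stop("duplicate source symbols in ortholog table")
  map
}

#' Read a two-column ortholog table from TSV
#'
#' @param path TSV with a header and at least two columns: source symbol,
#'   target symbol (empty target = no ortholog).
#' @return named character vector, source -> target.
#' @export
read_ortholog_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 2L) stop("ortholog table needs two columns: ", path)
  map <- as.character(df[[2L]])
  map[!nzchar(map)] <- NA_character_
  names(map) <- as.character(df[[1L]])
  if (anyDuplicated(names(map))) stop("duplicate source symbols in ", path)
  map
}
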