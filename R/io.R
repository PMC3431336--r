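# Readers and writers for the pipeline's tabular and sequence formats.

#' Write / read a gene x sample expression matrix as TSV
#'
#' First column `gene`, remaining columns sample IDs.
#'
#' @param expr numeric matrix with dimnames.
#' @param path TSV path.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Write / read a gene role table as TSV (columns gene, role)
#'
#' @param role_map data.frame with columns `gene`, `role`.
#' @param path TSV path.
#' @export
write_roles_tsv <- function(role_map, path) {
  utils::write.table(role_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_roles_tsv
#' @export
read_roles_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read promoter sequences as FASTA
#'
#' One record per target gene, header = gene symbol.
#'
#' @param promoters named character vector of sequences.
#' @param path FASTA path.
#' @export
write_promoters_fasta <- function(promoters, path) {
  x <- Biostrings::DNAStringSet(promoters)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_promoters_fasta
#' @export
read_promoters_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a PPI network as a two-column TSV edge list
#'
#' @param network an `igraph` object.
#' @param path TSV path.
#' @export
write_ppi_tsv <- function(network, path) {
  el <- igraph::as_edgelist(network)
  writeLines(paste(el[, 1], el[, 2], sep = "\t"), path)
  invisible(path)
}

#' Write / read a triplet table as TSV
#'
#' @param triplets data.frame (modulator, tf, target, statistics...).
#' @param path TSV path.
#' @export
write_triplets_tsv <- function(triplets, path) {
  utils::write.table(triplets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_triplets_tsv
#' @export
read_triplets_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
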