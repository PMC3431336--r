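# Binary regulatory profiles of modulators and their hierarchical clustering.

#' Build binary regulatory profiles for the modulators
#'
#' One row per modulator.  On the `tf` axis, entry (M, T) is 1 iff the
#' modulation edge M -> T exists; on the `target` axis, entry (M, G) is 1 iff
#' some TF T carries both M -> T and T -> G (two-hop reachability).  Columns
#' span all TFs (or all targets) of the network, so profiles of different
#' modulators are comparable.
#'
#' @param network a `regnet`.
#' @param axis `"tf"` or `"target"`.
#' @return binary integer matrix, rownames = modulators, colnames = TFs or
#'   targets.
#' @export
build_profiles <- function(network, axis = c("tf", "target")) {
  axis <- match.arg(axis)
  mods <- network$modulators
  cols <- if (axis == "tf") network$tfs else network$targets
  prof <- matrix(0L, length(mods), length(cols),
                 dimnames = list(mods, cols))
  if (axis == "tf") {
    prof[cbind(network$modulation$modulator, network$modulation$tf)] <- 1L
  } else {
    two_hop <- merge(network$modulation[c("modulator", "tf")],
                     network$regulation[c("tf", "target")], by = "tf")
    prof[unique(cbind(two_hop$modulator, two_hop$target))] <- 1L
  }
  prof
}

#' Hierarchically cluster modulator profiles
#'
#' Agglomerative clustering of the binary profile rows.  Defaults are
#' euclidean distance with complete linkage; `jaccard` (binary) distance and
#' `average` linkage are available for sparse binary data.  All-zero rows are
#' retained and flagged.
#'
#' @param profile binary matrix from [build_profiles()].
#' @param distance `"euclidean"` or `"jaccard"`.
#' @param linkage `"complete"` or `"average"`.
#' @return an `hclust` object with attributes `distance`, `linkage`,
#'   `zero_rows`.
#' @export
hcluster <- function(profile, distance = c("euclidean", "jaccard"),
                     linkage = c("complete", "average")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (nrow(profile) < 2) .err("need at least 2 rows to cluster")
  d <- stats::dist(profile,
                   method = if (distance == "jaccard") "binary" else "euclidean")
  hc <- stats::hclust(d, method = linkage)
  attr(hc, "distance") <- distance
  attr(hc, "linkage") <- linkage
  zero <- rownames(profile)[rowSums(profile) == 0]
  if (length(zero)) message(length(zero), " all-zero profile row(s): ",
                            paste(zero, collapse = ", "))
  attr(hc, "zero_rows") <- zero
  hc
}

#' Class purity of the branches at a dendrogram cut
#'
#' Cuts the tree into `k` branches and reports, per branch, its size, the
#' majority class and the majority fraction (purity).
#'
#' @param tree an `hclust` from [hcluster()].
#' @param k number of branches (>= 2).
#' @param class_labels named character vector, names covering all clustered
#'   rows.
#' @return data.frame: branch, size, majority, purity; mean purity as
#'   attribute `"mean_purity"`.
#' @export
branch_purity <- function(tree, k, class_labels) {
  if (k < 2) .err("k must be >= 2")
  ct <- stats::cutree(tree, k = k)
  if (!all(names(ct) %in% names(class_labels)))
    .err("class_labels must cover all clustered rows")
  lab <- class_labels[names(ct)]
  out <- do.call(rbind, lapply(sort(unique(ct)), function(b) {
    tb <- table(lab[ct == b])
    data.frame(branch = b, size = sum(tb),
               majority = names(tb)[which.max(tb)],
               purity = max(tb) / sum(tb), stringsAsFactors = FALSE)
  }))
  attr(out, "mean_purity") <- mean(out$purity)
  out
}

#' Export a dendrogram in Newick format
#'
#' @param tree an `hclust`.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Write / read a binary profile matrix as TSV
#'
#' @param profile binary matrix.
#' @param path TSV path (first column `modulator`).
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(modulator = rownames(profile), profile, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- d[[1]]
  m
}
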