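# PPI topology: loading, centrality statistics, KS comparisons, empirical
# resampling p-values and seed-neighborhood extraction.

#' Load a protein-protein interaction network from a two-column edge list
#'
#' Reads a tab-separated edge list of gene symbols, drops self-interactions,
#' and collapses duplicate edges in either orientation.  The number of dropped
#' records is reported.
#'
#' @param path TSV file, two columns per line.
#' @param header logical; does the file start with a header line?
#' @param strict if `TRUE` (default) a line without exactly two non-empty
#'   fields is an error naming the line number; otherwise it is skipped with
#'   a warning.
#' @return an undirected simple `igraph` object.
#' @export
load_ppi <- function(path, header = FALSE, strict = TRUE) {
  lines <- readLines(path)
  if (header && length(lines)) lines <- lines[-1]
  lines_no <- seq_along(lines) + as.integer(header)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]; lines_no <- lines_no[keep]
  if (!length(lines)) {
    warning("empty edge list: returning an empty network")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) < 2 || !nzchar(p[1]) || !nzchar(p[2]),
                logical(1))
  if (any(bad)) {
    if (strict) .err("malformed edge list line ", lines_no[which(bad)[1]],
                     " in ", path)
    warning(sum(bad), " malformed line(s) skipped")
    parts <- parts[!bad]
  }
  a <- vapply(parts, `[`, character(1), 1)
  b <- vapply(parts, `[`, character(1), 2)
  self <- a == b
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  dup <- duplicated(key) & !self
  dropped <- sum(self) + sum(dup)
  if (dropped) message(dropped, " self-interaction/duplicate record(s) dropped")
  keep <- !self & !duplicated(key)
  if (!any(keep)) {
    warning("no edges left after filtering")
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(igraph::add_vertices(g, length(unique(c(a, b))),
                                name = unique(c(a, b))))
  }
  igraph::graph_from_data_frame(data.frame(a[keep], b[keep]), directed = FALSE)
}

#' Per-node topology statistics of a PPI network
#'
#' Degree, betweenness centrality and closeness centrality for every node.
#' Closeness is the inverse mean shortest-path distance within a node's
#' component, scaled by `(reachable - 1) / (n - 1)` so values are comparable
#' across components and lie in `[0, 1]`; isolated nodes get closeness 0.
#' Betweenness counts shortest paths through a node; set
#' `normalize_betweenness = TRUE` to divide by `(n-1)(n-2)/2`.
#'
#' @param network an `igraph` object.
#' @param normalize_betweenness logical, default `FALSE` (raw path counts).
#' @return data.frame with columns gene, degree, betweenness, closeness.
#' @export
topology_stats <- function(network, normalize_betweenness = FALSE) {
  n <- igraph::vcount(network)
  if (n == 0) .err("network is empty")
  deg <- igraph::degree(network)
  btw <- igraph::betweenness(network, directed = FALSE,
                             normalized = normalize_betweenness)
  d <- igraph::distances(network)
  clo <- apply(d, 1, function(row) {
    reach <- sum(is.finite(row)) - 1
    if (reach <= 0 || n == 1) return(0)
    (reach / sum(row[is.finite(row)])) * (reach / (n - 1))
  })
  nm <- igraph::V(network)$name %||% as.character(seq_len(n))
  data.frame(gene = nm, degree = as.numeric(deg), betweenness = as.numeric(btw),
             closeness = as.numeric(clo), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-tailed KS test of two samples of a topology metric, using the
#' asymptotic two-sample null distribution.
#'
#' @param values_a,values_b numeric vectors (each length >= 2).
#' @return list with `D` (sup distance) and `p` (two-tailed p-value).
#' @export
ks_compare <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    .err("both samples must have size >= 2")
  kt <- suppressWarnings(stats::ks.test(values_a, values_b, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Empirical resampling p-value for a gene set's mean topology metric
#'
#' Draws `R` random gene sets of the same size (without replacement) from a
#' background pool and counts how many have a strictly greater mean metric
#' than the observed set; `p = N_exceed / R`.  A p of 0 is reported with a
#' note that it should be read as `< 1/R`.
#'
#' @param stats data.frame from [topology_stats()].
#' @param gene_set character vector of genes (subset of `stats$gene`).
#' @param background_pool character vector to resample from.
#' @param metric one of `"degree"`, `"betweenness"`, `"closeness"`.
#' @param R number of resamples (default 10000).
#' @param seed integer seed.
#' @return object of class `resampling_result`: list with `observed_mean`,
#'   `N_exceed`, `R`, `p`, `metric`, `seed`, `note`.
#' @export
resampling_pvalue <- function(stats, gene_set, background_pool, metric,
                              R = 10000L, seed = 1L) {
  if (!metric %in% c("degree", "betweenness", "closeness"))
    .err("unknown metric: ", metric)
  vals <- stats::setNames(stats[[metric]], stats$gene)
  missing <- setdiff(gene_set, names(vals))
  if (length(missing)) .err("gene_set members absent from stats: ",
                            paste(missing, collapse = ", "))
  pool <- sort(intersect(background_pool, names(vals)))
  if (length(gene_set) > length(pool))
    .err("gene_set larger than background pool")
  observed <- mean(vals[gene_set])
  set.seed(as.integer(seed))
  pv <- vals[pool]
  means <- vapply(seq_len(R), function(.)
    mean(pv[sample.int(length(pv), length(gene_set))]), numeric(1))
  n_exceed <- sum(means > observed)
  structure(list(observed_mean = observed, N_exceed = n_exceed, R = as.integer(R),
                 p = n_exceed / R, metric = metric, seed = as.integer(seed),
                 note = if (n_exceed == 0) sprintf("p < 1/%d", R) else NA_character_),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("Resampling test (%s): observed mean %.4g, N = %d / R = %d, p = %.4g%s\n",
              x$metric, x$observed_mean, x$N_exceed, x$R, x$p,
              if (!is.na(x$note)) paste0(" (", x$note, ")") else ""))
  invisible(x)
}

#' Extract the closed neighborhood subnetwork of a seed gene set
#'
#' Node set is the seeds present in the network plus all their direct
#' interactors; edges are those induced among this node set.  Seeds missing
#' from the network are reported, not fatal.
#'
#' @param network an `igraph` object.
#' @param seed_genes character vector of seed genes.
#' @return induced `igraph` subnetwork.
#' @export
extract_neighborhood <- function(network, seed_genes) {
  nm <- igraph::V(network)$name
  missing <- setdiff(seed_genes, nm)
  if (length(missing)) message(length(missing), " seed gene(s) not in network: ",
                               paste(utils::head(missing, 5), collapse = ", "))
  present <- intersect(seed_genes, nm)
  if (!length(present)) return(igraph::make_empty_graph(0, directed = FALSE))
  nb <- igraph::ego(network, order = 1, nodes = present)
  nodes <- unique(c(present, unlist(lapply(nb, function(v) v$name))))
  igraph::induced_subgraph(network, nodes)
}
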