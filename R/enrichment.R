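# Gene-set over-representation: exact hypergeometric upper tail with
# Benjamini-Hochberg adjustment, plus the random-gene-list distribution
# comparison.

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' drawn without replacement from a universe of `N` genes of which `K` are
#' annotated.  Vectorized over `k`, `K`, `n`.
#'
#' @param k overlap count(s).
#' @param K annotated genes in the universe.
#' @param n query size.
#' @param N universe size.
#' @return exact tail probability in (0, 1].
#' @export
hypergeom_p <- function(k, K, n, N) {
  if (any(k < 0 | k > pmin(K, n)) || any(K > N) || any(n > N))
    .err("require 0 <= k <= min(K, n) <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_(j >= i) m p_(j) / j`, clipped at 1, mapped back to the input
#' order (delegates to `stats::p.adjust`).
#'
#' @param p_values numeric vector in [0, 1].
#' @return adjusted values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    .err("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then member genes.
#'
#' @param path GMT file.
#' @return named list of character vectors; descriptions as attribute
#'   `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) .err("malformed GMT line ", bad[1], " (need name, ",
                        "description and at least one gene)")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description single string or vector recycled across sets.
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1)), path)
  invisible(path)
}

#' Hypergeometric over-representation test of a query gene list
#'
#' Tests every set of the collection against the query with the exact
#' hypergeometric upper tail and adjusts across terms by Benjamini-Hochberg.
#' The background defaults to the union of the collection's genes; query
#' genes outside the background are dropped with a message, and terms with no
#' background member are dropped before testing (they would not enter `m`).
#'
#' @param query character vector of gene symbols.
#' @param collection named list of character vectors (e.g. [read_gmt()]).
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @param background universe override (default: union of the collection).
#' @param ease if `TRUE`, apply the EASE-style penalization (overlap counted
#'   as `k - 1`).
#' @return data.frame: term, k, K, n, N, p, q, significant; sorted by (q, p).
#' @export
enrich <- function(query, collection, alpha = 0.05, background = NULL,
                   ease = FALSE) {
  if (!length(query)) .err("query is empty")
  background <- unique(background %||% unlist(collection, use.names = FALSE))
  outside <- setdiff(query, background)
  if (length(outside))
    message(length(outside), " query gene(s) outside the background dropped")
  query <- unique(intersect(query, background))
  Ks <- vapply(collection, function(s) length(intersect(s, background)),
               integer(1))
  drop <- Ks == 0
  if (any(drop)) message(sum(drop), " term(s) with empty background overlap dropped")
  collection <- collection[!drop]; Ks <- Ks[!drop]
  ks <- vapply(collection, function(s) length(intersect(s, query)), integer(1))
  kk <- if (ease) pmax(ks - 1L, 0L) else ks
  p <- hypergeom_p(kk, Ks, length(query), length(background))
  out <- data.frame(term = names(collection), k = ks, K = Ks,
                    n = length(query), N = length(background),
                    p = p, q = bh_adjust(p), stringsAsFactors = FALSE)
  out$significant <- out$q < alpha
  out <- out[order(out$q, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare a query's enrichment profile with random same-size gene lists
#'
#' Draws `n_random` gene lists of the query's size from a candidate pool,
#' enriches each against the collection, and compares the adjusted-p
#' distributions (truncated at `trunc`) of the observed versus each random
#' list by two-sample KS tests.
#'
#' @param query character vector.
#' @param candidate_pool pool to draw random lists from (`|query| <= |pool|`).
#' @param collection named list of gene sets.
#' @param n_random number of random lists (default 10).
#' @param trunc keep only adjusted p-values `<= trunc` in the compared
#'   distributions (default 0.05).
#' @param seed integer seed.
#' @param ... passed to [enrich()].
#' @return list with `observed` (enrichment table), `observed_q`, `random_q`
#'   (list), and `ks` (data.frame draw, D, p).
#' @export
random_list_comparison <- function(query, candidate_pool, collection,
                                   n_random = 10L, trunc = 0.05, seed = 1L,
                                   ...) {
  if (length(query) > length(candidate_pool))
    .err("query larger than candidate pool")
  obs <- enrich(query, collection, ...)
  obs_q <- obs$q[obs$q <= trunc]
  set.seed(as.integer(seed))
  random_q <- lapply(seq_len(n_random), function(.) {
    e <- enrich(sample(candidate_pool, length(query)), collection, ...)
    e$q[e$q <= trunc]
  })
  ks <- do.call(rbind, lapply(seq_len(n_random), function(i) {
    if (length(obs_q) < 2 || length(random_q[[i]]) < 2)
      return(data.frame(draw = i, D = NA_real_, p = NA_real_))
    kt <- ks_compare(obs_q, random_q[[i]])
    data.frame(draw = i, D = kt$D, p = kt$p)
  }))
  list(observed = obs, observed_q = obs_q, random_q = random_q, ks = ks)
}
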