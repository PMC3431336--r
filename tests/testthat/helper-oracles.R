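# Independent oracles and fixture builders used across the test files.
# Everything here is deliberately naive (BFS from scratch, per-window
# rescoring, enumeration) and never calls the code paths it checks.

triplet_key <- function(df) paste(df$modulator, df$tf, df$target)

# ---- graph oracles (plain BFS on an adjacency list; no igraph) ----

adj_list <- function(edges, nodes) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

bfs_dist <- function(adj, src) {
  d <- stats::setNames(rep(Inf, length(adj)), names(adj))
  d[src] <- 0
  queue <- src
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (is.infinite(d[w])) {
      d[w] <- d[v] + 1
      queue <- c(queue, w)
    }
  }
  d
}

# per-node degree / betweenness / closeness by brute force; same conventions
# as topology_stats (raw path counts, component-scaled closeness)
oracle_topology <- function(edges, nodes) {
  adj <- adj_list(edges, nodes)
  n <- length(nodes)
  deg <- vapply(adj, length, numeric(1))
  dmat <- t(vapply(nodes, function(s) bfs_dist(adj, s), numeric(n)))
  colnames(dmat) <- nodes
  clo <- vapply(nodes, function(v) {
    dv <- dmat[v, ]
    reach <- sum(is.finite(dv)) - 1
    if (reach <= 0 || n == 1) return(0)
    (reach / sum(dv[is.finite(dv)])) * (reach / (n - 1))
  }, numeric(1))
  # shortest-path counts via BFS sigma accumulation
  btw <- stats::setNames(rep(0, n), nodes)
  for (s in nodes) for (t in nodes) {
    if (s >= t || is.infinite(dmat[s, t])) next
    sigma <- count_paths(adj, dmat, s, t)          # total shortest paths
    for (v in setdiff(nodes, c(s, t))) {
      if (dmat[s, v] + dmat[v, t] == dmat[s, t]) {
        via <- count_paths(adj, dmat, s, v) * count_paths(adj, dmat, v, t)
        btw[v] <- btw[v] + via / sigma
      }
    }
  }
  data.frame(gene = nodes, degree = deg, betweenness = unname(btw),
             closeness = unname(clo), row.names = NULL,
             stringsAsFactors = FALSE)
}

# number of shortest s-t paths, by dynamic programming on BFS levels
count_paths <- function(adj, dmat, s, t) {
  if (s == t) return(1)
  sum(vapply(adj[[t]], function(w)
    if (dmat[s, w] == dmat[s, t] - 1) count_paths(adj, dmat, s, w) else 0,
    numeric(1)))
}

random_graph_edges <- function(n, p = 0.25) {
  nodes <- paste0("n", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p
  list(nodes = nodes, edges = pairs[keep, , drop = FALSE])
}

edges_to_igraph <- function(edges, nodes) {
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(nodes)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  g
}

# ---- PWM oracles ----

revcomp_chr <- function(s) {
  paste(rev(c(A = "T", C = "G", G = "C", T = "A",
              N = "N")[strsplit(s, "")[[1]]]), collapse = "")
}

# naive all-window scanner: one score_window call per window and strand
oracle_scan <- function(sequence, pwm, config) {
  L <- ncol(pwm$mat)
  n <- nchar(sequence)
  core <- pwm$core_offset + 1:5
  out <- NULL
  eps <- 1e-9
  for (start in 0:(n - L)) {
    win <- substr(sequence, start + 1, start + L)
    strands <- if (config$both_strands) c("+", "-") else "+"
    for (st in strands) {
      w <- if (st == "+") win else revcomp_chr(win)
      if (grepl("N", w, fixed = TRUE)) next  # policy "skip"
      wb <- strsplit(w, "")[[1]]
      cs <- score_window(pwm, wb[core], positions = core)
      ms <- score_window(pwm, wb)
      if (cs >= config$core_threshold - eps && ms >= config$matrix_threshold - eps)
        out <- rbind(out, data.frame(start = start, strand = st,
                                     core_score = min(cs, 1),
                                     matrix_score = min(ms, 1)))
    }
  }
  if (is.null(out)) return(data.frame(start = integer(), strand = character(),
                                      core_score = numeric(),
                                      matrix_score = numeric()))
  out[order(out$start, out$strand), , drop = FALSE]
}

random_pwm <- function(L = 8, name = "rnd") {
  counts <- matrix(stats::rexp(4 * L), 4, L)
  new_pwm(counts, name = name)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# ---- enrichment oracles ----

# exact upper tail by explicit enumeration of the hypergeometric pmf
oracle_hyper <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# BH step-up by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rep(NA_real_, m)
  prev <- Inf
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- min(prev, 1)
  }
  q
}

# ---- random regulatory networks for loop / dual-role oracles ----

random_regnet <- function(n_mod = 4, n_tf = 3, n_tgt = 6, n_triplets = 10,
                          dual_frac = 0.4) {
  mods <- paste0("M", seq_len(n_mod))
  tfs <- paste0("F", seq_len(n_tf))
  tgts <- paste0("G", seq_len(n_tgt))
  role_map <- data.frame(
    gene = c(mods, tfs, tgts),
    role = c(sample(c("TSG", "OCG"), n_mod, replace = TRUE),
             rep("TF", n_tf), rep("target", n_tgt)),
    stringsAsFactors = FALSE)
  # targets drawn from plain targets plus (dual-role) modulators
  tgt_pool <- c(tgts, sample(mods, max(1, round(dual_frac * n_mod))))
  triplets <- unique(data.frame(
    modulator = sample(mods, n_triplets, replace = TRUE),
    tf = sample(tfs, n_triplets, replace = TRUE),
    target = sample(tgt_pool, n_triplets, replace = TRUE),
    stringsAsFactors = FALSE))
  triplets <- triplets[triplets$modulator != triplets$target, , drop = FALSE]
  if (!nrow(triplets))
    triplets <- data.frame(modulator = mods[1], tf = tfs[1], target = tgts[1])
  build_network(triplets, role_map)
}

# loops by exhaustive pair enumeration over the edge tables
oracle_loops <- function(net) {
  out <- NULL
  for (i in seq_len(nrow(net$regulation))) for (j in seq_len(nrow(net$modulation))) {
    if (net$regulation$tf[i] == net$modulation$tf[j] &&
        net$regulation$target[i] == net$modulation$modulator[j])
      out <- rbind(out, data.frame(tf = net$regulation$tf[i],
                                   gene = net$regulation$target[i]))
  }
  if (is.null(out)) return(data.frame(tf = character(), gene = character()))
  out <- unique(out)
  out[order(out$tf, out$gene), , drop = FALSE]
}

# dual-role genes by a plain scan over every gene's memberships
oracle_dual <- function(net) {
  genes <- names(net$roles)
  keep <- vapply(genes, function(g) {
    layers <- c(g %in% net$modulators, g %in% net$tfs, g %in% net$targets)
    sum(layers) >= 2 ||
      (layers[3] && !layers[1] && !layers[2] && net$roles[[g]] != "target")
  }, logical(1))
  sort(genes[keep])
}

# small expression world with one planted triplet, for MI tests
tiny_planted <- function(n = 489, beta_high = 1.5, seed = 1) {
  cfg <- synthetic_config(n_samples = n,
                          role_counts = c(TSG = 2, OCG = 1, TF = 2, common = 4),
                          n_planted_triplets = 1, beta_high = beta_high,
                          seed = seed)
  truth <- generate_ground_truth(cfg, seed)
  expr <- generate_expression(cfg, truth, seed + 1)
  list(cfg = cfg, truth = truth, expr = expr)
}
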