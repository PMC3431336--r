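# Synthetic-data generators with planted ground truth.
#
# Every downstream stage (topology, CMI inference, PWM confirmation,
# assembly, clustering, enrichment, subnetworks) is exercised against data
# generated here, so recovery can be checked against a known answer.

#' Configuration for the synthetic benchmark world
#'
#' Bundles the dimensions and effect sizes of the simulated study: a cohort of
#' `n_samples` expression profiles over `n_genes` genes partitioned into
#' tumor-suppressor (TSG), oncogene (OCG), transcription-factor (TF) and
#' common (candidate target) roles, with `n_planted_triplets` genuine
#' modulator->TF->target relationships planted into the expression matrix and
#' matching TF binding sites planted into target promoters.
#'
#' The planted dependence is piecewise linear: for a triplet (M, T, G) the
#' target is `G = beta(M) * T + eps`, `eps ~ N(0, noise_sd^2)`, where
#' `beta(M) = beta_high` in the samples falling in M's own top `f` quantile
#' and `beta_low` elsewhere (bottom tail and middle).  This is the simplest
#' generative model with the conditional-dependence structure that the
#' CMI contrast assumes, and it gives closed-form within-tail correlations
#' `rho = beta / sqrt(beta^2 + noise_sd^2)` for tests.
#'
#' @param n_samples number of samples (default 489, a TCGA-scale serous
#'   ovarian cohort).
#' @param role_counts named integer vector with entries `TSG`, `OCG`, `TF`,
#'   `common`.
#' @param n_genes total gene count; defaults to `sum(role_counts)`.
#' @param n_planted_triplets number of true (modulator, TF, target) triplets.
#' @param beta_high,beta_low TF->target coupling in modulator-high samples
#'   and everywhere else.
#' @param noise_sd residual standard deviation of planted targets.
#' @param modulator_fraction tail fraction `f` in (0, 0.5] used both when
#'   planting and when inferring.
#' @param promoter_length promoter length in bp.
#' @param motif_copies planted motif copies per positive promoter.
#' @param motif_length consensus length of generated PWMs.
#' @param motif_concentration PWM concentration; `Inf` plants exact consensus.
#' @param gc background GC content of promoters.
#' @param ppi_edges_per_node attachment parameter of the scale-free PPI model.
#' @param seed integer seed recorded in the config.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 489L,
                             role_counts = c(TSG = 20L, OCG = 10L, TF = 5L, common = 50L),
                             n_genes = sum(role_counts),
                             n_planted_triplets = 40L,
                             beta_high = 0.8,
                             beta_low = 0,
                             noise_sd = 1,
                             modulator_fraction = 0.35,
                             promoter_length = 1000L,
                             motif_copies = 1L,
                             motif_length = 12L,
                             motif_concentration = Inf,
                             gc = 0.5,
                             ppi_edges_per_node = 3L,
                             seed = 1L) {
  stopifnot(all(c("TSG", "OCG", "TF", "common") %in% names(role_counts)))
  if (modulator_fraction <= 0 || modulator_fraction > 0.5)
    .err("modulator_fraction must lie in (0, 0.5]")
  if (sum(role_counts) > n_genes) .err("role counts exceed n_genes")
  if (beta_high < beta_low) .err("beta_high must be >= beta_low")
  if (noise_sd <= 0) .err("noise_sd must be positive")
  if (n_planted_triplets > role_counts[["common"]])
    .err("cannot plant more triplets than candidate target genes")
  structure(list(n_samples = as.integer(n_samples),
                 role_counts = role_counts, n_genes = as.integer(n_genes),
                 n_planted_triplets = as.integer(n_planted_triplets),
                 beta_high = beta_high, beta_low = beta_low,
                 noise_sd = noise_sd,
                 modulator_fraction = modulator_fraction,
                 promoter_length = as.integer(promoter_length),
                 motif_copies = as.integer(motif_copies),
                 motif_length = as.integer(motif_length),
                 motif_concentration = motif_concentration,
                 gc = gc, ppi_edges_per_node = as.integer(ppi_edges_per_node),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a scale-free protein-protein interaction network
#'
#' Barabasi-Albert preferential attachment, giving the heavy-tailed degree
#' distribution characteristic of the experimentally supported human
#' interactome.  The result is connected and simple (no self-loops or
#' multi-edges).
#'
#' @param n_genes number of nodes.
#' @param edges_per_new_node edges attached by each arriving node.
#' @param seed integer seed.
#' @param gene_names optional character vector of node names (length
#'   `n_genes`); defaults to `g1..gn`.
#' @return an `igraph` object with vertex `name` attributes.
#' @export
generate_ppi <- function(n_genes, edges_per_new_node = 3L, seed = 1L,
                         gene_names = NULL) {
  if (n_genes < edges_per_new_node + 1)
    .err("n_genes must exceed edges_per_new_node")
  if (edges_per_new_node < 1) .err("edges_per_new_node must be >= 1")
  set.seed(as.integer(seed))
  g <- igraph::sample_pa(n_genes, m = edges_per_new_node, directed = FALSE)
  g <- igraph::simplify(g)
  if (is.null(gene_names)) gene_names <- paste0("g", seq_len(n_genes))
  stopifnot(length(gene_names) == n_genes)
  igraph::V(g)$name <- gene_names
  g
}

#' Generate role labels and planted regulatory triplets
#'
#' Assigns TSG/OCG/TF/common roles to named genes and draws
#' `n_planted_triplets` true (modulator, TF, target) triplets: targets are
#' distinct common genes (a target's expression is fully determined by one
#' triplet), while modulators and TFs may recur across triplets.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return list with `role_map` (data.frame gene, role) and
#'   `planted_triplets` (data.frame modulator, tf, target).
#' @export
generate_ground_truth <- function(config, seed = config$seed) {
  rc <- config$role_counts
  genes <- c(sprintf("TSG%02d", seq_len(rc[["TSG"]])),
             sprintf("OCG%02d", seq_len(rc[["OCG"]])),
             sprintf("TF%02d",  seq_len(rc[["TF"]])),
             sprintf("CG%03d",  seq_len(rc[["common"]])))
  extra <- config$n_genes - length(genes)
  if (extra > 0) genes <- c(genes, sprintf("XG%03d", seq_len(extra)))
  role <- c(rep("TSG", rc[["TSG"]]), rep("OCG", rc[["OCG"]]),
            rep("TF", rc[["TF"]]), rep("common", rc[["common"]]),
            rep("common", max(extra, 0)))
  role_map <- data.frame(gene = genes, role = role, stringsAsFactors = FALSE)
  set.seed(as.integer(seed))
  modulators <- role_map$gene[role_map$role %in% c("TSG", "OCG")]
  tfs <- role_map$gene[role_map$role == "TF"]
  common <- role_map$gene[role_map$role == "common"][seq_len(rc[["common"]])]
  targets <- sample(common, config$n_planted_triplets)
  triplets <- data.frame(
    modulator = sample(modulators, config$n_planted_triplets, replace = TRUE),
    tf = sample(tfs, config$n_planted_triplets, replace = TRUE),
    target = targets, stringsAsFactors = FALSE)
  if (anyDuplicated(triplets$target))
    .err("conflicting planted roles: a target gene was planted twice")
  list(role_map = role_map, planted_triplets = triplets)
}

#' Generate a standardized expression matrix with planted modulation
#'
#' Non-participating genes are i.i.d. standard normal across samples.  For
#' each planted triplet (M, T, G), M and T are standard normal and
#' `G = beta(M) * T + eps` with `beta(M) = beta_high` in M's top
#' `modulator_fraction` sample quantile and `beta_low` otherwise
#' (`eps ~ N(0, noise_sd^2)`).  Every gene row is finally re-standardized to
#' mean 0, sd 1, emulating relative expression scores.
#'
#' @param config a [synthetic_config()].
#' @param ground_truth output of [generate_ground_truth()].
#' @param seed integer seed.
#' @return numeric matrix genes x samples with dimnames.
#' @export
generate_expression <- function(config, ground_truth, seed = config$seed) {
  rm_ <- ground_truth$role_map
  tr <- ground_truth$planted_triplets
  if (anyDuplicated(tr$target))
    .err("conflicting planted roles: a target gene appears in two triplets")
  if (any(tr$modulator == tr$tf | tr$tf == tr$target | tr$modulator == tr$target))
    .err("conflicting planted roles: degenerate triplet with repeated gene")
  n <- config$n_samples
  set.seed(as.integer(seed))
  x <- matrix(stats::rnorm(nrow(rm_) * n), nrow = nrow(rm_),
              dimnames = list(rm_$gene, sprintf("S%03d", seq_len(n))))
  k <- floor(config$modulator_fraction * n)
  for (i in seq_len(nrow(tr))) {
    m <- x[tr$modulator[i], ]
    tf <- x[tr$tf[i], ]
    beta <- rep(config$beta_low, n)
    beta[order(m)[(n - k + 1):n]] <- config$beta_high
    x[tr$target[i], ] <- beta * tf + stats::rnorm(n, sd = config$noise_sd)
  }
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  (x - mu) / sdv
}

#' Generate a position weight matrix around a consensus
#'
#' Column frequencies are `(1 + concentration * [b == consensus_i]) /
#' (4 + concentration)`, so the consensus base is modal in every column and
#' `concentration -> Inf` gives a point mass on the consensus.  A pseudocount
#' is then folded in by [new_pwm()] so no frequency is exactly zero.
#'
#' @param consensus character string over A/C/G/T.
#' @param concentration positive scalar (may be `Inf`).
#' @param pseudocount pseudocount passed to [new_pwm()].
#' @param name matrix identifier.
#' @return a `pwm` object.
#' @export
generate_pwm <- function(consensus, concentration = 20, pseudocount = 1e-3,
                         name = consensus) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T")))
    .err("consensus must be over {A,C,G,T}")
  if (!(concentration > 0)) .err("concentration must be positive")
  L <- length(bases)
  mat <- matrix(0, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_len(L)) {
    if (is.infinite(concentration)) {
      mat[bases[i], i] <- 1
    } else {
      mat[, i] <- 1 / (4 + concentration)
      mat[bases[i], i] <- (1 + concentration) / (4 + concentration)
    }
  }
  new_pwm(mat, name = name, pseudocount = pseudocount)
}

#' Generate promoter sequences with planted motif occurrences
#'
#' Backgrounds are i.i.d. with the configured GC content; each planted copy is
#' sampled column-wise from its PWM, placed at a uniform position on a uniform
#' strand without overlapping another insert, and recorded in the returned
#' ground truth.
#'
#' @param targets character vector of target gene names (one promoter each).
#' @param pwm_library named list of `pwm` objects.
#' @param planted_map data.frame with columns `tf`, `target`, `matrix`
#'   (PWM name) and optionally `copies`.
#' @param promoter_length promoter length (bp).
#' @param gc background GC fraction.
#' @param seed integer seed.
#' @return list with `promoters` (named character vector of sequences) and
#'   `tfbs` (data.frame target, tf, matrix, start, strand; start is 0-based).
#' @export
generate_promoters <- function(targets, pwm_library, planted_map,
                               promoter_length = 1000L, gc = 0.5, seed = 1L) {
  set.seed(as.integer(seed))
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(targets, function(g)
    paste(sample(names(probs), promoter_length, replace = TRUE, prob = probs),
          collapse = ""), character(1))
  if (!is.null(planted_map$copies)) {
    planted_map <- planted_map[rep(seq_len(nrow(planted_map)), planted_map$copies), ]
  }
  tfbs <- NULL
  occupied <- stats::setNames(vector("list", length(targets)), targets)
  for (i in seq_len(nrow(planted_map))) {
    g <- planted_map$target[i]
    pwm <- pwm_library[[planted_map$matrix[i]]]
    if (is.null(pwm)) .err("planted matrix not in pwm_library: ", planted_map$matrix[i])
    L <- ncol(pwm$mat)
    if (L > promoter_length) .err("promoter too short for motif")
    freqs <- pwm$raw %||% pwm$mat  # sample from pre-pseudocount frequencies
    word <- vapply(seq_len(L), function(j)
      sample(rownames(freqs), 1, prob = freqs[, j]), character(1))
    strand <- sample(c("+", "-"), 1)
    if (strand == "-") word <- rev(c(A = "T", C = "G", G = "C", T = "A")[word])
    placed <- FALSE
    for (try in seq_len(1000L)) {
      start <- sample.int(promoter_length - L + 1L, 1) - 1L  # 0-based
      span <- seq(start + 1L, start + L)
      if (!any(span %in% occupied[[g]])) {
        substr(seqs[[g]], start + 1L, start + L) <- paste(word, collapse = "")
        occupied[[g]] <- c(occupied[[g]], span)
        tfbs <- rbind(tfbs, data.frame(
          target = g, tf = planted_map$tf[i], matrix = pwm$name,
          start = start, strand = strand, stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
    }
    if (!placed) .err("promoter too short to place all requested motif copies")
  }
  list(promoters = seqs, tfbs = tfbs)
}

#' Generate random gene-set collections (GMT-style)
#'
#' Draws `n_sets` random sets from a gene universe, optionally appending named
#' "coherent" sets supplied by the caller (e.g. the planted targets of one
#' process), for exercising enrichment analyses.
#'
#' @param genes universe of gene symbols.
#' @param n_sets number of random sets.
#' @param size_range integer range of set sizes.
#' @param coherent optional named list of character vectors appended as-is.
#' @param seed integer seed.
#' @return named list of character vectors.
#' @export
generate_gene_sets <- function(genes, n_sets = 10, size_range = c(10, 40),
                               coherent = list(), seed = 1L) {
  set.seed(as.integer(seed))
  sizes <- sample(seq(size_range[1], min(size_range[2], length(genes))),
                  n_sets, replace = TRUE)
  sets <- lapply(sizes, function(s) sample(genes, s))
  names(sets) <- sprintf("RANDSET_%02d", seq_len(n_sets))
  c(sets, coherent)
}

#' Generate the full synthetic benchmark world
#'
#' One call producing every input of the pipeline: PPI network, role labels,
#' planted triplets, standardized expression, one PWM per TF, the TF->matrix
#' map, promoters with planted binding sites, and candidate sets for
#' inference.  Motifs are planted only for the planted (TF, target) pairs, so
#' under stringent scan thresholds the PWM layer confirms exactly the planted
#' regulations.
#'
#' @param config a [synthetic_config()].
#' @param seed master seed; per-stage seeds are derived with [split_seed()].
#' @return list with elements `config`, `truth`, `expr`, `ppi`, `pwms`,
#'   `tf_map`, `promoters`, `tfbs`, `candidates`.
#' @export
generate_benchmark <- function(config = synthetic_config(), seed = config$seed) {
  seeds <- split_seed(seed, 5L)
  truth <- generate_ground_truth(config, seeds[1])
  expr <- generate_expression(config, truth, seeds[2])
  ppi <- generate_ppi(config$n_genes, config$ppi_edges_per_node, seeds[3],
                      gene_names = truth$role_map$gene)
  tfs <- truth$role_map$gene[truth$role_map$role == "TF"]
  set.seed(seeds[4])
  consensi <- vapply(tfs, function(.)
    paste(sample(c("A", "C", "G", "T"), config$motif_length, replace = TRUE),
          collapse = ""), character(1))
  pwms <- lapply(seq_along(tfs), function(i)
    generate_pwm(consensi[i], config$motif_concentration,
                 name = paste0("M_", tfs[i])))
  names(pwms) <- paste0("M_", tfs)
  tf_map <- data.frame(tf = tfs, matrix = names(pwms), stringsAsFactors = FALSE)
  planted_map <- unique(data.frame(tf = truth$planted_triplets$tf,
                                   target = truth$planted_triplets$target,
                                   stringsAsFactors = FALSE))
  planted_map$matrix <- paste0("M_", planted_map$tf)
  planted_map$copies <- config$motif_copies
  common <- truth$role_map$gene[truth$role_map$role == "common"]
  prom <- generate_promoters(common, pwms, planted_map,
                             promoter_length = config$promoter_length,
                             gc = config$gc, seed = seeds[5])
  candidates <- list(
    modulators = truth$role_map$gene[truth$role_map$role %in% c("TSG", "OCG")],
    tfs = tfs, targets = common)
  list(config = config, truth = truth, expr = expr, ppi = ppi, pwms = pwms,
       tf_map = tf_map, promoters = prom$promoters, tfbs = prom$tfbs,
       candidates = candidates)
}
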