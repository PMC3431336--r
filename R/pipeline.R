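# End-to-end pipeline orchestration: generate (or load) inputs, topology,
# CMI inference, PWM confirmation, assembly, profiles, enrichment and
# process subnetworks, all reproducible from one master seed.

#' Assemble a pipeline configuration
#'
#' Either a `synthetic` block ([synthetic_config()]) or a `paths` list with
#' entries `ppi`, `expression`, `roles`, `pwms` (TRANSFAC flat file),
#' `tf_map` (TSV tf, matrix), `promoters` (FASTA) and optionally `gene_sets`
#' (GMT) must be supplied.
#'
#' @param synthetic a [synthetic_config()] or `NULL`.
#' @param paths named list of input paths or `NULL`.
#' @param inference an [inference_config()].
#' @param scan a [scan_config()].
#' @param clustering list with `distance`, `linkage`, `k`.
#' @param enrichment_alpha adjusted-p threshold for enrichment calls.
#' @param resampling_R resamples for topology p-values.
#' @param stages character vector of stages to run (default: all of
#'   `generate`, `topology`, `infer`, `scan`, `assemble`, `profiles`,
#'   `enrich`, `subnets`).
#' @param seed master seed propagated (via [split_seed()]) to every
#'   stochastic stage.
#' @param outdir output directory (`NULL`: nothing written).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(), paths = NULL,
                            inference = inference_config(),
                            scan = scan_config(),
                            clustering = list(distance = "euclidean",
                                              linkage = "complete", k = 2L),
                            enrichment_alpha = 0.05,
                            resampling_R = 1000L,
                            stages = c("generate", "topology", "infer", "scan",
                                       "assemble", "profiles", "enrich",
                                       "subnets"),
                            seed = 1L, outdir = NULL) {
  if (is.null(synthetic) && is.null(paths))
    .err("either a synthetic block or input paths must be given")
  if (!is.null(paths)) {
    need <- c("ppi", "expression", "roles", "pwms", "tf_map", "promoters")
    miss <- setdiff(need, names(paths))
    if (length(miss)) .err("missing input paths: ", paste(miss, collapse = ", "))
    gone <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(gone)) .err("input path does not exist: ",
                           paste(gone, collapse = ", "))
  }
  structure(list(synthetic = synthetic, paths = paths, inference = inference,
                 scan = scan, clustering = clustering,
                 enrichment_alpha = enrichment_alpha,
                 resampling_R = as.integer(resampling_R), stages = stages,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML map onto the arguments of [pipeline_config()],
#' [synthetic_config()], [inference_config()] and [scan_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- if (!is.null(y$synthetic)) {
    args <- y$synthetic
    if (!is.null(args$role_counts)) args$role_counts <- unlist(args$role_counts)
    do.call(synthetic_config, args)
  }
  pipeline_config(
    synthetic = syn, paths = y$paths,
    inference = do.call(inference_config, y$inference %||% list()),
    scan = do.call(scan_config, y$scan %||% list()),
    clustering = y$clustering %||% list(distance = "euclidean",
                                        linkage = "complete", k = 2L),
    enrichment_alpha = y$enrichment_alpha %||% 0.05,
    resampling_R = y$resampling_R %||% 1000L,
    stages = y$stages %||% c("generate", "topology", "infer", "scan",
                             "assemble", "profiles", "enrich", "subnets"),
    seed = y$seed %||% 1L, outdir = y$outdir)
}

#' Run the full three-layer regulatory network pipeline
#'
#' Executes the configured stages in order: input generation (or loading),
#' PPI topology with resampling significance of the modulator set, CMI
#' modulator inference, PWM confirmation scanning, edge intersection and
#' network assembly, regulatory-profile clustering, enrichment of the network
#' genes, and process subnetwork extraction.  A manifest records parameters,
#' per-stage seeds and record counts (and input digests when files are
#' written).
#'
#' @param config a [pipeline_config()].
#' @return list with the stage outputs and `manifest`.
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  seeds <- split_seed(config$seed, 8L)
  names(seeds) <- c("generate", "topology", "infer", "scan", "assemble",
                    "profiles", "enrich", "subnets")
  out <- list()
  manifest <- list(package_version = as.character(utils::packageVersion("modnet")),
                   seed = config$seed, stage_seeds = as.list(seeds),
                   stages = config$stages, counts = list())
  run <- function(stage) stage %in% config$stages
  fail <- function(stage, e) .err("pipeline stage '", stage, "' failed: ",
                                  conditionMessage(e))

  # ---- inputs ----
  if (run("generate") && !is.null(config$synthetic)) {
    bench <- tryCatch(generate_benchmark(config$synthetic, seeds[["generate"]]),
                      error = function(e) fail("generate", e))
  } else if (!is.null(config$paths)) {
    p <- config$paths
    bench <- tryCatch(list(
      ppi = load_ppi(p$ppi),
      expr = read_expression_tsv(p$expression),
      truth = list(role_map = read_roles_tsv(p$roles), planted_triplets = NULL),
      pwms = read_transfac(p$pwms),
      tf_map = utils::read.delim(p$tf_map, stringsAsFactors = FALSE),
      promoters = read_promoters_fasta(p$promoters),
      gene_sets = if (!is.null(p$gene_sets)) read_gmt(p$gene_sets)),
      error = function(e) fail("generate", e))
    rm_ <- bench$truth$role_map
    bench$candidates <- list(
      modulators = rm_$gene[rm_$role %in% c("TSG", "OCG")],
      tfs = rm_$gene[rm_$role == "TF"],
      targets = rm_$gene[rm_$role %in% c("common", "target")])
  } else .err("no inputs: stage 'generate' skipped and no paths given")
  out$inputs <- bench
  manifest$counts$genes <- nrow(bench$truth$role_map)
  manifest$counts$samples <- ncol(bench$expr)

  # ---- topology ----
  if (run("topology")) {
    out$topology <- tryCatch({
      ts <- topology_stats(bench$ppi)
      mods <- intersect(bench$candidates$modulators, ts$gene)
      res <- lapply(c("degree", "betweenness", "closeness"), function(m)
        resampling_pvalue(ts, mods, ts$gene, m, R = config$resampling_R,
                          seed = seeds[["topology"]]))
      names(res) <- c("degree", "betweenness", "closeness")
      nb <- extract_neighborhood(bench$ppi,
                                 c(bench$candidates$modulators,
                                   bench$candidates$tfs))
      list(stats = ts, resampling = res, neighborhood = nb)
    }, error = function(e) fail("topology", e))
    manifest$counts$neighborhood_nodes <- igraph::vcount(out$topology$neighborhood)
  }

  # ---- CMI inference ----
  if (run("infer")) {
    icfg <- config$inference
    icfg$seed <- seeds[["infer"]]
    out$triplets <- tryCatch(
      infer_modulations(bench$expr, bench$candidates, icfg),
      error = function(e) fail("infer", e))
    manifest$counts$cmi_triplets <- nrow(out$triplets)
  }

  # ---- PWM scan ----
  if (run("scan")) {
    out$pwm_edges <- tryCatch(
      predict_tf_targets(bench$promoters, bench$pwms, bench$tf_map,
                         config$scan),
      error = function(e) fail("scan", e))
    manifest$counts$pwm_edges <- nrow(out$pwm_edges)
  }

  # ---- assembly ----
  if (run("assemble") && !is.null(out$triplets) && !is.null(out$pwm_edges)) {
    out$network <- tryCatch({
      confirmed <- intersect_edges(out$triplets, out$pwm_edges)
      build_network(confirmed, bench$truth$role_map)
    }, error = function(e) fail("assemble", e))
    out$degrees <- degree_summary(out$network)
    out$loops <- detect_feedback_loops(out$network)
    out$dual_roles <- dual_role_genes(out$network)
    manifest$counts$network_genes <- out$network$summary$n_genes
    manifest$counts$network_links <- out$network$summary$n_links
    manifest$counts$feedback_loops <- nrow(out$loops)
  }

  # ---- profiles ----
  if (run("profiles") && !is.null(out$network) &&
      length(out$network$modulators) >= 2) {
    cl <- config$clustering
    out$profiles <- tryCatch({
      lapply(c(tf = "tf", target = "target"), function(ax) {
        prof <- build_profiles(out$network, ax)
        hc <- hcluster(prof, cl$distance, cl$linkage)
        labels <- out$network$roles[rownames(prof)]
        list(profile = prof, tree = hc,
             purity = branch_purity(hc, cl$k, labels))
      })
    }, error = function(e) fail("profiles", e))
  }

  # ---- enrichment ----
  if (run("enrich") && !is.null(out$network)) {
    out$enrichment <- tryCatch({
      universe <- bench$truth$role_map$gene
      sets <- bench$gene_sets %||%
        generate_gene_sets(universe, n_sets = 10,
                           coherent = list(NETWORK_TARGETS = out$network$targets),
                           seed = seeds[["enrich"]])
      enrich(names(out$network$roles), sets, alpha = config$enrichment_alpha,
             background = universe)
    }, error = function(e) fail("enrich", e))
  }

  # ---- process subnetworks ----
  if (run("subnets") && !is.null(out$network)) {
    out$subnets <- tryCatch({
      net <- out$network
      set.seed(seeds[["subnets"]])
      members <- names(net$roles)
      procs <- lapply(c(apoptosis = .6, cell_cycle = .5, hormone = .4,
                        reproduction = .3), function(fr)
                          sample(members, max(2, round(fr * length(members)))))
      lapply(names(procs), function(nm)
        extract_process_subnetwork(net, procs[[nm]], name = nm))
    }, error = function(e) fail("subnets", e))
  }

  out$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  out$manifest <- manifest  # deliberately time-free so reruns are byte-identical

  if (!is.null(config$outdir)) .write_pipeline_outputs(out, config)
  out
}

# persist stage outputs as TSV / SIF / JSON under config$outdir
.write_pipeline_outputs <- function(out, config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(config$outdir, ...)
  b <- out$inputs
  write_expression_tsv(b$expr, fp("expression.tsv"))
  write_roles_tsv(b$truth$role_map, fp("roles.tsv"))
  write_ppi_tsv(b$ppi, fp("ppi.tsv"))
  write_promoters_fasta(b$promoters, fp("promoters.fasta"))
  write_transfac(b$pwms, fp("pwms.transfac"))
  if (!is.null(b$truth$planted_triplets))
    write_triplets_tsv(b$truth$planted_triplets, fp("planted_triplets.tsv"))
  if (!is.null(out$topology))
    utils::write.table(out$topology$stats, fp("topology_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(out$triplets)) write_triplets_tsv(out$triplets, fp("triplets.tsv"))
  if (!is.null(out$pwm_edges))
    utils::write.table(out$pwm_edges, fp("pwm_edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(out$network)) {
    write_sif(out$network, fp("network.sif"))
    write_node_attributes(out$network, fp("node_attributes.tsv"))
    write_network_json(out$network, fp("network.json"))
  }
  if (!is.null(out$profiles)) {
    write_profile_tsv(out$profiles$tf$profile, fp("profile_tf.tsv"))
    write_profile_tsv(out$profiles$target$profile, fp("profile_target.tsv"))
    write_newick(out$profiles$target$tree, fp("dendrogram_target.nwk"))
  }
  if (!is.null(out$enrichment))
    utils::write.table(out$enrichment, fp("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  man <- out$manifest
  digests <- tools::md5sum(list.files(config$outdir,
                                      pattern = "\\.(tsv|fasta|transfac)$",
                                      full.names = TRUE))
  names(digests) <- basename(names(digests))
  man$input_digests <- as.list(digests)
  jsonlite::write_json(man, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(config$outdir)
}
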