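# Assembly of the three-layer regulatory network: intersection of CMI and
# PWM evidence, layer construction, degree statistics, feedback loops and
# dual-role genes, plus SIF / node-attribute / node-link JSON export.

#' Filter CMI triplets by PWM-confirmed TF -> target edges
#'
#' A triplet (M, T, G) survives iff the (T, G) regulation is also predicted
#' by the PWM scan; surviving triplets are returned unchanged.
#'
#' @param cmi_triplets data.frame with columns `tf` and `target` (plus any
#'   others, e.g. the output of [infer_modulations()]).
#' @param pwm_edges data.frame with columns `tf` and `target`.
#' @return the surviving rows of `cmi_triplets`.
#' @export
intersect_edges <- function(cmi_triplets, pwm_edges) {
  if (!nrow(cmi_triplets) || !nrow(pwm_edges))
    return(cmi_triplets[integer(0), , drop = FALSE])
  keep <- paste(cmi_triplets$tf, cmi_triplets$target, sep = "\r") %in%
    paste(pwm_edges$tf, pwm_edges$target, sep = "\r")
  out <- cmi_triplets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the three-layer regulatory network from confirmed triplets
#'
#' Each distinct (modulator, TF) pair becomes one modulation edge and each
#' distinct (TF, target) pair one regulation edge, with supporting-triplet
#' counts kept as edge attributes.  Genes keep their annotated class (TSG,
#' OCG, TF, or target for common genes) and may occupy several layers: a
#' TF-class gene that regulates nothing but is itself regulated sits in the
#' bottom layer only (it is "assigned as a target gene").
#'
#' @param confirmed_triplets data.frame with columns `modulator`, `tf`,
#'   `target`.
#' @param role_map data.frame with columns `gene`, `role` (TSG, OCG, TF,
#'   common/target).
#' @return object of class `regnet`: list with `modulation`, `regulation`
#'   edge data.frames, `modulators`, `tfs`, `targets` layer vectors, `roles`
#'   named character vector (annotated class), and `summary` counts.
#' @export
build_network <- function(confirmed_triplets, role_map) {
  tr <- confirmed_triplets
  roles <- stats::setNames(role_map$role, role_map$gene)
  roles[roles == "common"] <- "target"
  for (g in unique(c(tr$modulator, tr$tf, tr$target)))
    if (!g %in% names(roles)) .err("gene without a role: ", g)
  bad <- unique(tr$modulator[!roles[tr$modulator] %in% c("TSG", "OCG")])
  if (length(bad)) .err("modulator without TSG/OCG role: ",
                        paste(bad, collapse = ", "))
  bad <- unique(tr$tf[roles[tr$tf] != "TF"])
  if (length(bad)) .err("TF without TF role: ", paste(bad, collapse = ", "))
  mod_key <- paste(tr$modulator, tr$tf, sep = "\r")
  reg_key <- paste(tr$tf, tr$target, sep = "\r")
  modulation <- data.frame(modulator = tr$modulator, tf = tr$tf,
                           stringsAsFactors = FALSE)[!duplicated(mod_key), ]
  modulation$n_support <- as.integer(table(mod_key)[unique(mod_key)])
  regulation <- data.frame(tf = tr$tf, target = tr$target,
                           stringsAsFactors = FALSE)[!duplicated(reg_key), ]
  regulation$n_support <- as.integer(table(reg_key)[unique(reg_key)])
  modulation <- modulation[order(modulation$modulator, modulation$tf), ]
  regulation <- regulation[order(regulation$tf, regulation$target), ]
  rownames(modulation) <- rownames(regulation) <- NULL
  modulators <- sort(unique(modulation$modulator))
  tfs <- sort(unique(regulation$tf))
  targets <- sort(unique(regulation$target))
  genes <- sort(unique(c(modulators, tfs, targets)))
  net <- structure(list(modulation = modulation, regulation = regulation,
                        modulators = modulators, tfs = tfs, targets = targets,
                        roles = roles[genes]),
                   class = "regnet")
  cls <- net$roles
  net$summary <- list(
    n_genes = length(genes),
    n_tsg = sum(cls == "TSG"), n_ocg = sum(cls == "OCG"),
    n_tf = sum(cls == "TF"), n_target_class = sum(cls == "target"),
    n_target_layer = length(targets),
    n_modulation_edges = nrow(modulation),
    n_regulation_edges = nrow(regulation),
    n_links = nrow(modulation) + nrow(regulation),
    demoted_tfs = sort(setdiff(names(cls)[cls == "TF"], tfs)))
  net
}

#' @export
print.regnet <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("Three-layer regulatory network: %d genes ",
                     "(%d TSG, %d OCG, %d TF, %d target-class), %d links\n"),
              s$n_genes, s$n_tsg, s$n_ocg, s$n_tf, s$n_target_class, s$n_links))
  cat(sprintf("  layers: %d modulators -> %d TFs -> %d targets\n",
              length(x$modulators), length(x$tfs), length(x$targets)))
  if (length(s$demoted_tfs))
    cat("  TF-class genes assigned as targets:",
        paste(s$demoted_tfs, collapse = ", "), "\n")
  invisible(x)
}

#' In/out-degree summary of the TF layer
#'
#' In-degree of a TF is its number of modulator neighbors, out-degree its
#' number of target neighbors; the two are correlated across TFs (Pearson,
#' two-sided).  The correlation is reported as `NA` with a note when fewer
#' than 3 TFs exist or a degree vector has zero variance.
#'
#' @param network a `regnet`.
#' @return list with `degrees` (data.frame tf, in_degree, out_degree),
#'   `pearson_r`, `r_pvalue`, `note`.
#' @export
degree_summary <- function(network) {
  tfs <- network$tfs
  ind <- as.integer(table(factor(network$modulation$tf, levels = tfs)))
  outd <- as.integer(table(factor(network$regulation$tf, levels = tfs)))
  df <- data.frame(tf = tfs, in_degree = ind, out_degree = outd,
                   stringsAsFactors = FALSE)
  if (length(tfs) < 3 || stats::sd(ind) == 0 || stats::sd(outd) == 0) {
    return(list(degrees = df, pearson_r = NA_real_, r_pvalue = NA_real_,
                note = "correlation not computable (fewer than 3 TFs or zero variance)"))
  }
  ct <- stats::cor.test(ind, outd, method = "pearson")
  list(degrees = df, pearson_r = unname(ct$estimate),
       r_pvalue = ct$p.value, note = NA_character_)
}

#' Detect modulator-TF feedback loops
#'
#' A loop is a pair (TF, gene) such that the gene modulates the TF (top
#' layer) and the TF regulates the same gene as a target (bottom layer).
#' Each loop is reported once, sorted by (tf, gene).
#'
#' @param network a `regnet`.
#' @return data.frame with columns tf, gene.
#' @export
detect_feedback_loops <- function(network) {
  mod <- paste(network$modulation$tf, network$modulation$modulator, sep = "\r")
  reg <- paste(network$regulation$tf, network$regulation$target, sep = "\r")
  both <- sort(unique(intersect(mod, reg)))
  if (!length(both))
    return(data.frame(tf = character(), gene = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(both, "\r", fixed = TRUE)
  data.frame(tf = vapply(parts, `[`, character(1), 1),
             gene = vapply(parts, `[`, character(1), 2),
             stringsAsFactors = FALSE)
}

#' Genes holding more than one role in the network
#'
#' A dual-role gene either occupies several layers (e.g. a TSG that is also a
#' target) or carries a regulator class (TSG/OCG/TF) while sitting in the
#' bottom layer.  Returned grouped by role combination.
#'
#' @param network a `regnet`.
#' @return data.frame with columns gene, roles (sorted, "+"-joined), n_roles.
#' @export
dual_role_genes <- function(network) {
  genes <- names(network$roles)
  rolesets <- lapply(genes, function(g) {
    r <- character()
    if (g %in% network$modulators) r <- c(r, network$roles[[g]])  # TSG or OCG
    if (g %in% network$tfs) r <- c(r, "TF")
    if (g %in% network$targets) {
      r <- c(r, "target")
      # a regulator-class gene in the bottom layer keeps its class label
      if (!g %in% c(network$modulators, network$tfs) &&
          network$roles[[g]] != "target")
        r <- c(r, network$roles[[g]])
    }
    sort(unique(r))
  })
  n <- lengths(rolesets)
  keep <- n >= 2
  out <- data.frame(gene = genes[keep],
                    roles = vapply(rolesets[keep], paste, character(1),
                                   collapse = "+"),
                    n_roles = n[keep], stringsAsFactors = FALSE)
  out <- out[order(out$roles, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a regulatory network as SIF
#'
#' One line per edge: `source<TAB>modulates|regulates<TAB>target`.
#'
#' @param network a `regnet`.
#' @param path output file.
#' @export
write_sif <- function(network, path) {
  lines <- c(sprintf("%s\tmodulates\t%s", network$modulation$modulator,
                     network$modulation$tf),
             sprintf("%s\tregulates\t%s", network$regulation$tf,
                     network$regulation$target))
  writeLines(lines, path)
  invisible(path)
}

#' Read a SIF file back into edge tables
#'
#' @param path SIF file with interaction types `modulates` / `regulates`.
#' @return list with `modulation` and `regulation` data.frames.
#' @export
read_sif <- function(path) {
  d <- utils::read.delim(path, header = FALSE,
                         col.names = c("from", "type", "to"),
                         stringsAsFactors = FALSE)
  list(modulation = data.frame(modulator = d$from[d$type == "modulates"],
                               tf = d$to[d$type == "modulates"],
                               stringsAsFactors = FALSE),
       regulation = data.frame(tf = d$from[d$type == "regulates"],
                               target = d$to[d$type == "regulates"],
                               stringsAsFactors = FALSE))
}

#' Export node attributes (gene, class, layers) as TSV
#'
#' @param network a `regnet`.
#' @param path output file.
#' @export
write_node_attributes <- function(network, path) {
  genes <- names(network$roles)
  layers <- vapply(genes, function(g) paste(
    c(if (g %in% network$modulators) "modulator",
      if (g %in% network$tfs) "tf",
      if (g %in% network$targets) "target"), collapse = ","), character(1))
  utils::write.table(data.frame(gene = genes, class = unname(network$roles),
                                layers = layers, stringsAsFactors = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export / import a regulatory network as node-link JSON
#'
#' Round-trips the full `regnet` object (edges with support counts, layers,
#' roles) for programmatic reload.
#'
#' @param network a `regnet`.
#' @param path JSON file.
#' @return `read_network_json` returns the reconstructed `regnet`.
#' @export
write_network_json <- function(network, path) {
  obj <- list(modulation = network$modulation, regulation = network$regulation,
              roles = as.list(network$roles))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  roles <- unlist(obj$roles)
  role_map <- data.frame(gene = names(roles), role = unname(roles),
                         stringsAsFactors = FALSE)
  tr <- merge(obj$modulation[c("modulator", "tf")],
              obj$regulation[c("tf", "target")], by = "tf")
  net <- build_network(tr[c("modulator", "tf", "target")], role_map)
  # restore exact support counts (merge-reconstruction inflates them)
  net$modulation <- obj$modulation[order(obj$modulation$modulator,
                                         obj$modulation$tf), ]
  net$regulation <- obj$regulation[order(obj$regulation$tf,
                                         obj$regulation$target), ]
  rownames(net$modulation) <- rownames(net$regulation) <- NULL
  net$summary$n_modulation_edges <- nrow(net$modulation)
  net$summary$n_regulation_edges <- nrow(net$regulation)
  net$summary$n_links <- nrow(net$modulation) + nrow(net$regulation)
  net
}
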