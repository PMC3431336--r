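# Process-specific subnetworks: bottom-up three-step extraction and
# cross-process overlap statistics.

#' Extract a process-specific subnetwork
#'
#' Three-step, bottom-up: (1) map the process gene set onto the bottom layer
#' to get the member targets; (2) recruit every TF with a regulation edge
#' onto a member target (TFs not themselves process-annotated are flagged
#' `added_tf`); (3) recruit the process-annotated modulators with a
#' modulation edge onto a member TF.  Edges are those induced among the
#' members.
#'
#' @param network a `regnet`.
#' @param process_gene_set character vector of process-annotated genes.
#' @param name process name.
#' @return object of class `process_subnet`: list with `name`, `targets`,
#'   `tfs` (data.frame tf, added_tf), `modulators`, `modulation`,
#'   `regulation`.
#' @export
extract_process_subnetwork <- function(network, process_gene_set,
                                       name = "process") {
  if (!length(process_gene_set)) .err("process gene set is empty")
  targets <- intersect(network$targets, process_gene_set)
  reg <- network$regulation[network$regulation$target %in% targets, ,
                            drop = FALSE]
  tfs <- sort(unique(reg$tf))
  mod <- network$modulation[network$modulation$tf %in% tfs &
                              network$modulation$modulator %in% process_gene_set, ,
                            drop = FALSE]
  modulators <- sort(unique(mod$modulator))
  if (!length(targets) && !length(modulators))
    warning("no process gene maps to any network layer: empty subnetwork")
  rownames(reg) <- rownames(mod) <- NULL
  structure(list(name = name, targets = sort(targets),
                 tfs = data.frame(tf = tfs,
                                  added_tf = !tfs %in% process_gene_set,
                                  stringsAsFactors = FALSE),
                 modulators = modulators, modulation = mod, regulation = reg,
                 roles = network$roles[intersect(names(network$roles),
                                                 c(targets, tfs, modulators))]),
            class = "process_subnet")
}

#' @export
print.process_subnet <- function(x, ...) {
  cat(sprintf("Process subnetwork '%s': %d modulators -> %d TFs (%d added) -> %d targets\n",
              x$name, length(x$modulators), nrow(x$tfs), sum(x$tfs$added_tf),
              length(x$targets)))
  invisible(x)
}

# role members of a subnetwork, for overlap statistics
.subnet_role_members <- function(subnet, role) {
  switch(role,
         TSG = subnet$modulators[subnet$roles[subnet$modulators] == "TSG"],
         OCG = subnet$modulators[subnet$roles[subnet$modulators] == "OCG"],
         TF = subnet$tfs$tf,
         target = subnet$targets,
         .err("role must be one of TSG, OCG, TF, target"))
}

#' Shared members of two process subnetworks for one role
#'
#' Fraction shared is `|A intersect B| / |A|` with the first subnetwork's
#' role members as denominator (overlap percentages are directional).
#'
#' @param subnet_a,subnet_b `process_subnet` objects.
#' @param role `"TSG"`, `"OCG"`, `"TF"` or `"target"`.
#' @return list with `role`, `n_a`, `n_b`, `shared`, `fraction`, `note`.
#' @export
subnetwork_overlap <- function(subnet_a, subnet_b, role) {
  a <- .subnet_role_members(subnet_a, role)
  b <- .subnet_role_members(subnet_b, role)
  shared <- length(intersect(a, b))
  list(role = role, n_a = length(a), n_b = length(b), shared = shared,
       fraction = if (length(a)) shared / length(a) else 0,
       note = if (!length(a)) "first subnetwork has no members of this role"
       else NA_character_)
}
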