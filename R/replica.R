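# Synthetic replica of the published ovarian-cancer regulatory network's
# printed structure.  The real 112-gene network depends on TCGA expression,
# PINA interactions and TRANSFAC matrices and cannot be rebuilt here; this
# replica reproduces, by construction, every structural fact reported for
# it, so the assembly/loop/dual-role machinery can be demonstrated and
# checked against the printed numbers.  All filler genes carry synthetic
# names; only the loop participants and demoted TFs use their real symbols.

#' Synthetic replica of the published three-layer network structure
#'
#' Builds a `regnet` with 29 TSGs, 13 OCGs, 15 TF-class genes and 65 target
#' genes (112 unique genes): 10 dual-role genes (3 TSGs, 3 OCGs and 4 TF
#' genes also appear as targets), six modulator-TF feedback loops
#' (E2F3-CHEK2, ETS1-EGFR, ETS1-ERBB2, ETS1-SPARC, HMGA2-MYC, HNF1B-MYC),
#' and four TF-class genes (FOXM1, MSX1, PPARG, STAT5A) that regulate
#' nothing and are therefore assigned to the bottom layer.  Loop genes and
#' demoted TFs carry their published symbols; every other gene is a synthetic
#' placeholder (the full membership of the real network is not printed).
#'
#' @return a `regnet` object.
#' @export
replica_network <- function() {
  tsg_dual <- c("CHEK2", "SPARC", "sTSG3")         # 3rd dual TSG unprinted
  tsg <- c(tsg_dual, sprintf("sTSG%02d", 4:29))    # 29 TSG-class genes
  ocg_dual <- c("EGFR", "ERBB2", "MYC")
  ocg <- c(ocg_dual, sprintf("sOCG%02d", 4:13))    # 13 OCG-class genes
  tf_demoted <- c("FOXM1", "MSX1", "PPARG", "STAT5A")
  tf_active <- c("E2F3", "ETS1", "HMGA2", "HNF1B", sprintf("sTF%02d", 5:11))
  tf <- c(tf_active, tf_demoted)                   # 15 TF-class genes
  tgt_plain <- sprintf("sTGT%02d", 1:55)           # 55 target-only genes
  targets <- c(tsg_dual, ocg_dual, tf_demoted, tgt_plain)  # 65 targets

  role_map <- data.frame(
    gene = c(tsg, ocg, tf, tgt_plain),
    role = c(rep("TSG", length(tsg)), rep("OCG", length(ocg)),
             rep("TF", length(tf)), rep("target", length(tgt_plain))),
    stringsAsFactors = FALSE)

  # loop-forming triplets: gene -> TF modulation and TF -> gene regulation
  loops <- data.frame(
    tf = c("E2F3", "ETS1", "ETS1", "ETS1", "HMGA2", "HNF1B"),
    gene = c("CHEK2", "EGFR", "ERBB2", "SPARC", "MYC", "MYC"),
    stringsAsFactors = FALSE)
  triplets <- data.frame(modulator = loops$gene, tf = loops$tf,
                         target = loops$gene, stringsAsFactors = FALSE)

  # every modulator modulates at least one active TF (round-robin) and every
  # active TF regulates a spread of plain targets plus the demoted TF genes
  mods <- c(tsg, ocg)
  rr_tf <- tf_active[(seq_along(mods) - 1L) %% length(tf_active) + 1L]
  rr_tg <- tgt_plain[(seq_along(mods) - 1L) %% length(tgt_plain) + 1L]
  triplets <- rbind(triplets, data.frame(modulator = mods, tf = rr_tf,
                                         target = rr_tg,
                                         stringsAsFactors = FALSE))
  # cover all remaining plain targets
  left <- setdiff(tgt_plain, triplets$target)
  if (length(left)) {
    rr_tf2 <- tf_active[(seq_along(left) - 1L) %% length(tf_active) + 1L]
    triplets <- rbind(triplets, data.frame(
      modulator = mods[seq_along(left)], tf = rr_tf2, target = left,
      stringsAsFactors = FALSE))
  }
  # the third dual-role TSG is a target of a TF it does not modulate,
  # so it adds no seventh loop
  triplets <- rbind(triplets, data.frame(
    modulator = "sTSG06", tf = "E2F3", target = "sTSG3",
    stringsAsFactors = FALSE))
  # the four demoted TF genes are regulated by other TFs, regulate nothing
  triplets <- rbind(triplets, data.frame(
    modulator = c("sTSG04", "sTSG05", "sOCG04", "sOCG05"),
    tf = c("E2F3", "HMGA2", "HNF1B", "ETS1"), target = tf_demoted,
    stringsAsFactors = FALSE))
  build_network(unique(triplets), role_map)
}
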