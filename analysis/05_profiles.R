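#!/usr/bin/env Rscript
# Stage 5 — regulatory-profile clustering.
#
# Builds the binary TF-profile (direct modulation) and target-profile
# (two-hop regulation) for every modulator and clusters modulators
# hierarchically under both euclidean/complete and jaccard/average settings;
# branch purity at k = 2 quantifies how well the TSG and OCG classes
# separate.

library(modnet)

outdir <- "results/profiles"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

net <- read_network_json("results/network/network.json")
labels <- net$roles[net$modulators]

for (axis in c("tf", "target")) {
  prof <- build_profiles(net, axis)
  write_profile_tsv(prof, file.path(outdir, paste0("profile_", axis, ".tsv")))
  for (setting in list(c("euclidean", "complete"), c("jaccard", "average"))) {
    hc <- hcluster(prof, setting[1], setting[2])
    bp <- branch_purity(hc, 2, labels)
    cat(sprintf("%-6s axis, %s/%s: branch purities %s (mean %.3f)\n",
                axis, setting[1], setting[2],
                paste(sprintf("%.2f", bp$purity), collapse = ", "),
                attr(bp, "mean_purity")))
    if (setting[1] == "euclidean") {
      write_newick(hc, file.path(outdir, paste0("dendrogram_", axis, ".nwk")))
      write.table(bp, file.path(outdir, paste0("purity_", axis, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
}
cat("Profiles, dendrograms and purity tables under", outdir, "\n")
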