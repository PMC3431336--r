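#!/usr/bin/env Rscript
# Stage 1 — simulate the benchmark world.
#
# Generates the full synthetic study: a scale-free PPI network, role-labeled
# genes (20 TSG + 10 OCG modulators, 5 TFs, 50 candidate targets), a
# 489-sample standardized expression matrix with 40 planted
# modulator->TF->target triplets, one PWM per TF and 1-kb promoters carrying
# planted binding sites for the planted regulations.  All downstream stages
# read the files written here.

library(modnet)

outdir <- "results/benchmark"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260921L

cfg <- synthetic_config(seed = seed)
bench <- generate_benchmark(cfg, seed = seed)

write_expression_tsv(bench$expr, file.path(outdir, "expression.tsv"))
write_roles_tsv(bench$truth$role_map, file.path(outdir, "roles.tsv"))
write_ppi_tsv(bench$ppi, file.path(outdir, "ppi.tsv"))
write_promoters_fasta(bench$promoters, file.path(outdir, "promoters.fasta"))
write_transfac(bench$pwms, file.path(outdir, "pwms.transfac"))
write.table(bench$tf_map, file.path(outdir, "tf_map.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_triplets_tsv(bench$truth$planted_triplets,
                   file.path(outdir, "planted_triplets.tsv"))
write.table(bench$tfbs, file.path(outdir, "planted_tfbs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Simulated %d genes x %d samples; %d planted triplets over %d TFs;\n",
            nrow(bench$expr), ncol(bench$expr),
            nrow(bench$truth$planted_triplets),
            length(unique(bench$truth$planted_triplets$tf))))
cat(sprintf("PPI: %d nodes / %d links; %d promoters with %d planted sites.\n",
            igraph::vcount(bench$ppi), igraph::ecount(bench$ppi),
            length(bench$promoters), nrow(bench$tfbs)))
cat("Outputs under", outdir, "\n")
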