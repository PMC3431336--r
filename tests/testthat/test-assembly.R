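# Edge intersection, network assembly, degree statistics, feedback loops and
# dual-role genes.

toy_roles <- function() data.frame(
  gene = c("M1", "M2", "O1", "T1", "T2", "G1", "G2", "G3"),
  role = c("TSG", "TSG", "OCG", "TF", "TF", "target", "target", "target"),
  stringsAsFactors = FALSE)

test_that("edge intersection is an exact membership filter", {
  tr <- data.frame(modulator = c("M1", "M1", "M2"), tf = c("T1", "T1", "T2"),
                   target = c("G1", "G2", "G1"), stringsAsFactors = FALSE)
  expect_equal(nrow(intersect_edges(tr, tr[0, c("tf", "target")])), 0)
  expect_equal(intersect_edges(tr, tr[c("tf", "target")]), tr)
  set.seed(3)
  for (i in 1:20) {
    pw <- data.frame(tf = sample(c("T1", "T2"), 4, TRUE),
                     target = sample(c("G1", "G2", "G3"), 4, TRUE))
    got <- intersect_edges(tr, pw)
    want <- tr[paste(tr$tf, tr$target) %in% paste(pw$tf, pw$target), ]
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("a single triplet builds a 3-node, 2-edge network", {
  net <- build_network(data.frame(modulator = "M1", tf = "T1", target = "G1"),
                       toy_roles())
  expect_equal(net$summary$n_genes, 3)
  expect_equal(net$summary$n_links, 2)
  expect_equal(net$modulators, "M1")
  expect_equal(net$tfs, "T1")
  expect_equal(net$targets, "G1")
})

test_that("edge multiplicity is collapsed with support counts", {
  tr <- data.frame(modulator = c("M1", "M2", "M1"), tf = "T1",
                   target = c("G1", "G1", "G2"), stringsAsFactors = FALSE)
  net <- build_network(tr, toy_roles())
  ds <- degree_summary(net)
  expect_equal(ds$degrees$in_degree, 2)
  expect_equal(ds$degrees$out_degree, 2)
  expect_equal(sum(net$modulation$n_support), 3)
  expect_equal(net$regulation$n_support[net$regulation$target == "G1"], 2)
  # conservation: degree sums equal edge counts
  expect_equal(sum(ds$degrees$in_degree), nrow(net$modulation))
  expect_equal(sum(ds$degrees$out_degree), nrow(net$regulation))
})

test_that("role violations are reported with the offending gene", {
  expect_error(build_network(data.frame(modulator = "G1", tf = "T1",
                                        target = "G2"), toy_roles()),
               "G1")
  expect_error(build_network(data.frame(modulator = "M1", tf = "G1",
                                        target = "G2"), toy_roles()),
               "G1")
  expect_error(build_network(data.frame(modulator = "M1", tf = "T1",
                                        target = "ZZZ"), toy_roles()),
               "ZZZ")
})

test_that("degree correlation handles collinear and degenerate cases", {
  tr <- do.call(rbind, list(
    data.frame(modulator = "M1", tf = "T1", target = "G1"),
    data.frame(modulator = c("M1", "M2"), tf = "T2", target = c("G1", "G2"))))
  roles <- rbind(toy_roles(),
                 data.frame(gene = "T3", role = "TF"))
  tr <- rbind(tr, data.frame(modulator = c("M1", "M2", "O1"), tf = "T3",
                             target = c("G1", "G2", "G3")))
  net <- build_network(tr, roles)
  ds <- degree_summary(net)
  expect_equal(ds$pearson_r, 1)                  # in = out for every TF
  one <- build_network(data.frame(modulator = "M1", tf = "T1", target = "G1"),
                       toy_roles())
  expect_true(is.na(degree_summary(one)$pearson_r))
})

test_that("the six published feedback loops are recovered among decoys", {
  tfs <- c("E2F3", "ETS1", "HMGA2", "HNF1B")
  partners <- c("CHEK2", "EGFR", "ERBB2", "SPARC", "MYC")
  roles <- data.frame(
    gene = c(tfs, partners, "TSGX", "TGTX"),
    role = c(rep("TF", 4), "TSG", "OCG", "OCG", "TSG", "OCG", "TSG", "target"),
    stringsAsFactors = FALSE)
  loops <- data.frame(
    tf = c("E2F3", "ETS1", "ETS1", "ETS1", "HMGA2", "HNF1B"),
    gene = c("CHEK2", "EGFR", "ERBB2", "SPARC", "MYC", "MYC"))
  triplets <- rbind(
    data.frame(modulator = loops$gene, tf = loops$tf, target = loops$gene),
    # decoy one-way edges: modulation without the return regulation and
    # regulation onto a gene that does not modulate
    data.frame(modulator = "TSGX", tf = c("E2F3", "ETS1"), target = "TGTX"),
    data.frame(modulator = "CHEK2", tf = "HMGA2", target = "TGTX"))
  net <- build_network(triplets, roles)
  got <- detect_feedback_loops(net)
  expect_equal(nrow(got), 6)
  expect_equal(got, got[order(got$tf, got$gene), ])
  expect_setequal(paste(got$tf, got$gene), paste(loops$tf, loops$gene))
})

test_that("loop and dual-role detection equal exhaustive oracles", {
  set.seed(12)
  for (i in 1:60) {
    net <- random_regnet(n_mod = sample(2:5, 1), n_tf = sample(2:4, 1),
                         n_tgt = sample(3:7, 1), n_triplets = sample(4:14, 1))
    expect_equal(detect_feedback_loops(net), oracle_loops(net),
                 ignore_attr = TRUE)
    expect_equal(sort(dual_role_genes(net)$gene), oracle_dual(net))
  }
})

test_that("disjoint layers carry no loops and no dual roles", {
  tr <- data.frame(modulator = c("M1", "M2"), tf = c("T1", "T2"),
                   target = c("G1", "G2"))
  net <- build_network(tr, toy_roles())
  expect_equal(nrow(detect_feedback_loops(net)), 0)
  expect_equal(nrow(dual_role_genes(net)), 0)
})

test_that("SIF and JSON exports round-trip", {
  set.seed(21)
  net <- random_regnet(4, 3, 6, 12)
  sif <- withr::local_tempfile(fileext = ".sif")
  write_sif(net, sif)
  back <- read_sif(sif)
  expect_setequal(paste(back$modulation$modulator, back$modulation$tf),
                  paste(net$modulation$modulator, net$modulation$tf))
  # write -> read -> write is byte-stable
  sif2 <- withr::local_tempfile(fileext = ".sif")
  net2 <- net
  net2$modulation <- back$modulation
  net2$regulation <- back$regulation
  write_sif(net2, sif2)
  expect_identical(readLines(sif), readLines(sif2))

  js <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, js)
  rnet <- read_network_json(js)
  expect_equal(rnet$modulation, net$modulation)
  expect_equal(rnet$regulation, net$regulation)
  expect_equal(rnet$roles, net$roles)
  expect_equal(rnet$summary$n_genes, net$summary$n_genes)
})

test_that("the published-structure replica reproduces every printed fact", {
  net <- replica_network()
  s <- net$summary
  expect_equal(s$n_genes, 112)
  expect_equal(s$n_tsg, 29)
  expect_equal(s$n_ocg, 13)
  expect_equal(s$n_tf, 15)
  expect_equal(length(net$targets), 65)
  expect_setequal(s$demoted_tfs, c("FOXM1", "MSX1", "PPARG", "STAT5A"))
  loops <- detect_feedback_loops(net)
  expect_equal(nrow(loops), 6)
  expect_setequal(paste(loops$tf, loops$gene),
                  c("E2F3 CHEK2", "ETS1 EGFR", "ETS1 ERBB2", "ETS1 SPARC",
                    "HMGA2 MYC", "HNF1B MYC"))
  dual <- dual_role_genes(net)
  expect_equal(nrow(dual), 10)
  expect_equal(sum(grepl("TSG", dual$roles)), 3)
  expect_equal(sum(grepl("OCG", dual$roles)), 3)
  expect_equal(sum(grepl("TF", dual$roles)), 4)
})
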