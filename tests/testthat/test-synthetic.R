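# Synthetic-data generators: planted structure, standardization, determinism.

test_that("generated PPI networks are simple, connected and heavy-tailed", {
  g <- generate_ppi(5, 1, seed = 3)
  expect_equal(igraph::ecount(g), 4)            # tree: n - 1 edges
  expect_true(igraph::is_connected(g))
  for (s in 1:5) {
    g <- generate_ppi(200, 2, seed = s)
    expect_true(igraph::is_simple(g))
    expect_equal(sum(igraph::degree(g)), 2 * igraph::ecount(g))  # handshake
  }
  ratios <- vapply(1:20, function(s) {
    d <- igraph::degree(generate_ppi(2000, 3, seed = s))
    max(d) / stats::median(d)
  }, numeric(1))
  expect_true(all(ratios > 10))                 # scale-free hubs
  expect_error(generate_ppi(3, 3), "exceed")
})

test_that("expression planting gives the analytic within-tail correlation", {
  cfg <- synthetic_config(n_samples = 5000, n_planted_triplets = 5,
                          beta_high = 1, beta_low = 0, noise_sd = 1,
                          modulator_fraction = 0.35)
  truth <- generate_ground_truth(cfg, seed = 5)
  expr <- generate_expression(cfg, truth, seed = 6)
  expect_true(all(abs(rowMeans(expr)) < 1e-9))
  expect_true(all(abs(apply(expr, 1, sd) - 1) < 1e-9))
  k <- floor(0.35 * 5000)
  for (i in 1:5) {
    tr <- truth$planted_triplets[i, ]
    top <- order(expr[tr$modulator, ])[(5000 - k + 1):5000]
    r <- cor(expr[tr$tf, top], expr[tr$target, top])
    expect_equal(r, 1 / sqrt(2), tolerance = 0.05)  # rho = beta/sqrt(beta^2+sd^2)
  }
})

test_that("expression generation is deterministic and rejects conflicts", {
  cfg <- synthetic_config(n_samples = 50, role_counts = c(TSG = 3, OCG = 2,
                                                          TF = 2, common = 5),
                          n_planted_triplets = 3)
  truth <- generate_ground_truth(cfg, seed = 2)
  e1 <- generate_expression(cfg, truth, seed = 9)
  e2 <- generate_expression(cfg, truth, seed = 9)
  expect_identical(e1, e2)
  bad <- truth
  bad$planted_triplets <- rbind(bad$planted_triplets,
                                bad$planted_triplets[1, ])
  expect_error(generate_expression(cfg, bad, seed = 9), "conflicting")
})

test_that("a symmetric construction centers the Delta-I null at zero", {
  cfg <- synthetic_config(n_samples = 400,
                          role_counts = c(TSG = 5, OCG = 0, TF = 1, common = 8),
                          n_planted_triplets = 5, beta_high = 0.5,
                          beta_low = 0.5)
  ds <- vapply(1:10, function(s) {
    truth <- generate_ground_truth(cfg, seed = s)
    expr <- generate_expression(cfg, truth, seed = s + 100)
    tr <- truth$planted_triplets[1, ]
    delta_mi(expr, tr$modulator, tr$tf, tr$target)$delta_I
  }, numeric(1))
  expect_lt(abs(mean(ds)), 0.05)
})

test_that("generated PWMs are normalized with a modal consensus", {
  p <- generate_pwm("TATAA", 10)
  expect_equal(colSums(p$mat), rep(1, 5), tolerance = 1e-12)
  expect_equal(rownames(p$mat)[apply(p$mat, 2, which.max)],
               strsplit("TATAA", "")[[1]])
  expect_true(all(p$info > 0))
  pinf <- generate_pwm("ACGT", Inf)
  expect_equal(unname(pinf$raw["A", 1]), 1)     # point mass before pseudocount
  expect_error(generate_pwm("ACGX", 5), "consensus")
})

test_that("promoter planting records positions that the scanner recovers", {
  pwm <- generate_pwm("TGACGTCATTGA", Inf)
  pm <- data.frame(tf = "TF1", target = c("g1", "g2"), matrix = pwm$name,
                   copies = c(1L, 2L))
  out <- generate_promoters(c("g1", "g2"), stats::setNames(list(pwm), pwm$name),
                            pm, promoter_length = 300, seed = 4)
  expect_identical(nchar(out$promoters), c(g1 = 300L, g2 = 300L))
  expect_equal(nrow(out$tfbs), 3)
  for (i in seq_len(nrow(out$tfbs))) {
    h <- scan_sequence(out$promoters[[out$tfbs$target[i]]], pwm)
    expect_true(any(h$start == out$tfbs$start[i] &
                      h$strand == out$tfbs$strand[i]))
  }
  again <- generate_promoters(c("g1", "g2"),
                              stats::setNames(list(pwm), pwm$name), pm,
                              promoter_length = 300, seed = 4)
  expect_identical(out, again)                  # seed determinism
  expect_error(generate_promoters("g1", stats::setNames(list(pwm), pwm$name),
                                  data.frame(tf = "TF1", target = "g1",
                                             matrix = pwm$name, copies = 40L),
                                  promoter_length = 100, seed = 1),
               "too short")
})

test_that("unplanted promoters yield no stringent-threshold hits", {
  pwm <- generate_pwm("TGACGTCATTGA", Inf)
  set.seed(11)
  for (i in 1:5) {
    bg <- random_dna(1000)
    expect_equal(nrow(scan_sequence(bg, pwm)), 0)
  }
})

test_that("the full benchmark carries consistent ground truth", {
  b <- suppressMessages(generate_benchmark(synthetic_config(), seed = 5))
  tr <- b$truth$planted_triplets
  rm_ <- b$truth$role_map
  roles <- stats::setNames(rm_$role, rm_$gene)
  expect_true(all(roles[tr$modulator] %in% c("TSG", "OCG")))
  expect_true(all(roles[tr$tf] == "TF"))
  expect_true(all(roles[tr$target] == "common"))
  expect_true(all(b$tfbs$start >= 0 &
                    b$tfbs$start <= b$config$promoter_length - 12))
  b2 <- suppressMessages(generate_benchmark(synthetic_config(), seed = 5))
  expect_identical(b$expr, b2$expr)
  expect_identical(b$promoters, b2$promoters)
})
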