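# Mutual information estimation and modulator inference.

test_that("MI estimates track the bivariate-Gaussian closed form", {
  set.seed(1)
  x <- rnorm(5000); y <- rnorm(5000)
  expect_lt(estimate_mi(x, y), 0.01)            # independence

  errs <- vapply(1:10, function(s) {
    set.seed(s)
    x <- rnorm(2000)
    y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(2000)
    estimate_mi(x, y) - (-0.5 * log(1 - 0.25))
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.03)              # -1/2 ln(1 - rho^2) = 0.1438
})

test_that("the binning estimator reproduces the exact plug-in MI of a 2x2 table", {
  x <- rep(c(0, 1, 0, 1), c(40, 40, 10, 10))
  y <- rep(c(0, 1, 1, 0), c(40, 40, 10, 10))
  # hand-computed: 2*.4*ln(1.6) + 2*.1*ln(0.4)
  want <- 0.8 * log(1.6) + 0.2 * log(0.4)
  expect_equal(estimate_mi(x, y, "equal-frequency-binning"), want,
               tolerance = 1e-12)
})

test_that("MI is symmetric and invariant under monotone transforms", {
  set.seed(3)
  x <- rnorm(300); y <- 0.6 * x + rnorm(300)
  expect_equal(estimate_mi(x, y), estimate_mi(y, x))
  expect_equal(estimate_mi(exp(x), y^3 + y), estimate_mi(x, y))
  expect_warning(mi0 <- estimate_mi(rep(1, 50), rnorm(50)), "constant")
  expect_equal(mi0, 0)
  expect_error(estimate_mi(1:5, 1:5), "at least 8")
})

test_that("the Delta-I contrast recovers the planted-triplet closed form", {
  cfg <- synthetic_config(n_samples = 5000,
                          role_counts = c(TSG = 2, OCG = 1, TF = 2, common = 4),
                          n_planted_triplets = 1, beta_high = 1, beta_low = 0)
  truth <- generate_ground_truth(cfg, seed = 2)
  expr <- generate_expression(cfg, truth, seed = 3)
  tr <- truth$planted_triplets[1, ]
  d <- delta_mi(expr, tr$modulator, tr$tf, tr$target)
  # top tail: rho = 1/sqrt(2) -> I = -1/2 ln(1/2) = 0.3466; bottom: ~0
  expect_equal(d$delta_I, 0.3466, tolerance = 0.05)
  expect_gt(d$I_high, d$I_low)

  # flipping the modulator swaps the tails and the sign
  expr_neg <- expr
  expr_neg[tr$modulator, ] <- -expr[tr$modulator, ]
  d2 <- delta_mi(expr_neg, tr$modulator, tr$tf, tr$target)
  expect_equal(d2$delta_I, -d$delta_I, tolerance = 1e-12)

  # column order must not matter
  perm <- sample(ncol(expr))
  d3 <- delta_mi(expr[, perm], tr$modulator, tr$tf, tr$target)
  expect_equal(d3$delta_I, d$delta_I, tolerance = 1e-12)
})

test_that("permutation p-values hit the floor for strong triplets and stay null otherwise", {
  w <- tiny_planted(n = 489, beta_high = 1.5, seed = 4)
  tr <- w$truth$planted_triplets[1, ]
  cfg <- inference_config(n_perm = 200, seed = 10)
  strong <- permutation_pvalue(w$expr, tr$modulator, tr$tf, tr$target, cfg)
  expect_equal(strong$p_perm, 1 / 201)          # minimum attainable

  others <- setdiff(rownames(w$expr), unlist(tr))
  nullp <- permutation_pvalue(w$expr, others[1], others[2], others[3], cfg)
  expect_gt(nullp$p_perm, 0.01)
  expect_lte(nullp$p_perm, 1)

  # a zero observed contrast gives p = 1: make target identical to the TF,
  # so both tails carry the same (clamped) dependence
  w$expr[others[3], ] <- w$expr[others[2], ]
  zero <- permutation_pvalue(w$expr, others[1], others[2], others[3], cfg)
  expect_equal(zero$delta_I, 0)
  expect_equal(zero$p_perm, 1)
})

test_that("inference recovers a single planted triplet under a permissive alpha", {
  w <- tiny_planted(n = 300, beta_high = 1.5, seed = 6)
  rm_ <- w$truth$role_map
  cands <- list(modulators = rm_$gene[rm_$role %in% c("TSG", "OCG")],
                tfs = rm_$gene[rm_$role == "TF"],
                targets = rm_$gene[rm_$role == "common"])
  cfg <- inference_config(n_perm = 200, fdr_alpha = 1, seed = 3)
  hits <- infer_modulations(w$expr, cands, cfg)
  expect_true(triplet_key(w$truth$planted_triplets) %in% triplet_key(hits))
  expect_true(all(hits$I_high >= 0 & hits$I_low >= 0))
  expect_true(all(hits$p > 0 & hits$p <= 1))
  expect_true(all(hits$q >= hits$p))
})

test_that("batch inference agrees with the single-triplet contrast", {
  w <- tiny_planted(n = 200, seed = 8)
  rm_ <- w$truth$role_map
  cands <- list(modulators = rm_$gene[rm_$role %in% c("TSG", "OCG")],
                tfs = rm_$gene[rm_$role == "TF"],
                targets = rm_$gene[rm_$role == "common"])
  cfg <- inference_config(n_perm = 100, seed = 5)
  all_t <- infer_modulations(w$expr, cands, cfg, keep_all = TRUE)
  for (i in sample(nrow(all_t), 5)) {
    d <- delta_mi(w$expr, all_t$modulator[i], all_t$tf[i], all_t$target[i])
    expect_equal(all_t$delta_I[i], d$delta_I, tolerance = 1e-10)
  }
})

test_that("empty candidate sets yield an empty result with a warning", {
  w <- tiny_planted(n = 100, seed = 9)
  cands <- list(modulators = character(), tfs = "TF01", targets = "CG001")
  expect_warning(res <- infer_modulations(w$expr, cands), "empty")
  expect_equal(nrow(res), 0)
})

test_that("degenerate self-triplets are skipped", {
  w <- tiny_planted(n = 100, seed = 10)
  cands <- list(modulators = c("TSG01", "TF01"), tfs = "TF01",
                targets = "CG001")
  expect_message(
    res <- infer_modulations(w$expr, cands,
                             inference_config(n_perm = 100, fdr_alpha = 1)),
    "degenerate")
  expect_false(any(res$modulator == res$tf))
})
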