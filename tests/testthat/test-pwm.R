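# MATCH-style PWM machinery: information vectors, core location, min-max
# scores, scanning, TF-target prediction and flat-file round trips.

test_that("information vector follows the f ln(4f) formula", {
  m <- cbind(c(.25, .25, .25, .25), c(1, 0, 0, 0), c(.5, .5, 0, 0))
  p <- new_pwm(m, pseudocount = 0)
  expect_equal(p$info[1], 0)
  expect_equal(p$info[2], log(4))
  expect_equal(p$info[3], log(2))
  expect_true(all(p$info >= 0 & p$info <= log(4) + 1e-12))
})

test_that("core location maximizes windowed information, leftmost on ties", {
  p5 <- generate_pwm("ACGTA", 10)
  expect_equal(p5$core_offset, 0L)

  # L = 8 with the informative stretch at offsets 2..6
  m <- matrix(0.25, 4, 8)
  for (i in 3:7) { m[, i] <- 0; m[1, i] <- 1 }
  p8 <- new_pwm(m, pseudocount = 0)
  expect_equal(p8$core_offset, 2L)

  set.seed(5)
  for (i in 1:20) {
    p <- random_pwm(sample(5:12, 1))
    sums <- vapply(0:(ncol(p$mat) - 5), function(o) sum(p$info[o + 1:5]),
                   numeric(1))
    expect_equal(p$core_offset, which.max(sums) - 1L)
  }
  expect_error(find_core(new_pwm(matrix(0.25, 4, 4))), "at least 5")
})

test_that("min-max scores hit their bounds at consensus and anti-consensus", {
  set.seed(6)
  for (i in 1:10) {
    p <- random_pwm(8)
    consensus <- rownames(p$mat)[apply(p$mat, 2, which.max)]
    anti <- rownames(p$mat)[apply(p$mat, 2, which.min)]
    expect_equal(score_window(p, consensus), 1)
    expect_equal(score_window(p, anti), 0)
    w <- sample(c("A", "C", "G", "T"), 8, replace = TRUE)
    I <- p$info
    cur <- sum(I * p$mat[cbind(match(w, rownames(p$mat)), 1:8)])
    mn <- sum(I * apply(p$mat, 2, min)); mx <- sum(I * apply(p$mat, 2, max))
    expect_equal(score_window(p, w), (cur - mn) / (mx - mn))
  }
  expect_error(score_window(new_pwm(matrix(1, 4, 6)), rep("A", 6)),
               "degenerate")
})

test_that("scanning finds a planted consensus exactly once", {
  p <- generate_pwm("TGACGTCA", Inf)
  seqchr <- paste0(strrep("C", 17), "TGACGTCA", strrep("C", 20))
  h <- scan_sequence(seqchr, p)
  # TGACGTCA is palindromic: the same window matches on both strands
  expect_equal(h$start, c(17L, 17L))
  expect_setequal(h$strand, c("+", "-"))
  expect_equal(h$core_score, c(1, 1))
  expect_equal(h$matrix_score, c(1, 1))

  p2 <- generate_pwm("TTGACGCATGA", Inf)
  seq2 <- paste0(strrep("C", 9), "TTGACGCATGA", strrep("A", 10))
  h2 <- scan_sequence(seq2, p2)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$start, 9L)
  expect_equal(h2$strand, "+")
  expect_equal(h2$end, 20L)
})

test_that("vectorized scanning equals the naive per-window oracle", {
  set.seed(7)
  cfgs <- list(scan_config(0.9, 0.7), scan_config(1.0, 0.95),
               scan_config(0.8, 0.5, both_strands = FALSE))
  for (i in 1:60) {
    p <- random_pwm(sample(6:10, 1))
    s <- random_dna(120)
    cfg <- cfgs[[(i %% 3) + 1]]
    got <- scan_sequence(s, p, cfg)
    want <- oracle_scan(s, p, cfg)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
      expect_equal(got$core_score, want$core_score, tolerance = 1e-12)
      expect_equal(got$matrix_score, want$matrix_score, tolerance = 1e-12)
    }
  }
})

test_that("raising thresholds never adds hits", {
  set.seed(8)
  for (i in 1:15) {
    p <- random_pwm(8)
    s <- random_dna(300)
    loose <- scan_sequence(s, p, scan_config(0.7, 0.5))
    tight <- scan_sequence(s, p, scan_config(0.9, 0.7))
    k <- function(h) paste(h$start, h$strand)
    expect_true(all(k(tight) %in% k(loose)))
  }
})

test_that("N handling follows the ambiguity policy", {
  p <- generate_pwm("ACGTACGT", Inf)
  s <- paste0("AAA", "ACGTNCGT", "AAA")
  expect_equal(nrow(scan_sequence(s, p, scan_config(0, 0))), 0)  # all skipped
  h <- scan_sequence(s, p, scan_config(0, 0, ambiguity_policy = "min-frequency"))
  expect_gt(nrow(h), 0)
  expect_true(all(h$matrix_score < 1))
})

test_that("strand convention mirrors hits under reverse complement", {
  set.seed(9)
  for (i in 1:10) {
    p <- random_pwm(7)
    s <- random_dna(100)
    cfg <- scan_config(0.8, 0.6)
    fwd <- scan_sequence(s, p, cfg)
    rc <- scan_sequence(revcomp_chr(s), p, cfg)
    # a + hit at start on s maps to a - hit at n - end on revcomp(s)
    k1 <- sort(paste(fwd$start, fwd$strand))
    k2 <- sort(paste(100 - rc$end, ifelse(rc$strand == "+", "-", "+")))
    expect_equal(k1, k2)
  }
})

test_that("TF-target prediction recovers planted consensus edges", {
  pwms <- list(M_A = generate_pwm("TGCACGTCAGTA", Inf, name = "M_A"),
               M_B = generate_pwm("CCGGATATCGGA", Inf, name = "M_B"))
  pm <- data.frame(tf = c("TFA", "TFB"), target = c("g1", "g2"),
                   matrix = c("M_A", "M_B"), copies = 1L)
  prom <- generate_promoters(c("g1", "g2", "g3"), pwms, pm,
                             promoter_length = 500, seed = 2)
  tf_map <- data.frame(tf = c("TFA", "TFB"), matrix = c("M_A", "M_B"))
  edges <- predict_tf_targets(prom$promoters, pwms, tf_map)
  k <- paste(edges$tf, edges$target)
  expect_true(all(c("TFA g1", "TFB g2") %in% k))
  expect_true(all(edges$n_hits >= 1))

  empty <- predict_tf_targets(character(0) |> stats::setNames(character(0)),
                              pwms, tf_map)
  expect_equal(nrow(empty), 0)
  expect_error(predict_tf_targets(prom$promoters, pwms,
                                  data.frame(tf = "TFC", matrix = "M_X")),
               "no mapped PWM")
})

test_that("TRANSFAC and TSV round trips preserve the matrices", {
  pwms <- list(ONE = generate_pwm("ACGTGT", 8, name = "ONE"),
               TWO = generate_pwm("TTTAAACG", 3, name = "TWO"))
  f <- withr::local_tempfile(fileext = ".transfac")
  write_transfac(pwms, f)
  back <- read_transfac(f, pseudocount = 0)
  expect_setequal(names(back), c("ONE", "TWO"))
  expect_equal(back$ONE$mat, pwms$ONE$mat, tolerance = 1e-5)
  expect_equal(back$TWO$core_offset, pwms$TWO$core_offset)

  ftsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(as.data.frame(t(pwms$ONE$mat)), ftsv, sep = "\t",
              row.names = FALSE, quote = FALSE)
  p <- read_pwm_tsv(ftsv, name = "ONE", pseudocount = 0)
  expect_equal(p$mat, pwms$ONE$mat, tolerance = 1e-12)
})
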