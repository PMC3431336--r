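# MATCH-style PWM scanning: information-vector weighting, core (5-position)
# and full-matrix min-max-normalized similarity scores, thresholded hit
# calling, and TF -> target edge prediction from promoter scans.

.BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' Adds a pseudocount to every cell, normalizes columns to frequencies, and
#' precomputes the information vector `I(i) = sum_b f(i,b) ln(4 f(i,b))`
#' (natural log; `0 ln 0 := 0`) and the core offset — the start of the five
#' consecutive positions maximizing the summed information (leftmost on
#' ties).
#'
#' @param mat 4 x L numeric matrix of counts or frequencies; rows A, C, G, T
#'   (row names optional, this order assumed if absent).
#' @param name matrix identifier.
#' @param pseudocount added to every cell before normalization (default
#'   1e-3); avoids `ln 0` for hard-zero columns.
#' @return object of class `pwm`: list with `name`, `mat` (pseudocounted
#'   scoring frequencies), `raw` (generative frequencies without
#'   pseudocount), `pseudocount`, `info`, `core_offset` (0-based; `NA` when
#'   L < 5).
#' @export
new_pwm <- function(mat, name = "pwm", pseudocount = 1e-3) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) .err("PWM must have 4 rows (A, C, G, T)")
  if (any(mat < 0)) .err("PWM entries must be non-negative")
  rownames(mat) <- .BASES
  raw <- sweep(mat, 2, colSums(mat), "/")  # generative frequencies
  mat <- mat + pseudocount
  mat <- sweep(mat, 2, colSums(mat), "/")
  obj <- structure(list(name = name, mat = mat, raw = raw,
                        pseudocount = pseudocount),
                   class = "pwm")
  obj$info <- information_vector(obj)
  obj$core_offset <- if (ncol(mat) >= 5) find_core(obj) else NA_integer_
  obj
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': %d positions, core offset %s, total information %.3f nats\n",
              x$name, ncol(x$mat), x$core_offset, sum(x$info)))
  invisible(x)
}

#' Per-position information vector of a PWM
#'
#' `I(i) = sum_b f(i,b) ln(4 f(i,b))` with `0 ln 0 := 0`; 0 for a uniform
#' column, `ln 4` for a point mass.
#'
#' @param pwm a `pwm` object (or bare 4 x L frequency matrix).
#' @return numeric vector of length L.
#' @export
information_vector <- function(pwm) {
  f <- if (inherits(pwm, "pwm")) pwm$mat else pwm
  apply(f, 2, function(col) {
    nz <- col > 0
    sum(col[nz] * log(4 * col[nz]))
  })
}

#' Locate the core of a PWM
#'
#' The core is the window of 5 consecutive positions maximizing the summed
#' information vector; ties resolve to the leftmost window.
#'
#' @param pwm a `pwm` object.
#' @return 0-based core offset.
#' @export
find_core <- function(pwm) {
  I <- pwm$info %||% information_vector(pwm)
  L <- length(I)
  if (L < 5) .err("PWM must have at least 5 positions")
  sums <- vapply(0:(L - 5), function(o) sum(I[o + 1:5]), numeric(1))
  which.max(sums) - 1L  # which.max returns the first (leftmost) maximum
}

#' Min-max-normalized similarity of a sequence window to a PWM
#'
#' `score = (Current - Min) / (Max - Min)` with
#' `Current = sum_i I(i) f(i, b_i)`, and `Min`/`Max` the analogous sums with
#' the least/most frequent base at each position.  The full-matrix score uses
#' all positions; the core score restricts to the 5 core positions.
#'
#' @param pwm a `pwm` object.
#' @param window character vector of single bases (or a string) matching the
#'   length of `positions`.
#' @param positions 1-based PWM positions to score (default: all).
#' @return similarity in [0, 1].
#' @export
score_window <- function(pwm, window, positions = seq_len(ncol(pwm$mat))) {
  if (length(window) == 1 && nchar(window[1]) > 1)
    window <- strsplit(window, "")[[1]]
  if (length(window) != length(positions))
    .err("window length must match the scored positions")
  f <- pwm$mat[, positions, drop = FALSE]
  I <- pwm$info[positions]
  bi <- match(toupper(window), .BASES)
  if (anyNA(bi)) .err("window contains a non-ACGT base")
  cur <- sum(I * f[cbind(bi, seq_along(positions))])
  mn <- sum(I * apply(f, 2, min))
  mx <- sum(I * apply(f, 2, max))
  if (mx - mn <= 0) .err("degenerate PWM: maximal and minimal scores coincide")
  (cur - mn) / (mx - mn)
}

# reverse complement of a pwm (columns reversed, A<->T and C<->G swapped);
# frequencies already include the pseudocount, so none is re-added
.revcomp_pwm <- function(pwm) {
  mat <- pwm$mat[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm$mat)))]
  rownames(mat) <- .BASES
  obj <- structure(list(name = paste0(pwm$name, "_rc"), mat = mat,
                        pseudocount = pwm$pseudocount), class = "pwm")
  obj$info <- information_vector(obj)
  obj$core_offset <- if (ncol(mat) >= 5) find_core(obj) else NA_integer_
  obj
}

#' Scan configuration for PWM hit calling
#'
#' @param core_threshold minimum core score (default 1.00: the core window
#'   must attain the maximum attainable weighted sum).
#' @param matrix_threshold minimum full-matrix score (default 0.95).
#' @param both_strands scan the reverse complement too (default `TRUE`).
#' @param ambiguity_policy windows containing `N`: `"skip"` (default) or
#'   `"min-frequency"` (an `N` contributes the column's minimum frequency).
#' @return object of class `scan_config`.
#' @export
scan_config <- function(core_threshold = 1.00, matrix_threshold = 0.95,
                        both_strands = TRUE,
                        ambiguity_policy = c("skip", "min-frequency")) {
  structure(list(core_threshold = core_threshold,
                 matrix_threshold = matrix_threshold,
                 both_strands = both_strands,
                 ambiguity_policy = match.arg(ambiguity_policy)),
            class = "scan_config")
}

# score every window of one strand; returns start (0-based), core, matrix
.scan_strand <- function(code, pwm, policy) {
  L <- ncol(pwm$mat)
  n <- length(code)
  if (n < L) return(data.frame(start = integer(), core_score = numeric(),
                               matrix_score = numeric()))
  nwin <- n - L + 1L
  I <- pwm$info
  S <- sweep(pwm$mat, 2, I, "*")          # S[b, i] = I(i) f(i, b)
  smin <- apply(S, 2, min)
  smax <- apply(S, 2, max)
  core <- pwm$core_offset + 1:5
  cur_all <- numeric(nwin)
  cur_core <- numeric(nwin)
  nbad <- logical(nwin)
  for (i in seq_len(L)) {
    b <- code[i:(i + nwin - 1L)]
    na <- is.na(b)
    contrib <- numeric(nwin)
    contrib[!na] <- S[cbind(b[!na], i)]
    if (any(na)) {
      if (policy == "skip") nbad[na] <- TRUE else contrib[na] <- smin[i]
    }
    cur_all <- cur_all + contrib
    if (i %in% core) cur_core <- cur_core + contrib
  }
  rng_all <- sum(smax) - sum(smin)
  rng_core <- sum(smax[core]) - sum(smin[core])
  if (rng_all <= 0 || rng_core <= 0)
    .err("degenerate PWM: maximal and minimal scores coincide")
  out <- data.frame(start = 0:(nwin - 1L),
                    core_score = (cur_core - sum(smin[core])) / rng_core,
                    matrix_score = (cur_all - sum(smin)) / rng_all)
  out[!nbad, , drop = FALSE]
}

#' Scan a sequence with a PWM and call hits
#'
#' Every window of the motif length is scored on the forward strand and (by
#' default) on the reverse complement; a hit requires core score >=
#' `core_threshold` and matrix score >= `matrix_threshold` (comparisons allow
#' 1e-9 numerical slack).  Minus-strand hits are reported in forward
#' coordinates.  Hits are sorted by position, `+` before `-`.
#'
#' @param sequence character string over A/C/G/T/N (or a
#'   `Biostrings::DNAString`).
#' @param pwm a `pwm` object with at least 5 positions.
#' @param config a [scan_config()].
#' @param seqid optional sequence identifier attached to the hits.
#' @return data.frame: seqid, start (0-based), end (half-open), strand,
#'   core_score, matrix_score, matrix.
#' @export
scan_sequence <- function(sequence, pwm, config = scan_config(),
                          seqid = NA_character_) {
  if (is.na(pwm$core_offset)) .err("PWM must have at least 5 positions")
  seq <- toupper(as.character(sequence))
  code <- match(strsplit(seq, "")[[1]], .BASES)  # N and friends -> NA
  eps <- 1e-9
  fw <- .scan_strand(code, pwm, config$ambiguity_policy)
  fw$strand <- rep("+", nrow(fw))
  hits <- fw
  if (config$both_strands) {
    rv <- .scan_strand(code, .revcomp_pwm(pwm), config$ambiguity_policy)
    rv$strand <- rep("-", nrow(rv))
    hits <- rbind(fw, rv)
  }
  hits <- hits[hits$core_score >= config$core_threshold - eps &
                 hits$matrix_score >= config$matrix_threshold - eps, ,
               drop = FALSE]
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  L <- ncol(pwm$mat)
  data.frame(seqid = rep(seqid, nrow(hits)), start = hits$start,
             end = hits$start + L, strand = hits$strand,
             core_score = pmin(hits$core_score, 1),
             matrix_score = pmin(hits$matrix_score, 1),
             matrix = rep(pwm$name, nrow(hits)), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Predict TF -> target edges from promoter scans
#'
#' A TF is predicted to regulate a gene iff any of its mapped PWMs yields at
#' least one hit in that gene's promoter at the configured thresholds.
#'
#' @param promoters named character vector (or `DNAStringSet`) of promoter
#'   sequences, names = target genes.
#' @param pwm_library named list of `pwm` objects.
#' @param tf_to_matrix_map data.frame with columns `tf` and `matrix`.
#' @param config a [scan_config()].
#' @return data.frame: tf, target, n_hits (supporting hit count), plus the
#'   full hit table as attribute `"hits"`.
#' @export
predict_tf_targets <- function(promoters, pwm_library, tf_to_matrix_map,
                               config = scan_config()) {
  if (inherits(promoters, "XStringSet"))
    promoters <- stats::setNames(as.character(promoters), names(promoters))
  tfs <- unique(tf_to_matrix_map$tf)
  bad <- tfs[!tfs %in% tf_to_matrix_map$tf[tf_to_matrix_map$matrix %in%
                                             names(pwm_library)]]
  if (length(bad)) .err("TF(s) with no mapped PWM in library: ",
                        paste(bad, collapse = ", "))
  all_hits <- list()
  edges <- list()
  for (i in seq_len(nrow(tf_to_matrix_map))) {
    tf <- tf_to_matrix_map$tf[i]
    pwm <- pwm_library[[tf_to_matrix_map$matrix[i]]]
    for (g in names(promoters)) {
      h <- scan_sequence(promoters[[g]], pwm, config, seqid = g)
      if (nrow(h)) {
        h$tf <- tf
        all_hits[[length(all_hits) + 1L]] <- h
        key <- paste(tf, g, sep = "\r")
        edges[[key]] <- (edges[[key]] %||% 0L) + nrow(h)
      }
    }
  }
  if (!length(edges)) {
    out <- data.frame(tf = character(), target = character(), n_hits = integer())
  } else {
    parts <- strsplit(names(edges), "\r", fixed = TRUE)
    out <- data.frame(tf = vapply(parts, `[`, character(1), 1),
                      target = vapply(parts, `[`, character(1), 2),
                      n_hits = unlist(edges, use.names = FALSE),
                      stringsAsFactors = FALSE)
    out <- out[order(out$tf, out$target), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "hits") <- if (length(all_hits)) do.call(rbind, all_hits) else NULL
  out
}

#' Read PWMs from a TRANSFAC-style flat file
#'
#' Minimal dialect: records delimited by `//`, an `ID <name>` line, a
#' `P0 A C G T` header and numbered rows of four counts.  (No installed
#' package parses this format, so the reader lives here.)
#'
#' @param path flat file path.
#' @param pseudocount passed to [new_pwm()].
#' @return named list of `pwm` objects.
#' @export
read_transfac <- function(path, pseudocount = 1e-3) {
  lines <- readLines(path)
  pwms <- list()
  id <- NULL; rows <- list()
  flush <- function() {
    if (is.null(id)) return()
    if (!length(rows)) .err("TRANSFAC record without matrix rows: ", id)
    mat <- t(do.call(rbind, rows))
    pwms[[id]] <<- new_pwm(mat, name = id, pseudocount = pseudocount)
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (startsWith(ln, "ID")) {
      id <- trimws(sub("^ID\\s+", "", ln))
      rows <- list()
    } else if (ln == "//") {
      flush(); id <- NULL; rows <- list()
    } else if (grepl("^[0-9]+\\s", ln) && !startsWith(ln, "P0")) {
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) < 5) .err("malformed TRANSFAC matrix row: ", ln)
      rows[[length(rows) + 1L]] <- as.numeric(f[2:5])
    }
  }
  flush()
  pwms
}

#' Write PWMs to a TRANSFAC-style flat file
#'
#' @param pwms named list of `pwm` objects.
#' @param path output path.
#' @export
write_transfac <- function(pwms, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (p in pwms) {
    writeLines(c(paste("ID", p$name), "P0  A  C  G  T"), con)
    for (i in seq_len(ncol(p$mat)))
      writeLines(sprintf("%02d  %.6f  %.6f  %.6f  %.6f", i,
                         p$mat["A", i], p$mat["C", i], p$mat["G", i],
                         p$mat["T", i]), con)
    writeLines("//", con)
  }
  invisible(path)
}

#' Read a PWM from a 4-column TSV (columns A, C, G, T; one row per position)
#'
#' @param path TSV with header `A C G T`.
#' @param name matrix identifier (default: file stem).
#' @param pseudocount passed to [new_pwm()].
#' @return a `pwm` object.
#' @export
read_pwm_tsv <- function(path, name = sub("\\.[^.]*$", "", basename(path)),
                         pseudocount = 1e-3) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(.BASES %in% names(d))) .err("PWM TSV must have columns A, C, G, T")
  new_pwm(t(as.matrix(d[, .BASES])), name = name, pseudocount = pseudocount)
}
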