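# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive independent per-stage seeds from one master seed
#'
#' A single master seed is expanded into `n` stage seeds so that every
#' stochastic stage of a pipeline run is reproducible from one knob, yet
#' stages draw from effectively independent streams.  All derived seeds stay
#' below `.Machine$integer.max`.
#'
#' @param seed master integer seed.
#' @param n number of seeds to derive.
#' @return integer vector of length `n`.
#' @export
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# stop() with a consistent prefix so callers can grep module errors
.err <- function(...) stop(..., call. = FALSE)

# coerce a two-column object to a character edge data.frame
.as_edge_df <- function(x, cols = c("from", "to")) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  stopifnot(ncol(x) >= 2)
  out <- data.frame(a = as.character(x[[1]]), b = as.character(x[[2]]),
                    stringsAsFactors = FALSE)
  names(out) <- cols
  out
}
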