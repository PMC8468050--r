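# Internal helpers shared across the package.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Shannon entropy of a probability vector, in bits
#'
#' Convention: terms with `p == 0` contribute nothing (0 log 0 = 0).
#' @param p numeric vector of probabilities (need not be normalized exactly,
#'   but should be non-negative).
#' @return entropy in bits.
#' @keywords internal
#' @noRd
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream.  `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  # Mersenne-Twister pinned explicitly so ensembles are reproducible even if
  # the caller switched RNG kinds.
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# Derive a stream of sub-seeds from a master seed, kept well inside the
# 32-bit signed range.
derive_seeds <- function(seed, n) {
  (as.numeric(seed) * 48271 + 7 * seq_len(n)) %% 2147483629
}

stop_zml <- function(fmt, ..., class) {
  stop(structure(class = c(class, "zml_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    abs(x - round(x)) < 1e-8
}

# Round-half-up with a floor, used wherever a continuous alphabet-size
# estimate must become a finite rank support.
round_support <- function(M, floor = 2L) {
  s <- base::floor(M + 0.5)           # kept numeric: M_hat can exceed .Machine$integer.max
  if (s <= .Machine$integer.max) s <- as.integer(s)
  max(floor, s)
}
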