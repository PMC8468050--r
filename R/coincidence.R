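#' Observed coincidence distances of a symbol
#'
#' The coincidence distance between two consecutive occurrences of the same
#' symbol at positions `j1 < j2` is `D = j2 - j1 + 1`, i.e. the first
#' occurrence counts as draw 1 and the repeat happens "at the D-th draw".
#' In `abcdabc` the distance for `a` is 5.  All consecutive occurrence
#' pairs contribute (not just the first repeat), which maximizes the data
#' used at small sample sizes.
#'
#' @param seq a [symbol_sequence()] (or a plain string / token vector).
#' @param symbol the symbol whose repeats are measured.
#' @return object of class `coincidence_stats`: list with `symbol`,
#'   `distances`, `D_bar` (their mean), `k` (number of gaps) and
#'   `occurrences`.
#' @examples
#' observed_distances("abcdabc", "a")$D_bar   # 5
#' observed_distances("ababa", "a")$distances # 3 3
#' @export
observed_distances <- function(seq, symbol) {
  seq <- as_symbol_sequence(seq)
  pos <- which(seq$tokens == symbol)
  if (length(pos) < 2L)
    stop_zml("no coincidence observed: symbol '%s' occurs %d time(s)",
             as.character(symbol), length(pos),
             class = "zml_no_coincidence")
  d <- diff(pos) + 1L
  structure(list(symbol = symbol, distances = d, D_bar = mean(d),
                 k = length(d), occurrences = length(pos)),
            class = "coincidence_stats")
}

#' @export
print.coincidence_stats <- function(x, ...) {
  cat(sprintf("<coincidence_stats> symbol='%s' k=%d gaps, D_bar=%.4f\n",
              as.character(x$symbol), x$k, x$D_bar))
  invisible(x)
}

#' Symbol of a given empirical rank
#'
#' The `r`-th most frequent symbol of a sequence; ties are broken by order
#' of first occurrence in the sequence, so the result is deterministic.
#'
#' @param seq a [symbol_sequence()] (or string / token vector).
#' @param r rank, `1 <=  r <=` number of distinct observed symbols.
#' @return the symbol (same type as the tokens).
#' @examples
#' rank_symbol("aabbbc", 1)  # "b"
#' rank_symbol("abab", 1)    # "a" (2-2 tie, first occurrence wins)
#' @export
rank_symbol <- function(seq, r) {
  seq <- as_symbol_sequence(seq)
  if (seq$N == 0)
    stop_zml("empty sequence", class = "zml_rank_error")
  syms <- unique(seq$tokens)            # first-occurrence order
  counts <- tabulate(match(seq$tokens, syms), nbins = length(syms))
  if (!is_count(r) || r > length(syms))
    stop_zml("rank r=%s exceeds the %d distinct observed symbols",
             format(r), length(syms), class = "zml_rank_error")
  syms[order(-counts)[r]]               # order() is stable: ties keep
}                                       # first-occurrence order

#' First-coincidence probability mass function
#'
#' Distribution of the draw index `n` at which an i.i.d. stream first
#' repeats a symbol.  The survival probability (no repeat within `n`
#' draws) of a distribution `p` over `M` symbols is
#' `F~(n) = n! e_n(p)` where `e_n` is the `n`-th elementary symmetric
#' polynomial of the probabilities (every ordered selection of `n` distinct
#' symbols); the mass is `f(n) = F~(n-1) - F~(n)`.  The per-draw repeat
#' hazards `P_h = 1 - F~(h)/F~(h-1)` recover the product form
#' `F~(n) = prod(1 - P_h)`, and reduce to the birthday-problem
#' `P_h = (h-1)/M` in the equiprobable case.  By pigeonhole the support
#' ends at `n = M + 1`.
#'
#' @param dist a [zml_model()], a bare probability vector, or `NULL` when
#'   `M` is given (equiprobable over `M` symbols).
#' @param M equiprobable alphabet size (used when `dist` is `NULL`).
#' @param n_max support cap (defaults to the full support `M + 1`).
#' @return object of class `coincidence_pmf`: a `data.frame` with columns
#'   `n`, `f`, `F` (cumulative), `survival`, `per_draw` (`P_h`), plus
#'   attribute `M`.
#' @examples
#' first_coincidence_pmf(M = 2)          # f(2) = f(3) = 1/2
#' pmf <- first_coincidence_pmf(M = 365)
#' expected_coincidence_distance(pmf)    # ~ 24.62, the birthday expectation
#' @export
first_coincidence_pmf <- function(dist = NULL, M = NULL, n_max = NULL) {
  p <- if (is.null(dist)) {
    if (!is_count(M, 1))
      stop_zml("supply a distribution or an equiprobable M >= 1",
               class = "zml_coincidence_error")
    rep(1 / M, M)
  } else if (inherits(dist, "zml_model")) {
    if (is.null(dist$p))
      stop_zml("support %s too large for a dense coincidence pmf",
               format(dist$support), class = "zml_coincidence_error")
    dist$p
  } else as.numeric(dist)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
    stop_zml("probabilities must be non-negative and sum to 1",
             class = "zml_coincidence_error")
  M_eff <- length(p)
  n_max <- n_max %||% (M_eff + 1L)
  if (!is_count(n_max, 2))
    stop_zml("n_max must be an integer >= 2", class = "zml_coincidence_error")
  n_top <- min(n_max, M_eff + 1L)

  # elementary symmetric polynomials e_0..e_{n_top} by the standard DP
  e <- numeric(n_top + 1L); e[1] <- 1
  for (pi in p) {
    kmax <- n_top
    e[(kmax + 1L):2L] <- e[(kmax + 1L):2L] + pi * e[kmax:1L]
  }
  surv <- numeric(n_top + 1L)           # survival at n = 0..n_top
  surv[1] <- 1
  for (n in seq_len(n_top)) {
    ratio <- if (surv[n] > 0 && e[n] > 0) n * e[n + 1L] / e[n] else 0
    surv[n + 1L] <- surv[n] * ratio
  }
  n <- 2:n_max
  # sv[k] = survival after k-1 draws; pad with 0 beyond the pigeonhole bound
  sv <- c(surv, rep(0, max(0, n_max + 1L - length(surv))))
  f <- sv[n] - sv[n + 1L]
  f[f < 0] <- 0                                  # guard fp dust
  per_draw <- ifelse(sv[n] > 0, 1 - sv[n + 1L] / sv[n], 1)
  out <- data.frame(n = n, f = f, F = cumsum(f), survival = sv[n + 1L],
                    per_draw = per_draw)
  attr(out, "M") <- M_eff
  class(out) <- c("coincidence_pmf", "data.frame")
  out
}

#' Expected first-coincidence distance
#'
#' The model-side coincidence distance `D(M) = E[n] = sum n f(n; M)`, the
#' counterpart of the observed mean distance `D_bar`.
#'
#' @param pmf a [first_coincidence_pmf()].
#' @return the expectation `E[n]`.
#' @examples
#' expected_coincidence_distance(first_coincidence_pmf(M = 2))  # 2.5
#' @export
expected_coincidence_distance <- function(pmf) {
  if (!inherits(pmf, "coincidence_pmf"))
    stop_zml("expected a coincidence_pmf", class = "zml_coincidence_error")
  sum(pmf$n * pmf$f)
}
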