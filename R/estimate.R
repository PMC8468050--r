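new_entropy_estimate <- function(value, method, M_hat = NA_real_,
                                 rank_used = NA_integer_, n_samples = NA_integer_,
                                 warnings = character(0)) {
  structure(list(value = value, method = method, M_hat = M_hat,
                 rank_used = rank_used, n_samples = n_samples,
                 perplexity = 2^value, warnings = warnings),
            class = "entropy_estimate")
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf("<entropy_estimate> H = %.4f bits  (perplexity %.3f)\n",
              x$value, x$perplexity))
  cat(sprintf("  method=%s", x$method))
  if (!is.na(x$M_hat)) cat(sprintf("  M_hat=%.3f", x$M_hat))
  if (length(x$rank_used) && !all(is.na(x$rank_used)))
    cat(sprintf("  rank=%s", paste(x$rank_used, collapse = ",")))
  if (!is.na(x$n_samples)) cat(sprintf("  n=%d", x$n_samples))
  cat("\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Model-based coincidence entropy estimate
#'
#' The headline estimator.  Pipeline: measure the mean coincidence distance
#' `D_bar` of the empirically rank-`r` symbol, invert the calibration to an
#' alphabet-size estimate `M_hat = G(theta; D_bar)`, instantiate the model
#' family at `M_hat` (rank support `round(M_hat)`, minimum 2), and report
#' the Shannon entropy of that full estimated distribution:
#' `H = -sum P_hat(h) log2 P_hat(h)`.  Because only the distances of one
#' frequent symbol are needed -- not the probabilities of all `M` symbols --
#' the estimate stabilizes with far fewer samples than plug-in estimation.
#'
#' With `ranks` a vector, `M_hat` is estimated at each rank and combined by
#' a weighted mean with the observed coincidence counts as weights (ranks
#' whose symbol never repeats are skipped with a warning).
#'
#' @param seq a [symbol_sequence()] (or string / token vector).
#' @param calib a `zml_calibration`; defaults to the exact
#'   [analytic_calibration()] of `family`.
#' @param family model family used both to invert the distance and to
#'   synthesize the estimated distribution.
#' @param r estimation rank (default 1, the most frequent symbol: it has
#'   the most coincidences, hence the tightest `D_bar`).
#' @param ranks optional vector of ranks for the multi-rank mode
#'   (overrides `r`).
#' @param B continuation branching for `czml2`.
#' @param bias_correct apply the second-order delta-method correction
#'   `-(1/2) H''(D_bar) var(D_bar)` for the curvature of the
#'   distance-to-entropy map (single-rank mode only).  The sampling noise
#'   of `D_bar` passes through a concave transformation, which otherwise
#'   biases the estimate slightly downward at small sample sizes.
#' @param M_max optional hard upper bound on `M_hat`.  Used by
#'   [block_entropy()] to enforce the combinatorial limit on a derived
#'   n-gram alphabet (there are at most `N_w(M, n)` admissible n-grams);
#'   a capped estimate is flagged in `warnings`.
#' @return an `entropy_estimate` (value in bits, `M_hat`, rank(s) used,
#'   sample count, perplexity, warning flags).
#' @examples
#' set.seed(1)
#' x <- sample_iid_sequence(zml_model(30), 5000)
#' estimate_entropy_model(x)            # close to model_entropy(zml_model(30))
#' @seealso [plugin_entropy()], [miller_madow_entropy()],
#'   [estimate_entropy_equiprobable()]
#' @export
estimate_entropy_model <- function(seq,
                                   calib = NULL,
                                   family = c("zml", "czml1", "czml2"),
                                   r = 1L, ranks = NULL, B = NULL,
                                   bias_correct = TRUE, M_max = NULL) {
  family <- match.arg(family)
  seq <- as_symbol_sequence(seq)
  calib <- calib %||% analytic_calibration(family, B = B)
  ranks <- as.integer(ranks %||% r)
  warns <- character(0)

  M_hats <- numeric(0); wts <- numeric(0); used <- integer(0)
  last_st <- NULL
  for (rk in ranks) {
    st <- tryCatch(observed_distances(seq, rank_symbol(seq, rk)),
                   zml_no_coincidence = function(e) e,
                   zml_rank_error = function(e) e)
    if (inherits(st, "condition")) {
      if (length(ranks) == 1L)
        stop_zml(paste0("no coincidence for rank %d (%s); use a lower rank ",
                        "or more data"), rk, conditionMessage(st),
                 class = "zml_no_coincidence")
      warns <- c(warns, sprintf("rank %d skipped: %s", rk,
                                conditionMessage(st)))
      next
    }
    mh <- withCallingHandlers(
      predict_M(calib, st$D_bar, rk),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    M_hats <- c(M_hats, as.numeric(mh)); wts <- c(wts, st$k)
    used <- c(used, rk); last_st <- st
    if (isTRUE(attr(mh, "extrapolated")))
      warns <- c(warns, sprintf("extrapolated beyond calibration at rank %d", rk))
  }
  if (!length(M_hats))
    stop_zml("no rank produced a coincidence estimate",
             class = "zml_no_coincidence")
  M_hat <- sum(M_hats * wts) / sum(wts)
  if (round_support(M_hat) < 2 || M_hat < 2)
    stop_zml("estimated alphabet size M_hat=%.3f < 2", M_hat,
             class = "zml_estimate_error")
  capped <- FALSE
  if (!is.null(M_max) && M_hat > M_max) {
    M_hat <- M_max
    capped <- TRUE
    warns <- c(warns, sprintf("M_hat capped at the combinatorial bound %g",
                              M_max))
  }
  est_dist <- zml_model(M_hat, family, B = B)
  value <- model_entropy(est_dist)
  if (!capped && bias_correct && length(used) == 1L && last_st$k >= 3L) {
    corr <- delta_bias_correction(calib, family, B, used,
                                  last_st$D_bar,
                                  stats::var(last_st$distances) / last_st$k)
    # entropy bounds still apply after correction
    value <- min(max(value + corr, 0), log2(est_dist$support))
  }
  new_entropy_estimate(value = value,
                       method = paste0(family, "_coincidence"),
                       M_hat = M_hat, rank_used = used,
                       n_samples = seq$N, warnings = warns)
}

# Second-order delta-method bias correction: the estimate is a smooth(ish)
# concave map H(D_bar), so E[H(D_bar)] ~ H(E D_bar) + H''(D) var(D_bar)/2.
# H'' is taken by central differences at the scale of the sampling noise,
# which also averages across the small steps the rank-support rounding
# introduces.
delta_bias_correction <- function(calib, family, B, r, D_bar, v) {
  if (!is.finite(v) || v <= 0) return(0)
  h <- max(0.05, sqrt(v))
  if (D_bar - h <= 1) return(0)
  Hf <- function(d) {
    mh <- suppressWarnings(as.numeric(predict_M(calib, d, r)))
    model_entropy(zml_model(max(mh, 2), family, B = B))
  }
  H2 <- (Hf(D_bar + h) - 2 * Hf(D_bar) + Hf(D_bar - h)) / h^2
  if (!is.finite(H2)) return(0)
  -0.5 * H2 * v
}

#' Equiprobable coincidence entropy estimate
#'
#' The classical coincidence-counting baseline: assumes all symbols
#' equiprobable, so `H0 = log2(M_hat)` with `M_hat` inverted from the mean
#' coincidence distance.  Under equiprobability every symbol shares the
#' same gap law, so by default the mean distance pools the repeat gaps of
#' *all* observed symbols (`r = NULL`).  Pooling matters: picking the
#' empirically most frequent of many equally likely symbols selects, by
#' construction, a symbol whose in-window gaps ran short, which biases
#' `D_bar` low and the entropy with it.  Supplying a rank `r` restores the
#' single-symbol variant.
#'
#' @inheritParams estimate_entropy_model
#' @param r optional rank; `NULL` (default) pools all symbols' gaps.
#' @return an `entropy_estimate`.
#' @examples
#' set.seed(1)
#' x <- sample_iid_sequence(zml_model(20, "equiprobable"), 5000)
#' estimate_entropy_equiprobable(x)   # ~ log2(20)
#' @export
estimate_entropy_equiprobable <- function(seq, calib = NULL, r = NULL) {
  seq <- as_symbol_sequence(seq)
  calib <- calib %||% analytic_calibration("equiprobable")
  st <- if (is.null(r)) pooled_distance_stats(seq)
        else observed_distances(seq, rank_symbol(seq, r))
  warns <- character(0)
  mh <- withCallingHandlers(
    predict_M(calib, st$D_bar, r %||% 1L),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  M_hat <- as.numeric(mh)
  if (M_hat < 2)
    stop_zml("estimated alphabet size M_hat=%.3f < 2", M_hat,
             class = "zml_estimate_error")
  new_entropy_estimate(value = log2(M_hat),
                       method = "equiprobable_coincidence",
                       M_hat = M_hat, rank_used = r %||% NA_integer_,
                       n_samples = seq$N, warnings = warns)
}

# Mean coincidence distance pooled over every symbol with >= 2 occurrences.
pooled_distance_stats <- function(seq) {
  pos_by_sym <- split(seq_along(seq$tokens), as.character(seq$tokens))
  gap_sum <- 0; k <- 0L
  for (pos in pos_by_sym) {
    if (length(pos) >= 2L) {
      gap_sum <- gap_sum + (pos[length(pos)] - pos[1L]) + (length(pos) - 1L)
      k <- k + length(pos) - 1L
    }
  }
  if (k == 0L)
    stop_zml("no coincidence observed for any symbol",
             class = "zml_no_coincidence")
  list(D_bar = gap_sum / k, k = k)
}

as_counts <- function(x) {
  if (inherits(x, "symbol_sequence")) {
    syms <- unique(x$tokens)
    tabulate(match(x$tokens, syms), nbins = length(syms))
  } else if (is.numeric(x)) {
    if (any(x < 0) || any(!is.finite(x)))
      stop_zml("counts must be finite and non-negative",
               class = "zml_estimate_error")
    x
  } else {
    as_counts(as_symbol_sequence(x))
  }
}

#' Plug-in (maximum-likelihood) entropy estimate
#'
#' `H = -sum p_hat log2 p_hat` with `p_hat` the empirical frequencies and
#' the convention `0 log 0 = 0`.  Negatively biased when undersampled.
#'
#' @param x per-symbol occurrence counts, or a [symbol_sequence()] / string.
#' @return an `entropy_estimate`.
#' @examples
#' plugin_entropy(c(1, 1, 1, 1))$value  # 2 bits
#' plugin_entropy(c(2, 1, 1))$value     # 1.5 bits
#' @export
plugin_entropy <- function(x) {
  counts <- as_counts(x)
  N <- sum(counts)
  if (N <= 0) stop_zml("all counts are zero", class = "zml_estimate_error")
  new_entropy_estimate(value = entropy_bits(counts / N), method = "plugin",
                       n_samples = as.integer(N))
}

#' Miller-Madow bias-corrected entropy estimate
#'
#' Plug-in estimate plus the first-order bias correction
#' `(m_hat - 1) / (2 N ln 2)` bits, where `m_hat` is the number of symbols
#' with nonzero count and `N` the total count.
#'
#' @inheritParams plugin_entropy
#' @return an `entropy_estimate`.
#' @examples
#' miller_madow_entropy(c(1, 1))$value  # 1 + 1/(4 log(2))
#' @export
miller_madow_entropy <- function(x) {
  counts <- as_counts(x)
  N <- sum(counts)
  if (N <= 0) stop_zml("all counts are zero", class = "zml_estimate_error")
  m_hat <- sum(counts > 0)
  new_entropy_estimate(value = entropy_bits(counts / N) +
                         (m_hat - 1) / (2 * N * log(2)),
                       method = "miller_madow", n_samples = as.integer(N))
}

#' Perplexity of an entropy value
#'
#' `2^H`: the effective number of equiprobable alternatives.
#'
#' @param H entropy in bits (`>= 0`); an `entropy_estimate` is also
#'   accepted.
#' @return the perplexity.
#' @examples
#' perplexity(log2(30))  # 30
#' @export
perplexity <- function(H) {
  if (inherits(H, "entropy_estimate")) H <- H$value
  if (any(H < 0)) stop_zml("entropy must be non-negative",
                           class = "zml_estimate_error")
  2^H
}
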