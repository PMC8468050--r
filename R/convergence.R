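#' Rank gap of a distribution
#'
#' `Delta_r = P(r; M) - P(r+1; M)`, the probability gap separating a rank
#' from its successor.  Strictly positive for the ZML families; zero (an
#' error, since the sample bound is then undefined) for the equiprobable
#' distribution.
#'
#' @param dist a [zml_model()] (or probability vector sorted by rank).
#' @param r rank, `1 <= r <= M - 1`.
#' @return the gap `Delta_r`.
#' @examples
#' rank_gap(zml_model(30), 1)
#' @export
rank_gap <- function(dist, r) {
  if (inherits(dist, "zml_model")) {
    S <- dist$support
    if (!is_count(r) || r > S - 1)
      stop_zml("rank r must satisfy 1 <= r <= M-1 = %d (got %s)", S - 1,
               format(r), class = "zml_convergence_error")
    d <- prob_of_rank(dist, r) - prob_of_rank(dist, r + 1L)
    if (d <= 0)
      stop_zml("Delta_%d = 0: adjacent ranks are equiprobable, bound undefined",
               r, class = "zml_convergence_error")
    return(d)
  }
  p <- as.numeric(dist)
  M <- length(p)
  if (!is_count(r) || r > M - 1)
    stop_zml("rank r must satisfy 1 <= r <= M-1 = %d (got %s)", M - 1,
             format(r), class = "zml_convergence_error")
  d <- p[r] - p[r + 1]
  if (d <= 0)
    stop_zml("Delta_%d = 0: adjacent ranks are equiprobable, bound undefined",
             r, class = "zml_convergence_error")
  d
}

#' DKW confidence level for a sample size and precision
#'
#' The Dvoretzky-Kiefer-Wolfowitz guarantee: with `n_r` samples the
#' empirical probability deviates from its target by less than `epsilon_r`
#' with confidence `zeta' = 1 - 2 exp(-2 n_r epsilon_r^2)`.  Values below 0
#' (too few samples for any guarantee) are clamped to 0.
#'
#' @param n_r sample count (`> 0`).
#' @param epsilon_r precision (`> 0`).
#' @return the confidence level in `[0, 1)`.
#' @examples
#' dkw_confidence(log(2 / 0.05) / (2 * 0.01^2), 0.01)  # 0.95
#' @export
dkw_confidence <- function(n_r, epsilon_r) {
  if (any(n_r <= 0) || any(epsilon_r <= 0))
    stop_zml("n_r and epsilon_r must be positive",
             class = "zml_convergence_error")
  pmax(0, 1 - 2 * exp(-2 * n_r * epsilon_r^2))
}

#' Required sample count for a ranked probability (DKW planner)
#'
#' The number of samples sufficient to pin down the rank-`r` probability of
#' a ranked distribution to within its own rank gap, at confidence
#' `zeta'`:
#' `N_r = ceiling( 8 P(r) / Delta_r^2 * ln(2 / (1 - zeta')) )`.
#' The default precision target is `epsilon_r = Delta_r / 2`, the largest
#' precision that still separates adjacent ranks.
#'
#' @param dist a [zml_model()], or a bare rank-ordered probability vector.
#' @param r rank.
#' @param zeta_prime confidence level in (0, 1).
#' @return object of class `sample_bound`: list with `r`, `p_r`, `Delta_r`,
#'   `epsilon_r`, `zeta_prime`, `N_r`.
#' @examples
#' required_samples(zml_model(30), 1, 0.95)
#' @export
required_samples <- function(dist, r, zeta_prime = 0.95) {
  if (zeta_prime <= 0 || zeta_prime >= 1)
    stop_zml("zeta_prime must be in (0, 1)", class = "zml_convergence_error")
  Delta_r <- rank_gap(dist, r)
  is_model <- inherits(dist, "zml_model")
  p_r <- if (is_model) prob_of_rank(dist, r) else as.numeric(dist)[r]
  N_r <- ceiling(8 * p_r / Delta_r^2 * log(2 / (1 - zeta_prime)))
  structure(list(r = r, M = if (is_model) dist$M else length(dist),
                 family = if (is_model) dist$family else "custom",
                 p_r = p_r,
                 Delta_r = Delta_r, epsilon_r = Delta_r / 2,
                 zeta_prime = zeta_prime, N_r = N_r),
            class = "sample_bound")
}

#' @export
print.sample_bound <- function(x, ...) {
  cat(sprintf("<sample_bound> family=%s M=%g rank=%d\n", x$family, x$M, x$r))
  cat(sprintf("  p_r=%.5f Delta_r=%.5f eps_r=%.5f zeta'=%.3f -> N_r = %d\n",
              x$p_r, x$Delta_r, x$epsilon_r, x$zeta_prime, x$N_r))
  invisible(x)
}

#' Convergence factor of rank-1 estimation
#'
#' The ratio of the DKW sample requirement for the hardest (rank `M`)
#' symbol to that of the easiest (rank 1) symbol under the ZML law:
#' `lambda_f(M) = (P_M / Delta_(M-1)^2) / (P_1 / Delta_1^2)`, where
#' `Delta_(M-1)` is the gap separating the rank-`M` symbol from its
#' neighbour.  The `ln(2/(1 - zeta'))` factors cancel, so `lambda_f` is
#' independent of the confidence level.  Oriented so `lambda_f >= 1`:
#' it is the factor by which rank-1 coincidence estimation needs fewer
#' samples than an estimator that must resolve the rarest symbol, and it
#' exceeds two orders of magnitude for the alphabet sizes of typical
#' interest (20-40).
#'
#' @param M alphabet size (`>= 3` so both gaps exist; vectorized).
#' @param zeta_prime accepted and ignored (the factor is confidence-free).
#' @param family model family (default `"zml"`).
#' @param B continuation branching for `czml2`.
#' @return `lambda_f(M)`.
#' @examples
#' convergence_factor(30)
#' @export
convergence_factor <- function(M, zeta_prime = NULL, family = "zml",
                               B = NULL) {
  vapply(M, function(mm) {
    dist <- zml_model(mm, family, B = B)
    S <- dist$support
    if (S < 3)
      stop_zml("convergence factor needs M >= 3", class = "zml_convergence_error")
    d1 <- rank_gap(dist, 1)
    dM <- rank_gap(dist, S - 1L)
    (prob_of_rank(dist, S) / dM^2) / (prob_of_rank(dist, 1L) / d1^2)
  }, numeric(1))
}
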