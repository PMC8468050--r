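#' Analytic Zipf-Mandelbrot-Li rank-probability models
#'
#' Constructs the rank-probability distribution `P(r; M)` of a
#' Zipf-Mandelbrot-Li (ZML) family over ranks `r = 1..M`.  All parameters
#' are closed-form functions of the alphabet size `M` (and, for the second
#' constrained family, the continuation branching `B`):
#'
#' \describe{
#'   \item{`zml`}{the unconstrained law derived by Li from the random
#'     word-length model: `alpha = log(M+1)/log(M)`, `beta = M/(M+1)`.}
#'   \item{`czml1`}{the constrained law obtained by forbidding adjacent
#'     repeated letters in the underlying word space, which reduces the
#'     per-position branching from `M` to `M-1`:
#'     `alpha = log(M+1)/log(M-1)`, `beta = (M-1)/M`.  Requires `M >= 3`.}
#'   \item{`czml2`}{a further lexicon reduction in the style of
#'     continuation n-grams, with a free branching parameter
#'     `2 <= B <= M-1`: `alpha = log(M+1)/log(B)`, `beta = B/(B+1)`.
#'     Default `B = max(2, ceiling((M-1)/2))`; `B = M-1` recovers `czml1`.}
#'   \item{`equiprobable`}{the uniform distribution `p(r) = 1/M`, the
#'     baseline assumed by classical coincidence counting.}
#' }
#'
#' The unnormalized mass is `(r + beta)^(-alpha)`; a final normalization by
#' the direct sum `kappa` over ranks `1..round(M)` guarantees the
#' probabilities add to 1 regardless of closed-form scale constants.
#' Non-integer `M` is accepted (the coincidence estimator produces a
#' continuous alphabet-size estimate); the rank support is then
#' `1..round(M)` (half-up, minimum 2) while `alpha`, `beta` use `M` itself.
#'
#' @param M alphabet size, `>= 2` (`>= 3` for the constrained families).
#'   May be non-integer.
#' @param family one of `"zml"`, `"czml1"`, `"czml2"`, `"equiprobable"`.
#' @param B continuation branching for `czml2` (`2 <= B <= M-1`).
#' @return an object of class `zml_model`: a list with `family`, `M`,
#'   `support` (number of ranks), `branching`, `alpha`, `beta`, `gamma`
#'   (closed-form scale before normalization, `NA` for equiprobable),
#'   `kappa` (normalizing sum) and `p` (probability vector by rank).
#' @examples
#' m <- zml_model(30)
#' m$alpha                 # log(31)/log(30)
#' sum(m$p)                # 1
#' model_entropy(m)        # reference entropy in bits
#' zml_model(10, "czml2")  # default B = 5
#' @seealso [model_entropy()], [alpha_ratio_curve()], [word_space()],
#'   [sample_iid_sequence()]
#' @export
zml_model <- function(M, family = c("zml", "czml1", "czml2", "equiprobable"),
                      B = NULL) {
  family <- match.arg(family)
  if (!is.numeric(M) || length(M) != 1L || !is.finite(M))
    stop_zml("M must be a single finite number", class = "zml_model_error")
  if (M < 2)
    stop_zml("M must be >= 2 (got %g)", M, class = "zml_model_error")
  if (family %in% c("czml1", "czml2") && M < 3)
    stop_zml("family '%s' needs M >= 3 for a nondegenerate branching",
             family, class = "zml_model_error")
  support <- round_support(M)

  if (family == "equiprobable") {
    branching <- M
    alpha <- NA_real_; beta <- NA_real_; gamma <- NA_real_
    kappa <- support
    p <- if (support <= .zml_dense_support) rep(1 / support, support)
  } else {
    branching <- switch(family,
      zml = M,
      czml1 = M - 1,
      czml2 = {
        B <- B %||% max(2, ceiling((M - 1) / 2))
        if (!is_count(B, min = 2) || B > M - 1)
          stop_zml("czml2 branching B must satisfy 2 <= B <= M-1 (got %s)",
                   format(B), class = "zml_model_error")
        B
      })
    alpha <- log(M + 1) / log(branching)
    beta <- branching / (branching + 1)
    # Li's closed-form scale for the word-length construction; informative
    # only -- kappa normalization below is what fixes the pmf.
    gamma <- branching^(alpha - 1) / (branching - 1)^alpha
    if (support <= .zml_dense_support) {
      f <- (seq_len(support) + beta)^(-alpha)
      kappa <- sum(f)
      p <- f / kappa
      log_weight_sum <- NULL
    } else {
      sums <- zml_rank_sums(support, alpha, beta)
      kappa <- sums$kappa
      p <- NULL
      log_weight_sum <- sums$T
    }
  }
  structure(list(family = family, M = M, support = support,
                 branching = branching, B = if (family == "czml2") B else NULL,
                 alpha = alpha, beta = beta, gamma = gamma, kappa = kappa,
                 p = p,
                 log_weight_sum = if (family != "equiprobable" &&
                                      is.null(p)) log_weight_sum),
            class = "zml_model")
}

# Beyond this support size the pmf vector is not materialized; rank sums
# are evaluated analytically instead (the coincidence estimator can return
# very large continuous alphabet-size estimates for sparse n-gram streams).
.zml_dense_support <- 3e5

# kappa = sum_{r=1}^{S} (r+beta)^-alpha and the log-weighted sum
# T = sum (r+beta)^-alpha log(r+beta).  Direct summation for moderate S;
# for large S the head is summed directly and the tail taken as a midpoint
# integral, with the exponent eps = alpha - 1 handled by series when tiny.
zml_rank_sums <- function(S, alpha, beta) {
  if (S <= .zml_dense_support) {
    u <- seq_len(S) + beta
    w <- u^(-alpha)
    return(list(kappa = sum(w), T = sum(w * log(u))))
  }
  head_n <- 1000L
  u <- seq_len(head_n) + beta
  w <- u^(-alpha)
  eps <- alpha - 1
  ta <- log(head_n + 0.5 + beta); tb <- log(S + 0.5 + beta)
  # substituting t = log(u): int u^-alpha du = int exp(-eps t) dt,
  # int u^-alpha log(u) du = int t exp(-eps t) dt
  I1 <- if (abs(eps) * tb < 1e-4) {
    (tb - ta) - eps * (tb^2 - ta^2) / 2 + eps^2 * (tb^3 - ta^3) / 6
  } else (exp(-eps * ta) - exp(-eps * tb)) / eps
  I2 <- if (abs(eps) * tb < 1e-4) {
    (tb^2 - ta^2) / 2 - eps * (tb^3 - ta^3) / 3 + eps^2 * (tb^4 - ta^4) / 8
  } else {
    (exp(-eps * ta) * (ta / eps + 1 / eps^2) -
       exp(-eps * tb) * (tb / eps + 1 / eps^2))
  }
  list(kappa = sum(w) + I1, T = sum(w * log(u)) + I2)
}

# P(r; M) for a possibly large-support model, without materializing p.
prob_of_rank <- function(dist, r) {
  if (r > dist$support)
    stop_zml("rank %s exceeds the model support %s", format(r), format(dist$support),
             class = "zml_model_error")
  if (!is.null(dist$p)) return(dist$p[r])
  if (dist$family == "equiprobable") return(1 / dist$support)
  (r + dist$beta)^(-dist$alpha) / dist$kappa
}

#' @export
print.zml_model <- function(x, ...) {
  cat(sprintf("<zml_model> family=%s M=%g (support %s ranks)\n",
              x$family, x$M, format(x$support)))
  if (!is.na(x$alpha))
    cat(sprintf("  alpha=%.5f beta=%.5f branching=%g kappa=%.6f\n",
                x$alpha, x$beta, x$branching, x$kappa))
  cat(sprintf("  p(1)=%.5g p(%s)=%.5g  H=%.4f bits\n",
              prob_of_rank(x, 1L), format(x$support), prob_of_rank(x, x$support),
              model_entropy(x)))
  invisible(x)
}

#' @export
as.data.frame.zml_model <- function(x, ...) {
  if (is.null(x$p))
    stop_zml("support %s too large to materialize the pmf", format(x$support),
             class = "zml_model_error")
  data.frame(rank = seq_len(x$support), p = x$p)
}

#' @export
plot.zml_model <- function(x, ..., log = "xy") {
  graphics::plot(seq_len(x$support), x$p, log = log, type = "b",
                 xlab = "rank", ylab = "probability",
                 main = sprintf("%s, M = %g", x$family, x$M), ...)
  invisible(x)
}

#' Model entropy of a rank distribution, in bits
#'
#' The Shannon entropy `-sum p(r) log2 p(r)` of the model's own
#' probabilities; used as the "true entropy" reference in simulations.
#'
#' @param dist a [zml_model()] (or bare probability vector).
#' @return entropy in bits.
#' @examples
#' model_entropy(zml_model(30, "equiprobable"))  # log2(30)
#' @export
model_entropy <- function(dist) {
  if (!inherits(dist, "zml_model")) return(entropy_bits(dist))
  if (!is.null(dist$p)) return(entropy_bits(dist$p))
  # large-support model: -sum p log2 p = (alpha * T/kappa + log kappa)/log 2
  if (dist$family == "equiprobable") return(log2(dist$support))
  (dist$alpha * dist$log_weight_sum / dist$kappa + log(dist$kappa)) / log(2)
}

#' Constraint effect on the ZML exponent
#'
#' Ratio of the constrained-model exponent to the unconstrained exponent,
#' `alpha_czml1 / alpha_zml = log(M) / log(M-1)`, per alphabet size.  The
#' ratio exceeds 1, is largest for small `M`, and tends to 1 as `M` grows,
#' i.e. the no-adjacent-repeat constraint matters most for small alphabets.
#'
#' @param M_values integer vector of alphabet sizes, all `>= 3`.
#' @return `data.frame` with columns `M` and `ratio`.
#' @examples
#' alpha_ratio_curve(3:12)
#' @export
alpha_ratio_curve <- function(M_values) {
  if (any(M_values < 3))
    stop_zml("all alphabet sizes must be >= 3", class = "zml_model_error")
  ratio <- vapply(M_values, function(M) {
    zml_model(M, "czml1")$alpha / zml_model(M, "zml")$alpha
  }, numeric(1))
  data.frame(M = M_values, ratio = ratio)
}

#' Word-space counts and per-word probabilities
#'
#' The word-length model behind the ZML law: words of length `L` over an
#' alphabet of `M` letters (plus a word-terminating space, giving the
#' `M + 1` in the probability decay).  The admissible-word count is
#' `N_w(L) = M * branching^(L-1)` -- `M^L` unconstrained, `M (M-1)^(L-1)`
#' with no adjacent repeats, `M B^(L-1)` for continuation branching `B`.
#' Each admissible word of length `L` has probability
#' `p_i(L) = gamma_w (M+1)^-(L+2)` where `gamma_w` solves the
#' geometric-series conservation `sum_L N_w(L) p_i(L) = 1`, giving
#' `gamma_w = (M+1)^2 (M+1-branching) / M` (`(M+1)^2 / M` unconstrained).
#'
#' @param M alphabet size (`>= 2`).
#' @param L word length (`>= 1`).
#' @param family `"zml"`, `"czml1"` or `"czml2"`.
#' @param B continuation branching for `czml2`.
#' @return list with `M`, `L`, `branching`, `N_w` (admissible words of
#'   length `L`), `p_word` (probability of each), `gamma_w`.
#' @examples
#' word_space(26, 5)$N_w            # 26^5 = 11881376
#' word_space(26, 2)$N_w            # the 676 two-letter bigrams
#' word_space(3, 2, "czml1")$N_w    # 6 of the 9 bigrams lack a double letter
#' @export
word_space <- function(M, L, family = c("zml", "czml1", "czml2"), B = NULL) {
  family <- match.arg(family)
  if (!is_count(M, 2)) stop_zml("M must be an integer >= 2",
                                class = "zml_model_error")
  if (!is_count(L, 1)) stop_zml("L must be an integer >= 1",
                                class = "zml_model_error")
  branching <- switch(family,
    zml = M,
    czml1 = M - 1,
    czml2 = {
      B <- B %||% max(2, ceiling((M - 1) / 2))
      if (!is_count(B, 2) || B > M - 1)
        stop_zml("czml2 branching B must satisfy 2 <= B <= M-1",
                 class = "zml_model_error")
      B
    })
  if (family != "zml" && M < 3)
    stop_zml("constrained families need M >= 3", class = "zml_model_error")
  gamma_w <- (M + 1)^2 * (M + 1 - branching) / M
  list(M = M, L = L, family = family, branching = branching,
       N_w = M * branching^(L - 1),
       p_word = gamma_w * (M + 1)^(-(L + 2)),
       gamma_w = gamma_w)
}

#' Word-space probability conservation check
#'
#' Numerically verifies `sum_L N_w(L) p_i(L) = 1` by truncated summation,
#' returning the partial sum (the geometric tail beyond `L_max` is bounded
#' by the first neglected term over `1 - branching/(M+1)`).
#'
#' @inheritParams word_space
#' @param L_max truncation length (chosen so the tail is `< 1e-12` for the
#'   default).
#' @return the truncated series sum.
#' @keywords internal
#' @export
word_space_series <- function(M, family = c("zml", "czml1", "czml2"),
                              B = NULL, L_max = NULL) {
  family <- match.arg(family)
  ws1 <- word_space(M, 1, family, B)
  q <- ws1$branching / (M + 1)
  L_max <- L_max %||% max(50, ceiling(log(1e-15) / log(q)))
  L <- seq_len(L_max)
  # N_w(L) overflows double for large L; assemble each term in log space
  log_terms <- log(M) + (L - 1) * log(ws1$branching) + log(ws1$gamma_w) -
    (L + 2) * log(M + 1)
  sum(exp(log_terms))
}
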