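# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths (direct summation, exhaustive enumeration,
# closed forms) so that agreement is evidence, not tautology.

# ZML-family pmf from the closed-form parameters, by direct summation.
oracle_zml_pmf <- function(M, branching = M) {
  alpha <- log(M + 1) / log(branching)
  beta <- branching / (branching + 1)
  r <- seq_len(round(M))
  f <- (r + beta)^(-alpha)
  f / sum(f)
}

oracle_entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Exact first-coincidence pmf by exhaustive enumeration over all draw
# sequences (feasible for M <= 4, n_max <= 6): grow every repeat-free
# sequence one draw at a time and collect the probability mass that
# repeats at each draw.
oracle_first_coincidence <- function(p, n_max) {
  M <- length(p)
  alive_seq <- matrix(seq_len(M), ncol = 1)   # repeat-free so far
  alive_w <- p
  probs <- numeric(n_max - 1L)
  for (n in 2:n_max) {
    k <- nrow(alive_seq)
    if (k == 0) break
    ns <- matrix(0L, k * M, n); nw <- numeric(k * M); hit <- logical(k * M)
    row <- 0L
    for (i in seq_len(k)) for (s in seq_len(M)) {
      row <- row + 1L
      prev <- alive_seq[i, ]
      ns[row, ] <- c(prev, s)
      nw[row] <- alive_w[i] * p[s]
      hit[row] <- s %in% prev
    }
    probs[n - 1L] <- sum(nw[hit])
    keep <- which(!hit)
    alive_seq <- ns[keep, , drop = FALSE]
    alive_w <- nw[keep]
  }
  data.frame(n = 2:n_max, f = probs)
}

# Equiprobable survival by the direct product formula (birthday problem).
oracle_birthday_expectation <- function(M) {
  surv <- cumprod(c(1, 1 - (seq_len(M) - 1) / M))  # survival after 0..M draws
  sum(surv)  # E[n] = sum_{n>=0} P(first repeat > n)
}

# Words of length L over M letters with no adjacent equal letters, counted
# by brute-force enumeration.
oracle_count_no_adjacent <- function(M, L) {
  if (L == 1) return(M)
  words <- as.matrix(expand.grid(rep(list(seq_len(M)), L)))
  sum(apply(words, 1, function(w) all(diff(w) != 0)))
}

# Stationary distribution of a transition matrix.
oracle_stationary <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# Analytic conditional entropy rate of a first-order Markov chain, bits.
oracle_markov_rate <- function(P) {
  pi <- oracle_stationary(P)
  -sum(vapply(seq_len(nrow(P)), function(i)
    pi[i] * sum(ifelse(P[i, ] > 0, P[i, ] * log2(P[i, ]), 0)), numeric(1)))
}

# First-order Markov chain simulation (transition CDF lookup per step).
sim_markov_chain <- function(P, n, seed) {
  set.seed(seed)
  cdf <- t(apply(P, 1, cumsum))
  x <- integer(n)
  x[1] <- sample.int(nrow(P), 1)
  u <- stats::runif(n)
  for (t in 2:n) x[t] <- findInterval(u[t], cdf[x[t - 1L], ]) + 1L
  x
}

# A hand-built power-law calibration object for forced-M_hat scenarios.
make_power_calibration <- function(a, b, c, family = "equiprobable",
                                   ranks = 1L, valid = c(1, 1e6)) {
  structure(list(fit = "power", family = family, B = NULL, ranks = ranks,
                 models = stats::setNames(lapply(ranks, function(r)
                   list(a = a, b = b, c = c, valid_range = valid,
                        max_rel_resid = 0)), as.character(ranks)),
                 metadata = list(m_grid = NULL, trials = 0, samples = 0,
                                 seed = NA)),
            class = "zml_calibration")
}

# A sequence whose rank-1 symbol repeats at exact distance D (gap D-1),
# padded with distinct rare filler symbols so the target stays rank 1.
make_fixed_distance_sequence <- function(D, repeats = 12) {
  gap <- D - 1
  fillers <- paste0("f", seq_len(2 * gap))
  toks <- character(0)
  fi <- 0
  for (i in seq_len(repeats)) {
    toks <- c(toks, "x")
    if (i < repeats) for (j in seq_len(gap - 1)) {
      fi <- fi %% length(fillers) + 1
      toks <- c(toks, fillers[fi])
    }
  }
  toks
}
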