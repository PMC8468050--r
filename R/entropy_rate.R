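#' Normalize raw text for character-level entropy analysis
#'
#' Lowercases, removes every character outside `[a-z0-9 ]`, collapses runs
#' of spaces and strips leading/trailing spaces.  Idempotent.
#'
#' @param text character vector (collapsed with newlines treated as
#'   spaces).
#' @return a single normalized string.
#' @examples
#' preprocess_text("Hello, World!")  # "hello world"
#' @export
preprocess_text <- function(text) {
  x <- tolower(paste(text, collapse = " "))
  x <- gsub("[^a-z0-9 ]+", "", x)
  x <- gsub(" +", " ", x)
  sub("^ ", "", sub(" $", "", x))
}

#' Overlapping n-gram stream of a symbol sequence
#'
#' Slides a length-`n` window over the sequence.  With
#' `within_words = TRUE` any n-gram containing a space is dropped, so only
#' n-grams lying inside words survive.
#'
#' @param seq a [symbol_sequence()] (or string / token vector).
#' @param n block size (`>= 1`).
#' @param within_words drop n-grams that straddle a word boundary (space).
#' @return character vector of n-gram tokens (possibly empty, with a
#'   warning, when no n-gram fits inside a word).
#' @examples
#' ngram_stream("ab cd", 2)                        # "ab" "cd"
#' ngram_stream("ab cd", 2, within_words = FALSE)  # includes "b " and " c"
#' @export
ngram_stream <- function(seq, n, within_words = TRUE) {
  seq <- as_symbol_sequence(seq)
  if (!is_count(n, 1)) stop_zml("n must be a positive integer",
                                class = "zml_rate_error")
  toks <- as.character(seq$tokens)
  if (n == 1) {
    out <- if (within_words) toks[toks != " "] else toks
    return(out)
  }
  if (length(toks) < n) return(character(0))
  idx <- seq_len(length(toks) - n + 1L)
  grams <- vapply(seq_len(n), function(k) toks[idx + k - 1L],
                  character(length(idx)))
  if (length(idx) == 1L) grams <- matrix(grams, nrow = 1)
  has_space <- rowSums(grams == " ") > 0
  out <- do.call(paste0, as.data.frame(grams, stringsAsFactors = FALSE))
  if (within_words) {
    out <- out[!has_space]
    if (!length(out))
      warning(sprintf("no n-gram of size %d fits within a word", n))
  }
  out
}

#' Block entropy of a sequence at block size n
#'
#' Treats each distinct (overlapping) n-gram as one symbol of a derived
#' alphabet and applies the chosen unigram estimator to the n-gram stream.
#'
#' @inheritParams ngram_stream
#' @param method `"plugin"`, `"miller_madow"` or `"model"` (model-based
#'   coincidence estimation on the n-gram alphabet).
#' @param calib calibration for the model method (default analytic).
#' @param family model family for the model method.
#' @param B continuation branching for `czml2`.
#' @return block entropy `H_N` in bits (attribute `n_grams_observed` gives
#'   the number of distinct n-grams).
#' @examples
#' block_entropy(strrep("ab", 50), 2, within_words = FALSE)  # 1 bit
#' @export
block_entropy <- function(seq, n, method = c("plugin", "miller_madow",
                                             "model"),
                          calib = NULL, family = "czml1", B = NULL,
                          within_words = TRUE) {
  method <- match.arg(method)
  grams <- ngram_stream(seq, n, within_words = within_words)
  if (!length(grams))
    stop_zml("empty n-gram stream at n=%d", n, class = "zml_rate_error")
  gseq <- symbol_sequence(grams)
  H <- switch(method,
    plugin = plugin_entropy(gseq)$value,
    miller_madow = miller_madow_entropy(gseq)$value,
    model = {
      # the derived alphabet cannot exceed the family's admissible word
      # count N_w(M1, n) over the observed base alphabet
      base <- as.character(seq$tokens)
      if (within_words) base <- base[base != " "]
      M1 <- length(unique(base))
      cap <- if (n >= 2 && M1 >= 3)
        word_space(M1, n, family = family, B = B)$N_w
      suppressWarnings(
        estimate_entropy_model(gseq, calib = calib, family = family,
                               B = B, M_max = cap)$value)
    })
  structure(H, n_grams_observed = length(unique(grams)),
            stream_len = length(grams))
}

#' Block and conditional n-gram entropies; entropy-rate estimate
#'
#' Computes block entropies `H_1 .. H_Nmax` on overlapping n-gram streams
#' and the conditional rates `h_N = H_N - H_(N-1)` (with `h_1 = H_1`),
#' which for a stationary source decrease towards the entropy rate.  The
#' reported rate is `h_N` at the largest *reliable* block size:
#' for the plug-in and Miller-Madow estimators a block is reliable while
#' the number of distinct n-grams stays below `max_distinct_frac` of the
#' stream length (beyond that the empirical n-gram distribution is too
#' sparse to trust); for the model-based estimator the requirement is the
#' one its theory implies -- at least `min_coincidences` repeat gaps of the
#' rank-1 n-gram -- which is satisfied much deeper into the block hierarchy.
#' That asymmetry is the practical advantage of the coincidence method for
#' rate estimation: it can report `h_N` at block sizes the plug-in
#' estimator cannot reach reliably.
#'
#' @inheritParams block_entropy
#' @param N_max largest block size.
#' @param max_distinct_frac reliability cap for plugin/Miller-Madow.
#' @param min_coincidences reliability floor for the model method.
#' @return object of class `block_entropy_series`: a `data.frame` with
#'   columns `N`, `H_N`, `h_N`, `n_grams_observed`, `stream_len`,
#'   `reliable`; attributes `rate` (the reported bits/symbol), `rate_N`
#'   (the block size it came from) and `method`.
#' @examples
#' set.seed(1)
#' x <- paste(sample(c("a", "b"), 2000, replace = TRUE), collapse = "")
#' entropy_rate(x, N_max = 3, within_words = FALSE)  # rate ~ 1 bit/symbol
#' @export
entropy_rate <- function(seq, N_max = 4,
                         method = c("plugin", "miller_madow", "model"),
                         calib = NULL, family = "czml1", B = NULL,
                         within_words = TRUE,
                         max_distinct_frac = 0.1, min_coincidences = 30) {
  method <- match.arg(method)
  seq <- as_symbol_sequence(seq)
  if (seq$N == 0) stop_zml("empty sequence", class = "zml_rate_error")
  if (!is_count(N_max, 1)) stop_zml("N_max must be >= 1",
                                    class = "zml_rate_error")
  rows <- vector("list", N_max)
  H_prev <- 0
  for (n in seq_len(N_max)) {
    grams <- suppressWarnings(ngram_stream(seq, n,
                                           within_words = within_words))
    if (!length(grams)) {
      rows[[n]] <- data.frame(N = n, H_N = NA, h_N = NA,
                              n_grams_observed = 0, stream_len = 0,
                              reliable = FALSE)
      next
    }
    gseq <- symbol_sequence(grams)
    distinct <- length(unique(grams))
    reliable <- if (method == "model") {
      top <- rank_symbol(gseq, 1)
      k <- sum(gseq$tokens == top) - 1L
      k >= min_coincidences
    } else {
      distinct <= max_distinct_frac * length(grams)
    }
    H_n <- tryCatch(
      as.numeric(block_entropy(seq, n, method = method, calib = calib,
                               family = family, B = B,
                               within_words = within_words)),
      zml_error = function(e) NA_real_)
    if (is.na(H_n)) reliable <- FALSE
    rows[[n]] <- data.frame(N = n, H_N = H_n,
                            h_N = if (n == 1) H_n else H_n - H_prev,
                            n_grams_observed = distinct,
                            stream_len = length(grams),
                            reliable = reliable)
    if (!is.na(H_n)) H_prev <- H_n
  }
  out <- do.call(rbind, rows)
  rel <- out$N[out$reliable & !is.na(out$h_N)]
  rate_N <- if (length(rel)) max(rel) else 1L
  class(out) <- c("block_entropy_series", "data.frame")
  attr(out, "rate") <- out$h_N[out$N == rate_N]
  attr(out, "rate_N") <- rate_N
  attr(out, "method") <- method
  out
}

#' @export
print.block_entropy_series <- function(x, ...) {
  cat(sprintf("<block_entropy_series> method=%s  rate = %.4f bits/symbol (at N=%d)\n",
              attr(x, "method"), attr(x, "rate"), attr(x, "rate_N")))
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

#' @export
plot.block_entropy_series <- function(x, ...) {
  graphics::plot(x$N, x$h_N, type = "b", xlab = "block size N",
                 ylab = "h_N (bits/symbol)", ...)
  graphics::abline(h = attr(x, "rate"), lty = 2)
  invisible(x)
}

#' Joint probability of a block under a Markov conditional table
#'
#' Multiplies the chain-rule conditionals
#' `p(s_i | s_(i-k) .. s_(i-1))` with the context capped at the table's
#' order.  The table is a list with elements `order` (integer `>= 0`),
#' `start` (named probability vector used where the context is empty:
#' every position for an order-0 table, the first position otherwise) and
#' `cond`, a named list mapping a context string (preceding symbols pasted
#' together) to a named probability vector over next symbols.  A missing
#' conditional signals an unseen context and is an error; a present
#' conditional of value 0 yields probability 0.
#'
#' @param conditional_table the table described above.
#' @param s symbol block (character vector or single string of
#'   single-character symbols).
#' @return the joint probability of the block.
#' @examples
#' iid <- list(order = 0, start = c(a = 0.5, b = 0.5))
#' markov_joint_probability(iid, "ab")  # 0.25
#' chain <- list(order = 1, start = c(a = 1), cond = list(a = c(b = 1)))
#' markov_joint_probability(chain, "ab")  # 1
#' @export
markov_joint_probability <- function(conditional_table, s) {
  if (is.character(s) && length(s) == 1L)
    s <- strsplit(s, "", fixed = TRUE)[[1]]
  ord <- conditional_table$order
  cond <- conditional_table$cond
  prob <- 1
  for (i in seq_along(s)) {
    ctx_len <- min(i - 1L, ord)
    ctx <- if (ctx_len == 0) "" else
      paste(s[(i - ctx_len):(i - 1L)], collapse = "")
    pv <- if (ctx_len == 0) {
      conditional_table$start %||%
        (if (length(cond) == 1L && is.null(names(cond))) cond[[1L]])
    } else {
      idx <- match(ctx, names(cond))
      if (!is.na(idx)) cond[[idx]] else NULL
    }
    if (is.null(pv) || !(s[i] %in% names(pv)))
      stop_zml("missing conditional p(%s | '%s'): unseen context",
               s[i], ctx, class = "zml_markov_error")
    prob <- prob * pv[[s[i]]]
  }
  unname(prob)
}
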