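#' Declare a symbol alphabet
#'
#' An alphabet is an ordered set of `M >= 2` distinct tokens over which
#' symbol sequences are defined.  Built-in kinds cover the character-level
#' DNA (`M = 4`) and protein (`M = 20`) alphabets; any character vector of
#' tokens defines a custom alphabet.
#'
#' @param symbols character vector of distinct tokens, or one of the
#'   shorthand kinds `"dna"`, `"protein"`.
#' @param kind one of `"text"`, `"dna"`, `"protein"`, `"custom"`.  Inferred
#'   when `symbols` is a shorthand.
#' @return an object of class `alphabet_spec` with fields `symbols`, `M`,
#'   `kind`.
#' @examples
#' alphabet_spec("dna")
#' alphabet_spec(c("a", "b", "c"), kind = "text")
#' @export
alphabet_spec <- function(symbols, kind = NULL) {
  if (length(symbols) == 1L && symbols %in% c("dna", "protein")) {
    kind <- symbols
    symbols <- switch(symbols,
      dna = c("A", "C", "G", "T"),
      protein = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))
  }
  symbols <- as.character(symbols)
  if (anyDuplicated(symbols))
    stop_zml("alphabet symbols must be distinct", class = "zml_alphabet_error")
  if (length(symbols) < 2L)
    stop_zml("an alphabet needs at least 2 symbols (got %d)", length(symbols),
             class = "zml_alphabet_error")
  kind <- match.arg(kind %||% "custom", c("text", "dna", "protein", "custom"))
  structure(list(symbols = symbols, M = length(symbols), kind = kind),
            class = "alphabet_spec")
}

#' @export
print.alphabet_spec <- function(x, ...) {
  shown <- if (x$M > 12) paste(c(x$symbols[1:12], "..."), collapse = " ")
           else paste(x$symbols, collapse = " ")
  cat(sprintf("<alphabet_spec> kind=%s M=%d: %s\n", x$kind, x$M, shown))
  invisible(x)
}

#' Construct a symbol sequence over an alphabet
#'
#' @param tokens vector of tokens (character, or integer rank labels).
#' @param alphabet an [alphabet_spec()]; inferred from the distinct tokens
#'   when omitted.
#' @param id optional identifier (e.g. a FASTA record id).
#' @param validate check every token against the alphabet (skip for large
#'   machine-generated streams that are correct by construction).
#' @return an object of class `symbol_sequence` with fields `tokens`, `N`,
#'   `alphabet`, `id`.
#' @examples
#' symbol_sequence(strsplit("abcdabc", "")[[1]])
#' @export
symbol_sequence <- function(tokens, alphabet = NULL, id = NULL,
                            validate = TRUE) {
  if (is.null(alphabet)) {
    syms <- as.character(unique(tokens))
    if (length(syms) < 2L)   # pad degenerate alphabets to the minimum size
      syms <- c(syms,
                setdiff(paste0(".pad", 1:2), syms)[seq_len(2 - length(syms))])
    alphabet <- alphabet_spec(syms)
    validate <- FALSE
  }
  if (validate && length(tokens)) {
    ok <- as.character(tokens) %in% alphabet$symbols
    if (!all(ok))
      stop_zml("token(s) outside the alphabet: %s",
               paste(utils::head(unique(tokens[!ok]), 5), collapse = ", "),
               class = "zml_alphabet_error")
  }
  structure(list(tokens = tokens, N = length(tokens), alphabet = alphabet,
                 id = id),
            class = "symbol_sequence")
}

#' @export
print.symbol_sequence <- function(x, ...) {
  prev <- paste(utils::head(x$tokens, 20), collapse = "")
  if (x$N > 20) prev <- paste0(prev, "...")
  cat(sprintf("<symbol_sequence> N=%d over M=%d symbols%s\n  %s\n",
              x$N, x$alphabet$M,
              if (is.null(x$id)) "" else paste0(" id=", x$id), prev))
  invisible(x)
}

#' @export
length.symbol_sequence <- function(x) x$N

as_symbol_sequence <- function(x) {
  if (inherits(x, "symbol_sequence")) return(x)
  if (is.character(x) && length(x) == 1L)
    return(symbol_sequence(strsplit(x, "", fixed = TRUE)[[1]]))
  symbol_sequence(x)
}
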