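#' Read a plain-text corpus as a character-level symbol sequence
#'
#' The symbol unit is the character; a word-level tokenizer is available via
#' `tokenizer = "word"` for corpora where the word is the natural symbol.
#'
#' @param path path to a UTF-8 text file.
#' @param alphabet_policy `"infer"` (alphabet = distinct observed tokens) or
#'   `"fixed"` (every token must be in `alphabet`, otherwise an error).
#' @param alphabet an [alphabet_spec()], required for `"fixed"`.
#' @param tokenizer `"character"` (default) or `"word"` (whitespace split).
#' @return a [symbol_sequence()].
#' @examples
#' f <- tempfile(); writeLines("abcdabc", f)
#' read_text_corpus(f)
#' @export
read_text_corpus <- function(path,
                             alphabet_policy = c("infer", "fixed"),
                             alphabet = NULL,
                             tokenizer = c("character", "word")) {
  alphabet_policy <- match.arg(alphabet_policy)
  tokenizer <- match.arg(tokenizer)
  if (!file.exists(path))
    stop_zml("cannot read corpus: no such file '%s'", path,
             class = "zml_io_error")
  txt <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
               collapse = "\n")
  tokens <- if (tokenizer == "character") {
    strsplit(txt, "", fixed = TRUE)[[1]]
  } else {
    toks <- strsplit(txt, "[[:space:]]+")[[1]]
    toks[nzchar(toks)]
  }
  if (alphabet_policy == "fixed") {
    if (is.null(alphabet))
      stop_zml("alphabet_policy = 'fixed' requires an alphabet",
               class = "zml_io_error")
    symbol_sequence(tokens, alphabet = alphabet, validate = TRUE)
  } else {
    if (length(tokens) == 0)
      return(symbol_sequence(character(0),
                             alphabet = alphabet_spec(c("a", "b")),
                             validate = FALSE))
    symbol_sequence(tokens)
  }
}

#' Read FASTA records as symbol sequences
#'
#' Residues are matched case-insensitively and uppercased.  In strict mode
#' (default) a residue outside the alphabet is an error -- silent dropping
#' would hide alphabet mis-specification, which is fatal to an estimator of
#' the alphabet size.  In lenient mode unknown residues are dropped with a
#' warning.
#'
#' @param path path to a FASTA file (multi-record supported).
#' @param alphabet an [alphabet_spec()]; defaults to the DNA alphabet.
#' @param strict error on unknown residues (default `TRUE`).
#' @return a list of [symbol_sequence()], record ids preserved in `$id`.
#' @examples
#' f <- system.file("extdata", "example_dna.fasta", package = "zmlentropy")
#' read_fasta(f)
#' @export
read_fasta <- function(path, alphabet = alphabet_spec("dna"), strict = TRUE) {
  if (!file.exists(path))
    stop_zml("cannot read FASTA: no such file '%s'", path,
             class = "zml_io_error")
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0)
    stop_zml("FASTA file '%s' contains no records", path,
             class = "zml_io_error")
  lapply(seq_along(recs), function(i) {
    toks <- toupper(as.character(recs[[i]]))
    if (length(toks) == 0)
      stop_zml("FASTA record '%s' is empty", names(recs)[i],
               class = "zml_io_error")
    bad <- !(toks %in% alphabet$symbols)
    if (any(bad)) {
      if (strict)
        stop_zml("record '%s': residue(s) outside alphabet: %s",
                 names(recs)[i],
                 paste(unique(toks[bad]), collapse = ", "),
                 class = "zml_io_error")
      warning(sprintf("record '%s': dropping %d residue(s) outside alphabet",
                      names(recs)[i], sum(bad)))
      toks <- toks[!bad]
    }
    symbol_sequence(toks, alphabet = alphabet, id = names(recs)[i],
                    validate = FALSE)
  })
}

#' Read a ranked frequency table
#'
#' Expects a TSV with columns `token` and `count` (header optional when the
#' columns are in that order).  Rows are sorted by descending count,
#' probabilities normalized to sum to 1, and ranks `1..K` assigned with ties
#' broken by lexicographic token order so output is deterministic.
#'
#' @param path path to the TSV file.
#' @param case_fold lowercase tokens before ranking (and merge counts of
#'   tokens that collide after folding).
#' @return a `data.frame` with columns `rank`, `token`, `count`, `p`.
#' @export
read_rank_table <- function(path, case_fold = FALSE) {
  if (!file.exists(path))
    stop_zml("cannot read rank table: no such file '%s'", path,
             class = "zml_io_error")
  first <- readLines(path, n = 1L)
  has_header <- grepl("token", first, ignore.case = TRUE)
  tab <- utils::read.delim(path, header = has_header,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    stop_zml("rank table needs token and count columns",
             class = "zml_io_error")
  names(tab)[1:2] <- c("token", "count")
  tab$token <- as.character(tab$token)
  if (case_fold) {
    tab$token <- tolower(tab$token)
    tab <- stats::aggregate(count ~ token, data = tab, FUN = sum)
  }
  if (any(!is.finite(tab$count)) || any(tab$count < 0))
    stop_zml("rank table counts must be non-negative numbers",
             class = "zml_io_error")
  if (anyDuplicated(tab$token))
    stop_zml("duplicate token(s) in rank table: %s",
             paste(utils::head(tab$token[duplicated(tab$token)], 5),
                   collapse = ", "),
             class = "zml_io_error")
  ord <- order(-tab$count, tab$token)
  tab <- tab[ord, c("token", "count"), drop = FALSE]
  total <- sum(tab$count)
  if (total <= 0)
    stop_zml("rank table has zero total count", class = "zml_io_error")
  data.frame(rank = seq_len(nrow(tab)), token = tab$token,
             count = tab$count, p = tab$count / total,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write / read a token stream (one token per line)
#'
#' A minimal interchange format for pre-tokenized symbol streams; writing a
#' sequence and re-reading it round-trips the token vector exactly.
#'
#' @param seq a [symbol_sequence()].
#' @param path file path.
#' @return `write_tokens` returns `path` invisibly; `read_tokens` a
#'   [symbol_sequence()].
#' @export
write_tokens <- function(seq, path) {
  seq <- as_symbol_sequence(seq)
  writeLines(as.character(seq$tokens), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_tokens
#' @export
read_tokens <- function(path) {
  if (!file.exists(path))
    stop_zml("cannot read tokens: no such file '%s'", path,
             class = "zml_io_error")
  toks <- readLines(path, encoding = "UTF-8", warn = FALSE)
  symbol_sequence(toks)
}
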