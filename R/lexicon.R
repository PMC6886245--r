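fold_tokens <- function(tokens) {
  # case-fold after NFC normalization; keys are space-joined token sequences
  tolower(enc2utf8(tokens))
}

lex_key <- function(tokens) paste(fold_tokens(tokens), collapse = " ")

#' Build a gazetteer from multi-token names
#'
#' The gazetteer backs the dictionary feature: known bacterial names, each a
#' sequence of one or more tokens. Entries are case-folded and
#' NFC-normalized, duplicates collapse, and lookups are O(1) via a hashed set
#' keyed on the joined token sequence (the maximum-matching scans only ever
#' probe contiguous token windows up to `L_max` tokens long).
#'
#' @param names character vector, one whitespace-tokenized name per element.
#' @return An object of class `ner_lexicon` with fields `entries` (sorted
#'   character vector of folded names), `index` (hash environment), `L_max`
#'   (maximum entry length in tokens) and `n`.
#' @export
ner_lexicon <- function(names = character()) {
  names <- names[nzchar(trimws(names))]
  toks <- lapply(strsplit(trimws(names), "[[:space:]]+"), fold_tokens)
  keys <- unique(vapply(toks, paste, "", collapse = " "))
  index <- new.env(parent = emptyenv(), hash = TRUE)
  for (k in keys) assign(k, TRUE, envir = index)
  lens <- if (length(keys)) lengths(strsplit(keys, " ", fixed = TRUE)) else integer()
  structure(list(entries = sort(keys), index = index,
                 L_max = if (length(lens)) max(lens) else 0L,
                 n = length(keys)),
            class = "ner_lexicon")
}

#' @export
print.ner_lexicon <- function(x, ...) {
  cat(sprintf("<ner_lexicon> %d entries, L_max = %d tokens\n", x$n, x$L_max))
  invisible(x)
}

#' Load a gazetteer from a plain-text file
#'
#' @param path UTF-8 text file, one name per line.
#' @return A [ner_lexicon()]. An empty file yields a valid empty lexicon with
#'   a warning.
#' @export
load_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lex <- ner_lexicon(lines)
  if (lex$n == 0L) warning("lexicon file '", path, "' contains no entries")
  lex
}

#' Write a gazetteer to a plain-text file
#'
#' @param lex a [ner_lexicon()].
#' @param path output path; one folded entry per line.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  writeLines(lex$entries, path, useBytes = TRUE)
  invisible(path)
}

lex_has <- function(lex, key) {
  exists(key, envir = lex$index, inherits = FALSE)
}

#' Forward maximum matching
#'
#' Greedy longest-first scan left to right: at each position take the longest
#' gazetteer entry (up to `L_max` tokens) starting there, jump past it on a
#' match, else advance one token. Matches are disjoint by construction.
#'
#' @param tokens character vector of surface forms.
#' @param lex a [ner_lexicon()].
#' @return data.frame of matches with 1-based inclusive `start`, `end`.
#' @export
forward_max_match <- function(tokens, lex) {
  folded <- fold_tokens(tokens)
  n <- length(folded)
  starts <- integer(); ends <- integer()
  i <- 1L
  while (i <= n) {
    hit <- 0L
    for (l in seq.int(min(lex$L_max, n - i + 1L), 1L)) {
      if (l < 1L) break
      key <- paste(folded[i:(i + l - 1L)], collapse = " ")
      if (lex_has(lex, key)) { hit <- l; break }
    }
    if (hit > 0L) {
      starts <- c(starts, i); ends <- c(ends, i + hit - 1L)
      i <- i + hit
    } else i <- i + 1L
  }
  data.frame(start = starts, end = ends)
}

#' Backward maximum matching
#'
#' Mirror of [forward_max_match()]: scan right to left, at each cursor take
#' the longest entry ending there.
#'
#' @inheritParams forward_max_match
#' @return data.frame of matches with 1-based inclusive `start`, `end`,
#'   sorted by `start`.
#' @export
backward_max_match <- function(tokens, lex) {
  folded <- fold_tokens(tokens)
  n <- length(folded)
  starts <- integer(); ends <- integer()
  j <- n
  while (j >= 1L) {
    hit <- 0L
    for (l in seq.int(min(lex$L_max, j), 1L)) {
      if (l < 1L) break
      key <- paste(folded[(j - l + 1L):j], collapse = " ")
      if (lex_has(lex, key)) { hit <- l; break }
    }
    if (hit > 0L) {
      starts <- c(j - hit + 1L, starts); ends <- c(j, ends)
      j <- j - hit
    } else j <- j - 1L
  }
  data.frame(start = starts, end = ends)
}

#' Bidirectional maximum matching (BDMM) dictionary tagger
#'
#' Runs [forward_max_match()] and [backward_max_match()] and keeps one match
#' set: the direction covering more tokens wins; on a coverage tie the
#' direction with fewer matches (longer average match) wins; a final tie
#' keeps the backward result. The selected matches are emitted as IOB2
#' dictionary features via [spans_to_tags()].
#'
#' @inheritParams forward_max_match
#' @param etype entity type label used in the emitted tags.
#' @return character vector of IOB2 dictionary features
#'   (`B-etype`/`I-etype`/`O`), one per token.
#' @export
bdmm_tag <- function(tokens, lex, etype = "bacteria") {
  n <- length(tokens)
  if (n == 0L || lex$n == 0L) return(rep("O", n))
  fwd <- forward_max_match(tokens, lex)
  bwd <- backward_max_match(tokens, lex)
  cov <- function(m) if (nrow(m)) sum(m$end - m$start + 1L) else 0L
  sel <-
    if (cov(fwd) > cov(bwd)) fwd
    else if (cov(bwd) > cov(fwd)) bwd
    else if (nrow(fwd) < nrow(bwd)) fwd
    else bwd
  if (!nrow(sel)) return(rep("O", n))
  sel$type <- etype
  spans_to_tags(sel, n)
}

#' Attach POS features via a pluggable tagger
#'
#' The tagger contract: a function mapping a character vector of surfaces to
#' an equal-length character vector of POS tags. An existing POS column
#' (e.g. read from file) is left untouched unless `overwrite = TRUE`.
#'
#' @param sentence a [ner_sentence()].
#' @param tagger `function(surface) -> character` of the same length.
#' @param overwrite replace an existing POS column?
#' @return The sentence with its `pos` field filled.
#' @export
attach_pos <- function(sentence, tagger, overwrite = FALSE) {
  stopifnot(inherits(sentence, "ner_sentence"), is.function(tagger))
  if (!overwrite && sentence$n > 0 && !anyNA(sentence$pos)) return(sentence)
  pos <- as.character(tagger(sentence$surface))
  if (length(pos) != sentence$n) {
    stop("POS tagger returned ", length(pos), " tags for ", sentence$n, " tokens")
  }
  sentence$pos <- pos
  sentence
}

#' Fill the dictionary feature column of a whole corpus
#'
#' @param corpus a [ner_corpus()].
#' @param lex a [ner_lexicon()].
#' @param etype entity type label for the emitted features.
#' @return The corpus with every sentence's `dict` column set by [bdmm_tag()].
#' @export
attach_dict <- function(corpus, lex, etype = "bacteria") {
  corpus$sentences <- lapply(corpus$sentences, function(s) {
    s$dict <- bdmm_tag(s$surface, lex, etype)
    s
  })
  corpus
}
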