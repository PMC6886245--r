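IOB2_RE <- "^(O|[BI]-[^[:space:]]+)$"

#' Construct a tokenized sentence
#'
#' A sentence is the unit the tagger operates on: parallel character vectors
#' holding the surface forms and the three per-token annotation columns
#' (part-of-speech tag, gazetteer feature, gold tag). The two tag columns use
#' the IOB2 scheme: `B-X` opens an entity of type `X`, `I-X` continues it,
#' `O` is outside any entity.
#'
#' @param surface character vector of token surface forms (non-empty strings).
#' @param pos character vector of POS tags (Penn Treebank style), or `NA`.
#' @param dict character vector of gazetteer features (IOB2 over
#'   `B-bacteria`/`I-bacteria`/`O`), or `NA`.
#' @param tag character vector of gold IOB2 tags, or `NA`.
#' @return An object of class `ner_sentence` with fields `surface`, `pos`,
#'   `dict`, `tag` and token count `n`.
#' @export
ner_sentence <- function(surface, pos = NA, dict = NA, tag = NA) {
  surface <- as.character(surface)
  n <- length(surface)
  if (n > 0 && any(!nzchar(surface))) {
    stop("sentence contains an empty surface form")
  }
  fill <- function(x) {
    if (length(x) == 1L && is.na(x[1L])) rep(NA_character_, n) else as.character(x)
  }
  pos <- fill(pos); dict <- fill(dict); tag <- fill(tag)
  for (col in list(pos, dict, tag)) {
    if (length(col) != n) stop("annotation column length != token count")
  }
  structure(list(surface = surface, pos = pos, dict = dict, tag = tag, n = n),
            class = "ner_sentence")
}

#' Construct a corpus
#'
#' @param sentences list of [ner_sentence()] objects.
#' @param tag_alphabet ordered character vector of IOB2 tags; if `NULL`,
#'   collected from the sentences (with `"O"` always present and first).
#' @return An object of class `ner_corpus`.
#' @export
ner_corpus <- function(sentences = list(), tag_alphabet = NULL) {
  stopifnot(is.list(sentences))
  if (is.null(tag_alphabet)) {
    seen <- unique(unlist(lapply(sentences, function(s) s$tag), use.names = FALSE))
    seen <- seen[!is.na(seen)]
    tag_alphabet <- union("O", sort(seen))
  }
  bad <- tag_alphabet[!grepl(IOB2_RE, tag_alphabet)]
  if (length(bad)) stop("invalid IOB2 tag(s) in alphabet: ", paste(bad, collapse = ", "))
  structure(list(sentences = sentences, tag_alphabet = tag_alphabet),
            class = "ner_corpus")
}

#' @export
print.ner_corpus <- function(x, ...) {
  st <- corpus_stats(x)
  cat(sprintf("<ner_corpus> %d sentences, %d tokens, %d entities; tags: %s\n",
              st$sentences, st$tokens, st$entities,
              paste(x$tag_alphabet, collapse = " ")))
  invisible(x)
}

#' @export
print.ner_sentence <- function(x, ...) {
  cat(sprintf("<ner_sentence> %d tokens: %s\n", x$n,
              paste(x$surface, collapse = " ")))
  invisible(x)
}

#' @export
length.ner_corpus <- function(x) length(x$sentences)

#' Read a CoNLL-style column corpus
#'
#' Reads the tab-separated token-per-line format: each non-blank line carries
#' `token<TAB>pos<TAB>dict<TAB>tag` (4-column full format) or `token<TAB>tag`
#' (2-column); blank lines separate sentences. Trailing blank lines produce no
#' empty sentence.
#'
#' @param path file path (UTF-8 text).
#' @return A [ner_corpus()] whose `tag_alphabet` is collected from the tag
#'   column.
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sentences <- list()
  buf <- list()
  flush <- function() {
    if (!length(buf)) return(invisible())
    m <- do.call(rbind, buf)
    sentences[[length(sentences) + 1L]] <<-
      ner_sentence(m[, 1L], m[, 2L], m[, 3L], m[, 4L])
    buf <<- list()
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) { flush(); next }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (!length(f) %in% c(2L, 4L)) {
      stop(sprintf("line %d: expected 2 or 4 tab-separated columns, got %d",
                   i, length(f)))
    }
    if (length(f) == 2L) f <- c(f[1L], NA, NA, f[2L])
    tg <- f[4L]
    if (!is.na(tg) && !grepl(IOB2_RE, tg)) {
      stop(sprintf("line %d: tag '%s' is not IOB2 (O or B-/I-TYPE)", i, tg))
    }
    buf[[length(buf) + 1L]] <- f
  }
  flush()
  ner_corpus(sentences)
}

#' Write a corpus in CoNLL-style 4-column format
#'
#' Inverse of [read_conll()]: each sentence becomes a block of
#' `token<TAB>pos<TAB>dict<TAB>tag` lines followed by one blank line.
#' `NA` annotation values are written as `O`.
#'
#' @param corpus a [ner_corpus()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_conll <- function(corpus, path) {
  stopifnot(inherits(corpus, "ner_corpus"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (s in corpus$sentences) {
    if (s$n > 0) {
      fix <- function(x) ifelse(is.na(x), "O", x)
      writeLines(paste(s$surface, fix(s$pos), fix(s$dict), fix(s$tag),
                       sep = "\t"), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Decode IOB2 tags into entity spans
#'
#' Every maximal `B-X (I-X)*` run becomes one span. Invalid sequences — an
#' `I-X` not preceded by `B-X` or `I-X` of the same type — are repaired first
#' by re-reading the stray `I-X` as `B-X` (the usual IOB2 repair); the number
#' of repairs is attached as attribute `"repairs"`.
#'
#' Token indices are 1-based; `start`/`end` are both inclusive.
#'
#' @param tags character vector of IOB2 tags.
#' @return data.frame with columns `start`, `end`, `type`, sorted by `start`,
#'   plus attribute `repairs` (integer count of applied repairs).
#' @export
tags_to_spans <- function(tags) {
  tags <- as.character(tags)
  repairs <- 0L
  starts <- integer(); ends <- integer(); types <- character()
  cur_start <- 0L; cur_type <- ""
  close_cur <- function(i) {
    if (cur_start > 0L) {
      starts[[length(starts) + 1L]] <<- cur_start
      ends[[length(ends) + 1L]] <<- i
      types[[length(types) + 1L]] <<- cur_type
      cur_start <<- 0L
    }
  }
  for (i in seq_along(tags)) {
    t <- tags[[i]]
    if (!grepl(IOB2_RE, t)) stop("not an IOB2 tag: '", t, "'")
    if (t == "O") { close_cur(i - 1L); next }
    pre <- substr(t, 1L, 1L)
    typ <- substr(t, 3L, nchar(t))
    if (pre == "I" && cur_start > 0L && typ == cur_type) next
    if (pre == "I") repairs <- repairs + 1L  # stray I- becomes B-
    close_cur(i - 1L)
    cur_start <- i; cur_type <- typ
  }
  close_cur(length(tags))
  out <- data.frame(start = starts, end = ends, type = types,
                    stringsAsFactors = FALSE)
  attr(out, "repairs") <- repairs
  out
}

#' Encode entity spans as IOB2 tags
#'
#' Inverse of [tags_to_spans()] for valid span sets:
#' `tags_to_spans(spans_to_tags(s, n))` reproduces `s`.
#'
#' @param spans data.frame with 1-based inclusive `start`, `end` and `type`.
#' @param n sentence length in tokens.
#' @return character vector of `n` IOB2 tags.
#' @export
spans_to_tags <- function(spans, n) {
  tags <- rep("O", n)
  if (is.null(spans) || nrow(spans) == 0L) return(tags)
  o <- order(spans$start)
  spans <- spans[o, , drop = FALSE]
  last_end <- 0L
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[[i]]; e <- spans$end[[i]]; ty <- spans$type[[i]]
    if (s < 1L || e > n || s > e) stop("span out of range: [", s, ", ", e, "]")
    if (s <= last_end) stop("overlapping spans at token ", s)
    tags[[s]] <- paste0("B-", ty)
    if (e > s) tags[(s + 1L):e] <- paste0("I-", ty)
    last_end <- e
  }
  tags
}

#' Count the IOB2 repairs a tag sequence needs
#'
#' @param tags character vector of IOB2 tags.
#' @return integer: number of stray `I-X` tags that [tags_to_spans()] would
#'   re-read as `B-X` (0 for a valid sequence).
#' @export
validate_iob2 <- function(tags) {
  attr(tags_to_spans(tags), "repairs")
}
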