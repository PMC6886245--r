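UNK <- "<unk>"
PAD <- "<pad>"

#' Uniform embedding initialization
#'
#' Draws every entry from `U[-sqrt(3/dim), +sqrt(3/dim)]`, the scaling that
#' gives unit-variance-per-dimension lookup tables. Deterministic under
#' `set.seed()`.
#'
#' @param vocab_size number of rows.
#' @param dim embedding dimension (> 0).
#' @return `vocab_size x dim` numeric matrix.
#' @export
init_uniform <- function(vocab_size, dim) {
  if (dim <= 0) stop("embedding dimension must be positive")
  r <- sqrt(3 / dim)
  matrix(stats::runif(vocab_size * dim, -r, r), nrow = vocab_size)
}

#' Glorot (Xavier) uniform initialization
#'
#' `U[-l, l]` with `l = sqrt(6 / (fan_in + fan_out))`; used for convolution
#' kernels, LSTM weights and the emission projection.
#'
#' @param nrow,ncol matrix shape (`fan_out`, `fan_in`).
#' @return `nrow x ncol` numeric matrix.
#' @export
init_glorot <- function(nrow, ncol) {
  l <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -l, l), nrow = nrow)
}

#' Build an embedding table over a vocabulary
#'
#' The table carries an `<unk>` row (always index 1) for out-of-vocabulary
#' lookups; a `<pad>` row can be requested for the character table (its
#' vector is fixed at zero).
#'
#' @param vocab character vector of (unique) symbols.
#' @param dim embedding dimension.
#' @param pad add a zero `<pad>` row?
#' @return list with `vocab` (including special symbols), `dim`, `matrix`
#'   (`length(vocab) x dim`), and `index` (hash environment symbol -> row).
#' @export
embedding_table <- function(vocab, dim, pad = FALSE) {
  vocab <- setdiff(unique(vocab), c(UNK, PAD))
  vocab <- c(if (pad) PAD, UNK, vocab)
  mat <- init_uniform(length(vocab), dim)
  if (pad) mat[1L, ] <- 0
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_along(vocab)) assign(vocab[[i]], i, envir = idx)
  list(vocab = vocab, dim = dim, matrix = mat, index = idx)
}

lookup_ids <- function(table, symbols) {
  unk <- get(UNK, envir = table$index)
  vapply(symbols, function(s) {
    if (exists(s, envir = table$index, inherits = FALSE)) {
      get(s, envir = table$index)
    } else unk
  }, integer(1), USE.NAMES = FALSE)
}

#' Load word vectors in word2vec text format
#'
#' Format: a header line `"<count> <dim>"`, then one line per token holding
#' the token and `dim` whitespace-separated floats.
#'
#' @param path file path.
#' @return list with `vocab` (character) and `matrix` (`count x dim`).
#' @export
load_word2vec <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hd <- suppressWarnings(
    as.integer(strsplit(trimws(lines[[1L]]), "[[:space:]]+")[[1L]]))
  if (length(hd) != 2L || anyNA(hd)) stop("malformed word2vec header line")
  count <- hd[[1L]]; dim <- hd[[2L]]
  body <- lines[seq_len(count) + 1L]
  parts <- strsplit(trimws(body), "[[:space:]]+")
  vocab <- vapply(parts, `[[`, "", 1L)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(dim)))
  if (anyNA(mat)) stop("non-numeric embedding values in word2vec file")
  list(vocab = vocab, matrix = mat)
}

#' Write word vectors in word2vec text format
#'
#' @param vocab character vector of tokens.
#' @param mat numeric matrix, one row per token.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_word2vec <- function(vocab, mat, path) {
  stopifnot(length(vocab) == nrow(mat))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(mat), ncol(mat)), con)
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(vocab[[i]], paste(format(mat[i, ], scientific = FALSE), collapse = " "))
  }, "")
  writeLines(body, con)
  invisible(path)
}
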