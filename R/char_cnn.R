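#' Character-CNN parameters
#'
#' A word is embedded character by character, a width-`k` convolution with
#' `N` kernels slides over the padded character sequence, a ReLU is applied,
#' and max-pooling over positions yields an `N`-dimensional morphology vector
#' for the word. Windows use same-padding with a dedicated zero `<pad>`
#' character vector, so a 1-character word still yields one full window.
#'
#' @param chars character vector: the character inventory.
#' @param char_dim character embedding dimension.
#' @param k convolution window width (odd).
#' @param N number of kernels ("filter deep").
#' @return list with the character [embedding_table()] (`table`), kernel
#'   weight matrix `W1` (`N x k*char_dim`), bias `b1` (`N`), `k`, `N`.
#' @export
char_cnn_params <- function(chars, char_dim = 25, k = 3, N = 30) {
  if (k %% 2 != 1) stop("convolution window k must be odd (same-padding)")
  tab <- embedding_table(chars, char_dim, pad = TRUE)
  list(table = tab, W1 = init_glorot(N, k * char_dim), b1 = rep(0, N),
       k = k, N = N)
}

# Forward over one word given integer char ids (rows of the char table).
# Returns the pooled vector plus the cache needed for backprop.
char_cnn_forward <- function(ids, emb, W1, b1, k) {
  half <- (k - 1L) %/% 2L
  L <- length(ids)
  if (L == 0L) {
    return(list(out = rep(0, length(b1)), empty = TRUE))
  }
  p <- c(rep(1L, half), ids, rep(1L, half))  # row 1 is <pad>, fixed zero
  M <- t(emb[p, , drop = FALSE])             # char_dim x (L + 2*half)
  X <- do.call(rbind, lapply(seq_len(k), function(o) {
    M[, o:(o + L - 1L), drop = FALSE]
  }))                                        # (k*char_dim) x L
  A <- W1 %*% X + b1
  O <- pmax(A, 0)
  amax <- max.col(O, ties.method = "first")
  out <- O[cbind(seq_along(b1), amax)]
  list(out = out, X = X, A = A, amax = amax, p = p, L = L, empty = FALSE)
}

# Backprop for one word: dout is the gradient at the pooled output.
# Returns dW1, db1 and the sparse char-embedding gradient (ids + rows).
char_cnn_backward <- function(dout, cache, W1, k, char_dim) {
  if (cache$empty) return(NULL)
  N <- length(dout)
  act <- cache$A[cbind(seq_len(N), cache$amax)] > 0
  d <- dout * act                                   # grad at pre-activation argmax
  dW1 <- d * t(cache$X[, cache$amax, drop = FALSE]) # row r: d_r * X[, amax_r]
  db1 <- d
  S <- matrix(0, N, cache$L)
  S[cbind(seq_len(N), cache$amax)] <- d
  dX <- crossprod(W1, S)                            # (k*char_dim) x L
  Lp <- cache$L + (k - 1L)
  dM <- matrix(0, char_dim, Lp)
  for (o in seq_len(k)) {
    cols <- o:(o + cache$L - 1L)
    dM[, cols] <- dM[, cols] + dX[((o - 1L) * char_dim + 1L):(o * char_dim), ,
                                  drop = FALSE]
  }
  list(dW1 = dW1, db1 = db1, ids = cache$p, rows = t(dM))
}

#' Encode a word with the character CNN
#'
#' Applies the convolution + ReLU + max-pool of the character channel to one
#' word. An empty word maps to the zero vector.
#'
#' @param word a single character string.
#' @param params a [char_cnn_params()] object.
#' @return numeric vector of length `params$N`.
#' @export
char_cnn_encode <- function(word, params) {
  chars <- strsplit(word, "", fixed = TRUE)[[1L]]
  ids <- lookup_ids(params$table, chars)
  char_cnn_forward(ids, params$table$matrix, params$W1, params$b1, params$k)$out
}
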