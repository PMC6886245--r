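sigmoid <- function(x) 1 / (1 + exp(-x))

#' LSTM parameters
#'
#' One direction of the recurrent encoder. Gate weights act on the
#' concatenation `[h_prev; x]`:
#' forget `f_t = sigma(W_f [h,x] + b_f)`, input `i_t = sigma(W_i [h,x] + b_i)`,
#' output `o_t = sigma(W_o [h,x] + b_o)`, candidate `tanh(W_c [h,x] + b_c)`,
#' cell `C_t = f_t * C_{t-1} + i_t * tanh(...)`, state `h_t = o_t * tanh(C_t)`.
#'
#' @param input_dim dimension of `x_t`.
#' @param hidden state dimension.
#' @param init `"glorot"` (default) or `"zero"`.
#' @return list with `W_f`, `W_i`, `W_o`, `W_c` (each
#'   `hidden x (hidden + input_dim)`), biases `b_f`, `b_i`, `b_o`, `b_c`,
#'   and `hidden`, `input_dim`.
#' @export
lstm_params <- function(input_dim, hidden, init = c("glorot", "zero")) {
  init <- match.arg(init)
  mk <- function() {
    if (init == "zero") matrix(0, hidden, hidden + input_dim)
    else init_glorot(hidden, hidden + input_dim)
  }
  list(W_f = mk(), W_i = mk(), W_o = mk(), W_c = mk(),
       b_f = rep(0, hidden), b_i = rep(0, hidden),
       b_o = rep(0, hidden), b_c = rep(0, hidden),
       hidden = hidden, input_dim = input_dim)
}

#' One LSTM step
#'
#' Pure function computing the gate equations for a single time step.
#'
#' @param x_t input vector (`input_dim`).
#' @param h_prev,C_prev previous hidden state and cell (`hidden`).
#' @param params an [lstm_params()] object.
#' @return list with `h` and `C`.
#' @export
lstm_step <- function(x_t, h_prev, C_prev, params) {
  if (length(x_t) != params$input_dim || length(h_prev) != params$hidden ||
      length(C_prev) != params$hidden) {
    stop("lstm_step: dimension mismatch")
  }
  v <- c(h_prev, x_t)
  f <- sigmoid(drop(params$W_f %*% v) + params$b_f)
  i <- sigmoid(drop(params$W_i %*% v) + params$b_i)
  o <- sigmoid(drop(params$W_o %*% v) + params$b_o)
  g <- tanh(drop(params$W_c %*% v) + params$b_c)
  C <- f * C_prev + i * g
  list(h = o * tanh(C), C = C)
}

# --- fast combined-gate kernels used by the model ------------------------
# W is the row-bound (f, i, o, c) gate matrix: (4H x (H + D)); b likewise.

combine_lstm <- function(p) {
  list(W = rbind(p$W_f, p$W_i, p$W_o, p$W_c),
       b = c(p$b_f, p$b_i, p$b_o, p$b_c),
       hidden = p$hidden, input_dim = p$input_dim)
}

split_lstm_grad <- function(dW, db, H) {
  list(W_f = dW[1:H, , drop = FALSE],          b_f = db[1:H],
       W_i = dW[(H + 1):(2 * H), , drop = FALSE], b_i = db[(H + 1):(2 * H)],
       W_o = dW[(2 * H + 1):(3 * H), , drop = FALSE], b_o = db[(2 * H + 1):(3 * H)],
       W_c = dW[(3 * H + 1):(4 * H), , drop = FALSE], b_c = db[(3 * H + 1):(4 * H)])
}

# Forward pass over a whole sequence. X is D x n (columns are time steps).
# The input contribution W_x X is computed in one GEMM; only the recurrent
# H-part stays in the time loop.
lstm_run <- function(X, W, b, H) {
  D <- nrow(X); n <- ncol(X)
  Wh <- W[, 1:H, drop = FALSE]
  Wx <- W[, (H + 1):(H + D), drop = FALSE]
  Zx <- Wx %*% X + b
  Fm <- matrix(0, H, n); Im <- Fm; Om <- Fm; Gm <- Fm
  Cm <- Fm; TC <- Fm; Hm <- Fm
  h <- rep(0, H); Cc <- rep(0, H)
  i1 <- 1:H; i2 <- (H + 1):(2 * H); i3 <- (2 * H + 1):(3 * H); i4 <- (3 * H + 1):(4 * H)
  for (t in seq_len(n)) {
    z <- Zx[, t] + drop(Wh %*% h)
    f <- sigmoid(z[i1]); i <- sigmoid(z[i2]); o <- sigmoid(z[i3]); g <- tanh(z[i4])
    Cc <- f * Cc + i * g
    tc <- tanh(Cc)
    h <- o * tc
    Fm[, t] <- f; Im[, t] <- i; Om[, t] <- o; Gm[, t] <- g
    Cm[, t] <- Cc; TC[, t] <- tc; Hm[, t] <- h
  }
  list(H = Hm, F = Fm, I = Im, O = Om, G = Gm, C = Cm, TC = TC, X = X)
}

# BPTT. dH is H x n. Returns dX plus the per-step pre-activation gradients
# DZ (4H x n) and the step inputs M ((H+D) x n), so weight gradients can be
# formed later as one GEMM (possibly pooled over a whole mini-batch):
# dW = DZ %*% t(M), db = rowSums(DZ).
lstm_backward <- function(dH, run, W, H) {
  X <- run$X; D <- nrow(X); n <- ncol(X)
  Wh <- W[, 1:H, drop = FALSE]
  Wx <- W[, (H + 1):(H + D), drop = FALSE]
  DZ <- matrix(0, 4 * H, n)
  dh_next <- rep(0, H); dC_next <- rep(0, H)
  i1 <- 1:H; i2 <- (H + 1):(2 * H); i3 <- (2 * H + 1):(3 * H); i4 <- (3 * H + 1):(4 * H)
  for (t in seq.int(n, 1L)) {
    dh <- dH[, t] + dh_next
    f <- run$F[, t]; i <- run$I[, t]; o <- run$O[, t]; g <- run$G[, t]
    tc <- run$TC[, t]
    do <- dh * tc
    dC <- dC_next + dh * o * (1 - tc * tc)
    C_prev <- if (t > 1L) run$C[, t - 1L] else rep(0, H)
    df <- dC * C_prev
    di <- dC * g
    dg <- dC * i
    dC_next <- dC * f
    dz <- c(df * f * (1 - f), di * i * (1 - i), do * o * (1 - o), dg * (1 - g * g))
    DZ[, t] <- dz
    dh_next <- drop(crossprod(Wh, dz))
  }
  Hprev <- cbind(rep(0, H), run$H[, seq_len(max(n - 1L, 0L)), drop = FALSE])
  list(dX = crossprod(Wx, DZ), DZ = DZ, M = rbind(Hprev, X))
}

#' Bidirectional LSTM encoding
#'
#' Runs a forward LSTM over the sequence and a backward LSTM over its
#' reversal (both from zero initial states) and concatenates the states:
#' position `t` of the output is `[h_fwd_t; h_bwd_t]`. The first half
#' depends only on inputs `1..t`, the second only on `t..n`.
#'
#' @param inputs `input_dim x n` matrix (columns are positions).
#' @param fwd,bwd [lstm_params()] for the two directions.
#' @return `2*hidden x n` matrix.
#' @export
bilstm_encode <- function(inputs, fwd, bwd) {
  if (!is.matrix(inputs) || ncol(inputs) == 0L) {
    stop("bilstm_encode: inputs must be a non-empty input_dim x n matrix")
  }
  n <- ncol(inputs)
  cf <- combine_lstm(fwd); cb <- combine_lstm(bwd)
  Hf <- lstm_run(inputs, cf$W, cf$b, fwd$hidden)$H
  Hb <- lstm_run(inputs[, n:1, drop = FALSE], cb$W, cb$b, bwd$hidden)$H
  rbind(Hf, Hb[, n:1, drop = FALSE])
}

#' Emission scores from encoded states
#'
#' Affine projection of each BiLSTM state to per-tag scores: row `t` of the
#' returned matrix holds the scores of the `m` tags for token `t`.
#'
#' @param encoded `2*hidden x n` matrix from [bilstm_encode()].
#' @param W `m x 2*hidden` projection matrix.
#' @param b length-`m` bias.
#' @return `n x m` emission matrix.
#' @export
emission_scores <- function(encoded, W, b) {
  t(W %*% encoded + b)
}
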