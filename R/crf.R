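CRF_MASK <- -1e4

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Linear-chain CRF parameters
#'
#' The transition matrix is `(m+2) x (m+2)`: entry `[i, j]` scores the
#' transition tag `i -> j`. Index `m+1` is the start state, `m+2` the end
#' state. Transitions into start and out of end are structurally impossible
#' and carry a fixed large-negative mask score; all other entries are
#' learned.
#'
#' @param tag_alphabet ordered character vector of `m` tags.
#' @param init `"zero"` or `"gauss"` (standard normal, for testing).
#' @return list of class `crf_params` with `T` (`(m+2) x (m+2)`),
#'   `tag_alphabet`, `m`, `start`, `end`.
#' @export
crf_params <- function(tag_alphabet, init = c("zero", "gauss")) {
  init <- match.arg(init)
  m <- length(tag_alphabet)
  Tm <- if (init == "zero") matrix(0, m + 2, m + 2)
        else matrix(stats::rnorm((m + 2)^2), m + 2, m + 2)
  Tm <- apply_crf_mask(Tm)
  structure(list(T = Tm, tag_alphabet = tag_alphabet, m = m,
                 start = m + 1L, end = m + 2L),
            class = "crf_params")
}

# fixed -1e4 on transitions into start and out of end
apply_crf_mask <- function(Tm) {
  k <- nrow(Tm)
  Tm[, k - 1L] <- CRF_MASK
  Tm[k, ] <- CRF_MASK
  Tm
}

crf_mask_positions <- function(m) {
  M <- matrix(FALSE, m + 2, m + 2)
  M[, m + 1L] <- TRUE
  M[m + 2L, ] <- TRUE
  M
}

check_emissions <- function(P, m) {
  if (!is.matrix(P) || ncol(P) != m) stop("emission matrix must be n x m")
  if (!all(is.finite(P))) stop("non-finite emission scores")
}

#' Score of one tag path
#'
#' `S(X, y) = T[start, y_1] + sum_i T[y_i, y_{i+1}] + T[y_n, end] +
#' sum_i P[i, y_i]` — the emission scores of the chosen tags plus all
#' transition scores including the start and end transitions.
#'
#' @param P `n x m` emission matrix.
#' @param crf a [crf_params()] object.
#' @param y integer vector of tag indices in `1..m`.
#' @return scalar path score.
#' @export
path_score <- function(P, crf, y) {
  n <- nrow(P); m <- crf$m
  check_emissions(P, m)
  if (length(y) != n) stop("path length != sentence length")
  if (any(y < 1L | y > m)) stop("tag index out of range 1..m")
  Tm <- crf$T
  s <- Tm[crf$start, y[1L]] + Tm[y[n], crf$end] + sum(P[cbind(seq_len(n), y)])
  if (n > 1L) s <- s + sum(Tm[cbind(y[-n], y[-1L])])
  s
}

#' Log-partition of the CRF
#'
#' `log sum_y exp(S(X, y))` over all `m^n` tag paths, computed by the
#' log-space forward recursion (never by literal enumeration), so it is the
#' exact normalizer of the path softmax.
#'
#' @inheritParams path_score
#' @return scalar log-partition value.
#' @export
log_partition <- function(P, crf) {
  crf_forward(P, crf)$logZ
}

crf_forward <- function(P, crf) {
  n <- nrow(P); m <- crf$m
  check_emissions(P, m)
  Tm <- crf$T[1:m, 1:m, drop = FALSE]
  alpha <- matrix(0, m, n)
  alpha[, 1L] <- crf$T[crf$start, 1:m] + P[1L, ]
  if (n > 1L) for (t in 2:n) {
    A <- alpha[, t - 1L] + Tm            # A[i, j] = alpha_i + T[i -> j]
    alpha[, t] <- apply(A, 2L, logsumexp) + P[t, ]
  }
  logZ <- logsumexp(alpha[, n] + crf$T[1:m, crf$end])
  list(alpha = alpha, logZ = logZ)
}

crf_backward_rec <- function(P, crf) {
  n <- nrow(P); m <- crf$m
  Tm <- crf$T[1:m, 1:m, drop = FALSE]
  beta <- matrix(0, m, n)
  beta[, n] <- crf$T[1:m, crf$end]
  if (n > 1L) for (t in (n - 1L):1L) {
    B <- Tm + rep(P[t + 1L, ] + beta[, t + 1L], each = m)
    beta[, t] <- apply(B, 1L, logsumexp)
  }
  beta
}

#' CRF negative log-likelihood
#'
#' `-log P(y_gold | X) = log_partition - path_score(y_gold)`; non-negative,
#' and exactly the training loss maximizing the log-probability of the gold
#' path.
#'
#' @inheritParams path_score
#' @param y_gold integer vector of gold tag indices.
#' @return scalar loss.
#' @export
crf_nll <- function(P, crf, y_gold) {
  log_partition(P, crf) - path_score(P, crf, y_gold)
}

#' CRF loss gradients
#'
#' Exact gradients of [crf_nll()] from the forward-backward marginals:
#' `dP[t, j] = p(y_t = j | X) - 1{gold_t = j}` and
#' `dT[i, j] = E[count(i -> j)] - observed count(i -> j)` (including the
#' start/end transitions; masked entries get zero gradient).
#'
#' @inheritParams crf_nll
#' @return list with `nll`, `dP` (`n x m`), `dT` (`(m+2) x (m+2)`).
#' @export
crf_nll_grad <- function(P, crf, y_gold) {
  n <- nrow(P); m <- crf$m
  fw <- crf_forward(P, crf)
  beta <- crf_backward_rec(P, crf)
  logZ <- fw$logZ
  gamma <- exp(fw$alpha + beta - logZ)   # m x n posterior tag marginals
  dP <- t(gamma)
  dP[cbind(seq_len(n), y_gold)] <- dP[cbind(seq_len(n), y_gold)] - 1
  dT <- matrix(0, m + 2, m + 2)
  Tm <- crf$T[1:m, 1:m, drop = FALSE]
  if (n > 1L) for (t in seq_len(n - 1L)) {
    xi <- exp(fw$alpha[, t] + Tm +
              rep(P[t + 1L, ] + beta[, t + 1L], each = m) - logZ)
    dT[1:m, 1:m] <- dT[1:m, 1:m] + xi
    dT[y_gold[t], y_gold[t + 1L]] <- dT[y_gold[t], y_gold[t + 1L]] - 1
  }
  dT[crf$start, 1:m] <- gamma[, 1L]
  dT[crf$start, y_gold[1L]] <- dT[crf$start, y_gold[1L]] - 1
  dT[1:m, crf$end] <- dT[1:m, crf$end] + gamma[, n]
  dT[y_gold[n], crf$end] <- dT[y_gold[n], crf$end] - 1
  nll <- logZ - path_score(P, crf, y_gold)
  list(nll = nll, dP = dP, dT = dT)
}

#' Viterbi decoding
#'
#' Dynamic program over the lattice returning the highest-scoring tag path
#' `y* = argmax_y S(X, y)` and its score. Ties break toward the
#' lowest-index tag.
#'
#' @inheritParams path_score
#' @return list with `tags` (integer indices 1..m) and `score`.
#' @export
viterbi_decode <- function(P, crf) {
  n <- nrow(P); m <- crf$m
  check_emissions(P, m)
  Tm <- crf$T[1:m, 1:m, drop = FALSE]
  delta <- matrix(0, m, n)
  bp <- matrix(0L, m, n)
  delta[, 1L] <- crf$T[crf$start, 1:m] + P[1L, ]
  if (n > 1L) for (t in 2:n) {
    A <- delta[, t - 1L] + Tm
    bp[, t] <- max.col(t(A), ties.method = "first")
    delta[, t] <- A[cbind(bp[, t], 1:m)] + P[t, ]
  }
  fin <- delta[, n] + crf$T[1:m, crf$end]
  y <- integer(n)
  y[n] <- which.max(fin)
  if (n > 1L) for (t in seq.int(n, 2L)) y[t - 1L] <- bp[y[t], t]
  list(tags = y, score = max(fin))
}
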