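# --- flat parameter view ----------------------------------------------
# Every trainable array under one name, so the optimizer is generic.

get_params <- function(model) {
  list(word_emb = model$word$matrix,
       char_emb = model$cnn$table$matrix,
       cnn_W1 = model$cnn$W1, cnn_b1 = model$cnn$b1,
       pos_emb = model$pos$matrix, dict_emb = model$dict$matrix,
       lf_W_f = model$lstm_f$W_f, lf_W_i = model$lstm_f$W_i,
       lf_W_o = model$lstm_f$W_o, lf_W_c = model$lstm_f$W_c,
       lf_b_f = model$lstm_f$b_f, lf_b_i = model$lstm_f$b_i,
       lf_b_o = model$lstm_f$b_o, lf_b_c = model$lstm_f$b_c,
       lb_W_f = model$lstm_b$W_f, lb_W_i = model$lstm_b$W_i,
       lb_W_o = model$lstm_b$W_o, lb_W_c = model$lstm_b$W_c,
       lb_b_f = model$lstm_b$b_f, lb_b_i = model$lstm_b$b_i,
       lb_b_o = model$lstm_b$b_o, lb_b_c = model$lstm_b$b_c,
       proj_W = model$proj_W, proj_b = model$proj_b,
       crf_T = model$crf$T)
}

set_params <- function(model, p) {
  model$word$matrix <- p$word_emb
  model$cnn$table$matrix <- p$char_emb
  model$cnn$W1 <- p$cnn_W1; model$cnn$b1 <- p$cnn_b1
  model$pos$matrix <- p$pos_emb; model$dict$matrix <- p$dict_emb
  for (nm in c("W_f", "W_i", "W_o", "W_c", "b_f", "b_i", "b_o", "b_c")) {
    model$lstm_f[[nm]] <- p[[paste0("lf_", nm)]]
    model$lstm_b[[nm]] <- p[[paste0("lb_", nm)]]
  }
  model$proj_W <- p$proj_W; model$proj_b <- p$proj_b
  model$crf$T <- p$crf_T
  model
}

# Re-impose structural constraints after an optimizer step: the <pad>
# character vector stays zero and the impossible CRF transitions stay at
# the mask score.
apply_constraints <- function(model) {
  model$cnn$table$matrix[1L, ] <- 0
  model$crf$T <- apply_crf_mask(model$crf$T)
  model
}

new_batch_acc <- function(model) {
  m <- length(model$tag_alphabet)
  acc <- new.env(parent = emptyenv())
  acc$proj_W <- matrix(0, m, 2 * model$config$lstm_hidden)
  acc$proj_b <- rep(0, m)
  acc$cnn_W1 <- matrix(0, nrow(model$cnn$W1), ncol(model$cnn$W1))
  acc$cnn_b1 <- rep(0, model$config$filter_deep)
  acc$crf_T <- matrix(0, m + 2, m + 2)
  acc$DZf <- list(); acc$Mf <- list(); acc$DZb <- list(); acc$Mb <- list()
  acc$word_ids <- integer(); acc$word_g <- list()
  acc$pos_ids <- integer(); acc$pos_g <- list()
  acc$dict_ids <- integer(); acc$dict_g <- list()
  acc$char_ids <- integer(); acc$char_g <- list()
  acc
}

scatter_rows <- function(nrow_total, ncol, ids, blocks) {
  out <- matrix(0, nrow_total, ncol)
  if (!length(ids)) return(out)
  rows <- do.call(rbind, blocks)
  s <- rowsum(rows, group = ids)
  out[as.integer(rownames(s)), ] <- s
  out
}

# Pool a mini-batch accumulator into one gradient list (mean over the batch).
assemble_grads <- function(acc, model, nsent) {
  H <- model$config$lstm_hidden
  pool_lstm <- function(DZs, Ms) {
    DZ <- do.call(cbind, DZs); M <- do.call(cbind, Ms)
    split_lstm_grad(DZ %*% t(M), rowSums(DZ), H)
  }
  gf <- pool_lstm(acc$DZf, acc$Mf)
  gb <- pool_lstm(acc$DZb, acc$Mb)
  g <- list(
    word_emb = scatter_rows(nrow(model$word$matrix), model$config$word_dim,
                            acc$word_ids, acc$word_g),
    char_emb = scatter_rows(nrow(model$cnn$table$matrix), model$config$char_dim,
                            acc$char_ids, acc$char_g),
    cnn_W1 = acc$cnn_W1, cnn_b1 = acc$cnn_b1,
    pos_emb = scatter_rows(nrow(model$pos$matrix), model$config$pos_dim,
                           acc$pos_ids, acc$pos_g),
    dict_emb = scatter_rows(nrow(model$dict$matrix), model$config$dict_dim,
                            acc$dict_ids, acc$dict_g),
    lf_W_f = gf$W_f, lf_W_i = gf$W_i, lf_W_o = gf$W_o, lf_W_c = gf$W_c,
    lf_b_f = gf$b_f, lf_b_i = gf$b_i, lf_b_o = gf$b_o, lf_b_c = gf$b_c,
    lb_W_f = gb$W_f, lb_W_i = gb$W_i, lb_W_o = gb$W_o, lb_W_c = gb$W_c,
    lb_b_f = gb$b_f, lb_b_i = gb$b_i, lb_b_o = gb$b_o, lb_b_c = gb$b_c,
    proj_W = acc$proj_W, proj_b = acc$proj_b,
    crf_T = acc$crf_T)
  g <- lapply(g, function(x) x / nsent)
  g$char_emb[1L, ] <- 0                       # frozen <pad> vector
  g$crf_T[crf_mask_positions(length(model$tag_alphabet))] <- 0
  if (model$config$freeze_word_emb) g$word_emb[] <- 0
  g
}

clip_grads <- function(g, clip) {
  if (!is.finite(clip)) return(g)
  nrm <- sqrt(sum(vapply(g, function(x) sum(x * x), 0)))
  if (nrm > clip) g <- lapply(g, function(x) x * (clip / nrm))
  g
}

adam_init <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(x) x * 0)
  st$v <- st$m
  st$t <- 0L
  st
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  params
}

#' Split a corpus into seeded mini-batches
#'
#' Sentence indices are shuffled with the current RNG stream and split into
#' consecutive groups of `batch_size` (the last batch may be smaller). Every
#' sentence appears exactly once. Sentences are processed individually
#' within a batch (gradients are accumulated then averaged), so no padded
#' positions ever enter the loss, partition or Viterbi computations.
#'
#' @param corpus a [ner_corpus()] (or an integer sentence count).
#' @param batch_size sentences per batch (>= 1).
#' @param shuffle randomize order (deterministic under `set.seed`)?
#' @return list of integer index vectors.
#' @export
make_batches <- function(corpus, batch_size, shuffle = TRUE) {
  n <- if (inherits(corpus, "ner_corpus")) length(corpus$sentences) else corpus
  if (n < 1L) stop("cannot batch an empty corpus")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  idx <- if (shuffle) sample.int(n) else seq_len(n)
  unname(split(idx, ceiling(seq_along(idx) / batch_size)))
}

#' Early-stopping rule
#'
#' Stop when the last `patience` evaluations all failed to exceed the best
#' score seen before them by more than `tol` (sub-tolerance gains do not
#' count as improvement).
#'
#' @param f1 numeric vector of per-epoch validation scores (or a
#'   `TrainHistory` data.frame with a `dev_f1` column).
#' @param patience number of non-improving evaluations tolerated (>= 1).
#' @param tol minimum gain counted as improvement.
#' @return `TRUE` if training should stop.
#' @export
early_stop <- function(f1, patience, tol = 1e-4) {
  if (is.data.frame(f1)) f1 <- f1$dev_f1
  if (patience < 1L) stop("patience must be >= 1")
  if (!length(f1)) return(FALSE)
  best <- f1[[1L]]; last_improve <- 1L
  for (i in seq_along(f1)[-1L]) {
    if (f1[[i]] > best + tol) { best <- f1[[i]]; last_improve <- i }
  }
  (length(f1) - last_improve) >= patience
}

#' Train the tagger
#'
#' Mini-batch Adam on the CRF negative log-likelihood with dropout on the
#' concatenated embeddings and on the BiLSTM output, per-epoch
#' multiplicative learning-rate decay, global gradient-norm clipping, and
#' early stopping on validation span-F1. The returned model carries the
#' parameters of the best validation epoch, not the last one. Fully
#' deterministic for a fixed `config$seed` (single-threaded).
#'
#' @param train_set,dev_set [ner_corpus()] objects with all columns filled
#'   and a shared tag alphabet.
#' @param config a [model_config()].
#' @param word_vectors optional pre-trained vectors (see [init_model()]).
#' @param verbose print one line per epoch?
#' @return list with `model` (best epoch), `history` (data.frame of
#'   `epoch`, `loss`, `dev_f1`, `lr`), `best_epoch`.
#' @export
train <- function(train_set, dev_set, config = model_config(),
                  word_vectors = NULL, verbose = FALSE) {
  stopifnot(inherits(train_set, "ner_corpus"), inherits(dev_set, "ner_corpus"))
  if (!setequal(train_set$tag_alphabet, dev_set$tag_alphabet)) {
    stop("train and dev tag alphabets differ")
  }
  model <- init_model(train_set, config, word_vectors)
  keep <- vapply(train_set$sentences, function(s) s$n > 0L, TRUE)
  train_enc <- lapply(train_set$sentences[keep], encode_sentence, model = model)
  dev_keep <- vapply(dev_set$sentences, function(s) s$n > 0L, TRUE)
  dev_enc <- lapply(dev_set$sentences[dev_keep], encode_sentence, model = model)
  dev_gold <- lapply(dev_set$sentences[dev_keep],
                     function(s) tags_to_spans(s$tag))
  if (!length(train_enc)) stop("training corpus has no non-empty sentences")

  params <- get_params(model)
  st <- adam_init(params)
  lr <- config$lr
  history <- data.frame(epoch = integer(), loss = numeric(),
                        dev_f1 = numeric(), lr = numeric())
  best <- list(f1 = -Inf, epoch = 0L, params = params)

  for (epoch in seq_len(config$max_epochs)) {
    batches <- make_batches(length(train_enc), config$batch_size)
    total_loss <- 0
    for (b in batches) {
      acc <- new_batch_acc(model)
      for (si in b) {
        enc <- train_enc[[si]]
        fwd <- model_forward(enc, model, train_mode = config$dropout > 0,
                             keep_cache = TRUE)
        cg <- crf_nll_grad(fwd$P, model$crf, enc$tag_ids)
        if (!is.finite(cg$nll)) {
          stop("training diverged: non-finite loss at epoch ", epoch)
        }
        total_loss <- total_loss + cg$nll
        acc$crf_T <- acc$crf_T + cg$dT
        model_backward(fwd, cg$dP, model, acc)
      }
      g <- assemble_grads(acc, model, length(b))
      g <- clip_grads(g, config$clip)
      params <- adam_step(params, g, st, lr)
      model <- apply_constraints(set_params(model, params))
      params <- get_params(model)
    }
    f1 <- dev_span_f1(model, dev_enc, dev_gold)
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                loss = total_loss / length(train_enc),
                                dev_f1 = f1, lr = lr))
    if (verbose) {
      message(sprintf("epoch %2d  loss %.4f  dev F1 %6.2f  lr %.2e",
                      epoch, total_loss / length(train_enc), f1, lr))
    }
    if (f1 > best$f1 + config$tol) {
      best <- list(f1 = f1, epoch = epoch, params = params)
    }
    if (early_stop(history$dev_f1, config$patience, config$tol)) break
    lr <- lr * config$decay
  }
  model <- apply_constraints(set_params(model, best$params))
  list(model = model, history = history, best_epoch = best$epoch)
}

# Span-level F1 on pre-encoded sentences (fast path used inside train()).
dev_span_f1 <- function(model, encs, gold_spans) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_along(encs)) {
    P <- model_forward(encs[[i]], model)$P
    y <- viterbi_decode(P, model$crf)$tags
    pred <- tags_to_spans(model$tag_alphabet[y])
    cnt <- match_spans(gold_spans[[i]], pred)
    tp <- tp + cnt$tp; fp <- fp + cnt$fp; fn <- fn + cnt$fn
  }
  prf(eval_counts(tp, fp, fn))$f1
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single serialized archive holding a format version,
#' the configuration, tag alphabet, all vocabularies and all parameters.
#'
#' @param model a trained `ner_model`.
#' @param path checkpoint file path (`.rds`).
#' @return `path` invisibly (`save_checkpoint`); the model
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "ner_model"))
  obj <- list(format = "bacner-checkpoint", version = 1L, model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "bacner-checkpoint")) {
    stop("not a model checkpoint: ", path)
  }
  obj$model
}
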