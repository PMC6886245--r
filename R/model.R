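#' Model configuration
#'
#' All hyper-parameters in one validated record. Defaults are the reference
#' configuration: 300-dim word, 25-dim character, 25-dim POS and 5-dim
#' dictionary embeddings, width-3 convolution with 30 kernels, 100-unit
#' LSTM per direction, dropout 0.5, Adam with learning rate 0.001 and
#' per-epoch decay 0.9, early-stopping patience 5.
#'
#' @param word_dim,char_dim,pos_dim,dict_dim embedding dimensions.
#' @param filter_size convolution window width (odd).
#' @param filter_deep number of convolution kernels.
#' @param lstm_hidden LSTM state size per direction.
#' @param dropout dropout rate in `[0, 1)`.
#' @param lr Adam learning rate.
#' @param decay per-epoch multiplicative learning-rate decay (1 = off).
#' @param patience early-stopping patience (epochs without improvement).
#' @param batch_size sentences per mini-batch.
#' @param max_epochs epoch cap.
#' @param clip global gradient-norm clip (`Inf` = off).
#' @param tol minimum validation-F1 gain counted as an improvement.
#' @param freeze_word_emb do not update word embeddings during training.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return validated list of class `model_config`.
#' @export
model_config <- function(word_dim = 300, char_dim = 25, pos_dim = 25,
                         dict_dim = 5, filter_size = 3, filter_deep = 30,
                         lstm_hidden = 100, dropout = 0.5, lr = 0.001,
                         decay = 0.9, patience = 5, batch_size = 16,
                         max_epochs = 50, clip = 5, tol = 1e-4,
                         freeze_word_emb = FALSE, seed = 1L) {
  cfg <- list(word_dim = word_dim, char_dim = char_dim, pos_dim = pos_dim,
              dict_dim = dict_dim, filter_size = filter_size,
              filter_deep = filter_deep, lstm_hidden = lstm_hidden,
              dropout = dropout, lr = lr, decay = decay, patience = patience,
              batch_size = batch_size, max_epochs = max_epochs, clip = clip,
              tol = tol, freeze_word_emb = isTRUE(freeze_word_emb),
              seed = as.integer(seed))
  dims <- c(word_dim, char_dim, pos_dim, dict_dim, filter_deep, lstm_hidden)
  if (any(dims <= 0)) stop("all dimensions must be positive")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (filter_size %% 2 != 1) stop("filter_size must be odd")
  if (patience < 1 || batch_size < 1 || max_epochs < 1) {
    stop("patience, batch_size and max_epochs must be >= 1")
  }
  structure(cfg, class = "model_config")
}

input_dim <- function(cfg) {
  cfg$word_dim + cfg$filter_deep + cfg$pos_dim + cfg$dict_dim
}

#' Initialize a tagger model from a training corpus
#'
#' Builds the word / character / POS / dictionary vocabularies from the
#' corpus (each with an `<unk>` row for unseen symbols; word lookups are
#' case-folded) and initializes all parameters: embedding tables uniform in
#' `[-sqrt(3/dim), sqrt(3/dim)]`, convolution and dense weights
#' Glorot-uniform, biases zero, CRF transitions zero (plus the structural
#' start/end mask).
#'
#' @param corpus training [ner_corpus()] with all four columns filled.
#' @param config a [model_config()].
#' @param word_vectors optional pre-trained vectors from [load_word2vec()];
#'   matching vocabulary rows are copied in (dimension must equal
#'   `config$word_dim`).
#' @return list of class `ner_model`.
#' @export
init_model <- function(corpus, config = model_config(), word_vectors = NULL) {
  stopifnot(inherits(corpus, "ner_corpus"))
  set.seed(config$seed)
  surfaces <- unlist(lapply(corpus$sentences, `[[`, "surface"), use.names = FALSE)
  words <- sort(unique(tolower(surfaces)))
  chars <- sort(unique(unlist(strsplit(surfaces, "", fixed = TRUE), use.names = FALSE)))
  pos <- sort(unique(unlist(lapply(corpus$sentences, `[[`, "pos"), use.names = FALSE)))
  dict <- sort(unique(unlist(lapply(corpus$sentences, `[[`, "dict"), use.names = FALSE)))
  if (anyNA(pos) || anyNA(dict)) stop("corpus must have pos and dict columns filled")
  tags <- corpus$tag_alphabet
  m <- length(tags)
  H <- config$lstm_hidden
  D <- input_dim(config)

  word_tab <- embedding_table(words, config$word_dim)
  if (!is.null(word_vectors)) {
    if (ncol(word_vectors$matrix) != config$word_dim) {
      stop("pre-trained vector dimension != config$word_dim")
    }
    hit <- match(word_tab$vocab, word_vectors$vocab)
    ok <- which(!is.na(hit))
    word_tab$matrix[ok, ] <- word_vectors$matrix[hit[ok], , drop = FALSE]
  }
  model <- list(
    config = config,
    tag_alphabet = tags,
    word = word_tab,
    cnn = char_cnn_params(chars, config$char_dim, config$filter_size,
                          config$filter_deep),
    pos = embedding_table(pos, config$pos_dim),
    dict = embedding_table(dict, config$dict_dim),
    lstm_f = lstm_params(D, H),
    lstm_b = lstm_params(D, H),
    proj_W = init_glorot(m, 2 * H),
    proj_b = rep(0, m),
    crf = crf_params(tags)
  )
  class(model) <- "ner_model"
  model
}

#' @export
print.ner_model <- function(x, ...) {
  cat(sprintf(paste0("<ner_model> %d tags, vocab %d words / %d chars / ",
                     "%d pos / %d dict; input %d -> BiLSTM 2x%d -> CRF\n"),
              length(x$tag_alphabet), length(x$word$vocab),
              length(x$cnn$table$vocab), length(x$pos$vocab),
              length(x$dict$vocab), input_dim(x$config),
              x$config$lstm_hidden))
  invisible(x)
}

# Pre-compute integer ids for a sentence (lookup tables are fixed during
# training; only their rows change).
encode_sentence <- function(sentence, model) {
  surf <- sentence$surface
  list(
    n = sentence$n,
    word_ids = lookup_ids(model$word, tolower(surf)),
    char_ids = lapply(strsplit(surf, "", fixed = TRUE),
                      function(ch) lookup_ids(model$cnn$table, ch)),
    pos_ids = lookup_ids(model$pos, sentence$pos),
    dict_ids = lookup_ids(model$dict, sentence$dict),
    tag_ids = if (anyNA(sentence$tag)) NULL
              else match(sentence$tag, model$tag_alphabet)
  )
}

# Full network forward. Returns the emission matrix plus (optionally) every
# intermediate needed for backprop. Dropout (inverted scaling) is drawn from
# the current RNG stream only when train_mode is TRUE and rate > 0.
model_forward <- function(enc, model, train_mode = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  n <- enc$n
  if (n == 0L) stop("cannot run the network on an empty sentence")
  H <- cfg$lstm_hidden
  cnn_caches <- vector("list", n)
  Cmat <- matrix(0, cfg$filter_deep, n)
  for (t in seq_len(n)) {
    cc <- char_cnn_forward(enc$char_ids[[t]], model$cnn$table$matrix,
                           model$cnn$W1, model$cnn$b1, cfg$filter_size)
    cnn_caches[[t]] <- cc
    Cmat[, t] <- cc$out
  }
  E <- rbind(t(model$word$matrix[enc$word_ids, , drop = FALSE]),
             Cmat,
             t(model$pos$matrix[enc$pos_ids, , drop = FALSE]),
             t(model$dict$matrix[enc$dict_ids, , drop = FALSE]))
  rate <- if (train_mode) cfg$dropout else 0
  mask1 <- if (rate > 0) {
    matrix((stats::runif(nrow(E) * n) >= rate) / (1 - rate), nrow(E), n)
  } else NULL
  Ed <- if (is.null(mask1)) E else E * mask1

  cf <- combine_lstm(model$lstm_f); cb <- combine_lstm(model$lstm_b)
  runf <- lstm_run(Ed, cf$W, cf$b, H)
  runb <- lstm_run(Ed[, n:1, drop = FALSE], cb$W, cb$b, H)
  H2 <- rbind(runf$H, runb$H[, n:1, drop = FALSE])
  mask2 <- if (rate > 0) {
    matrix((stats::runif(2 * H * n) >= rate) / (1 - rate), 2 * H, n)
  } else NULL
  H2d <- if (is.null(mask2)) H2 else H2 * mask2
  P <- t(model$proj_W %*% H2d + model$proj_b)
  if (!keep_cache) return(list(P = P))
  list(P = P, cnn = cnn_caches, mask1 = mask1, mask2 = mask2,
       runf = runf, runb = runb, H2d = H2d, Wf = cf$W, Wb = cb$W, enc = enc)
}

#' Emission matrix for one sentence
#'
#' Runs the full embedding + BiLSTM + projection stack on a sentence and
#' returns the `n x m` emission matrix the CRF decodes. With
#' `train_mode = FALSE` (or dropout 0) the computation is deterministic.
#'
#' @param sentence a [ner_sentence()] with `pos` and `dict` columns filled.
#' @param model a [ner_model()][init_model()].
#' @param train_mode apply dropout (drawn from the current RNG stream)?
#' @return `n x m` emission matrix.
#' @export
forward_pass <- function(sentence, model, train_mode = FALSE) {
  stopifnot(inherits(sentence, "ner_sentence"))
  if (anyNA(sentence$pos) || anyNA(sentence$dict)) {
    stop("sentence is missing pos or dict features")
  }
  model_forward(encode_sentence(sentence, model), model,
                train_mode = train_mode)$P
}

# Backprop through the whole network given dP (n x m). Small dense gradients
# are accumulated into `acc` (an environment) immediately; the large LSTM
# weight gradients and the sparse embedding-row gradients are appended to
# lists in `acc` and pooled into single GEMMs / rowsums once per mini-batch
# (see training.R).
model_backward <- function(cache, dP, model, acc) {
  cfg <- model$config
  enc <- cache$enc
  n <- enc$n
  H <- cfg$lstm_hidden
  dPt <- t(dP)
  acc$proj_W <- acc$proj_W + dPt %*% t(cache$H2d)
  acc$proj_b <- acc$proj_b + rowSums(dPt)
  dH2d <- crossprod(model$proj_W, dPt)
  dH2 <- if (is.null(cache$mask2)) dH2d else dH2d * cache$mask2
  bf <- lstm_backward(dH2[1:H, , drop = FALSE], cache$runf, cache$Wf, H)
  bb <- lstm_backward(dH2[(H + 1):(2 * H), n:1, drop = FALSE],
                      cache$runb, cache$Wb, H)
  acc$DZf[[length(acc$DZf) + 1L]] <- bf$DZ
  acc$Mf[[length(acc$Mf) + 1L]] <- bf$M
  acc$DZb[[length(acc$DZb) + 1L]] <- bb$DZ
  acc$Mb[[length(acc$Mb) + 1L]] <- bb$M
  dEd <- bf$dX + bb$dX[, n:1, drop = FALSE]
  dE <- if (is.null(cache$mask1)) dEd else dEd * cache$mask1

  i_word <- 1:cfg$word_dim
  i_char <- cfg$word_dim + seq_len(cfg$filter_deep)
  i_pos <- cfg$word_dim + cfg$filter_deep + seq_len(cfg$pos_dim)
  i_dict <- cfg$word_dim + cfg$filter_deep + cfg$pos_dim + seq_len(cfg$dict_dim)

  acc$word_ids <- c(acc$word_ids, enc$word_ids)
  acc$word_g[[length(acc$word_g) + 1L]] <- t(dE[i_word, , drop = FALSE])
  acc$pos_ids <- c(acc$pos_ids, enc$pos_ids)
  acc$pos_g[[length(acc$pos_g) + 1L]] <- t(dE[i_pos, , drop = FALSE])
  acc$dict_ids <- c(acc$dict_ids, enc$dict_ids)
  acc$dict_g[[length(acc$dict_g) + 1L]] <- t(dE[i_dict, , drop = FALSE])

  dC <- dE[i_char, , drop = FALSE]
  for (t in seq_len(n)) {
    g <- char_cnn_backward(dC[, t], cache$cnn[[t]], model$cnn$W1,
                           cfg$filter_size, cfg$char_dim)
    if (is.null(g)) next
    acc$cnn_W1 <- acc$cnn_W1 + g$dW1
    acc$cnn_b1 <- acc$cnn_b1 + g$db1
    acc$char_ids <- c(acc$char_ids, g$ids)
    acc$char_g[[length(acc$char_g) + 1L]] <- g$rows
  }
  invisible(NULL)
}

#' Predict IOB2 tags for sentences
#'
#' Viterbi-decodes each sentence under the trained model. The CRF's start /
#' end handling and learned transitions make the output a valid IOB2
#' sequence in practice; it is nevertheless passed through the standard
#' repair as a guarantee.
#'
#' @param model a trained `ner_model`.
#' @param corpus a [ner_corpus()] with `pos` and `dict` columns filled.
#' @return The corpus with each sentence's `tag` column replaced by the
#'   predicted tags (the tag alphabet becomes the model's).
#' @export
predict_corpus <- function(model, corpus) {
  stopifnot(inherits(model, "ner_model"), inherits(corpus, "ner_corpus"))
  tags <- model$tag_alphabet
  corpus$sentences <- lapply(corpus$sentences, function(s) {
    if (s$n == 0L) return(s)
    P <- forward_pass(s, model, train_mode = FALSE)
    y <- viterbi_decode(P, model$crf)$tags
    pred <- tags[y]
    if (validate_iob2(pred) > 0L) {
      warning("predicted sequence needed IOB2 repair")
      pred <- spans_to_tags(tags_to_spans(pred), s$n)
    }
    s$tag <- pred
    s
  })
  corpus$tag_alphabet <- tags
  corpus
}
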