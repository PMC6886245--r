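test_that("batching partitions the corpus with seed-deterministic order", {
  set.seed(1)
  b <- make_batches(10L, 4L)
  expect_equal(lengths(b), c(4L, 4L, 2L))
  expect_setequal(unlist(b), 1:10)
  set.seed(7); b1 <- make_batches(20L, 6L)
  set.seed(7); b2 <- make_batches(20L, 6L)
  expect_identical(b1, b2)
  expect_error(make_batches(0L, 4L), "empty")
  expect_error(make_batches(5L, 0L), "batch_size")
})

test_that("accumulated batch loss equals the sum of per-sentence losses", {
  set.seed(12)
  cfg <- synth_config(n_sentences = 8, seed = 3)
  lx <- generate_lexicon(cfg)
  co <- generate_corpus(cfg, lx)
  model <- tiny_model(co)
  model$config$dropout <- 0
  encs <- lapply(co$sentences, bacner:::encode_sentence, model = model)
  per_sentence <- vapply(encs, function(e) {
    crf_nll(bacner:::model_forward(e, model)$P, model$crf, e$tag_ids)
  }, 0)
  batch_total <- net_loss(model, encs)
  expect_equal(batch_total, sum(per_sentence), tolerance = 1e-10)
})

test_that("early stopping fires only after `patience` sub-tolerance epochs", {
  expect_true(early_stop(c(80, 81, 81, 81, 81, 81, 81), patience = 5))
  expect_false(early_stop(c(80, 81, 81, 81, 81, 81), patience = 5))
  expect_false(early_stop(c(80, 81, 82, 83, 84, 85, 86), patience = 5))
  tol <- 1e-4
  expect_true(early_stop(c(80, rep(80 + tol / 2, 5)), patience = 5, tol = tol))
  expect_false(early_stop(numeric(), patience = 3))
  expect_error(early_stop(c(1, 2), patience = 0), "patience")
})

make_toy_sets <- function() {
  cfg <- synth_config(n_genera = 6, n_species_per_genus = 3,
                      n_sentences = 30, len_range = c(5, 9),
                      entities_range = c(1, 2), oov_entity_rate = 0,
                      abbrev_rate = 0, seed = 21)
  lx <- generate_lexicon(cfg)
  list(train = generate_corpus(cfg, lx),
       dev = generate_corpus(synth_config(n_genera = 6, n_species_per_genus = 3,
                                          n_sentences = 10, len_range = c(5, 9),
                                          entities_range = c(1, 2),
                                          oov_entity_rate = 0, abbrev_rate = 0,
                                          seed = 22), lx))
}

toy_config <- function(dropout = 0.2, ...) {
  model_config(word_dim = 16, char_dim = 8, pos_dim = 6, dict_dim = 4,
               filter_deep = 10, lstm_hidden = 12, batch_size = 8,
               dropout = dropout, seed = 5, ...)
}

test_that("a tiny model memorizes a toy corpus to perfect span F1", {
  sets <- make_toy_sets()
  fit <- train(sets$train, sets$train, toy_config(max_epochs = 30, lr = 0.01))
  expect_equal(max(fit$history$dev_f1), 100)
  rep <- evaluate_corpus(sets$train, fit$model)
  expect_equal(rep$f1, 100)
})

test_that("zero learning rate leaves parameters unchanged and loss flat", {
  sets <- make_toy_sets()
  cfg <- toy_config(max_epochs = 3, lr = 0, dropout = 0)
  fit <- train(sets$train, sets$dev, cfg)
  set.seed(cfg$seed)
  init <- init_model(sets$train, cfg)
  expect_equal(bacner:::get_params(fit$model), bacner:::get_params(init))
  expect_equal(fit$history$loss, rep(fit$history$loss[1], 3), tolerance = 1e-9)
})

test_that("training is seed-deterministic end to end", {
  sets <- make_toy_sets()
  cfg <- toy_config(max_epochs = 3)
  fit1 <- train(sets$train, sets$dev, cfg)
  fit2 <- train(sets$train, sets$dev, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(bacner:::get_params(fit1$model),
                   bacner:::get_params(fit2$model))
})

test_that("history tracks the learning-rate decay schedule and best epoch", {
  sets <- make_toy_sets()
  cfg <- toy_config(max_epochs = 4, decay = 0.9)
  fit <- train(sets$train, sets$dev, cfg)
  expect_equal(fit$history$lr, cfg$lr * 0.9^(0:3), tolerance = 1e-12)
  expect_true(all(is.finite(fit$history$loss)))
  # best_epoch attains the maximum recorded dev F1 (up to the improvement
  # tolerance used to update it)
  expect_lte(max(fit$history$dev_f1) - fit$history$dev_f1[fit$best_epoch],
             cfg$tol)
})

test_that("returned model carries best-epoch (not last-epoch) parameters", {
  sets <- make_toy_sets()
  cfg <- toy_config(max_epochs = 6, lr = 0.01)
  fit <- train(sets$train, sets$dev, cfg)
  rep <- evaluate_corpus(sets$dev, fit$model)
  expect_equal(rep$f1, fit$history$dev_f1[fit$best_epoch], tolerance = 1e-9)
})

test_that("checkpoints round-trip the full model", {
  sets <- make_toy_sets()
  fit <- train(sets$train, sets$dev, toy_config(max_epochs = 2))
  f <- tempfile(fileext = ".rds")
  save_checkpoint(fit$model, f)
  back <- load_checkpoint(f)
  expect_identical(bacner:::get_params(back), bacner:::get_params(fit$model))
  s <- sets$dev$sentences[[1]]
  expect_equal(forward_pass(s, back), forward_pass(s, fit$model))
  saveRDS(list(1), f)
  expect_error(load_checkpoint(f), "checkpoint")
})

test_that("pre-trained word vectors are copied into matching vocabulary rows", {
  co <- tiny_corpus()
  cfg <- model_config(word_dim = 4, char_dim = 4, pos_dim = 3, dict_dim = 2,
                      filter_deep = 5, lstm_hidden = 6, seed = 2)
  wv <- list(vocab = c("gingivalis", "notinvocab"),
             matrix = rbind(c(1, 2, 3, 4), c(9, 9, 9, 9)))
  model <- init_model(co, cfg, word_vectors = wv)
  row <- bacner:::lookup_ids(model$word, "gingivalis")
  expect_equal(model$word$matrix[row, ], c(1, 2, 3, 4))
  expect_error(init_model(co, cfg, list(vocab = "x", matrix = matrix(0, 1, 3))),
               "dimension")
})
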