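#!/usr/bin/env Rscript
# Full training protocol for an externally released bacterial-NER corpus.
#
# Expects a directory of 4-column CoNLL-style files (train / dev / test; dev
# is carved from train as a 20% tail split if absent), optionally a lexicon
# file for recomputing dictionary features and a word2vec text file of
# pre-trained vectors. Runs the reference configuration (300/25/25/5
# embeddings, 30 kernels of width 3, 100-unit BiLSTM, dropout 0.5, Adam
# lr 0.001 with decay 0.9, patience 5) and prints span-level P/R/F1.
#
# Usage:
#   Rscript full_protocol.R --data DIR [--lexicon FILE] [--embeddings FILE]
#                           [--seed N] [--out report.tsv]

suppressPackageStartupMessages(library(bacner))

args <- commandArgs(trailingOnly = TRUE)
opt <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[[i + 1L]]
}
data_dir <- opt("--data")
if (is.null(data_dir)) stop("--data DIR is required")
seed <- as.integer(opt("--seed", "1"))

find_file <- function(stem) {
  hits <- list.files(data_dir, pattern = paste0("^", stem, "\\.(txt|conll|tsv)$"),
                     full.names = TRUE)
  if (length(hits)) hits[[1L]] else NULL
}

train_path <- find_file("train")
if (is.null(train_path)) stop("no train.{txt,conll,tsv} under ", data_dir)
train_set <- read_conll(train_path)
dev_path <- find_file("dev")
if (is.null(dev_path)) {
  n <- length(train_set$sentences)
  cut <- floor(0.8 * n)
  dev_set <- ner_corpus(train_set$sentences[(cut + 1L):n],
                        train_set$tag_alphabet)
  train_set <- ner_corpus(train_set$sentences[1:cut], train_set$tag_alphabet)
  message("no dev split found; using a 20% tail split of train")
} else {
  dev_set <- read_conll(dev_path)
}
test_path <- find_file("test")
test_set <- if (is.null(test_path)) dev_set else read_conll(test_path)

lex_path <- opt("--lexicon")
if (!is.null(lex_path)) {
  lex <- load_lexicon(lex_path)
  train_set <- attach_dict(train_set, lex)
  dev_set <- attach_dict(dev_set, lex)
  test_set <- attach_dict(test_set, lex)
}

wv_path <- opt("--embeddings")
wv <- if (!is.null(wv_path)) load_word2vec(wv_path)

fit <- train(train_set, dev_set, model_config(seed = seed),
             word_vectors = wv, verbose = TRUE)
rep <- evaluate_corpus(test_set, fit$model)
print(rep)
out <- opt("--out")
if (!is.null(out)) write_report(rep, out)
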