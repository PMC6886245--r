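# The 9-token example sentence with its four printed columns.
table1_lines <- function() {
  c("Actinobacillus\tNNP\tB-bacteria\tB-bacteria",
    "actinomycetemcomitans\tNNS\tI-bacteria\tI-bacteria",
    ",\t,\tO\tO",
    "Porphyromonas\tNNP\tB-bacteria\tB-bacteria",
    "gingivalis\tNN\tI-bacteria\tI-bacteria",
    ",\t,\tO\tO",
    "and\tCC\tO\tO",
    "Peptostreptococcus\tNNP\tB-bacteria\tB-bacteria",
    "micros\tNNS\tI-bacteria\tI-bacteria")
}

table1_file <- function() {
  f <- tempfile(fileext = ".conll")
  writeLines(table1_lines(), f)
  f
}

table1_lexicon <- function() {
  ner_lexicon(c("Actinobacillus actinomycetemcomitans",
                "Porphyromonas gingivalis",
                "Peptostreptococcus micros"))
}

# Random corpus for I/O round-trip tests.
random_corpus <- function(n_sentences, max_len = 8) {
  vocab <- c("alpha", "beta", "gamma", "delta", ",", "x1", "longtokenname")
  sentences <- lapply(seq_len(n_sentences), function(i) {
    n <- sample.int(max_len, 1)
    tags <- rep("O", n)
    if (n >= 2 && runif(1) < 0.8) {
      s <- sample.int(n - 1, 1)
      tags[s] <- "B-bacteria"; tags[s + 1] <- "I-bacteria"
    }
    ner_sentence(sample(vocab, n, replace = TRUE),
                 sample(c("NN", "DT", "JJ"), n, replace = TRUE),
                 sample(c("O", "B-bacteria"), n, replace = TRUE),
                 tags)
  })
  ner_corpus(sentences)
}

# Random non-overlapping span set over n tokens (for round-trip properties).
random_span_set <- function(n, types = c("bacteria", "gene")) {
  spans <- data.frame(start = integer(), end = integer(), type = character())
  i <- 1L
  while (i <= n) {
    if (runif(1) < 0.4) {
      len <- sample.int(min(3L, n - i + 1L), 1)
      spans <- rbind(spans, data.frame(start = i, end = i + len - 1L,
                                       type = sample(types, 1)))
      i <- i + len + 1L   # gap so B/I boundaries stay unambiguous-free
    } else i <- i + 1L
  }
  spans
}

# --- independent CRF oracle: literal enumeration over all m^n paths ------
# Scores computed by explicit summation, independent of the package's
# recursions.
enum_path_scores <- function(P, crf) {
  n <- nrow(P); m <- crf$m
  paths <- as.matrix(expand.grid(rep(list(seq_len(m)), n)))
  Tm <- crf$T
  apply(paths, 1, function(y) {
    s <- Tm[crf$start, y[1]] + Tm[y[n], crf$end]
    for (t in seq_len(n)) s <- s + P[t, y[t]]
    if (n > 1) for (t in seq_len(n - 1)) s <- s + Tm[y[t], y[t + 1]]
    s
  }) -> scores
  list(paths = paths, scores = scores)
}

# --- independent greedy maximum-matching oracle --------------------------
# Linear scan over raw entry token lists; no trie/hash, no shared code.
oracle_max_match <- function(tokens, entries, direction) {
  toks <- tolower(tokens)
  ents <- lapply(strsplit(tolower(entries), " ", fixed = TRUE), identity)
  lmax <- if (length(ents)) max(lengths(ents)) else 0L
  is_entry <- function(seg) {
    any(vapply(ents, function(e) identical(e, seg), TRUE))
  }
  out <- NULL
  if (direction == "forward") {
    i <- 1L
    while (i <= length(toks)) {
      found <- 0L
      for (l in rev(seq_len(min(lmax, length(toks) - i + 1L)))) {
        if (is_entry(toks[i:(i + l - 1L)])) { found <- l; break }
      }
      if (found) { out <- rbind(out, c(i, i + found - 1L)); i <- i + found }
      else i <- i + 1L
    }
  } else {
    j <- length(toks)
    while (j >= 1L) {
      found <- 0L
      for (l in rev(seq_len(min(lmax, j)))) {
        if (is_entry(toks[(j - l + 1L):j])) { found <- l; break }
      }
      if (found) { out <- rbind(c(j - found + 1L, j), out); j <- j - found }
      else j <- j - 1L
    }
  }
  if (is.null(out)) data.frame(start = integer(), end = integer())
  else data.frame(start = out[, 1], end = out[, 2])
}

# --- independent span scorer (conlleval-style, straight off the tags) ----
oracle_entities <- function(tags) {
  out <- character()
  i <- 1L
  while (i <= length(tags)) {
    if (startsWith(tags[i], "B-")) {
      ty <- sub("^B-", "", tags[i])
      j <- i
      while (j + 1L <= length(tags) && tags[j + 1L] == paste0("I-", ty)) {
        j <- j + 1L
      }
      out <- c(out, paste(ty, i, j))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

oracle_counts <- function(gold_tags, pred_tags) {
  g <- oracle_entities(gold_tags)
  p <- oracle_entities(pred_tags)
  tp <- length(intersect(g, p))
  c(tp = tp, fp = length(p) - tp, fn = length(g) - tp)
}

# small deterministic model for network tests
tiny_model <- function(corpus, seed = 11, ...) {
  cfg <- model_config(word_dim = 8, char_dim = 5, pos_dim = 4, dict_dim = 3,
                      filter_deep = 6, lstm_hidden = 7, dropout = 0.5,
                      seed = seed, ...)
  init_model(corpus, cfg)
}

tiny_corpus <- function() {
  s1 <- ner_sentence(c("Porphyromonas", "gingivalis", "was", "detected"),
                     c("NNP", "NN", "VBD", "VBN"),
                     c("B-bacteria", "I-bacteria", "O", "O"),
                     c("B-bacteria", "I-bacteria", "O", "O"))
  s2 <- ner_sentence(c("no", "growth"), c("DT", "NN"), c("O", "O"),
                     c("O", "O"))
  ner_corpus(list(s1, s2))
}

# total loss over a corpus as a pure function of the flat parameter list
# (dropout off) — used for finite-difference checks of the full network.
net_loss <- function(model, encs) {
  tot <- 0
  for (e in encs) {
    P <- bacner:::model_forward(e, model)$P
    tot <- tot + crf_nll(P, model$crf, e$tag_ids)
  }
  tot
}
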