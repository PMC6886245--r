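test_that("exact span matching counts TP/FP/FN under the strict rule", {
  g <- data.frame(start = c(1, 4, 8), end = c(2, 5, 9), type = "bacteria")
  expect_equal(unclass(match_spans(g, g))[c("tp", "fp", "fn")],
               list(tp = 3L, fp = 0L, fn = 0L))
  empty <- g[0, ]
  expect_equal(match_spans(g, empty)$fn, 3L)
  expect_equal(match_spans(g, empty)$tp, 0L)
  # boundary error on one span: one TP, one FP, one FN
  g2 <- data.frame(start = c(1, 4), end = c(2, 5), type = "x")
  p2 <- data.frame(start = c(1, 4), end = c(2, 4), type = "x")
  cnt <- match_spans(g2, p2)
  expect_equal(c(cnt$tp, cnt$fp, cnt$fn), c(1L, 1L, 1L))
  # type mismatch is not a match
  p3 <- data.frame(start = 1, end = 2, type = "gene")
  expect_equal(match_spans(g2, p3)$tp, 0L)
  expect_error(match_spans(g2, data.frame(start = c(1, 2), end = c(2, 3),
                                          type = "x")), "overlap")
})

test_that("printed F1 values reproduce from each row's printed P and R", {
  rows <- list(c(88.476, 81.149, 84.654),   # CRF and dictionary
               c(89.443, 82.899, 86.047),   # Spark
               c(90.009, 88.300, 89.146),   # neural baseline
               c(90.502, 88.344, 89.410),   # + pos
               c(90.404, 89.007, 89.700))   # + pos + dict
  for (r in rows) {
    expect_equal(round(f1_score(r[1], r[2]), 3), r[3])
  }
})

test_that("prf applies the zero-division convention and percent scaling", {
  z <- prf(eval_counts(0, 0, 0))
  expect_equal(c(z$precision, z$recall, z$f1), c(0, 0, 0))
  expect_true(z$zero_division)
  r <- prf(eval_counts(3, 1, 2))
  expect_equal(r$precision, 75)
  expect_equal(r$recall, 60)
  expect_false(r$zero_division)
  # harmonic mean lies between P and R
  expect_gte(r$f1, min(r$precision, r$recall))
  expect_lte(r$f1, max(r$precision, r$recall))
  expect_error(eval_counts(-1, 0, 0), "non-negative")
})

test_that("corpus evaluation pools counts over sentences (micro-average)", {
  g1 <- c("B-bacteria", "I-bacteria", "O")
  g2 <- c("O", "B-bacteria", "O", "B-bacteria")
  gold <- ner_corpus(list(ner_sentence(c("a", "b", "c"), tag = g1),
                          ner_sentence(c("d", "e", "f", "g"), tag = g2)))
  pred <- list(g1, c("O", "B-bacteria", "O", "O"))
  rep <- evaluate_corpus(gold, pred)
  # sentence 1: TP 1; sentence 2: TP 1, FN 1 -> pooled 2/0/1
  expect_equal(c(rep$counts$tp, rep$counts$fp, rep$counts$fn), c(2L, 0L, 1L))
  expect_equal(rep$precision, 100)
  expect_equal(rep$recall, 100 * 2 / 3)
  # identity predictions: perfect scores
  perfect <- evaluate_corpus(gold, list(g1, g2))
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1),
               c(100, 100, 100))
  # all-O predictions: zero precision by convention, zero recall
  allo <- evaluate_corpus(gold, list(rep("O", 3), rep("O", 4)))
  expect_equal(c(allo$precision, allo$recall), c(0, 0))
  expect_true(allo$zero_division)
  expect_error(evaluate_corpus(gold, list(g1)), "counts differ")
  expect_error(evaluate_corpus(gold, list(g1, g1)), "length")
})

test_that("micro counts equal those on the concatenation of all sentences", {
  set.seed(202)
  alpha <- c("O", "B-bacteria", "I-bacteria")
  for (i in 1:30) {
    gold_tags <- lapply(1:4, function(j) {
      spans_to_tags(random_span_set(8, types = "bacteria"), 8)
    })
    pred_tags <- lapply(1:4, function(j) sample(alpha, 8, replace = TRUE))
    gold <- ner_corpus(lapply(gold_tags, function(tg) {
      ner_sentence(letters[1:8], tag = tg)
    }))
    rep <- evaluate_corpus(gold, pred_tags)
    # concatenation with O separators so no spans merge across sentences
    cat_g <- unlist(lapply(gold_tags, c, "O"))
    cat_p <- unlist(lapply(pred_tags, function(x) {
      c(spans_to_tags(tags_to_spans(x), length(x)), "O")
    }))
    cnt <- match_spans(tags_to_spans(cat_g), tags_to_spans(cat_p))
    expect_equal(rep$counts$tp, cnt$tp)
    expect_equal(rep$counts$fn, cnt$fn)
  }
})

test_that("span counts agree with an independent tag-walking scorer", {
  set.seed(303)
  alpha <- c("O", "B-bacteria", "I-bacteria", "B-gene", "I-gene")
  for (i in 1:100) {
    n <- sample(1:12, 1)
    gt <- sample(alpha, n, replace = TRUE)
    pt <- sample(alpha, n, replace = TRUE)
    # repair both so the comparison is over valid IOB2
    gt <- spans_to_tags(tags_to_spans(gt), n)
    pt <- spans_to_tags(tags_to_spans(pt), n)
    cnt <- match_spans(tags_to_spans(gt), tags_to_spans(pt))
    orc <- oracle_counts(gt, pt)
    expect_equal(c(cnt$tp, cnt$fp, cnt$fn), unname(orc))
  }
})

test_that("reports write as key-value text at full precision", {
  rep <- prf(eval_counts(2, 1, 1))
  f <- tempfile()
  write_report(rep, f)
  kv <- read.delim(f, header = FALSE, col.names = c("key", "value"))
  expect_equal(as.numeric(kv$value[kv$key == "precision"]), 100 * 2 / 3,
               tolerance = 1e-9)
  expect_equal(as.integer(kv$value[kv$key == "tp"]), 2L)
})
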