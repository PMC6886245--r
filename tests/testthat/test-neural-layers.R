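test_that("uniform initialization respects the sqrt(3/dim) bound and moments", {
  set.seed(1)
  E <- init_uniform(10, 3)
  expect_true(all(abs(E) <= 1))          # sqrt(3/3) = 1
  E2 <- init_uniform(1e4, 25)
  r <- sqrt(3 / 25)
  expect_true(max(abs(E2)) <= r)
  sigma <- sqrt((2 * r)^2 / 12)
  expect_lt(abs(mean(E2)), 3 * sigma / sqrt(length(E2)))
  expect_error(init_uniform(4, 0), "positive")
})

test_that("embedding tables route unknown symbols to the <unk> row", {
  set.seed(2)
  tab <- embedding_table(c("a", "b"), 4)
  ids <- bacner:::lookup_ids(tab, c("b", "zzz", "a"))
  expect_equal(tab$vocab[ids[2]], "<unk>")
  expect_equal(tab$vocab[ids[c(1, 3)]], c("b", "a"))
})

test_that("char-CNN degenerate parameter cases follow relu and max-pool", {
  set.seed(3)
  p <- char_cnn_params(letters, char_dim = 5, k = 3, N = 4)
  pz <- p; pz$W1[] <- 0; pz$b1[] <- 0
  expect_equal(char_cnn_encode("abc", pz), rep(0, 4))
  pn <- pz; pn$b1[2] <- -5
  expect_equal(char_cnn_encode("abc", pn)[2], 0)   # relu clips
  pn$b1[3] <- 2
  expect_equal(char_cnn_encode("abc", pn)[3], 2)
})

test_that("a 1-character word reduces to a single padded window", {
  set.seed(4)
  p <- char_cnn_params(letters, char_dim = 5, k = 3, N = 6)
  out <- char_cnn_encode("q", p)
  e <- p$table$matrix[bacner:::lookup_ids(p$table, "q"), ]
  win <- c(rep(0, 5), e, rep(0, 5))      # pad, e(c), pad
  expect_equal(out, pmax(drop(p$W1 %*% win) + p$b1, 0))
})

test_that("char-CNN output is invariant to explicit trailing pads", {
  set.seed(5)
  p <- char_cnn_params(letters, char_dim = 4, k = 3, N = 5)
  ids <- bacner:::lookup_ids(p$table, strsplit("abc", "")[[1]])
  # once the appended pads are beyond window reach of any real character,
  # every further pad adds only all-pad windows, which contribute
  # relu(b1) = 0 under the zero bias and cannot move the max-pool
  outs <- lapply(0:3, function(extra) {
    bacner:::char_cnn_forward(c(ids, rep(1L, 2L + extra)),
                              p$table$matrix, p$W1, p$b1, 3)$out
  })
  for (k in 2:4) expect_equal(outs[[k]], outs[[1]], tolerance = 1e-12)
})

test_that("lstm_step reproduces hand-evaluated gate equations", {
  H <- 3; D <- 2
  p <- lstm_params(D, H, init = "zero")
  z <- rep(0, H)
  # all-zero parameters: gates are 0.5, candidate 0 -> h = C = 0
  out <- lstm_step(c(1, -2), z, z, p)
  expect_equal(out$h, z)
  expect_equal(out$C, z)
  # zero weights, C_prev = 2: C = f*2 = 1, h = 0.5 * tanh(1)
  out2 <- lstm_step(c(0, 0), z, rep(2, H), p)
  expect_equal(out2$C, rep(1, H))
  expect_equal(out2$h, rep(0.5 * tanh(1), H), tolerance = 1e-6)
  expect_equal(out2$h[1], 0.380797, tolerance = 1e-6)
  # saturated forget gate: perfect memory of the cell
  p3 <- p; p3$b_f <- rep(50, H)
  cprev <- c(0.3, -1, 2)
  out3 <- lstm_step(c(0, 0), z, cprev, p3)
  expect_equal(out3$C, cprev, tolerance = 1e-12)
  expect_error(lstm_step(1, z, z, p), "dimension")
})

test_that("the fast combined-gate recurrence matches step-by-step lstm_step", {
  set.seed(6)
  H <- 4; D <- 3; n <- 5
  p <- lstm_params(D, H)
  X <- matrix(rnorm(D * n), D, n)
  cmb <- bacner:::combine_lstm(p)
  run <- bacner:::lstm_run(X, cmb$W, cmb$b, H)
  h <- rep(0, H); C <- rep(0, H)
  for (t in 1:n) {
    st <- lstm_step(X[, t], h, C, p)
    h <- st$h; C <- st$C
    expect_equal(run$H[, t], h, tolerance = 1e-12)
    expect_equal(run$C[, t], C, tolerance = 1e-12)
  }
})

test_that("bilstm output halves are causal and reverse-symmetric", {
  set.seed(7)
  H <- 4; D <- 3; n <- 6
  pf <- lstm_params(D, H); pb <- lstm_params(D, H)
  X <- matrix(rnorm(D * n), D, n)
  out <- bilstm_encode(X, pf, pb)
  expect_equal(dim(out), c(2 * H, n))
  # n = 1 equals single-step outputs from zero state
  o1 <- bilstm_encode(X[, 1, drop = FALSE], pf, pb)
  z <- rep(0, H)
  expect_equal(o1[1:H, 1], lstm_step(X[, 1], z, z, pf)$h)
  expect_equal(o1[(H + 1):(2 * H), 1], lstm_step(X[, 1], z, z, pb)$h)
  # reversing input with swapped directions reverses and swaps the halves
  rev_out <- bilstm_encode(X[, n:1], pb, pf)
  expect_equal(rev_out[1:H, n:1], out[(H + 1):(2 * H), ], tolerance = 1e-12)
  expect_equal(rev_out[(H + 1):(2 * H), n:1], out[1:H, ], tolerance = 1e-12)
  # causality: perturbing position t0+1 leaves forward half at t0 unchanged
  X2 <- X; X2[, 4] <- X2[, 4] + 10
  out2 <- bilstm_encode(X2, pf, pb)
  expect_equal(out2[1:H, 1:3], out[1:H, 1:3], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(out2[1:H, 4], out[1:H, 4])))
  # zero parameters give zero outputs
  expect_equal(bilstm_encode(X, lstm_params(D, H, "zero"),
                             lstm_params(D, H, "zero")),
               matrix(0, 2 * H, n))
  expect_error(bilstm_encode(matrix(0, D, 0), pf, pb), "non-empty")
})

test_that("emission projection is the plain affine map", {
  set.seed(8)
  Hmat <- matrix(rnorm(12), 4, 3)
  expect_equal(emission_scores(Hmat, matrix(0, 2, 4), rep(0, 2)),
               matrix(0, 3, 2))
  W <- matrix(rnorm(8), 2, 4); b <- rnorm(2)
  P <- emission_scores(Hmat, W, b)
  for (t in 1:3) expect_equal(P[t, ], drop(W %*% Hmat[, t]) + b)
})

test_that("forward_pass has contract shape and inference determinism", {
  set.seed(9)
  co <- tiny_corpus()
  model <- tiny_model(co)
  s <- co$sentences[[1]]
  P1 <- forward_pass(s, model)
  expect_equal(dim(P1), c(4L, 3L))
  expect_identical(P1, forward_pass(s, model))
  # dropout 0 in train mode equals inference
  m0 <- model; m0$config$dropout <- 0
  expect_equal(forward_pass(s, m0, train_mode = TRUE), P1)
  # train-mode dropout changes the result (stochastic masks)
  set.seed(10)
  expect_false(isTRUE(all.equal(forward_pass(s, model, train_mode = TRUE), P1)))
  # missing features are an error
  s_bad <- ner_sentence(c("a", "b"), tag = c("O", "O"))
  expect_error(forward_pass(s_bad, model), "missing")
})
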