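test_that("srn_step matches the recurrence equation", {
  H <- 3
  expect_equal(srn_step(rnorm(H), rnorm(2), matrix(0, H, H),
                        matrix(0, H, 2)),
               rep(0, H))
  v <- c(0.3, -1.2, 0.5)
  expect_equal(srn_step(rep(0, H), v, matrix(0, H, H), diag(H)), tanh(v))
  set.seed(42)
  W_h <- matrix(rnorm(9), 3, 3)
  W_w <- matrix(rnorm(9), 3, 3)
  h <- rnorm(3); w <- rnorm(3)
  oracle <- tanh(sapply(1:3, function(i)
    sum(W_h[i, ] * h) + sum(W_w[i, ] * w)))
  expect_equal(srn_step(h, w, W_h, W_w), oracle, tolerance = 1e-10)
  expect_error(srn_step(h, w, W_h, matrix(0, 3, 5)), "dimension")
})

test_that("lstm_step follows the gating equations and saturation limits", {
  H <- 4
  # all-zero parameters from a zero state: gates at 1/2, candidate 0
  st <- list(h = rep(0, H), c = rep(0, H))
  z0 <- lstm_step(st, rnorm(2), matrix(0, 4 * H, 2 + H), rep(0, 4 * H))
  expect_equal(z0$h, rep(0, H), tolerance = 1e-12)
  expect_equal(z0$c, rep(0, H), tolerance = 1e-12)
  # large negative input/forget preactivations: the cell decays toward 0
  b <- rep(0, 4 * H)
  b[1:(2 * H)] <- -30
  st <- list(h = rep(0, H), c = rep(1, H))
  for (i in 1:5) st <- lstm_step(st, rnorm(2), matrix(0, 4 * H, 2 + H), b)
  expect_lt(max(abs(st$c)), 1e-10)
})

test_that("the C++ encoder agrees with the R step functions", {
  m <- random_model(seed = 9, H = 5)
  ids <- c(4L, 5L, 6L, 4L)
  bos <- match(m$vocab$bos, m$vocab$words)
  hs <- agreesim:::cpp_rnn_hidden(m$params, m$arch, ids, bos)
  st <- list(h = rep(0, 5), c = rep(0, 5))
  inputs <- c(bos, ids)
  for (t in seq_along(inputs)) {
    st <- lstm_step(st, m$params$emb[inputs[t], ], m$params$Ws[[1]],
                    m$params$bs[[1]])
    expect_equal(unname(hs[t, ]), st$h, tolerance = 1e-6)
  }
  # srn architecture against srn_step
  ms <- random_model(seed = 10, H = 4)
  ms$arch <- "srn"
  ms$encoder$architecture <- "srn"
  ms$params$Ws <- list(matrix(rnorm(4 * 8, sd = 0.3), 4, 8))
  ms$params$bs <- list(rep(0, 4))
  hss <- agreesim:::cpp_rnn_hidden(ms$params, "srn", c(4L, 5L), bos)
  h <- rep(0, 4)
  W <- ms$params$Ws[[1]]
  W_w <- W[, 1:4]; W_h <- W[, 5:8]
  for (t in seq_along(c(bos, 4L, 5L))) {
    h <- srn_step(h, ms$params$emb[c(bos, 4L, 5L)[t], ], W_h, W_w)
    expect_equal(unname(hss[t, ]), h, tolerance = 1e-10)
  }
})

test_that("next-word distributions are proper and match a softmax oracle", {
  m <- random_model(seed = 1, H = 6)
  # all-zero decoder: uniform distribution
  m0 <- m
  m0$params$dec_w[] <- 0
  m0$params$dec_b[] <- 0
  p0 <- next_word_distribution(m0, c("w1", "w2"))
  expect_equal(unname(p0), rep(1 / length(m$vocab$words),
                               length(m$vocab$words)),
               tolerance = 1e-12)
  p <- next_word_distribution(m, c("w1", "w3"))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))
  # softmax oracle through the R-side LSTM chain
  bos <- match(m$vocab$bos, m$vocab$words)
  ids <- tokens_to_ids(m$vocab, c("w1", "w3"))
  st <- list(h = rep(0, 6), c = rep(0, 6))
  for (id in c(bos, ids))
    st <- lstm_step(st, m$params$emb[id, ], m$params$Ws[[1]],
                    m$params$bs[[1]])
  logits <- as.numeric(m$params$dec_w %*% st$h + m$params$dec_b)
  expect_equal(unname(p), exp(logits) / sum(exp(logits)), tolerance = 1e-6)
  # determinism
  expect_identical(p, next_word_distribution(m, c("w1", "w3")))
})

test_that("a small model memorizes a two-sentence corpus", {
  co <- as_corpus(list(c("w1", "w2", "w3"), c("w2", "w4", "w1")))
  v <- build_vocab(co)
  m <- language_model(v, encoder = encoder_config(num_layers = 1,
                                                  hidden_size = 24,
                                                  embedding_size = 12),
                      seed = 2)
  m <- train_lm(m, co, train_config(epochs = 600, lr = 0.5, batch_size = 2,
                                    seed = 1))
  expect_lt(perplexity(m, co), 1.5)
})

test_that("task weighting controls which decoders learn", {
  fx <- tiny_trained()
  small <- generate_corpus(tiny_grammar(41), 200)
  v <- build_vocab(small)
  m <- language_model(v, tagset = grammar_tagset(),
                      encoder = tiny_encoder(8), seed = 3)
  m1 <- train_lm(m, small, train_config(epochs = 1, lr = 0.5, w_tag = 0,
                                        seed = 2))
  expect_identical(m1$params$tag_w, m$params$tag_w)
  expect_identical(m1$params$tag_b, m$params$tag_b)
  expect_false(identical(m1$params$dec_w, m$params$dec_w))
  # equal weighting: both losses decrease over early epochs
  m2 <- train_lm(m, small, train_config(epochs = 3, lr = 0.5, seed = 2))
  expect_true(all(diff(m2$trace$word_loss) < 0))
  expect_true(all(diff(m2$trace$tag_loss) < 0))
})

test_that("training is reproducible given identical seeds", {
  small <- generate_corpus(tiny_grammar(43), 150)
  v <- build_vocab(small)
  run <- function() {
    m <- language_model(v, tagset = grammar_tagset(),
                        encoder = tiny_encoder(8), seed = 4)
    train_lm(m, small, train_config(epochs = 2, lr = 0.5, seed = 9))
  }
  expect_identical(run()$params, run()$params)
})

test_that("perplexity has its closed forms and floors", {
  m <- random_model(seed = 5, H = 4)
  m$params$dec_w[] <- 0
  m$params$dec_b[] <- 0
  co <- as_corpus(list(c("w1", "w2"), c("w3",
                                        "w4", "w1")))
  # uniform model: perplexity equals the vocabulary size
  expect_equal(perplexity(m, co), length(m$vocab$words), tolerance = 1e-9)
  expect_error(perplexity(m, as_corpus(list())), "empty")
  # a trained toy model beats the unigram baseline on held-out text
  fx <- tiny_trained()
  expect_lt(perplexity(fx$multitask, fx$heldout),
            unigram_perplexity(fx$train, fx$heldout, fx$vocab))
})

test_that("supertag accuracy is scored against the frequency baseline", {
  fx <- tiny_trained()
  acc <- supertag_accuracy(fx$multitask, fx$heldout)
  expect_true(acc$accuracy >= 0 && acc$accuracy <= 1)
  expect_true(acc$baseline > 0.5) # per-word majority is strong here
  expect_equal(acc$n, sum(lengths(lapply(fx$heldout$records,
                                         `[[`, "tokens"))))
})

test_that("unit ablation is a non-destructive diagonal mask", {
  fx <- tiny_trained()
  m <- fx$multitask
  H <- m$encoder$hidden_size
  ma <- ablate_unit(m, 3)
  expect_null(m$mask) # original untouched
  expect_equal(sum(ma$mask == 0), 1)
  # mask equivalence: ablation equals projecting with a diagonal mask
  ev1 <- evaluate_lm(ma, fx$heldout)
  ev2 <- evaluate_lm(m, fx$heldout, proj = diag(ma$mask))
  expect_identical(ev1$surprisal, ev2$surprisal)
  # a unit with zero outgoing decoder weights does not matter
  mz <- m
  mz$params$dec_w[, 5] <- 0
  mz$params$tag_w[, 5] <- 0
  expect_identical(evaluate_lm(ablate_unit(mz, 5), fx$heldout)$surprisal,
                   evaluate_lm(mz, fx$heldout)$surprisal)
  # ablating every unit: the decoder sees a zero vector -> softmax(bias)
  mall <- m
  mall$mask <- rep(0, H)
  p <- next_word_distribution(mall, c("the"))
  bias <- m$params$dec_b
  expect_equal(unname(p), exp(bias - max(bias)) / sum(exp(bias - max(bias))),
               tolerance = 1e-9)
  expect_error(ablate_unit(m, H + 1), "unit index")
})

test_that("analytic gradients match central finite differences", {
  cfg <- grammar_config(n_nouns = 3, n_verbs = 2, n_prepositions = 2,
                        n_adjectives = 2, seed = 11)
  co <- generate_corpus(cfg, 4)
  v <- build_vocab(co)
  for (arch in c("lstm", "srn")) {
    enc <- encoder_config(architecture = arch, num_layers = 2,
                          hidden_size = 3, embedding_size = 2,
                          init_scale = 0.5)
    m <- language_model(v, tagset = grammar_tagset(), encoder = enc,
                        seed = 2)
    res <- lm_loss_grad(m, co, 1, 1)
    blocks <- list("emb", c("Ws", 1), c("Ws", 2), c("bs", 1), c("bs", 2),
                   "dec_w", "dec_b", "tag_w", "tag_b")
    set.seed(7)
    for (path in blocks) {
      getb <- function(x) if (length(path) == 1) x[[path]] else
        x[[path[1]]][[as.integer(path[2])]]
      setb <- function(mm, bb) {
        if (length(path) == 1) mm$params[[path]] <- bb
        else mm$params[[path[1]]][[as.integer(path[2])]] <- bb
        mm
      }
      blk <- getb(m$params)
      gblk <- getb(res$grads)
      idx <- sample(length(blk), min(4, length(blk)))
      eps <- 1e-5
      for (i in idx) {
        b1 <- blk; b1[i] <- b1[i] + eps
        b2 <- blk; b2[i] <- b2[i] - eps
        fd <- (lm_loss_grad(setb(m, b1), co)$loss -
                 lm_loss_grad(setb(m, b2), co)$loss) / (2 * eps)
        expect_lt(abs(fd - gblk[i]) / (1e-6 + max(abs(gblk))), 1e-4)
      }
    }
  }
})
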