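#' Encoder configuration
#'
#' @param architecture `"lstm"` (default) or `"srn"`. The SRN merges the
#'   previous hidden state and the current input embedding through a single
#'   tanh layer, `h_i = tanh(W_h h_{i-1} + W_w w_i)`; the LSTM uses standard
#'   gating (input, forget, output gates and a tanh candidate cell).
#' @param num_layers number of recurrent layers (default 2).
#' @param hidden_size units per layer (default 650, the scale used for
#'   full-size simulations; tests and toy pipelines use smaller values).
#' @param embedding_size word-embedding dimension; defaults to
#'   `hidden_size`.
#' @param init_scale half-width of the uniform initialization interval.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(architecture = c("lstm", "srn"), num_layers = 2,
                           hidden_size = 650, embedding_size = NULL,
                           init_scale = 0.1) {
  architecture <- match.arg(architecture)
  num_layers <- assert_count(num_layers, "num_layers")
  hidden_size <- assert_count(hidden_size, "hidden_size")
  embedding_size <- assert_count(embedding_size %||% hidden_size,
                                 "embedding_size")
  structure(list(architecture = architecture, num_layers = num_layers,
                 hidden_size = hidden_size, embedding_size = embedding_size,
                 init_scale = init_scale),
            class = "encoder_config")
}

#' Training configuration
#'
#' The combined objective is `w_word * mean word cross-entropy + w_tag *
#' mean supertag cross-entropy` (means over tokens). Equal weighting of the
#' two tasks is the default. The learning rate is multiplied by
#' `lr_decay` after every epoch and halved whenever the epoch's training
#' loss fails to improve.
#'
#' @param epochs training epochs (default 12).
#' @param lr initial learning rate for plain SGD.
#' @param lr_decay multiplicative per-epoch decay.
#' @param batch_size sentences per minibatch.
#' @param w_word,w_tag task weights (>= 0) for word prediction and
#'   supertagging.
#' @param seed integer seed for shuffling (and, via [train_instances()],
#'   for initialization).
#' @param n_instances number of independently initialized model instances
#'   trained per configuration (default 5).
#' @param clip global gradient-norm clipping threshold.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 12, lr = 1, lr_decay = 1, batch_size = 32,
                         w_word = 1, w_tag = 1, seed = 1L, n_instances = 5,
                         clip = 5) {
  stopifnot(w_word >= 0, w_tag >= 0)
  structure(list(epochs = assert_count(epochs, "epochs"),
                 lr = lr, lr_decay = lr_decay,
                 batch_size = assert_count(batch_size, "batch_size"),
                 w_word = w_word, w_tag = w_tag, seed = as.integer(seed),
                 n_instances = assert_count(n_instances, "n_instances"),
                 clip = clip),
            class = "train_config")
}

#' Initialize a recurrent language model
#'
#' Parameters are drawn uniformly from `[-init_scale, init_scale]`; LSTM
#' forget-gate biases are initialized to 1 so early training does not
#' discard state.
#'
#' @param vocab an [build_vocab()] vocabulary.
#' @param tagset optional character vector of supertags; when supplied the
#'   model carries a second linear decoder that predicts the tag of the
#'   most recent input word (the multi-task "LM+CCG" setting).
#' @param encoder an [encoder_config()].
#' @param seed seed for the random initialization.
#' @return An object of class `agr_lm`.
#' @export
language_model <- function(vocab, tagset = NULL, encoder = encoder_config(),
                           seed = 1L) {
  stopifnot(inherits(vocab, "agr_vocab"))
  V <- length(vocab$words)
  D <- encoder$embedding_size
  H <- encoder$hidden_size
  L <- encoder$num_layers
  s <- encoder$init_scale
  lstm <- encoder$architecture == "lstm"
  params <- with_seed(seed, {
    rmat <- function(r, c) matrix(runif(r * c, -s, s), r, c)
    Ws <- vector("list", L)
    bs <- vector("list", L)
    for (l in seq_len(L)) {
      din <- if (l == 1) D else H
      rows <- if (lstm) 4L * H else H
      Ws[[l]] <- rmat(rows, din + H)
      b <- numeric(rows)
      if (lstm) b[(H + 1):(2 * H)] <- 1 # forget gate bias
      bs[[l]] <- b
    }
    p <- list(emb = rmat(V, D), Ws = Ws, bs = bs,
              dec_w = rmat(V, H), dec_b = numeric(V))
    if (!is.null(tagset)) {
      p$tag_w <- rmat(length(tagset), H)
      p$tag_b <- numeric(length(tagset))
    } else {
      p$tag_w <- NULL
      p$tag_b <- NULL
    }
    p
  })
  structure(list(params = params, arch = encoder$architecture,
                 vocab = vocab, tagset = tagset, encoder = encoder,
                 seed = as.integer(seed), mask = NULL, instance = NA_integer_,
                 trace = NULL),
            class = "agr_lm")
}

#' @export
print.agr_lm <- function(x, ...) {
  cat(sprintf("<agr_lm> %s, %d x %d, |V| = %d%s%s\n", x$arch,
              x$encoder$num_layers, x$encoder$hidden_size,
              length(x$vocab$words),
              if (!is.null(x$tagset)) sprintf(", %d supertags",
                                              length(x$tagset)) else "",
              if (!is.null(x$mask)) " [ablated]" else ""))
  invisible(x)
}

# Effective projection applied to the final hidden state, or NULL.
#' @noRd
proj_matrix <- function(model) {
  if (is.null(model$mask)) NULL else diag(model$mask)
}

# Convert a corpus to 1-based id lists for the C++ core.
#' @noRd
corpus_ids <- function(model, corpus, need_tags = FALSE) {
  sents <- lapply(corpus$records, function(r)
    tokens_to_ids(model$vocab, r$tokens))
  tags <- NULL
  if (need_tags) {
    if (is.null(model$tagset))
      stop("model has no supertag decoder/tagset", call. = FALSE)
    tags <- lapply(corpus$records, function(r) {
      ti <- match(r$supertags, model$tagset)
      if (anyNA(ti))
        stop("corpus contains supertags outside the model's tagset",
             call. = FALSE)
      ti
    })
  }
  list(sents = sents, tags = tags)
}

#' One step of a simple recurrent network
#'
#' Computes `tanh(W_h %*% h_prev + W_w %*% w)`, the SRN state update.
#'
#' @param h_prev previous hidden state (length H).
#' @param w input embedding vector.
#' @param W_h,W_w recurrence and input weight matrices.
#' @return The new hidden state, elementwise in (-1, 1).
#' @export
srn_step <- function(h_prev, w, W_h, W_w) {
  if (ncol(W_h) != length(h_prev) || ncol(W_w) != length(w) ||
      nrow(W_h) != nrow(W_w))
    stop("dimension mismatch in srn_step", call. = FALSE)
  as.numeric(tanh(W_h %*% h_prev + W_w %*% w))
}

#' One step of an LSTM cell
#'
#' Reference implementation of the gating equations used throughout the
#' package: with `z = [w; h_prev]` and preactivations `W %*% z + b` split
#' into four blocks, `i = sigmoid`, `f = sigmoid`, `g = tanh`,
#' `o = sigmoid`; `c = f * c_prev + i * g`; `h = o * tanh(c)`.
#'
#' @param state list with elements `h` and `c` (each length H).
#' @param w input vector.
#' @param W weight matrix of shape `4H x (length(w) + H)`.
#' @param b bias vector of length `4H`.
#' @return List with the new `h` and `c`.
#' @export
lstm_step <- function(state, w, W, b) {
  H <- length(state$h)
  if (nrow(W) != 4 * H || ncol(W) != length(w) + H || length(b) != 4 * H)
    stop("dimension mismatch in lstm_step", call. = FALSE)
  pre <- as.numeric(W %*% c(w, state$h) + b)
  i <- plogis(pre[1:H])
  f <- plogis(pre[(H + 1):(2 * H)])
  g <- tanh(pre[(2 * H + 1):(3 * H)])
  o <- plogis(pre[(3 * H + 1):(4 * H)])
  cc <- f * state$c + i * g
  list(h = o * tanh(cc), c = cc)
}

#' Next-word probability distribution
#'
#' Runs the encoder over `<s>` followed by the prefix and decodes the final
#' hidden state (after any ablation mask) into a probability distribution
#' over the vocabulary.
#'
#' @param model an `agr_lm`.
#' @param prefix character vector of tokens (may be empty: the start symbol
#'   alone conditions the first prediction). Out-of-vocabulary tokens map
#'   to the unknown token.
#' @return Named numeric vector of probabilities summing to 1.
#' @export
next_word_distribution <- function(model, prefix = character(0)) {
  ids <- if (length(prefix)) tokens_to_ids(model$vocab, prefix) else integer(0)
  bos <- match(model$vocab$bos, model$vocab$words)
  hs <- cpp_rnn_hidden(model$params, model$arch, as.integer(ids), bos)
  h <- hs[nrow(hs), ]
  if (!is.null(model$mask)) h <- h * model$mask
  logits <- as.numeric(model$params$dec_w %*% h + model$params$dec_b)
  z <- logits - max(logits)
  p <- exp(z) / sum(exp(z))
  names(p) <- model$vocab$words
  p
}

#' Evaluate a model over a corpus
#'
#' @param model an `agr_lm`.
#' @param corpus an `agr_corpus`.
#' @param proj optional H x H matrix applied to the final hidden state
#'   before both decoders (overrides any ablation mask on the model).
#' @param tags whether to evaluate the supertag decoder as well (requires a
#'   multitask model).
#' @return List with `word_loss` (mean nats/token, end-of-sentence
#'   predictions included), `perplexity`, `surprisal` (per-sentence vectors
#'   in bits, one value per token plus the end symbol), and, with
#'   `tags = TRUE`, `tag_loss`, `tag_accuracy` and `tag_pred`.
#' @export
evaluate_lm <- function(model, corpus, proj = NULL, tags = FALSE) {
  stopifnot(inherits(model, "agr_lm"), inherits(corpus, "agr_corpus"))
  ids <- corpus_ids(model, corpus, need_tags = tags)
  proj <- proj %||% proj_matrix(model)
  bos <- match(model$vocab$bos, model$vocab$words)
  eos <- match(model$vocab$eos, model$vocab$words)
  res <- cpp_rnn_eval(model$params, model$arch, ids$sents, ids$tags,
                      bos, eos, proj)
  out <- list(word_loss = res$word_loss_sum / res$n_word,
              perplexity = exp(res$word_loss_sum / res$n_word),
              n_word = res$n_word,
              surprisal = res$surprisal)
  if (tags) {
    out$tag_loss <- res$tag_loss_sum / res$n_tag
    out$tag_accuracy <- res$tag_correct / res$n_tag
    out$tag_pred <- res$tag_pred
    out$n_tag <- res$n_tag
  }
  out
}

#' Corpus perplexity
#'
#' `2 ^ (mean per-token surprisal in bits)`, equivalently `exp` of the mean
#' per-token cross-entropy in nats; end-of-sentence predictions are
#' included. A token with probability numerically zero yields infinite
#' perplexity.
#'
#' @inheritParams evaluate_lm
#' @return A positive number (possibly `Inf`), always >= 1 for a proper
#'   probability model.
#' @export
perplexity <- function(model, corpus) {
  if (length(corpus$records) == 0) stop("corpus is empty", call. = FALSE)
  evaluate_lm(model, corpus)$perplexity
}

#' Unigram baseline perplexity
#'
#' Laplace-smoothed unigram model estimated on `train`, evaluated on
#' `eval`, including the end-of-sentence symbol; this is the reference a
#' trained sequence model must beat.
#'
#' @param train,eval `agr_corpus` objects.
#' @param vocab the shared vocabulary.
#' @return Perplexity of the unigram model on `eval`.
#' @export
unigram_perplexity <- function(train, eval, vocab) {
  V <- length(vocab$words)
  eos <- match(vocab$eos, vocab$words)
  ids_of <- function(corpus) unlist(lapply(corpus$records, function(r)
    c(tokens_to_ids(vocab, r$tokens), eos)), use.names = FALSE)
  tr <- ids_of(train)
  cnt <- tabulate(tr, nbins = V) + 1 # Laplace smoothing
  logp <- log(cnt / sum(cnt))
  ev <- ids_of(eval)
  exp(-mean(logp[ev]))
}

#' Train a language model
#'
#' Plain SGD over sentence minibatches with full backpropagation through
#' time (sentences are bounded in this grammar, so no truncation is
#' needed). With a multitask model and a tagged corpus the loss is the
#' weighted sum of the two mean cross-entropies; `w_tag = 0` leaves the
#' supertag decoder untouched.
#'
#' @param model an `agr_lm`.
#' @param corpus training corpus.
#' @param config a [train_config()].
#' @return The trained model; `$trace` holds the per-epoch loss trace
#'   (mean nats per token for each task) and learning rates.
#' @export
train_lm <- function(model, corpus, config = train_config()) {
  stopifnot(inherits(model, "agr_lm"), inherits(corpus, "agr_corpus"))
  use_tags <- !is.null(model$tagset) && config$w_tag > 0
  ids <- corpus_ids(model, corpus, need_tags = use_tags)
  bos <- match(model$vocab$bos, model$vocab$words)
  eos <- match(model$vocab$eos, model$vocab$words)
  res <- cpp_rnn_train(model$params, model$arch, ids$sents, ids$tags,
                       bos, eos, config$epochs, config$lr, config$lr_decay,
                       config$batch_size, config$w_word, config$w_tag,
                       config$seed, config$clip)
  if (isTRUE(res$diverged))
    stop("training diverged: non-finite loss encountered; ",
         "lower the learning rate or enable gradient clipping",
         call. = FALSE)
  model$params <- res$params
  model$trace <- data.frame(epoch = seq_along(res$word_loss),
                            word_loss = res$word_loss,
                            tag_loss = res$tag_loss, lr = res$lr)
  model
}

#' Train independently initialized model instances
#'
#' Mirrors the multiple-instance protocol: `config$n_instances` models that
#' differ only in their initialization (and shuffling) seed are trained on
#' the same corpus; downstream statistics treat the instance as a grouping
#' factor.
#'
#' @param vocab,tagset,encoder passed to [language_model()].
#' @param corpus training corpus.
#' @param config a [train_config()]; instance k uses seed
#'   `config$seed + 1000 * k`.
#' @return List of trained `agr_lm` objects with `$instance` set.
#' @export
train_instances <- function(vocab, corpus, config = train_config(),
                            encoder = encoder_config(), tagset = NULL) {
  lapply(seq_len(config$n_instances), function(k) {
    sk <- config$seed + 1000L * k
    m <- language_model(vocab, tagset = tagset, encoder = encoder, seed = sk)
    cfg <- config
    cfg$seed <- sk
    m <- train_lm(m, corpus, cfg)
    m$instance <- k
    m
  })
}

#' Supertag top-1 accuracy and most-frequent-tag baseline
#'
#' The baseline picks, for every word type, the supertag most frequently
#' associated with it in the same evaluation data, ignoring context.
#'
#' @param model a multitask `agr_lm`.
#' @param corpus a tagged `agr_corpus`.
#' @return List with `accuracy`, `baseline` and `n` (tokens scored).
#' @export
supertag_accuracy <- function(model, corpus) {
  ev <- evaluate_lm(model, corpus, tags = TRUE)
  toks <- unlist(lapply(corpus$records, `[[`, "tokens"), use.names = FALSE)
  tags <- unlist(lapply(corpus$records, `[[`, "supertags"),
                 use.names = FALSE)
  tab <- table(toks, tags)
  best <- colnames(tab)[max.col(tab, ties.method = "first")]
  names(best) <- rownames(tab)
  baseline <- mean(best[toks] == tags)
  list(accuracy = ev$tag_accuracy, baseline = baseline, n = ev$n_tag)
}

#' Ablate one unit of the final recurrent layer
#'
#' Returns a non-destructive view of the model in which the chosen unit's
#' output is clamped to 0 before both decoders; the original model is
#' unchanged. Equivalent to multiplying the final hidden state by a
#' diagonal 0/1 mask.
#'
#' @param model an `agr_lm`.
#' @param unit unit index within the final layer (1-based).
#' @return The masked model.
#' @export
ablate_unit <- function(model, unit) {
  H <- model$encoder$hidden_size
  if (!is.numeric(unit) || length(unit) != 1 || unit < 1 || unit > H)
    stop(sprintf("unit index must be in 1..%d", H), call. = FALSE)
  mask <- model$mask %||% rep(1, H)
  mask[unit] <- 0
  model$mask <- mask
  model
}

#' Final-layer hidden states over a corpus
#'
#' One row per input token (after the token has been consumed), so row j of
#' sentence i aligns with the supertag of token j. Used to train frozen
#' probes and for representation analyses.
#'
#' @param model an `agr_lm`.
#' @param corpus an `agr_corpus`.
#' @return List with `h` (matrix, total tokens x H), `tag_id` (integer tag
#'   ids if the corpus is tagged and a tagset is supplied), `sentence`.
#' @param tagset tagset used to encode tags (defaults to the model's).
#' @export
hidden_states <- function(model, corpus, tagset = model$tagset) {
  bos <- match(model$vocab$bos, model$vocab$words)
  hs <- lapply(corpus$records, function(r) {
    ids <- tokens_to_ids(model$vocab, r$tokens)
    m <- cpp_rnn_hidden(model$params, model$arch, as.integer(ids), bos)
    m[-1, , drop = FALSE] # drop the start-symbol row
  })
  tag_id <- NULL
  if (!is.null(tagset)) {
    tag_id <- unlist(lapply(corpus$records, function(r)
      match(r$supertags, tagset)), use.names = FALSE)
  }
  list(h = do.call(rbind, hs),
       tag_id = tag_id,
       sentence = rep(seq_along(hs), vapply(hs, nrow, integer(1))))
}

#' Analytic loss and gradients (for verification)
#'
#' Computes the combined training loss and its analytic gradients over a
#' small corpus in a single batch; used to check backpropagation against
#' central finite differences.
#'
#' @param model an `agr_lm`.
#' @param corpus an `agr_corpus`.
#' @param w_word,w_tag task weights.
#' @return List with `loss` and `grads` (named like `model$params`).
#' @export
lm_loss_grad <- function(model, corpus, w_word = 1, w_tag = 1) {
  use_tags <- !is.null(model$tagset) && w_tag > 0
  ids <- corpus_ids(model, corpus, need_tags = use_tags)
  bos <- match(model$vocab$bos, model$vocab$words)
  eos <- match(model$vocab$eos, model$vocab$words)
  cpp_rnn_loss_grad(model$params, model$arch, ids$sents, ids$tags,
                    bos, eos, w_word, w_tag)
}
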