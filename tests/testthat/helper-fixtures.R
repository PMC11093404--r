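# Shared fixtures. Heavier artifacts (trained models) are built lazily and
# cached for the duration of the test run.

.cache <- new.env(parent = emptyenv())

tiny_grammar <- function(seed = 11) {
  grammar_config(n_nouns = 8, n_verbs = 4, n_prepositions = 2,
                 n_adjectives = 4, p_pp_modifier = 0.3, p_rc_modifier = 0.2,
                 p_nested_pp = 0.1, p_disjunct_subject = 0.1, seed = seed)
}

tiny_encoder <- function(H = 16) {
  encoder_config(num_layers = 2, hidden_size = H, embedding_size = H)
}

# A small trained multitask model + matching LM-only model, reused across
# unit tests that need non-degenerate representations.
tiny_trained <- function() {
  if (!is.null(.cache$tiny)) return(.cache$tiny)
  cfg <- tiny_grammar(31)
  train <- generate_corpus(cfg, 3000)
  ho_cfg <- cfg; ho_cfg$seed <- 32
  heldout <- generate_corpus(ho_cfg, 500)
  vocab <- build_vocab(train)
  tc <- train_config(epochs = 2, lr = 1, batch_size = 32, seed = 7)
  mt <- language_model(vocab, tagset = grammar_tagset(),
                       encoder = tiny_encoder(), seed = 5)
  mt <- train_lm(mt, train, tc)
  lo <- language_model(vocab, encoder = tiny_encoder(), seed = 6)
  lo <- train_lm(lo, train, tc)
  .cache$tiny <- list(config = cfg, train = train, heldout = heldout,
                      vocab = vocab, multitask = mt, lm_only = lo)
  .cache$tiny
}

# The toy-scale study models: 2x64 LSTMs trained on a 50k-sentence corpus,
# five independently initialized instances per variant. Built once and
# shared by the learning-sanity and probing acceptance checks.
toy_models <- function() {
  if (!is.null(.cache$toy)) return(.cache$toy)
  cfg <- grammar_config(seed = 101)
  train <- generate_corpus(cfg, 50000)
  ho_cfg <- cfg; ho_cfg$seed <- 102
  heldout <- generate_corpus(ho_cfg, 3000)
  pr_cfg <- cfg; pr_cfg$seed <- 103
  probe_split <- generate_corpus(pr_cfg, 3000)
  vocab <- build_vocab(train)
  enc <- encoder_config(num_layers = 2, hidden_size = 64,
                        embedding_size = 64)
  tc <- train_config(epochs = 2, lr = 1, batch_size = 64, n_instances = 5)
  tc_lo <- tc; tc_lo$seed <- 11L
  tc_mt <- tc; tc_mt$seed <- 22L
  lm_only <- train_instances(vocab, train, tc_lo, enc, tagset = NULL)
  multitask <- train_instances(vocab, train, tc_mt, enc,
                               tagset = grammar_tagset())
  .cache$toy <- list(config = cfg, train = train, heldout = heldout,
                     probe_split = probe_split, vocab = vocab,
                     lm_only = lm_only, multitask = multitask)
  .cache$toy
}

# A deliberately untrained small model over a fixed vocabulary, for
# closed-form and contract tests.
random_model <- function(seed = 3, H = 8, tagset = NULL, n_extra = 6) {
  words <- c("<unk>", "<s>", "</s>", paste0("w", seq_len(n_extra)))
  vocab <- structure(list(words = words, unk = "<unk>", bos = "<s>",
                          eos = "</s>", min_count = 1L),
                     class = "agr_vocab")
  language_model(vocab, tagset = tagset,
                 encoder = encoder_config(num_layers = 1, hidden_size = H,
                                          embedding_size = H),
                 seed = seed)
}

# Wrap raw token vectors as a corpus object.
as_corpus <- function(token_list, tag_list = NULL) {
  records <- lapply(seq_along(token_list), function(i) {
    r <- list(tokens = token_list[[i]])
    if (!is.null(tag_list)) r$supertags <- tag_list[[i]]
    r
  })
  structure(list(records = records, config = NULL), class = "agr_corpus")
}
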