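test_that("corpus generation is deterministic, grammatical and annotated", {
  cfg <- tiny_grammar(17)
  a <- generate_corpus(cfg, 300)
  b <- generate_corpus(cfg, 300)
  expect_identical(a, b)
  for (r in a$records) {
    expect_identical(r$subject_number, r$verb_number)
    expect_length(r$supertags, length(r$tokens))
    expect_true(r$subject_head_index >= 1 &&
                  r$subject_head_index <= length(r$tokens))
    expect_true(r$verb_index >= 1 && r$verb_index <= length(r$tokens))
    expect_length(r$attractor_numbers, length(r$attractor_indices))
    if (length(r$attractor_indices))
      expect_true(all(r$attractor_indices <= length(r$tokens)))
    # the annotated verb really is the main verb/copula
    expect_true(r$tokens[r$verb_index] %in%
                  c("is", "are", grammar_lexicon(cfg)$verbs_sg,
                    grammar_lexicon(cfg)$verbs_pl))
  }
  expect_identical(generate_corpus(cfg, 0)$records, list())
})

test_that("probability-zero constructions never occur", {
  cfg <- grammar_config(p_rc_modifier = 0, p_disjunct_subject = 0,
                        seed = 4)
  co <- generate_corpus(cfg, 5000)
  cc <- construction_counts(co)
  expect_equal(cc$count[cc$construction == "rc_subject_modifiers"], 0)
  expect_equal(cc$count[cc$construction == "disjunct_subjects"], 0)
  toks <- unlist(lapply(co$records, `[[`, "tokens"))
  expect_false(any(toks %in% c("that", "who", "or")))
})

test_that("construction frequencies track their configured probabilities", {
  cfg <- grammar_config(p_pp_modifier = 0.2, seed = 8)
  co <- generate_corpus(cfg, 10000)
  obs <- sum(vapply(co$records, function(r) r$constructions[["pp_modifier"]],
                    logical(1)))
  expect_lt(abs(obs - 10000 * 0.2), 3 * sqrt(10000 * 0.2 * 0.8))
})

test_that("frequency calibration holds across seeds for every construction", {
  probs <- c(pp_modifier = 0.15, rc_modifier = 0.05, nested_pp = 0.03,
             disjunct_subject = 0.02)
  n <- 5000
  hits <- 0L
  total <- 0L
  for (seed in 1:20) {
    cfg <- grammar_config(p_pp_modifier = probs[["pp_modifier"]],
                          p_rc_modifier = probs[["rc_modifier"]],
                          p_nested_pp = probs[["nested_pp"]],
                          p_disjunct_subject = probs[["disjunct_subject"]],
                          seed = seed)
    co <- generate_corpus(cfg, n)
    cc <- construction_counts(co)
    obs <- setNames(cc$count, cc$construction)
    rowname <- c(pp_modifier = "pp_subject_modifiers",
                 rc_modifier = "rc_subject_modifiers",
                 nested_pp = "nested_pp_subject_modifiers",
                 disjunct_subject = "disjunct_subjects")
    for (k in names(probs)) {
      p <- probs[[k]]
      cnt <- obs[[rowname[[k]]]]
      total <- total + 1L
      if (abs(cnt - n * p) <= 4 * sqrt(n * p * (1 - p))) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.99)
})

test_that("invalid configurations are rejected", {
  expect_error(grammar_config(p_pp_modifier = 1.2), "probability")
  expect_error(grammar_config(p_nested_pp = 0.3, p_pp_modifier = 0.2),
               "nesting")
  expect_error(grammar_config(n_nouns = 0), "integer")
})

test_that("vocabulary construction counts and thresholds words", {
  co <- as_corpus(list(c("a", "b", "a")))
  v2 <- build_vocab(co, min_count = 2)
  expect_true("a" %in% v2$words)
  expect_false("b" %in% v2$words)
  expect_true(v2$unk %in% v2$words)
  v1 <- build_vocab(co, min_count = 1)
  expect_true(all(c("a", "b") %in% v1$words))
  # set oracle on a generated corpus
  cg <- generate_corpus(tiny_grammar(5), 2000)
  v <- build_vocab(cg, min_count = 1)
  types <- unique(unlist(lapply(cg$records, `[[`, "tokens")))
  expect_setequal(setdiff(v$words, c("<unk>", "<s>", "</s>")), types)
  expect_length(v$words, length(types) + 3L)
  # ids are contiguous positions; OOV maps to the unknown id
  expect_identical(tokens_to_ids(v, v$words), seq_along(v$words))
  expect_identical(tokens_to_ids(v, "zzz-not-a-word"),
                   match(v$unk, v$words))
})

test_that("construction counts match a brute-force rescan of the flags", {
  co <- generate_corpus(tiny_grammar(9), 1000)
  cc <- construction_counts(co)
  rescan <- function(flag)
    sum(vapply(co$records, function(r) r$constructions[[flag]], logical(1)))
  expect_equal(cc$count[cc$construction == "pp_subject_modifiers"],
               rescan("pp_modifier"))
  expect_equal(cc$count[cc$construction == "rc_subject_modifiers"],
               rescan("rc_modifier"))
  expect_equal(cc$count[cc$construction == "nested_pp_subject_modifiers"],
               rescan("nested_pp"))
  expect_equal(cc$count[cc$construction == "disjunct_subjects"],
               rescan("disjunct_subject"))
  expect_equal(cc$per_sentence[cc$construction == "sentences"], 1.0)
  # sentences without an RC carry exactly one subject-verb relation
  no_rc <- Filter(function(r) !r$constructions[["rc_modifier"]], co$records)
  expect_true(all(vapply(no_rc, `[[`, numeric(1),
                         "n_agreement_relations") == 1))
  empty <- construction_counts(generate_corpus(tiny_grammar(1), 0))
  expect_true(all(empty$count == 0))
})

test_that("supertags come from the closed tagset and follow the scheme", {
  cfg <- tiny_grammar(13)
  co <- generate_corpus(cfg, 2000)
  tags <- unlist(lapply(co$records, `[[`, "supertags"))
  expect_true(all(tags %in% grammar_tagset()))
  expect_lte(length(unique(tags)), length(grammar_tagset()))
  # the determiner is tagged NP/N
  expect_identical(assign_supertags(c("the", "n01"), cfg)[1], "NP/N")
  # a sentence-final intransitive verb with its subject to the left
  expect_identical(assign_supertags(c("the", "n01", "v01s"), cfg)[3],
                   "S\\NP")
  # copula before a predicative adjective, as in "the key ... is rusty"
  st <- assign_supertags(c("the", "n01", "p01", "the", "n02s", "is", "a01"),
                         cfg)
  expect_identical(st, c("NP/N", "N", "(NP\\NP)/NP", "NP/N", "N",
                         "(S\\NP)/ADJ", "ADJ"))
  expect_error(assign_supertags(c("the", "zebra"), cfg), "outside")
})

test_that("corpus files round-trip tokens, tags and annotations", {
  co <- generate_corpus(tiny_grammar(21), 120)
  prefix <- file.path(withr::local_tempdir(), "corpus")
  write_corpus(co, prefix)
  back <- read_corpus(prefix)
  expect_length(back$records, length(co$records))
  for (i in seq_along(co$records)) {
    expect_identical(back$records[[i]]$tokens, co$records[[i]]$tokens)
    expect_identical(back$records[[i]]$supertags, co$records[[i]]$supertags)
    expect_identical(back$records[[i]]$subject_number,
                     co$records[[i]]$subject_number)
    expect_identical(back$records[[i]]$attractor_indices,
                     as.integer(co$records[[i]]$attractor_indices))
  }
})
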