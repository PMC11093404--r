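#' Configuration for the synthetic agreement grammar
#'
#' The generator emulates the statistical structure relevant to agreement
#' attraction in edited English text: number-marked subject-verb
#' dependencies, prepositional-phrase (PP) and relative-clause (RC) subject
#' modifiers, nested PPs, and disjunct subjects. Construction probabilities
#' are per-sentence rates; their defaults follow the per-sentence rates of
#' these constructions observed in large parsed corpora of edited text
#' (PP subject modifiers ~0.15/sentence, RC modifiers ~0.02, nested PPs
#' ~0.02, disjunct subjects ~0.005).
#'
#' Number is marked on surface forms: plural nouns end in `-s` (`n03` vs.
#' `n03s`), singular verbs end in `-s` (`v02s` vs. `v02`), and the copula is
#' `is`/`are`, so models can learn number from form alone.
#'
#' @param n_nouns,n_verbs,n_prepositions,n_adjectives,n_determiners lexicon
#'   sizes per category (positive integers).
#' @param p_pp_modifier probability that the subject carries a PP modifier.
#' @param p_rc_modifier probability that the subject carries an RC modifier
#'   (mutually exclusive with the PP modifier within a sentence, so
#'   `p_pp_modifier + p_rc_modifier` must be at most 1).
#' @param p_nested_pp marginal probability of a nested PP; realized only
#'   inside a PP, so must not exceed `p_pp_modifier`.
#' @param p_disjunct_subject probability that the subject is a disjunction.
#' @param p_plural_subject probability that any given noun is plural.
#' @param p_attributive_adj probability that a noun phrase carries an
#'   attributive adjective.
#' @param seed integer seed controlling corpus generation.
#' @return An object of class `grammar_config`.
#' @export
grammar_config <- function(n_nouns = 40, n_verbs = 12, n_prepositions = 6,
                           n_adjectives = 10, n_determiners = 1,
                           p_pp_modifier = 0.15, p_rc_modifier = 0.02,
                           p_nested_pp = 0.02, p_disjunct_subject = 0.005,
                           p_plural_subject = 0.35,
                           p_attributive_adj = 0.25, seed = 1L) {
  for (nm in c("n_nouns", "n_verbs", "n_prepositions", "n_adjectives",
               "n_determiners"))
    assert_count(get(nm), nm)
  for (nm in c("p_pp_modifier", "p_rc_modifier", "p_nested_pp",
               "p_disjunct_subject", "p_plural_subject",
               "p_attributive_adj"))
    assert_prob(get(nm), nm)
  if (p_nested_pp > p_pp_modifier)
    stop("`p_nested_pp` must not exceed `p_pp_modifier`: ",
         "nesting occurs only inside a PP", call. = FALSE)
  if (p_pp_modifier + p_rc_modifier > 1)
    stop("`p_pp_modifier` + `p_rc_modifier` must be at most 1", call. = FALSE)
  structure(list(
    n_nouns = as.integer(n_nouns), n_verbs = as.integer(n_verbs),
    n_prepositions = as.integer(n_prepositions),
    n_adjectives = as.integer(n_adjectives),
    n_determiners = as.integer(n_determiners),
    p_pp_modifier = p_pp_modifier, p_rc_modifier = p_rc_modifier,
    p_nested_pp = p_nested_pp, p_disjunct_subject = p_disjunct_subject,
    p_plural_subject = p_plural_subject,
    p_attributive_adj = p_attributive_adj, seed = as.integer(seed)),
    class = "grammar_config")
}

#' Lexicon of a grammar configuration
#'
#' @param config a [grammar_config()].
#' @return A list of word vectors per category. Prepositions are split into
#'   a collective-biased and a distributive-biased set; in a toy lexicon the
#'   designation is arbitrary, but it gives the notional-number paradigm two
#'   distinct preposition classes to manipulate.
#' @export
grammar_lexicon <- function(config) {
  nouns_sg <- sprintf("n%02d", seq_len(config$n_nouns))
  dets <- c("the", if (config$n_determiners > 1)
    sprintf("d%02d", 1L + seq_len(config$n_determiners - 1L)))
  preps <- sprintf("p%02d", seq_len(config$n_prepositions))
  half <- ceiling(length(preps) / 2)
  list(
    nouns_sg = nouns_sg,
    nouns_pl = paste0(nouns_sg, "s"),
    verbs_sg = sprintf("v%02ds", seq_len(config$n_verbs)),
    verbs_pl = sprintf("v%02d", seq_len(config$n_verbs)),
    adjectives = sprintf("a%02d", seq_len(config$n_adjectives)),
    prepositions = preps,
    prep_collective = preps[seq_len(half)],
    prep_distributive = preps[-seq_len(half)],
    determiners = dets,
    copula_sg = "is", copula_pl = "are",
    rel_subj = "that", rel_obj = "who", conj = "or")
}

#' The grammar's closed supertag set
#'
#' Slash categories follow the usual convention: `Y/X` merges with an `X` on
#' its right to form a `Y`; `Y\X` does the same with the `X` on its left.
#'
#' @return Character vector of the supertags the grammar can emit.
#' @export
grammar_tagset <- function() {
  c("NP/N",                    # determiner
    "N",                       # noun
    "N/N",                     # attributive adjective
    "ADJ",                     # predicative adjective
    "(S\\NP)/ADJ",             # copula
    "S\\NP",                   # intransitive verb
    "(S\\NP)/NP",              # transitive verb
    "(NP\\NP)/NP",             # NP-modifying preposition; also disjunction
    "((S\\NP)\\(S\\NP))/NP",   # verb-modifying (oblique) preposition
    "(NP\\NP)/(S\\NP)",        # subject relativizer ("that")
    "(NP\\NP)/(S/NP)")         # object relativizer ("who")
}

# Classify a token into its lexical category, or NA if outside the grammar.
#' @noRd
classify_token <- function(tokens, lex) {
  cls <- rep(NA_character_, length(tokens))
  cls[tokens %in% lex$determiners] <- "det"
  cls[tokens %in% c(lex$nouns_sg, lex$nouns_pl)] <- "noun"
  cls[tokens %in% c(lex$verbs_sg, lex$verbs_pl)] <- "verb"
  cls[tokens %in% lex$adjectives] <- "adj"
  cls[tokens %in% lex$prepositions] <- "prep"
  cls[tokens %in% c(lex$copula_sg, lex$copula_pl)] <- "cop"
  cls[tokens == lex$rel_subj] <- "rel_subj"
  cls[tokens == lex$rel_obj] <- "rel_obj"
  cls[tokens == lex$conj] <- "conj"
  cls
}

#' Assign supertags to an in-grammar token sequence
#'
#' Tags come from the fixed closed tagset of [grammar_tagset()]. Lexically
#' ambiguous classes are disambiguated from their immediate context exactly
#' as the grammar realizes them: an adjective is predicative (`ADJ`) after
#' the copula and attributive (`N/N`) otherwise; a verb is transitive
#' (`(S\NP)/NP`) when a determiner follows and intransitive (`S\NP`)
#' otherwise; a preposition is verb-modifying after a non-copular verb and
#' NP-modifying otherwise. Note that the verb's tag depends on material to
#' its *right*, so a left-to-right supertagger faces genuine ambiguity
#' there, as with natural supertag inventories.
#'
#' @param x a sentence record (from [generate_corpus()]) or a character
#'   vector of tokens.
#' @param config the [grammar_config()] whose lexicon licenses the tokens.
#' @return Character vector of supertags, one per token.
#' @export
assign_supertags <- function(x, config) {
  tokens <- if (is.list(x)) x$tokens else x
  lex <- grammar_lexicon(config)
  cls <- classify_token(tokens, lex)
  if (anyNA(cls))
    stop("token(s) outside the grammar: ",
         paste(unique(tokens[is.na(cls)]), collapse = ", "), call. = FALSE)
  n <- length(tokens)
  prev <- c(NA_character_, cls[-n])
  nxt <- c(cls[-1], NA_character_)
  tags <- character(n)
  tags[cls == "det"] <- "NP/N"
  tags[cls == "noun"] <- "N"
  tags[cls == "cop"] <- "(S\\NP)/ADJ"
  tags[cls == "adj"] <-
    ifelse(prev[cls == "adj"] %in% "cop", "ADJ", "N/N")
  tags[cls == "verb"] <-
    ifelse(nxt[cls == "verb"] %in% "det", "(S\\NP)/NP", "S\\NP")
  tags[cls == "prep"] <-
    ifelse(prev[cls == "prep"] %in% "verb", "((S\\NP)\\(S\\NP))/NP",
           "(NP\\NP)/NP")
  tags[cls == "rel_subj"] <- "(NP\\NP)/(S\\NP)"
  tags[cls == "rel_obj"] <- "(NP\\NP)/(S/NP)"
  tags[cls == "conj"] <- "(NP\\NP)/NP"
  tags
}

# Internal: build a simple NP (det [adj] noun). Returns tokens and the
# index (relative to the NP) of the head noun.
#' @noRd
make_np <- function(number, lex, p_adj) {
  det <- if (length(lex$determiners) == 1) lex$determiners else
    sample(lex$determiners, 1)
  adj <- if (runif(1) < p_adj) sample(lex$adjectives, 1) else NULL
  noun <- if (number == "pl") sample(lex$nouns_pl, 1) else
    sample(lex$nouns_sg, 1)
  toks <- c(det, adj, noun)
  list(tokens = toks, head = length(toks))
}

#' Generate a synthetic training corpus
#'
#' Every generated sentence has grammatical agreement: the main verb (and
#' any relative-clause verb) matches the number of its subject. Agreement
#' noise in downstream simulations must therefore come from model learning,
#' not from corpus errors.
#'
#' @param config a [grammar_config()].
#' @param n_sentences number of sentences to generate (may be 0).
#' @return An object of class `agr_corpus`: a list with elements `records`
#'   (one record per sentence, each holding `tokens`, `supertags`,
#'   `subject_head_index`, `verb_index`, `subject_number`, `verb_number`,
#'   `attractor_indices`, `attractor_numbers`, `constructions`,
#'   `n_agreement_relations`) and `config`.
#' @export
generate_corpus <- function(config, n_sentences) {
  stopifnot(inherits(config, "grammar_config"))
  n_sentences <- assert_count(n_sentences, "n_sentences", min = 0)
  lex <- grammar_lexicon(config)
  p_adj <- config$p_attributive_adj
  p_pl <- config$p_plural_subject
  records <- vector("list", n_sentences)
  num <- function() if (runif(1) < p_pl) "pl" else "sg"
  vb <- function(number, i = sample(length(lex$verbs_sg), 1))
    if (number == "sg") lex$verbs_sg[i] else lex$verbs_pl[i]
  with_seed(config$seed, {
    for (s in seq_len(n_sentences)) {
      subj_num <- num()
      constructions <- c(pp_modifier = FALSE, rc_modifier = FALSE,
                         nested_pp = FALSE, disjunct_subject = FALSE)
      attractor_idx <- integer(0)
      attractor_num <- character(0)
      n_rel <- 1L
      if (runif(1) < config$p_disjunct_subject) {
        constructions["disjunct_subject"] <- TRUE
        num_a <- num(); num_b <- num()
        np_a <- make_np(num_a, lex, p_adj)
        np_b <- make_np(num_b, lex, p_adj)
        tokens <- c(np_a$tokens, lex$conj, np_b$tokens)
        head_idx <- length(np_a$tokens) + 1L + np_b$head
        # the verb agrees with the linearly closer (second) disjunct
        subj_num <- num_b
        attractor_idx <- np_a$head
        attractor_num <- num_a
      } else {
        np <- make_np(subj_num, lex, p_adj)
        tokens <- np$tokens
        head_idx <- np$head
        u <- runif(1)
        if (u < config$p_pp_modifier) {
          constructions["pp_modifier"] <- TRUE
          num2 <- num()
          np2 <- make_np(num2, lex, p_adj)
          tokens <- c(tokens, sample(lex$prepositions, 1), np2$tokens)
          attractor_idx <- length(tokens) - length(np2$tokens) + np2$head
          attractor_num <- num2
          if (runif(1) < config$p_nested_pp / config$p_pp_modifier) {
            constructions["nested_pp"] <- TRUE
            num3 <- num()
            np3 <- make_np(num3, lex, p_adj)
            tokens <- c(tokens, sample(lex$prepositions, 1), np3$tokens)
            attractor_idx <- c(attractor_idx,
                               length(tokens) - length(np3$tokens) + np3$head)
            attractor_num <- c(attractor_num, num3)
          }
        } else if (u < config$p_pp_modifier + config$p_rc_modifier) {
          constructions["rc_modifier"] <- TRUE
          n_rel <- 2L
          num2 <- num()
          np2 <- make_np(num2, lex, p_adj)
          kind <- sample(c("subj_trans", "subj_obl", "obj"), 1,
                         prob = c(0.4, 0.3, 0.3))
          rc <- switch(kind,
            subj_trans = c(lex$rel_subj, vb(subj_num), np2$tokens),
            subj_obl = c(lex$rel_subj, vb(subj_num),
                         sample(lex$prepositions, 1), np2$tokens),
            obj = c(lex$rel_obj, np2$tokens, vb(num2)))
          tokens <- c(tokens, rc)
          off <- length(tokens) - length(rc)
          rel_np_at <- switch(kind, subj_trans = 2L, subj_obl = 3L, obj = 1L)
          attractor_idx <- off + rel_np_at + np2$head
          attractor_num <- num2
        }
      }
      vp_kind <- sample(c("cop", "intrans", "trans"), 1,
                        prob = c(0.5, 0.3, 0.2))
      verb_idx <- length(tokens) + 1L
      vp <- switch(vp_kind,
        cop = c(if (subj_num == "sg") lex$copula_sg else lex$copula_pl,
                sample(lex$adjectives, 1)),
        intrans = vb(subj_num),
        trans = {
          obj <- make_np(num(), lex, p_adj)
          c(vb(subj_num), obj$tokens)
        })
      tokens <- c(tokens, vp)
      records[[s]] <- list(
        tokens = tokens,
        supertags = assign_supertags(tokens, config),
        subject_head_index = head_idx,
        verb_index = verb_idx,
        subject_number = subj_num,
        verb_number = subj_num,
        attractor_indices = attractor_idx,
        attractor_numbers = attractor_num,
        constructions = constructions,
        n_agreement_relations = n_rel)
    }
  })
  structure(list(records = records, config = config), class = "agr_corpus")
}

#' @export
print.agr_corpus <- function(x, ...) {
  cat(sprintf("<agr_corpus> %d sentences\n", length(x$records)))
  invisible(x)
}

#' @export
length.agr_corpus <- function(x) length(x$records)

#' Build a vocabulary from a corpus
#'
#' Words occurring fewer than `min_count` times are excluded and will map
#' to the reserved unknown token. The reserved tokens `<unk>`, `<s>` and
#' `</s>` are always present.
#'
#' @param corpus an `agr_corpus`.
#' @param min_count minimum corpus count for inclusion (>= 1).
#' @return An object of class `agr_vocab` with elements `words` (ids are
#'   positions in this vector), `unk`, `bos`, `eos`, `min_count`.
#' @export
build_vocab <- function(corpus, min_count = 1) {
  stopifnot(inherits(corpus, "agr_corpus"))
  min_count <- assert_count(min_count, "min_count")
  toks <- unlist(lapply(corpus$records, `[[`, "tokens"), use.names = FALSE)
  kept <- character(0)
  if (length(toks)) {
    cnt <- table(toks)
    cnt <- cnt[cnt >= min_count]
    kept <- names(cnt)[order(-as.integer(cnt), names(cnt))]
  }
  structure(list(words = c("<unk>", "<s>", "</s>", kept),
                 unk = "<unk>", bos = "<s>", eos = "</s>",
                 min_count = min_count),
            class = "agr_vocab")
}

#' @export
print.agr_vocab <- function(x, ...) {
  cat(sprintf("<agr_vocab> %d words (min_count = %d)\n",
              length(x$words), x$min_count))
  invisible(x)
}

#' Map tokens to vocabulary ids
#'
#' @param vocab an `agr_vocab`.
#' @param tokens character vector of tokens.
#' @return Integer ids; out-of-vocabulary tokens map to the unknown token.
#' @export
tokens_to_ids <- function(vocab, tokens) {
  ids <- match(tokens, vocab$words)
  ids[is.na(ids)] <- match(vocab$unk, vocab$words)
  ids
}

#' Per-construction counts and rates
#'
#' Counts come from the generator's own structural annotations; no parser
#' is involved.
#'
#' @param corpus an `agr_corpus`.
#' @return Data frame with columns `construction`, `count`, `per_sentence`.
#' @export
construction_counts <- function(corpus) {
  stopifnot(inherits(corpus, "agr_corpus"))
  n <- length(corpus$records)
  flags <- c("pp_modifier", "rc_modifier", "nested_pp", "disjunct_subject")
  cnt <- vapply(flags, function(f)
    sum(vapply(corpus$records, function(r) r$constructions[[f]], logical(1))),
    numeric(1))
  sv <- sum(vapply(corpus$records, `[[`, numeric(1), "n_agreement_relations"))
  out <- data.frame(
    construction = c("sentences", "subject_verb_relations",
                     "pp_subject_modifiers", "rc_subject_modifiers",
                     "nested_pp_subject_modifiers", "disjunct_subjects"),
    count = c(n, sv, unname(cnt)))
  out$per_sentence <- if (n > 0) out$count / n else 0
  out
}

#' Write a corpus to plain-text files
#'
#' Three sidecar files are produced: `<prefix>.txt` (one sentence per line,
#' space-separated tokens), `<prefix>.tags.tsv` (sentence_index,
#' token_index, token, supertag) and `<prefix>.jsonl` (one JSON object per
#' sentence with the structural annotations).
#'
#' @param corpus an `agr_corpus`.
#' @param prefix path prefix for the output files.
#' @return The prefix, invisibly.
#' @export
write_corpus <- function(corpus, prefix) {
  stopifnot(inherits(corpus, "agr_corpus"))
  lines <- vapply(corpus$records, function(r) paste(r$tokens, collapse = " "),
                  character(1))
  writeLines(lines, paste0(prefix, ".txt"))
  tags <- do.call(rbind, lapply(seq_along(corpus$records), function(i) {
    r <- corpus$records[[i]]
    data.frame(sentence_index = i, token_index = seq_along(r$tokens),
               token = r$tokens, supertag = r$supertags)
  }))
  if (is.null(tags))
    tags <- data.frame(sentence_index = integer(0), token_index = integer(0),
                       token = character(0), supertag = character(0))
  write.table(tags, paste0(prefix, ".tags.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  ann <- vapply(corpus$records, function(r) {
    jsonlite::toJSON(list(
      subject_head_index = r$subject_head_index,
      verb_index = r$verb_index,
      subject_number = r$subject_number,
      verb_number = r$verb_number,
      attractor_indices = as.integer(r$attractor_indices),
      attractor_numbers = r$attractor_numbers,
      constructions = as.list(r$constructions),
      n_agreement_relations = r$n_agreement_relations),
      auto_unbox = TRUE)
  }, character(1))
  writeLines(ann, paste0(prefix, ".jsonl"))
  invisible(prefix)
}

#' Read a corpus written by [write_corpus()]
#'
#' @param prefix path prefix used when writing.
#' @return An `agr_corpus` (its `config` element is `NULL`: the files do not
#'   carry the generating configuration).
#' @export
read_corpus <- function(prefix) {
  lines <- readLines(paste0(prefix, ".txt"))
  tags <- read.table(paste0(prefix, ".tags.tsv"), sep = "\t", header = TRUE,
                     colClasses = c("integer", "integer", "character",
                                    "character"))
  ann <- readLines(paste0(prefix, ".jsonl"))
  tag_split <- split(tags$supertag, tags$sentence_index)
  records <- lapply(seq_along(lines), function(i) {
    a <- jsonlite::fromJSON(ann[i])
    cons <- unlist(a$constructions)
    list(tokens = strsplit(lines[i], " ", fixed = TRUE)[[1]],
         supertags = as.character(tag_split[[as.character(i)]]),
         subject_head_index = as.integer(a$subject_head_index),
         verb_index = as.integer(a$verb_index),
         subject_number = a$subject_number,
         verb_number = a$verb_number,
         attractor_indices = as.integer(unlist(a$attractor_indices)),
         attractor_numbers = as.character(unlist(a$attractor_numbers)),
         constructions = cons,
         n_agreement_relations = as.integer(a$n_agreement_relations))
  })
  structure(list(records = records, config = NULL), class = "agr_corpus")
}
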