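#' Registry of the six simulated experimental paradigms
#'
#' Each entry declares the paradigm's measure (`completion` for sentence
#' completion, `reading` for self-paced reading) and its factorial design:
#'
#' * `bock_cutting` - PP vs. RC subject modifiers: subject number x
#'   subject-attractor match x modifier type; completion.
#' * `franck` - double-PP subjects ("the threat to the presidents of the
#'   companies"): subject number x match of the syntactically closer
#'   attractor x match of the linearly closer attractor; completion.
#' * `haskell_macdonald` - disjunct subjects ("the boy or the girls"):
#'   number of the linearly closer disjunct; completion (plural rate).
#' * `humphreys_bock` - collective subjects with collective- vs.
#'   distributive-biased prepositions; completion (plural rate).
#' * `parker_an` - attractors in core vs. oblique arguments of a subject
#'   relative clause: match x grammaticality x argument status; reading,
#'   critical word = the matrix verb.
#' * `wagers` - RC-internal agreement with the matrix subject as attractor:
#'   match x grammaticality; reading, critical word = the RC verb.
#'
#' @return Named list of paradigm descriptors (`measure`, `factors`).
#' @export
paradigm_registry <- function() {
  list(
    bock_cutting = list(
      measure = "completion",
      factors = list(subject_number = c("sg", "pl"),
                     attractor_match = c("match", "mismatch"),
                     modifier = c("pp", "rc"))),
    franck = list(
      measure = "completion",
      factors = list(subject_number = c("sg", "pl"),
                     syn_match = c("match", "mismatch"),
                     lin_match = c("match", "mismatch"))),
    haskell_macdonald = list(
      measure = "completion",
      factors = list(closer_number = c("sg", "pl"))),
    humphreys_bock = list(
      measure = "completion",
      factors = list(preposition_bias = c("collective", "distributive"))),
    parker_an = list(
      measure = "reading",
      factors = list(attractor_match = c("match", "mismatch"),
                     grammaticality = c("gram", "ungram"),
                     argument = c("core", "oblique"))),
    wagers = list(
      measure = "reading",
      factors = list(attractor_match = c("match", "mismatch"),
                     grammaticality = c("gram", "ungram"))))
}

#' @noRd
other_number <- function(x) ifelse(x == "sg", "pl", "sg")

#' @noRd
noun_form <- function(base, number) ifelse(number == "pl",
                                           paste0(base, "s"), base)

#' Validate an item table
#'
#' Checks the registry contract: declared factors present with legal
#' levels, a full factorial cell set per item, candidates for completion
#' items, and an in-range critical index for reading items.
#'
#' @param items an item data frame.
#' @return The items, invisibly; errors describe the first violation.
#' @export
validate_items <- function(items) {
  reg <- paradigm_registry()
  needed <- c("paradigm", "item", "measure", "tokens", "np_flags",
              "candidate_sg", "candidate_pl", "critical_index")
  miss <- setdiff(needed, names(items))
  if (length(miss))
    stop("item table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(items) == 0) return(invisible(items))
  for (p in unique(items$paradigm)) {
    if (!p %in% names(reg))
      stop("unknown paradigm: ", p, call. = FALSE)
    des <- reg[[p]]
    sub <- items[items$paradigm == p, , drop = FALSE]
    for (f in names(des$factors)) {
      if (!f %in% names(sub))
        stop(sprintf("paradigm %s: missing factor column `%s`", p, f),
             call. = FALSE)
      bad <- setdiff(unique(sub[[f]]), des$factors[[f]])
      if (length(bad))
        stop(sprintf("paradigm %s: illegal level(s) for `%s`: %s", p, f,
                     paste(bad, collapse = ", ")), call. = FALSE)
    }
    cells <- do.call(paste, c(sub[names(des$factors)], sep = "/"))
    n_cells <- prod(lengths(des$factors))
    for (it in unique(sub$item)) {
      cc <- cells[sub$item == it]
      if (length(cc) != n_cells || anyDuplicated(cc))
        stop(sprintf(
          "paradigm %s, item %s: expected one row per each of %d cells",
          p, it, n_cells), call. = FALSE)
    }
    if (des$measure == "completion") {
      if (any(!nzchar(sub$candidate_sg)) || any(!nzchar(sub$candidate_pl)))
        stop(sprintf("paradigm %s: completion items need a candidate pair",
                     p), call. = FALSE)
    } else {
      nt <- lengths(strsplit(sub$tokens, " ", fixed = TRUE))
      ci <- sub$critical_index
      if (anyNA(ci) || any(ci < 1 | ci > nt))
        stop(sprintf("paradigm %s: malformed critical index", p),
             call. = FALSE)
    }
  }
  invisible(items)
}

#' @noRd
new_items <- function(df) {
  class(df) <- c("agr_items", "data.frame")
  validate_items(df)
  df
}

#' Generate experimental items from the paradigm templates
#'
#' Builds a full factorial item set over the synthetic grammar's lexicon:
#' every item appears in every condition cell, and cells differ only in the
#' manipulated tokens (minimal pairs). Frames are distinct across items
#' (each item gets its own head noun), so the lexicon must be large enough.
#'
#' @param paradigm one of the names in [paradigm_registry()].
#' @param config the [grammar_config()] providing the lexicon.
#' @param n_items number of items (experimental frames).
#' @param seed seed controlling lexeme sampling.
#' @return An item table of class `agr_items`: one row per item x cell,
#'   with columns `paradigm`, `item`, the paradigm's factor columns,
#'   `measure`, `tokens` (space-joined), `np_flags` (comma-joined 0/1),
#'   `candidate_sg`, `candidate_pl`, `critical_index`.
#' @export
generate_paradigm_items <- function(paradigm, config, n_items = 24,
                                    seed = 1L) {
  reg <- paradigm_registry()
  if (!paradigm %in% names(reg))
    stop("unknown paradigm: ", paradigm, call. = FALSE)
  lex <- grammar_lexicon(config)
  n_items <- assert_count(n_items, "n_items")
  if (n_items > length(lex$nouns_sg))
    stop(sprintf(
      "lexicon too small: %d nouns cannot support %d distinct frames",
      length(lex$nouns_sg), n_items), call. = FALSE)
  des <- reg[[paradigm]]
  cells <- expand.grid(des$factors, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- with_seed(seed, {
    head_nouns <- sample(lex$nouns_sg, n_items)
    lapply(seq_len(n_items), function(i) {
      n1 <- head_nouns[i]
      others <- sample(setdiff(lex$nouns_sg, n1), 3)
      v <- sample(seq_along(lex$verbs_sg), 1)
      pp <- sample(lex$prepositions, 2)
      pc <- sample(lex$prep_collective, 1)
      pd <- sample(lex$prep_distributive, 1)
      adj <- sample(lex$adjectives, 1)
      per_cell <- lapply(seq_len(nrow(cells)), function(j) {
        cl <- cells[j, , drop = FALSE]
        build_item_tokens(paradigm, cl, lex, n1, others, v, pp, pc, pd, adj)
      })
      cbind(data.frame(paradigm = paradigm, item = i,
                       cells, row.names = NULL),
            do.call(rbind, per_cell))
    })
  })
  out <- do.call(rbind, rows)
  out$measure <- des$measure
  out <- out[c("paradigm", "item", names(des$factors), "measure", "tokens",
               "np_flags", "candidate_sg", "candidate_pl",
               "critical_index")]
  new_items(out)
}

# Token construction for one cell of one item frame.
#' @noRd
build_item_tokens <- function(paradigm, cl, lex, n1, others, v, pp, pc, pd,
                              adj) {
  vb <- function(number) if (number == "sg") lex$verbs_sg[v] else
    lex$verbs_pl[v]
  cop <- function(number) if (number == "sg") lex$copula_sg else
    lex$copula_pl
  toks <- np <- NULL
  ci <- NA_integer_
  cand <- c("", "")
  if (paradigm == "bock_cutting") {
    an <- if (cl$attractor_match == "match") cl$subject_number else
      other_number(cl$subject_number)
    if (cl$modifier == "pp") {
      toks <- c("the", noun_form(n1, cl$subject_number), pp[1], "the",
                noun_form(others[1], an))
      np <- c(1, 1, 0, 1, 1)
    } else {
      toks <- c("the", noun_form(n1, cl$subject_number), lex$rel_subj,
                vb(cl$subject_number), "the", noun_form(others[1], an))
      np <- c(1, 1, 0, 0, 1, 1)
    }
    cand <- c(lex$copula_sg, lex$copula_pl)
  } else if (paradigm == "franck") {
    syn_n <- if (cl$syn_match == "match") cl$subject_number else
      other_number(cl$subject_number)
    lin_n <- if (cl$lin_match == "match") cl$subject_number else
      other_number(cl$subject_number)
    toks <- c("the", noun_form(n1, cl$subject_number), pp[1], "the",
              noun_form(others[1], syn_n), pp[2], "the",
              noun_form(others[2], lin_n))
    np <- c(1, 1, 0, 1, 1, 0, 1, 1)
    cand <- c(lex$copula_sg, lex$copula_pl)
  } else if (paradigm == "haskell_macdonald") {
    toks <- c("the", noun_form(n1, other_number(cl$closer_number)),
              lex$conj, "the", noun_form(others[1], cl$closer_number))
    np <- c(1, 1, 0, 1, 1)
    cand <- c(lex$copula_sg, lex$copula_pl)
  } else if (paradigm == "humphreys_bock") {
    prep <- if (cl$preposition_bias == "collective") pc else pd
    toks <- c("the", n1, prep, "the", noun_form(others[1], "pl"))
    np <- c(1, 1, 0, 1, 1)
    cand <- c(lex$copula_sg, lex$copula_pl)
  } else if (paradigm == "parker_an") {
    an <- if (cl$attractor_match == "match") "sg" else "pl"
    mv <- if (cl$grammaticality == "gram") cop("sg") else cop("pl")
    if (cl$argument == "core") {
      toks <- c("the", n1, lex$rel_subj, vb("sg"), "the",
                noun_form(others[1], an), mv, adj)
      np <- c(1, 1, 0, 0, 1, 1, 0, 0)
      ci <- 7L
    } else {
      toks <- c("the", n1, lex$rel_subj, vb("sg"), pp[1], "the",
                noun_form(others[1], an), mv, adj)
      np <- c(1, 1, 0, 0, 0, 1, 1, 0, 0)
      ci <- 8L
    }
  } else if (paradigm == "wagers") {
    an <- if (cl$attractor_match == "match") "sg" else "pl"
    rcv <- if (cl$grammaticality == "gram") vb("sg") else vb("pl")
    toks <- c("the", noun_form(n1, an), lex$rel_obj, "the", others[1], rcv)
    np <- c(1, 1, 0, 1, 1, 0)
    ci <- 6L
  }
  data.frame(tokens = paste(toks, collapse = " "),
             np_flags = paste(np, collapse = ","),
             candidate_sg = cand[1], candidate_pl = cand[2],
             critical_index = ci)
}

#' Load experimental items from CSV
#'
#' @param path CSV file with the schema written by [write_items()]:
#'   `paradigm`, `item`, the paradigm's factor columns, `measure`, `tokens`
#'   (space-joined), `np_flags` (comma-joined 0/1 marking noun-phrase
#'   tokens), `candidate_sg`, `candidate_pl`, `critical_index`.
#' @return Validated `agr_items`.
#' @export
load_items <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(critical_index = "integer"))
  for (col in c("candidate_sg", "candidate_pl"))
    if (col %in% names(df)) df[[col]][is.na(df[[col]])] <- ""
  new_items(df)
}

#' Write experimental items to CSV
#'
#' @param items an `agr_items` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_items <- function(items, path) {
  write.csv(items, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Apply the out-of-vocabulary substitution policy
#'
#' Out-of-vocabulary tokens that sit inside a noun phrase (per `np_flags`)
#' or that are manipulated by the design (differ across cells of the same
#' item) carry number information and must be replaced by a curated,
#' in-vocabulary substitute from `table`; lacking an entry is an error.
#' All other OOV tokens are replaced by the reserved unknown token. The
#' operation is idempotent and returns a change log.
#'
#' @param items an `agr_items` table.
#' @param vocab an `agr_vocab`.
#' @param table named character vector mapping OOV words to in-vocabulary
#'   replacements.
#' @return List with `items` (sanitized) and `log` (data frame of changes:
#'   `paradigm`, `item`, `row`, `position`, `from`, `to`, `action`).
#' @export
apply_oov_policy <- function(items, vocab, table = NULL) {
  stopifnot(inherits(vocab, "agr_vocab"))
  if (!is.null(table)) {
    bad <- setdiff(unname(table), vocab$words)
    if (length(bad))
      stop("substitution table maps to out-of-vocabulary replacement(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  tok_list <- strsplit(items$tokens, " ", fixed = TRUE)
  np_list <- lapply(strsplit(items$np_flags, ",", fixed = TRUE), as.integer)
  # A token position is "manipulated" if the token at that position varies
  # across the cells of the same item (same-length frames only; frames of
  # different lengths vary structurally, which the np flags already cover).
  key <- paste(items$paradigm, items$item, lengths(tok_list))
  manip <- vector("list", nrow(items))
  for (k in unique(key)) {
    idx <- which(key == k)
    m <- do.call(rbind, tok_list[idx])
    varies <- apply(m, 2, function(col) length(unique(col)) > 1)
    for (i in idx) manip[[i]] <- varies
  }
  logs <- list()
  for (i in seq_len(nrow(items))) {
    toks <- tok_list[[i]]
    oov <- !(toks %in% vocab$words)
    if (!any(oov)) next
    protected <- (np_list[[i]] == 1) | manip[[i]]
    for (j in which(oov)) {
      w <- toks[j]
      if (protected[j]) {
        if (is.null(table) || !w %in% names(table))
          stop(sprintf(
            "out-of-vocabulary word `%s` is noun-phrase internal or design-",
            w), "manipulated and has no curated substitute in the table",
            call. = FALSE)
        toks[j] <- table[[w]]
        act <- "substituted"
      } else {
        toks[j] <- vocab$unk
        act <- "unk"
      }
      logs[[length(logs) + 1]] <- data.frame(
        paradigm = items$paradigm[i], item = items$item[i], row = i,
        position = j, from = w, to = toks[j], action = act)
    }
    tok_list[[i]] <- toks
  }
  # candidate pairs must survive sanitization as real words
  for (col in c("candidate_sg", "candidate_pl")) {
    cand <- items[[col]]
    oov <- nzchar(cand) & !(cand %in% vocab$words)
    for (i in which(oov)) {
      w <- cand[i]
      if (is.null(table) || !w %in% names(table))
        stop(sprintf("candidate form `%s` is out of vocabulary and has no ",
                     w), "curated substitute", call. = FALSE)
      items[[col]][i] <- table[[w]]
    }
  }
  items$tokens <- vapply(tok_list, paste, character(1), collapse = " ")
  log <- if (length(logs)) do.call(rbind, logs) else
    data.frame(paradigm = character(0), item = integer(0), row = integer(0),
               position = integer(0), from = character(0), to = character(0),
               action = character(0))
  list(items = items, log = log)
}
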