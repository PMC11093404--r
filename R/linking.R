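#' Candidate singular/plural verb pair
#'
#' The default pair is the present tense of *be* (`is`/`are`), which is
#' frequent and plausible after nearly any preamble.
#'
#' @param sg,pl the singular and plural surface forms (distinct).
#' @return An object of class `candidate_pair`.
#' @export
candidate_pair <- function(sg = "is", pl = "are") {
  if (!is.character(sg) || !is.character(pl) || sg == pl)
    stop("candidate forms must be distinct strings", call. = FALSE)
  structure(list(sg = sg, pl = pl), class = "candidate_pair")
}

# Extract the two candidate probabilities from a next-word distribution.
#' @noRd
pair_probs <- function(dist, pair, item_id = NULL) {
  if (is.numeric(dist) && length(dist) == 2 && is.null(names(dist))) {
    p <- c(sg = dist[1], pl = dist[2])
  } else {
    if (!all(c(pair$sg, pair$pl) %in% names(dist)))
      stop("candidate pair (", pair$sg, "/", pair$pl,
           ") not in the distribution's vocabulary; apply the OOV policy ",
           "before linking", call. = FALSE)
    p <- c(sg = unname(dist[[pair$sg]]), pl = unname(dist[[pair$pl]]))
  }
  if (any(!is.finite(p)) || any(p < 0))
    stop("candidate probabilities must be finite and nonnegative",
         call. = FALSE)
  if (sum(p) == 0)
    stop("both candidate forms have probability 0",
         if (!is.null(item_id)) paste0(" (item ", item_id, ")") else "",
         call. = FALSE)
  p
}

#' One-sample linking function
#'
#' Renormalizes the model's probabilities over the singular/plural
#' candidate pair; the renormalized singular probability is read as the
#' probability that a single production sample is the singular form.
#'
#' @param dist a named next-word probability vector (or an unnamed numeric
#'   pair `c(P(sg), P(pl))` for direct use).
#' @param pair a [candidate_pair()].
#' @param item_id optional identifier used in error messages.
#' @return A `completion_probability`: list with `p_singular`, `p_plural`
#'   (`= 1 - p_singular`), `rule`, `n`.
#' @export
one_sample <- function(dist, pair = candidate_pair(), item_id = NULL) {
  p <- pair_probs(dist, pair, item_id)
  ps <- p["sg"] / sum(p)
  structure(list(p_singular = unname(ps), p_plural = unname(1 - ps),
                 rule = "one_sample", n = 1L),
            class = "completion_probability")
}

#' Max-prob linking function
#'
#' Deterministically selects the candidate with the higher probability. An
#' exact tie is not defined by the rule; it is flagged as a distinct
#' outcome (with a warning) rather than broken arbitrarily, and tied
#' trials are excluded from error-rate summaries.
#'
#' @inheritParams one_sample
#' @return A `completion_probability` with `p_singular` in `{0, 1}` (or
#'   `NA` with `tie = TRUE`), and a `choice` field in `{"sg","pl","tie"}`.
#' @export
max_prob <- function(dist, pair = candidate_pair(), item_id = NULL) {
  p <- pair_probs(dist, pair, item_id)
  if (p["sg"] == p["pl"]) {
    warning("max_prob tie between candidates",
            if (!is.null(item_id)) paste0(" (item ", item_id, ")") else "",
            call. = FALSE)
    out <- list(p_singular = NA_real_, p_plural = NA_real_, choice = "tie",
                rule = "max_prob", n = NA_integer_, tie = TRUE)
  } else if (p["sg"] > p["pl"]) {
    out <- list(p_singular = 1, p_plural = 0, choice = "sg",
                rule = "max_prob", n = NA_integer_, tie = FALSE)
  } else {
    out <- list(p_singular = 0, p_plural = 1, choice = "pl",
                rule = "max_prob", n = NA_integer_, tie = FALSE)
  }
  structure(out, class = "completion_probability")
}

#' n-sample linking function
#'
#' Takes `n` independent draws from the renormalized candidate
#' distribution and selects the majority form; the returned `p_singular`
#' is the probability that the majority of draws is singular (the upper
#' binomial tail at `ceiling(n/2)`). `n = 1` reduces to [one_sample()];
#' as `n` grows the rule converges pointwise to [max_prob()].
#'
#' @inheritParams one_sample
#' @param n odd positive number of samples (even `n` leaves the majority
#'   undefined and is rejected).
#' @return A `completion_probability`.
#' @export
n_sample <- function(dist, pair = candidate_pair(), n = 1, item_id = NULL) {
  n <- assert_count(n, "n")
  if (n %% 2 == 0)
    stop("`n` must be odd: the majority of an even number of samples ",
         "is undefined", call. = FALSE)
  p <- pair_probs(dist, pair, item_id)
  ps <- unname(p["sg"] / sum(p))
  maj <- pbinom(ceiling(n / 2) - 1, n, ps, lower.tail = FALSE)
  structure(list(p_singular = maj, p_plural = 1 - maj,
                 rule = "n_sample", n = as.integer(n)),
            class = "completion_probability")
}

#' @export
print.completion_probability <- function(x, ...) {
  cat(sprintf("<completion_probability> rule = %s%s, p_singular = %s\n",
              x$rule, if (!is.na(x$n)) paste0(" (n = ", x$n, ")") else "",
              format(x$p_singular)))
  invisible(x)
}

#' Per-token surprisal series
#'
#' `surprisal(w_i) = -log2 P(w_i | w_0 ... w_{i-1})`, the standard linking
#' quantity for word-by-word reading times. Values are in bits and
#' nonnegative; a numerically zero probability yields `Inf` rather than an
#' error.
#'
#' @param model an `agr_lm`.
#' @param tokens character vector of tokens (out-of-vocabulary tokens map
#'   to the unknown token).
#' @return Named numeric vector of surprisals, one per token.
#' @export
surprisal_series <- function(model, tokens) {
  corp <- structure(list(records = list(list(tokens = tokens)),
                         config = NULL), class = "agr_corpus")
  s <- evaluate_lm(model, corp)$surprisal[[1]]
  s <- s[-length(s)] # drop the end-of-sentence prediction
  names(s) <- tokens
  s
}
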