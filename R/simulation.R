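#' Mock predictor with injected condition effects
#'
#' A test double usable wherever a list of trained models is: it produces
#' renormalized singular probabilities directly from a logistic model of
#' the condition labels, with optional item/instance random intercepts and
#' beta-distributed trial noise. Contributions are expressed as log-odds of
#' the *subject-incongruent* (error) response, so a positive contribution
#' raises the error rate regardless of the subject's number. For paradigms
#' without a subject number (disjunct/notional designs) the linear
#' predictor is read as the log-odds of a plural response.
#'
#' @param effects list of effect descriptors; each is a list with `when` (a
#'   named character vector of factor levels that must all hold) and
#'   `delta` (the log-odds contribution).
#' @param intercept baseline log-odds of an error.
#' @param item_sd,instance_sd standard deviations of the item and instance
#'   random intercepts (log-odds scale).
#' @param phi beta precision of trial noise; `Inf` disables noise.
#' @param n_instances number of simulated instances.
#' @param seed master seed; item, instance and trial draws are all derived
#'   from it.
#' @return An object of class `agr_oracle`.
#' @export
make_oracle_predictor <- function(effects = list(), intercept = 0,
                                  item_sd = 0, instance_sd = 0, phi = Inf,
                                  n_instances = 5, seed = 1L) {
  for (e in effects) {
    if (!is.list(e) || is.null(e$when) || is.null(e$delta))
      stop("each effect needs `when` (named levels) and `delta`",
           call. = FALSE)
  }
  structure(list(effects = effects, intercept = intercept,
                 item_sd = item_sd, instance_sd = instance_sd, phi = phi,
                 n_instances = assert_count(n_instances, "n_instances"),
                 seed = as.integer(seed)),
            class = "agr_oracle")
}

# Linear predictor (log-odds of an error / of plural) for each item row.
#' @noRd
oracle_eta <- function(oracle, items) {
  eta <- rep(oracle$intercept, nrow(items))
  for (e in oracle$effects) {
    fac <- names(e$when)
    miss <- setdiff(fac, names(items))
    if (length(miss))
      stop("oracle effect refers to unknown factor(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    hit <- rep(TRUE, nrow(items))
    for (f in fac) hit <- hit & items[[f]] == e$when[[f]]
    eta <- eta + e$delta * hit
  }
  eta
}

#' @noRd
is_model_list <- function(models) {
  is.list(models) && length(models) > 0 && inherits(models[[1]], "agr_lm")
}

#' Run the sentence-completion (production) harness
#'
#' For every model instance and every item row, feed the preamble to the
#' model, extract the next-word distribution, and apply the chosen linking
#' rule to the candidate pair. The per-trial error rate is the linked
#' probability of the verb form incongruent with the subject's number (a
#' continuous quantity, which is what the beta regression consumes); for
#' paradigms without a canonical agreement pattern the plural rate
#' `p_plural` is the measure of interest.
#'
#' @param models a list of `agr_lm` models (one per instance), a single
#'   model, or an [make_oracle_predictor()] object.
#' @param items completion items (`agr_items`).
#' @param linking `"one_sample"` (default), `"max_prob"` or `"n_sample"`.
#' @param n sample count for `"n_sample"`.
#' @return A `TrialResult` data frame: one row per instance x item x cell
#'   with `p_singular`, `p_plural`, `p_error` (NA when no subject number is
#'   defined) and `tie`.
#' @export
run_production <- function(models, items, linking = "one_sample", n = 1) {
  stopifnot(all(items$measure == "completion"))
  linking <- match.arg(linking, c("one_sample", "max_prob", "n_sample"))
  if (inherits(models, "agr_lm")) models <- list(models)
  if (inherits(models, "agr_oracle")) {
    return(oracle_production(models, items))
  }
  stopifnot(is_model_list(models))
  res <- list()
  for (k in seq_along(models)) {
    model <- models[[k]]
    inst <- if (!is.na(models[[k]]$instance)) models[[k]]$instance else k
    for (i in seq_len(nrow(items))) {
      toks <- strsplit(items$tokens[i], " ", fixed = TRUE)[[1]]
      pair <- candidate_pair(items$candidate_sg[i], items$candidate_pl[i])
      dist <- next_word_distribution(model, toks)
      cp <- switch(linking,
        one_sample = one_sample(dist, pair, item_id = items$item[i]),
        max_prob = max_prob(dist, pair, item_id = items$item[i]),
        n_sample = n_sample(dist, pair, n = n, item_id = items$item[i]))
      row <- items[i, , drop = FALSE]
      row$instance <- inst
      row$p_singular <- cp$p_singular
      row$p_plural <- cp$p_plural
      row$tie <- identical(cp$choice, "tie")
      res[[length(res) + 1]] <- row
    }
  }
  finish_production(do.call(rbind, res))
}

#' @noRd
oracle_production <- function(oracle, items) {
  eta <- oracle_eta(oracle, items)
  item_ids <- sort(unique(items$item))
  re_item <- with_seed(oracle$seed, rnorm(length(item_ids), 0,
                                          oracle$item_sd))
  names(re_item) <- as.character(item_ids)
  re_inst <- with_seed(oracle$seed + 1L,
                       rnorm(oracle$n_instances, 0, oracle$instance_sd))
  res <- list()
  for (k in seq_len(oracle$n_instances)) {
    row <- items
    row$instance <- k
    mu <- plogis(eta + re_item[as.character(items$item)] + re_inst[k])
    row$.mu <- mu
    res[[k]] <- row
  }
  out <- do.call(rbind, res)
  if (is.finite(oracle$phi)) {
    out$.mu <- with_seed(oracle$seed + 2L,
                         rbeta(nrow(out), out$.mu * oracle$phi,
                               (1 - out$.mu) * oracle$phi))
  }
  # .mu is the probability of the subject-incongruent (error) response,
  # or of a plural response when no subject number is defined
  if ("subject_number" %in% names(out)) {
    out$p_singular <- ifelse(out$subject_number == "sg", 1 - out$.mu,
                             out$.mu)
  } else {
    out$p_singular <- 1 - out$.mu
  }
  out$p_plural <- 1 - out$p_singular
  out$tie <- FALSE
  out$.mu <- NULL
  finish_production(out)
}

#' @noRd
finish_production <- function(out) {
  out$p_error <- if ("subject_number" %in% names(out)) {
    ifelse(out$subject_number == "sg", out$p_plural, out$p_singular)
  } else NA_real_
  rownames(out) <- NULL
  class(out) <- c("trial_result", "data.frame")
  out
}

#' Run the self-paced-reading (comprehension) harness
#'
#' Computes the per-token surprisal series for every item sentence; the
#' trial measure is the surprisal at the critical token. The full series is
#' retained in a list column for spillover reporting.
#'
#' @param models a list of `agr_lm` models or a single model.
#' @param items reading items (`agr_items`).
#' @return A `trial_result` data frame with `surprisal` (bits, at the
#'   critical index) and a `series` list column.
#' @export
run_comprehension <- function(models, items) {
  stopifnot(all(items$measure == "reading"))
  if (inherits(models, "agr_lm")) models <- list(models)
  stopifnot(is_model_list(models))
  res <- list()
  for (k in seq_along(models)) {
    model <- models[[k]]
    inst <- if (!is.na(models[[k]]$instance)) models[[k]]$instance else k
    for (i in seq_len(nrow(items))) {
      toks <- strsplit(items$tokens[i], " ", fixed = TRUE)[[1]]
      ci <- items$critical_index[i]
      if (ci > length(toks))
        stop(sprintf("item %s: critical index %d beyond sentence length %d",
                     items$item[i], ci, length(toks)), call. = FALSE)
      ss <- surprisal_series(model, toks)
      row <- items[i, , drop = FALSE]
      row$instance <- inst
      row$surprisal <- unname(ss[ci])
      row$series <- I(list(ss))
      res[[length(res) + 1]] <- row
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("trial_result", "data.frame")
  out
}

#' Attraction effect summary
#'
#' The attraction effect is the mismatch-condition mean minus the
#' match-condition mean of the response, computed per instance (and per
#' any additional grouping), after averaging within item cells.
#'
#' @param results a `trial_result` table.
#' @param response response column: `"p_error"` for production,
#'   `"surprisal"` for comprehension, `"p_plural"` for plural-rate designs.
#' @param factor the two-level match factor (levels `match`/`mismatch`).
#' @param by optional extra grouping columns.
#' @return Data frame with grouping columns and `effect`.
#' @export
attraction_effect <- function(results, response = "p_error",
                              factor = "attractor_match",
                              by = character(0)) {
  stopifnot(factor %in% names(results), response %in% names(results))
  groups <- c("instance", by)
  agg <- aggregate(results[[response]],
                   by = c(results[c(groups, factor)]), FUN = mean)
  names(agg)[ncol(agg)] <- "mean"
  wide <- merge(
    agg[agg[[factor]] == "mismatch", c(groups, "mean")],
    agg[agg[[factor]] == "match", c(groups, "mean")],
    by = groups, suffixes = c("_mismatch", "_match"))
  if (nrow(wide) == 0 || anyNA(wide$mean_mismatch) || anyNA(wide$mean_match))
    stop("both `match` and `mismatch` levels must be present in every group",
         call. = FALSE)
  wide$effect <- wide$mean_mismatch - wide$mean_match
  wide[c(groups, "effect")]
}

#' Paradigm-specific effect contrasts
#'
#' Computes the derived contrasts the six designs are analyzed for, each as
#' a per-instance difference:
#'
#' * `number_asymmetry` (PP/RC paradigm): attraction with singular subjects
#'   minus attraction with plural subjects (positive = the classic pattern
#'   of stronger attraction from plural attractors).
#' * `grammaticality_asymmetry` (reading paradigms): attraction in
#'   ungrammatical minus attraction in grammatical sentences. On a
#'   surprisal response, attraction is negative-going (facilitatory) in
#'   ungrammatical sentences, so the classic asymmetry is negative; on an
#'   error-rate response it is positive.
#' * `distance_contrast` (double-PP paradigm): attraction from the
#'   syntactically closer attractor minus attraction from the linearly
#'   closer one, each marginalizing over the other attractor's condition.
#' * `plural_rate_contrast` (disjunct paradigm): plural rate when the
#'   closer disjunct is plural minus when it is singular; (notional-number
#'   paradigm): plural rate under distributive-biased minus
#'   collective-biased prepositions.
#'
#' @param results a `trial_result` table for a single paradigm.
#' @return Data frame with `instance`, `effect_name` and `value`.
#' @export
asymmetry_contrasts <- function(results) {
  paradigm <- unique(results$paradigm)
  stopifnot(length(paradigm) == 1)
  out <- list()
  add <- function(name, df) {
    df$effect_name <- name
    names(df)[names(df) == "effect"] <- "value"
    out[[length(out) + 1]] <<- df[c("instance", "effect_name", "value")]
  }
  if (paradigm == "bock_cutting") {
    a <- attraction_effect(results, "p_error", by = "subject_number")
    sg <- a[a$subject_number == "sg", ]
    pl <- a[a$subject_number == "pl", ]
    m <- merge(sg[c("instance", "effect")], pl[c("instance", "effect")],
               by = "instance", suffixes = c("_sg", "_pl"))
    m$effect <- m$effect_sg - m$effect_pl
    add("number_asymmetry", m)
  } else if (paradigm == "franck") {
    syn <- attraction_effect(results, "p_error", factor = "syn_match")
    lin <- attraction_effect(results, "p_error", factor = "lin_match")
    m <- merge(syn, lin, by = "instance", suffixes = c("_syn", "_lin"))
    m$effect <- m$effect_syn - m$effect_lin
    add("distance_contrast", m)
  } else if (paradigm == "haskell_macdonald") {
    agg <- aggregate(p_plural ~ instance + closer_number, results, mean)
    m <- merge(agg[agg$closer_number == "pl", c("instance", "p_plural")],
               agg[agg$closer_number == "sg", c("instance", "p_plural")],
               by = "instance", suffixes = c("_pl", "_sg"))
    m$effect <- m$p_plural_pl - m$p_plural_sg
    add("plural_rate_contrast", m)
  } else if (paradigm == "humphreys_bock") {
    agg <- aggregate(p_plural ~ instance + preposition_bias, results, mean)
    m <- merge(
      agg[agg$preposition_bias == "distributive",
          c("instance", "p_plural")],
      agg[agg$preposition_bias == "collective", c("instance", "p_plural")],
      by = "instance", suffixes = c("_dist", "_coll"))
    m$effect <- m$p_plural_dist - m$p_plural_coll
    add("plural_rate_contrast", m)
  } else if (paradigm %in% c("parker_an", "wagers")) {
    resp <- if ("surprisal" %in% names(results)) "surprisal" else "p_error"
    a <- attraction_effect(results, resp, by = "grammaticality")
    g <- a[a$grammaticality == "gram", ]
    u <- a[a$grammaticality == "ungram", ]
    m <- merge(u[c("instance", "effect")], g[c("instance", "effect")],
               by = "instance", suffixes = c("_ungram", "_gram"))
    m$effect <- m$effect_ungram - m$effect_gram
    add("grammaticality_asymmetry", m)
  } else {
    stop("no contrasts registered for paradigm ", paradigm, call. = FALSE)
  }
  do.call(rbind, out)
}
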