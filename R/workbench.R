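#' @noRd
param_checksum <- function(model) {
  v <- unlist(lapply(model$params, function(x)
    if (is.list(x)) unlist(x) else x), use.names = FALSE)
  sprintf("%.10e/%.10e", sum(v), sum(abs(v)))
}

#' @noRd
default_stats_spec <- function(paradigm) {
  switch(paradigm,
    bock_cutting = regression_spec(
      "p_error", "attractor_match * subject_number * modifier"),
    franck = regression_spec("p_error", "syn_match + lin_match"),
    haskell_macdonald = regression_spec("p_plural", "closer_number"),
    humphreys_bock = regression_spec("p_plural", "preposition_bias"),
    parker_an = regression_spec(
      "surprisal", "attractor_match * grammaticality * argument"),
    wagers = regression_spec("surprisal",
                             "attractor_match * grammaticality"),
    stop("no default analysis registered for paradigm ", paradigm,
         call. = FALSE))
}

#' End-to-end toy replication driver
#'
#' Orchestrates the full pipeline at a configurable (by default small)
#' scale: generate a training and a held-out corpus, train LM-only and
#' multitask instance sets, generate paradigm items, run the production
#' and comprehension harnesses, fit the paradigm's mixed-effects analysis,
#' optionally run the probing analyses, and write per-paradigm trial,
#' effect and coefficient tables plus a run manifest to `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param corpus_config a [grammar_config()]; its seed is overridden by
#'   `seed`.
#' @param n_train,n_heldout corpus sizes in sentences.
#' @param encoder an [encoder_config()].
#' @param train a [train_config()] (its seed is derived from `seed`).
#' @param paradigms which paradigms to simulate.
#' @param n_items items per paradigm.
#' @param linking linking rule for production paradigms.
#' @param probing run the ablation sweep and amnesic report.
#' @param seed master seed; every stage's seed derives from it.
#' @return Invisibly, a list with the trained models, per-paradigm results
#'   (`trials`, `effects`, `fit`), the probing report, and the manifest.
#' @export
replicate_toy <- function(out_dir,
                          corpus_config = grammar_config(),
                          n_train = 10000, n_heldout = 1000,
                          encoder = encoder_config(num_layers = 2,
                                                   hidden_size = 64,
                                                   embedding_size = 64),
                          train = train_config(epochs = 2, n_instances = 2),
                          paradigms = c("bock_cutting", "wagers"),
                          n_items = 16, linking = "one_sample",
                          probing = TRUE, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  manifest <- list(seed = seed, package_version =
                     as.character(utils::packageVersion("agreesim")),
                   r_version = R.version.string,
                   config = list(n_train = n_train, n_heldout = n_heldout,
                                 encoder = unclass(encoder),
                                 train = unclass(train),
                                 corpus = unclass(corpus_config),
                                 paradigms = paradigms, n_items = n_items,
                                 linking = linking),
                   stages = list(), warnings = list())
  stage_times <- list()
  run_stage <- function(name, expr) {
    st <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      manifest$error <<- list(stage = name, message = conditionMessage(e))
      write_manifest(manifest, out_dir)
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    stage_times[[name]] <<- as.numeric(difftime(Sys.time(), st,
                                                units = "secs"))
    res
  }

  corpus_config$seed <- seed
  corpora <- run_stage("corpus", {
    tr_cfg <- corpus_config
    ho_cfg <- corpus_config
    ho_cfg$seed <- seed + 1L
    list(train = generate_corpus(tr_cfg, n_train),
         heldout = generate_corpus(ho_cfg, n_heldout))
  })
  vocab <- build_vocab(corpora$train)

  models <- run_stage("train", {
    cfg <- train
    cfg$seed <- seed + 100L
    lm_only <- train_instances(vocab, corpora$train, cfg, encoder,
                               tagset = NULL)
    cfg$seed <- seed + 200L
    multitask <- train_instances(vocab, corpora$train, cfg, encoder,
                                 tagset = grammar_tagset())
    list(lm_only = lm_only, multitask = multitask)
  })

  results <- list()
  for (p in paradigms) {
    results[[p]] <- run_stage(paste0("simulate_", p), {
      items <- generate_paradigm_items(p, corpus_config, n_items,
                                       seed = seed + 300L)
      items <- apply_oov_policy(items, vocab)$items
      reading <- unique(items$measure) == "reading"
      per_variant <- lapply(models, function(ms) {
        if (reading) run_comprehension(ms, items)
        else run_production(ms, items, linking = linking)
      })
      trials <- do.call(rbind, Map(function(tr, nm) {
        tr$model_variant <- nm
        tr
      }, per_variant, names(per_variant)))
      effects <- do.call(rbind, Map(function(tr, nm) {
        ef <- tryCatch(asymmetry_contrasts(tr), error = function(e) NULL)
        at <- if ("attractor_match" %in% names(tr)) {
          resp <- if (reading) "surprisal" else "p_error"
          a <- attraction_effect(tr, resp)
          data.frame(instance = a$instance, effect_name = "attraction",
                     value = a$effect)
        } else NULL
        out <- rbind(at, ef)
        if (!is.null(out)) out$model_variant <- nm
        out
      }, per_variant, names(per_variant)))
      spec <- default_stats_spec(p)
      fits <- lapply(per_variant, function(tr) {
        if (reading) fit_linear_mixed(tr, spec)
        else fit_beta_mixed(tr, spec)
      })
      coefs <- do.call(rbind, Map(function(f, nm) {
        cf <- f$coefficients
        cf$model_variant <- nm
        cf$converged <- f$converged
        cf
      }, fits, names(fits)))
      tr_out <- trials
      tr_out$series <- NULL
      write.csv(tr_out, file.path(out_dir, paste0("trials_", p, ".csv")),
                row.names = FALSE)
      write.csv(effects, file.path(out_dir, paste0("effects_", p, ".csv")),
                row.names = FALSE)
      write.csv(coefs, file.path(out_dir, paste0("coefs_", p, ".csv")),
                row.names = FALSE)
      list(items = items, trials = trials, effects = effects, fits = fits)
    })
  }

  probe_report <- NULL
  if (probing) {
    probe_report <- run_stage("probing", {
      mm <- models$multitask[[1]]
      lo <- models$lm_only[[1]]
      sweep <- ablation_sweep(mm, corpora$heldout)
      sweep_df <- rbind(
        cbind(sweep$records, baseline = FALSE),
        cbind(unit = NA, sweep$baseline, baseline = TRUE))
      write.csv(sweep_df, file.path(out_dir, "probe_ablation.csv"),
                row.names = FALSE)
      rep4 <- amnesic_report(mm, lo, corpora$heldout)
      write.csv(rep4, file.path(out_dir, "probe_amnesic.csv"),
                row.names = FALSE)
      list(ablation = sweep, amnesic = rep4)
    })
  }

  manifest$stages <- stage_times
  manifest$model_checksums <- list(
    lm_only = vapply(models$lm_only, param_checksum, character(1)),
    multitask = vapply(models$multitask, param_checksum, character(1)))
  manifest$total_seconds <- as.numeric(difftime(Sys.time(), t0,
                                                units = "secs"))
  write_manifest(manifest, out_dir)
  invisible(list(vocab = vocab, corpora = corpora, models = models,
                 results = results, probing = probe_report,
                 manifest = manifest))
}

# Manifest is written atomically: serialize to a temp file, then rename.
#' @noRd
write_manifest <- function(manifest, out_dir) {
  tmp <- tempfile(tmpdir = out_dir, fileext = ".json")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  invisible(NULL)
}
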