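test_that("the production harness counts rows and matches recomputation", {
  fx <- tiny_trained()
  items <- generate_paradigm_items("bock_cutting", fx$config, n_items = 3,
                                   seed = 2)
  models <- list(fx$multitask, fx$lm_only)
  res <- run_production(models, items)
  expect_equal(nrow(res), 2 * nrow(items)) # instances x (items x cells)
  expect_true(all(res$p_singular >= 0 & res$p_singular <= 1))
  expect_equal(res$p_singular + res$p_plural, rep(1, nrow(res)))
  # spot-check three random rows against a loop-free recomputation
  set.seed(5)
  for (i in sample(nrow(res), 3)) {
    model <- if (res$instance[i] == 1) fx$multitask else fx$lm_only
    d <- next_word_distribution(model,
                                strsplit(res$tokens[i], " ")[[1]])
    expect_equal(res$p_singular[i],
                 d[["is"]] / (d[["is"]] + d[["are"]]), tolerance = 1e-12)
  }
  # p_error is the subject-incongruent probability
  sg <- res$subject_number == "sg"
  expect_equal(res$p_error[sg], res$p_plural[sg])
  expect_equal(res$p_error[!sg], res$p_singular[!sg])
})

test_that("the comprehension harness measures surprisal at the critical token", {
  fx <- tiny_trained()
  items <- generate_paradigm_items("wagers", fx$config, n_items = 3,
                                   seed = 4)
  res <- run_comprehension(fx$multitask, items)
  expect_equal(nrow(res), nrow(items))
  for (i in seq_len(nrow(res))) {
    ss <- surprisal_series(fx$multitask, strsplit(res$tokens[i], " ")[[1]])
    expect_equal(res$surprisal[i], unname(ss[res$critical_index[i]]))
    expect_equal(unname(res$series[[i]]), unname(ss))
  }
  # statelessness: permuting item order leaves every measure unchanged
  set.seed(6)
  perm <- sample(nrow(items))
  res2 <- run_comprehension(fx$multitask, items[perm, ])
  expect_equal(res2$surprisal, res$surprisal[perm])
  # interleaving production does not change comprehension measures
  citems <- generate_paradigm_items("bock_cutting", fx$config, n_items = 2,
                                    seed = 4)
  invisible(run_production(fx$multitask, citems))
  res3 <- run_comprehension(fx$multitask, items)
  expect_identical(res3$surprisal, res$surprisal)
})

test_that("instance results are independent of the batch composition", {
  fx <- tiny_trained()
  items <- generate_paradigm_items("bock_cutting", fx$config, n_items = 2,
                                   seed = 8)
  both <- run_production(list(fx$multitask, fx$lm_only), items)
  solo <- run_production(list(fx$lm_only), items)
  expect_equal(both$p_singular[both$instance == 2], solo$p_singular)
})

test_that("attraction effects reduce to group-mean differences", {
  grid <- expand.grid(instance = 1:2, item = 1:3,
                      attractor_match = c("match", "mismatch"),
                      stringsAsFactors = FALSE)
  grid$p_error <- ifelse(grid$attractor_match == "mismatch", 0.6, 0.2)
  eff <- attraction_effect(grid)
  expect_equal(eff$effect, rep(0.4, 2))
  # equal cell means: zero effect
  grid$p_error <- 0.3
  expect_equal(attraction_effect(grid)$effect, rep(0, 2))
  # hand-computed groupby difference on an unbalanced-value fixture
  set.seed(9)
  grid$p_error <- runif(nrow(grid))
  eff <- attraction_effect(grid)
  for (k in 1:2) {
    sub <- grid[grid$instance == k, ]
    oracle <- mean(sub$p_error[sub$attractor_match == "mismatch"]) -
      mean(sub$p_error[sub$attractor_match == "match"])
    expect_equal(eff$effect[eff$instance == k], oracle)
  }
  expect_error(attraction_effect(grid[grid$attractor_match == "match", ]),
               "both")
})

test_that("asymmetry contrasts implement the paradigm definitions", {
  # number asymmetry: zero when attraction is equal across subject numbers
  g <- expand.grid(instance = 1, item = 1:4,
                   subject_number = c("sg", "pl"),
                   attractor_match = c("match", "mismatch"),
                   modifier = c("pp", "rc"), stringsAsFactors = FALSE)
  g$paradigm <- "bock_cutting"
  g$p_error <- ifelse(g$attractor_match == "mismatch", 0.5, 0.2)
  out <- asymmetry_contrasts(g)
  expect_equal(out$value[out$effect_name == "number_asymmetry"], 0)
  # grammaticality asymmetry from known attraction effects (0.4 vs 0.1)
  w <- expand.grid(instance = 1, item = 1:4,
                   attractor_match = c("match", "mismatch"),
                   grammaticality = c("gram", "ungram"),
                   stringsAsFactors = FALSE)
  w$paradigm <- "wagers"
  w$p_error <- 0.2 + ifelse(w$attractor_match == "mismatch",
                            ifelse(w$grammaticality == "ungram", 0.4, 0.1),
                            0)
  out <- asymmetry_contrasts(w)
  expect_equal(out$value[out$effect_name == "grammaticality_asymmetry"],
               0.3)
  # Franck marginalization equals brute-force averaging over the other
  # attractor's levels
  f <- expand.grid(instance = 1:2, item = 1:3,
                   syn_match = c("match", "mismatch"),
                   lin_match = c("match", "mismatch"),
                   stringsAsFactors = FALSE)
  f$paradigm <- "franck"
  set.seed(10)
  f$p_error <- runif(nrow(f))
  out <- asymmetry_contrasts(f)
  for (k in 1:2) {
    sub <- f[f$instance == k, ]
    syn <- mean(sub$p_error[sub$syn_match == "mismatch"]) -
      mean(sub$p_error[sub$syn_match == "match"])
    lin <- mean(sub$p_error[sub$lin_match == "mismatch"]) -
      mean(sub$p_error[sub$lin_match == "match"])
    expect_equal(out$value[out$instance == k], syn - lin)
  }
})

test_that("the oracle predictor has closed-form expectations", {
  cfg <- grammar_config(n_nouns = 80, seed = 1)
  items <- generate_paradigm_items("bock_cutting", cfg, n_items = 40,
                                   seed = 3)
  # no effects, no noise: every trial is at 0.5
  flat <- make_oracle_predictor(n_instances = 2, seed = 1)
  res <- run_production(flat, items)
  expect_equal(res$p_singular, rep(0.5, nrow(res)))
  expect_equal(nrow(res), 2 * nrow(items))
  # mismatch contribution +1: attraction = logistic(1) - logistic(0)
  orc <- make_oracle_predictor(
    effects = list(list(when = c(attractor_match = "mismatch"),
                        delta = 1.0)),
    n_instances = 2, seed = 2)
  eff <- attraction_effect(run_production(orc, items))
  expect_equal(eff$effect, rep(plogis(1) - plogis(0), 2), tolerance = 1e-12)
  # beta noise changes draws but not expectations (two seeds agree in mean)
  noisy1 <- make_oracle_predictor(
    effects = list(list(when = c(attractor_match = "mismatch"),
                        delta = 1.0)),
    phi = 200, n_instances = 5, seed = 31)
  noisy2 <- make_oracle_predictor(
    effects = list(list(when = c(attractor_match = "mismatch"),
                        delta = 1.0)),
    phi = 200, n_instances = 5, seed = 32)
  e1 <- mean(attraction_effect(run_production(noisy1, items))$effect)
  e2 <- mean(attraction_effect(run_production(noisy2, items))$effect)
  expect_false(identical(e1, e2))
  expect_equal(e1, e2, tolerance = 0.02)
  expect_equal(e1, plogis(1) - plogis(0), tolerance = 0.02)
  expect_error(run_production(
    make_oracle_predictor(effects = list(list(when = c(zzz = "a"),
                                              delta = 1))), items),
    "unknown factor")
})
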