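test_that("an intercept-only beta fit matches a grid-search ML oracle", {
  set.seed(21)
  y <- rbeta(400, 0.3 * 20, 0.7 * 20)
  dat <- data.frame(p_error = y, one = 1)
  spec <- regression_spec("p_error", "1", random_intercepts = character(0))
  fit <- fit_beta_mixed(dat, spec)
  expect_true(fit$converged)
  # grid-search oracle: profile the beta likelihood over the mean
  prof <- function(mu) optimize(function(phi)
    -sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE)),
    c(0.1, 2000))$objective
  grid <- seq(0.15, 0.45, by = 2e-4)
  mu_hat <- grid[which.min(vapply(grid, prof, numeric(1)))]
  expect_equal(plogis(fit$coefficients$estimate[1]), mu_hat,
               tolerance = 1e-3)
  # degenerate input: identical responses are rejected with a diagnostic
  expect_error(
    fit_beta_mixed(data.frame(p_error = rep(0.4, 50)), spec),
    "degenerate")
})

test_that("responses at 0/1 are squeezed, interior responses untouched", {
  y <- c(0, 0.5, 1)
  sq <- agreesim:::squeeze01(y)
  expect_true(all(sq > 0 & sq < 1))
  expect_equal(sq, (y * 2 + 0.5) / 3)
  expect_identical(agreesim:::squeeze01(c(0.2, 0.8)), c(0.2, 0.8))
})

test_that("linear fixed effects match closed-form level differences", {
  set.seed(22)
  d <- data.frame(x = rep(c("match", "mismatch"), each = 40))
  d$surprisal <- ifelse(d$x == "mismatch", 2, 1) + rnorm(80, sd = 0.3)
  names(d)[1] <- "attractor_match"
  spec <- regression_spec("surprisal", "attractor_match",
                          random_intercepts = character(0))
  fit <- fit_linear_mixed(d, spec)
  diff_means <- mean(d$surprisal[d$attractor_match == "mismatch"]) -
    mean(d$surprisal[d$attractor_match == "match"])
  # with +/-0.5 sum coding the slope is the full level difference and the
  # intercept is the grand mean
  expect_equal(fit$coefficients$estimate[2], diff_means, tolerance = 1e-8)
  expect_equal(fit$coefficients$estimate[1], mean(d$surprisal),
               tolerance = 1e-6)
  # constant response: flagged
  d$surprisal <- 3
  fit0 <- fit_linear_mixed(d, spec)
  expect_equal(fit0$coefficients$estimate[2], 0)
  expect_true(any(grepl("zero residual variance", fit0$flags)))
})

test_that("mixed fits recover simulated random-intercept structure", {
  set.seed(23)
  n_item <- 30; n_inst <- 4
  d <- expand.grid(item = seq_len(n_item), instance = seq_len(n_inst),
                   rep = 1:4)
  re_item <- rnorm(n_item, 0, 1)
  re_inst <- rnorm(n_inst, 0, 0.5)
  d$surprisal <- 2 + re_item[d$item] + re_inst[d$instance] + rnorm(nrow(d))
  spec <- regression_spec("surprisal", "1")
  fit <- fit_linear_mixed(d, spec)
  expect_true(fit$converged)
  expect_equal(unname(fit$ranef_variance[["item"]]), 1, tolerance = 0.5)
  expect_gt(fit$loglik,
            fit_linear_mixed(d, regression_spec(
              "surprisal", "1", random_intercepts = "item"))$loglik)
})

test_that("pruning keeps a converging maximal model and prunes degenerate ones", {
  set.seed(24)
  # rich data with real slope variance: the maximal model converges
  n_item <- 40
  d <- expand.grid(item = seq_len(n_item), instance = 1:5, rep = 1:6,
                   attractor_match = c("match", "mismatch"),
                   stringsAsFactors = FALSE)
  x <- ifelse(d$attractor_match == "mismatch", 0.5, -0.5)
  slope_item <- rnorm(n_item, 0, 0.8)
  d$surprisal <- 1 + (1 + slope_item[d$item]) * x +
    rnorm(n_item)[d$item] + rnorm(5, 0, 0.5)[d$instance] +
    rnorm(nrow(d), sd = 0.5)
  maximal <- regression_spec("surprisal", "attractor_match",
                             random_intercepts = c("item", "instance"),
                             random_slopes = list(item = "attractor_match"))
  pr <- prune_random_effects(d, maximal, kind = "linear")
  expect_identical(pr$spec$random_slopes, maximal$random_slopes)
  expect_equal(nrow(pr$path), 1)
  # one observation per item-cell with no slope variance: slopes pruned,
  # both intercepts kept
  d2 <- expand.grid(item = 1:12, instance = 1:3,
                    attractor_match = c("match", "mismatch"),
                    stringsAsFactors = FALSE)
  x2 <- ifelse(d2$attractor_match == "mismatch", 0.5, -0.5)
  d2$surprisal <- 1 + 0.5 * x2 + rnorm(12, 0, 0.5)[d2$item] +
    rnorm(3, 0, 0.3)[d2$instance] + rnorm(nrow(d2), sd = 0.2)
  maximal2 <- regression_spec(
    "surprisal", "attractor_match",
    random_intercepts = c("item", "instance"),
    random_slopes = list(item = "attractor_match",
                         instance = "attractor_match"))
  pr2 <- prune_random_effects(d2, maximal2, kind = "linear")
  expect_setequal(pr2$spec$random_intercepts, c("item", "instance"))
  expect_length(unlist(pr2$spec$random_slopes), 0)
  # deterministic pruning path
  pr3 <- prune_random_effects(d2, maximal2, kind = "linear")
  expect_identical(pr2$path, pr3$path)
})

test_that("the equality-constraint LRT behaves like a likelihood ratio", {
  set.seed(25)
  d <- expand.grid(item = 1:20, instance = 1:5, rep = 1:3)
  xa <- rnorm(nrow(d))
  xb <- rnorm(nrow(d))
  d$xa <- xa; d$xb <- xb
  d$surprisal <- 1 + 0.8 * xa + 0.2 * xb + rnorm(20, 0, 0.4)[d$item] +
    rnorm(nrow(d), sd = 0.5)
  spec <- regression_spec("surprisal", "xa + xb",
                          random_intercepts = "item")
  fit <- fit_linear_mixed(d, spec)
  # self-constraint: statistic 0, p = 1
  self <- linear_hypothesis_test(fit, "xa", "xa")
  expect_equal(self$statistic, 0)
  expect_equal(self$p, 1)
  lrt <- linear_hypothesis_test(fit, "xa", "xb")
  expect_gt(lrt$statistic, 0)
  expect_lt(lrt$p, 0.05)
  # independent recomputation of the two ML log-likelihoods
  full <- lme4::lmer(surprisal ~ xa + xb + (1 | item), d, REML = FALSE)
  d$xs <- d$xa + d$xb
  constr <- lme4::lmer(surprisal ~ xs + (1 | item), d, REML = FALSE)
  expect_equal(lrt$statistic,
               2 * (as.numeric(logLik(full)) - as.numeric(logLik(constr))),
               tolerance = 1e-6)
  expect_error(linear_hypothesis_test(fit, "xa", "nope"), "not in model")
})

test_that("Wald z and the 1-df LRT agree asymptotically", {
  set.seed(26)
  d <- expand.grid(item = 1:60, instance = 1:5, rep = 1:10,
                   attractor_match = c("match", "mismatch"),
                   stringsAsFactors = FALSE)
  x <- ifelse(d$attractor_match == "mismatch", 0.5, -0.5)
  mu <- plogis(-0.5 + 0.12 * x)
  d$p_error <- rbeta(nrow(d), mu * 60, (1 - mu) * 60)
  spec <- regression_spec("p_error", "attractor_match",
                          random_intercepts = character(0))
  fit <- fit_beta_mixed(d, spec)
  z <- fit$coefficients$statistic[2]
  # drop-term LRT computed directly from the two beta fits
  null_spec <- regression_spec("p_error", "1",
                               random_intercepts = character(0))
  fit0 <- fit_beta_mixed(d, null_spec)
  lrt <- 2 * (fit$loglik - fit0$loglik)
  expect_lt(abs(abs(z) - sqrt(lrt)) / sqrt(lrt), 0.10)
})

test_that("nested models never lose likelihood and stay nonnegative", {
  set.seed(27)
  d <- expand.grid(item = 1:15, instance = 1:4,
                   attractor_match = c("match", "mismatch"),
                   subject_number = c("sg", "pl"),
                   stringsAsFactors = FALSE)
  mu <- plogis(-0.3 + 0.5 * (d$attractor_match == "mismatch"))
  d$p_error <- rbeta(nrow(d), mu * 30, (1 - mu) * 30)
  full <- fit_beta_mixed(d, regression_spec(
    "p_error", "attractor_match * subject_number",
    random_intercepts = "item"))
  lrt <- linear_hypothesis_test(full, "attractor_match", "subject_number")
  expect_gte(lrt$statistic, 0)
  expect_gte(lrt$loglik_full, lrt$loglik_constrained)
  expect_true(lrt$p >= 0 && lrt$p <= 1)
})
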