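#' Linear supertag probe
#'
#' A linear classifier `C(x) = W x + b` over final-layer hidden states.
#'
#' @param W weight matrix (tagset size x hidden size).
#' @param b bias vector (tagset size).
#' @param tagset optional character vector naming the classes.
#' @return An object of class `linear_probe`.
#' @export
linear_probe <- function(W, b = numeric(nrow(W)), tagset = NULL) {
  W <- as.matrix(W)
  if (length(b) != nrow(W))
    stop("bias length must equal the number of classes", call. = FALSE)
  structure(list(W = W, b = as.numeric(b), tagset = tagset),
            class = "linear_probe")
}

#' Extract the internal supertag decoder as a probe
#'
#' @param model a multitask `agr_lm`.
#' @return A `linear_probe` wrapping the model's supertag decoder.
#' @export
probe_from_model <- function(model) {
  if (is.null(model$params$tag_w))
    stop("model has no supertag decoder", call. = FALSE)
  linear_probe(model$params$tag_w, model$params$tag_b, model$tagset)
}

#' @noRd
probe_predict <- function(probe, h) {
  logits <- h %*% t(probe$W)
  logits <- sweep(logits, 2, probe$b, `+`)
  max.col(logits, ties.method = "first")
}

#' Nullspace projector of a linear probe
#'
#' Constructs the orthogonal projector `T = I - W^+ W` onto the nullspace
#' of the probe's weight matrix (a single step of iterated nullspace
#' projection). For any representation `x`, `W (T x) = 0`: after
#' projection the classifier's input-dependent logit component vanishes
#' and its output reduces to the constant bias, so it can no longer
#' distinguish representations. The pseudo-inverse is computed by singular
#' value decomposition with a relative cutoff of 1e-10.
#'
#' @param probe a [linear_probe()].
#' @return An object of class `nullspace_projector` with elements `mat`
#'   (H x H, symmetric, idempotent) and `rank_deficit` (`rank(W)`). If `W`
#'   has full column rank the projector is the zero matrix (with a
#'   warning): every direction is predictive.
#' @export
nullspace_projector <- function(probe) {
  stopifnot(inherits(probe, "linear_probe"))
  W <- probe$W
  if (all(W == 0)) stop("probe weight matrix is zero", call. = FALSE)
  H <- ncol(W)
  sv <- svd(W, nu = 0, nv = min(nrow(W), H))
  r <- sum(sv$d > max(sv$d) * 1e-10)
  if (r >= H)
    warning("probe has full column rank: the nullspace projector is 0",
            call. = FALSE)
  Vr <- sv$v[, seq_len(r), drop = FALSE]
  Tm <- diag(H) - Vr %*% t(Vr)
  structure(list(mat = Tm, rank_deficit = r), class = "nullspace_projector")
}

#' @export
print.nullspace_projector <- function(x, ...) {
  cat(sprintf("<nullspace_projector> %d x %d, rank(W) = %d\n",
              nrow(x$mat), ncol(x$mat), x$rank_deficit))
  invisible(x)
}

#' Per-unit ablation sweep
#'
#' Zeroes, in turn, each unit of the final recurrent layer and records the
#' word-prediction and supertagging losses over the evaluation corpus,
#' along with the unablated baseline (the dashed-line reference). The
#' correlation between the two loss columns indicates how far the two
#' tasks share localized representations.
#'
#' @param model a multitask `agr_lm`.
#' @param corpus a tagged evaluation corpus.
#' @param units which units to sweep (default: all).
#' @return List with `records` (data frame: `unit`, `word_loss`,
#'   `tag_loss`), `baseline` (one-row data frame), and `correlation`
#'   (Pearson r between the two loss columns).
#' @export
ablation_sweep <- function(model, corpus, units = NULL) {
  if (is.null(model$tagset))
    stop("ablation sweep requires a multitask model", call. = FALSE)
  if (is.null(corpus$records[[1]]$supertags))
    stop("evaluation corpus must be tagged", call. = FALSE)
  H <- model$encoder$hidden_size
  units <- units %||% seq_len(H)
  base <- evaluate_lm(model, corpus, tags = TRUE)
  rec <- lapply(units, function(u) {
    ev <- evaluate_lm(ablate_unit(model, u), corpus, tags = TRUE)
    data.frame(unit = u, word_loss = ev$word_loss, tag_loss = ev$tag_loss)
  })
  records <- do.call(rbind, rec)
  list(records = records,
       baseline = data.frame(word_loss = base$word_loss,
                             tag_loss = base$tag_loss),
       correlation = if (nrow(records) > 1)
         stats::cor(records$word_loss, records$tag_loss) else NA_real_)
}

#' Amnesic evaluation
#'
#' Evaluates word-prediction loss and supertag accuracy before and after
#' applying a nullspace projector to every final-layer representation.
#' Projection is applied at evaluation time only (no retraining), matching
#' a single nullspace-projection step. After projection the probe's
#' predictions are constant (the argmax of its bias), so its accuracy
#' collapses to that single class's empirical rate.
#'
#' @param model an `agr_lm`.
#' @param probe the `linear_probe` whose information is removed (for a
#'   multitask model, typically [probe_from_model()]; for an LM-only
#'   model, a probe from [train_frozen_probe()]).
#' @param corpus tagged evaluation corpus.
#' @param projector optionally a precomputed [nullspace_projector()];
#'   defaults to the probe's.
#' @return Data frame with rows `baseline` and `amnesic` and columns
#'   `condition`, `lm_loss` (mean nats/token), `ccg_accuracy`.
#' @export
amnesic_eval <- function(model, probe, corpus, projector = NULL) {
  stopifnot(inherits(probe, "linear_probe"))
  projector <- projector %||% nullspace_projector(probe)
  Tm <- projector$mat
  if (ncol(Tm) != model$encoder$hidden_size)
    stop("projector width does not match the encoder output", call. = FALSE)
  hs <- hidden_states(model, corpus, tagset = probe$tagset %||% model$tagset)
  if (is.null(hs$tag_id))
    stop("corpus must carry supertags", call. = FALSE)
  acc <- function(h) mean(probe_predict(probe, h) == hs$tag_id)
  lm_base <- evaluate_lm(model, corpus)$word_loss
  lm_amn <- evaluate_lm(model, corpus, proj = Tm)$word_loss
  data.frame(condition = c("baseline", "amnesic"),
             lm_loss = c(lm_base, lm_amn),
             ccg_accuracy = c(acc(hs$h), acc(hs$h %*% Tm)))
}

#' Train a frozen-encoder supertag probe
#'
#' Trains only the probe's weights and bias by full-batch gradient descent
#' on the softmax cross-entropy over the (fixed) final-layer hidden states
#' of an LM-only model; the encoder parameters are untouched. This gives
#' the baseline for how much supertag information is present in
#' representations learned from word prediction alone.
#'
#' @param model an `agr_lm` without a supertag decoder.
#' @param corpus a tagged corpus.
#' @param tagset tagset to classify into (default [grammar_tagset()]).
#' @param iters gradient-descent iterations.
#' @param lr learning rate.
#' @return A `linear_probe`; its attribute `"trace"` holds the loss path.
#' @export
train_frozen_probe <- function(model, corpus, tagset = grammar_tagset(),
                               iters = 300, lr = 0.5) {
  if (!is.null(model$params$tag_w))
    stop("frozen-probe training expects an LM-only model ",
         "(no supertag decoder)", call. = FALSE)
  hs <- hidden_states(model, corpus, tagset = tagset)
  if (anyNA(hs$tag_id))
    stop("corpus tags outside the tagset", call. = FALSE)
  fit_linear_probe(hs$h, hs$tag_id, length(tagset), iters = iters, lr = lr,
                   tagset = tagset)
}

#' Fit a linear softmax classifier on fixed representations
#'
#' Full-batch gradient descent on the multinomial cross-entropy; this is
#' the optimizer behind [train_frozen_probe()], exposed so probes can be
#' fit on arbitrary representation sets.
#'
#' @param X representation matrix (rows are examples).
#' @param y integer class labels in `1..K`.
#' @param K number of classes.
#' @param iters,lr gradient-descent iterations and learning rate.
#' @param tagset optional class names.
#' @return A `linear_probe`; its attribute `"trace"` holds the loss path.
#' @export
fit_linear_probe <- function(X, y, K = max(y), iters = 300, lr = 0.5,
                             tagset = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  W <- matrix(0, K, ncol(X))
  b <- numeric(K)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), y)] <- 1
  trace <- numeric(iters)
  for (it in seq_len(iters)) {
    logits <- X %*% t(W)
    logits <- sweep(logits, 2, b, `+`)
    logits <- logits - apply(logits, 1, max)
    P <- exp(logits)
    P <- P / rowSums(P)
    trace[it] <- -mean(log(P[cbind(seq_len(n), y)]))
    G <- (P - Y) / n
    W <- W - lr * t(G) %*% X
    b <- b - lr * colSums(G)
  }
  out <- linear_probe(W, b, tagset)
  attr(out, "trace") <- trace
  out
}

#' Predicted classes of a linear probe
#'
#' @param probe a [linear_probe()].
#' @param h representation matrix (rows are examples).
#' @return Integer vector of predicted class indices.
#' @export
predict_probe <- function(probe, h) {
  probe_predict(probe, as.matrix(h))
}

#' Four-condition amnesic report
#'
#' Builds the standard report contrasting a multitask model (internal
#' probe) and an LM-only model (frozen probe) before and after amnesic
#' projection: rows `LM+CCG` / `LM-Only` x `baseline` / `amnesic` with
#' word-prediction loss and supertag accuracy.
#'
#' @param multitask_model a multitask `agr_lm`.
#' @param lm_only_model an LM-only `agr_lm`.
#' @param corpus tagged evaluation corpus.
#' @param frozen_probe optional pretrained probe for the LM-only model;
#'   trained on `corpus` if omitted.
#' @return Data frame with columns `model_variant`, `condition`,
#'   `lm_loss`, `ccg_accuracy`.
#' @export
amnesic_report <- function(multitask_model, lm_only_model, corpus,
                           frozen_probe = NULL) {
  pm <- probe_from_model(multitask_model)
  fp <- frozen_probe %||% train_frozen_probe(lm_only_model, corpus)
  a <- amnesic_eval(multitask_model, pm, corpus)
  b <- amnesic_eval(lm_only_model, fp, corpus)
  a$model_variant <- "LM+CCG"
  b$model_variant <- "LM-Only"
  out <- rbind(a, b)
  out[c("model_variant", "condition", "lm_loss", "ccg_accuracy")]
}
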