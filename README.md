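# agreesim

Simulating subject-verb agreement attraction with recurrent neural
language models.

## The problem

English subject-verb agreement requires the verb to match its subject's
number ("the key **is** rusty", "the keys **are** rusty"). Speakers and
readers nevertheless err systematically when a nearby noun phrase — an
*attractor* — differs in number from the subject ("the key to the
cabinets **are** rusty"). The strength of this *agreement attraction*
depends on the attractor's syntactic position, its linear distance to the
verb, its grammatical versus notional number, and the grammaticality of
the sentence being read; no single hand-built processing model covers all
of these findings.

`agreesim` implements a different modeling strategy: treat a
broad-coverage neural language model — a network trained only to predict
the next word — as the processing model, derive behavioral predictions
from its next-word distributions through explicit linking functions, and
run the model through the same factorial designs used in the human
experiments. The package is aimed at computational psycholinguists who
want a controlled, fully reproducible test bed for this paradigm: every
component, from the training corpus to the mixed-effects analysis, is
generated and fit in code.

## What is in the box

* **Synthetic corpus generator** — a probabilistic, number-marked toy
  grammar with PP and RC subject modifiers, nested PPs, disjunct subjects
  and per-token CCG-style supertags; construction rates are configurable
  and default to values typical of parsed edited text.
* **Recurrent language models** — word-level SRN
  (`h_i = tanh(W_h h_{i-1} + W_w w_i)`) and LSTM encoders with a softmax
  word decoder and an optional, equally weighted supertag decoder
  (the multi-task "LM+CCG" setting), trained by SGD with full
  backpropagation through time (compiled via RcppArmadillo).
* **Linking functions** — surprisal
  `s(w_i) = -log2 P(w_i | w_0..w_{i-1})` for self-paced-reading
  paradigms; *one-sample* (renormalized candidate probability),
  *max-prob* (argmax) and *n-sample* (majority of n draws) rules for
  sentence-completion paradigms, with the present-tense *be* pair
  (`is`/`are`) as the default candidates.
* **Six experimental paradigms** — PP vs. RC modifiers and the number
  asymmetry; syntactic vs. linear distance in double-PP subjects; linear
  distance in disjunct subjects; notional number with collective
  subjects; core vs. oblique attractors (reading); and the
  grammaticality asymmetry with RC-internal agreement (reading).
* **The inferential layer** — beta mixed-effects regression (logit link,
  Wald z tests) for probability responses, linear mixed-effects
  regression (t tests) for surprisal, convergence-driven random-effect
  pruning, and equality-constraint likelihood-ratio tests.
* **Representation probing** — per-unit ablation sweeps over the final
  layer, and single-step nullspace ("amnesic") projection
  `T = I - W^+ W` built from a supertag probe, with the frozen-encoder
  probe baseline for LM-only models.

## A worked example

Train two LSTM instances on a generated corpus and simulate a
sentence-completion experiment with PP/RC-modified subjects:

```r
library(agreesim)

cfg    <- grammar_config(seed = 1)            # construction rates, lexicon
corpus <- generate_corpus(cfg, 50000)
vocab  <- build_vocab(corpus)

models <- train_instances(
  vocab, corpus,
  train_config(epochs = 2, n_instances = 2, batch_size = 64, seed = 1),
  encoder_config(num_layers = 2, hidden_size = 64, embedding_size = 64))

items  <- generate_paradigm_items("bock_cutting", cfg, n_items = 16, seed = 2)
trials <- run_production(models, items, linking = "one_sample")

attraction_effect(trials)
#>   instance    effect
#> 1        1 0.2163162
#> 2        2 0.3855862

fit_beta_mixed(trials, regression_spec(
  "p_error", "attractor_match * subject_number"))
#> <fit_result> beta regression (z), converged
#>                             term estimate      se statistic         p
#> 1                    (Intercept)  -0.7333 0.09487    -7.730 1.078e-14
#> 2                attractor_match   1.5177 0.12585    12.059 1.738e-33
#> 3                 subject_number  -1.7604 0.12901   -13.645 2.152e-42
#> 4 attractor_match:subject_number  -0.5002 0.24001    -2.084 3.716e-02
#> random-intercept variances:
#>      item  instance
#> 1.580e-10 1.013e-02
```

The attraction effect is the rise in the model's error rate — the
renormalized probability of the subject-incongruent *be* form — when the
attractor mismatches the subject in number: here about 0.22 and 0.39 for
the two instances, and a strongly positive `attractor_match` coefficient
(log-odds, +/-0.5 sum coding) with |z| = 12.1. Factor coding is
sum-to-zero with the marked level (mismatch, singular subject, PP
modifier, ...) at +0.5, so main effects read as full level differences on
the link scale.

The whole pipeline — corpus, both model variants, all paradigms, the
mixed-effects fits and the probing analyses — can be run in one call:

```r
replicate_toy("runs/demo", n_train = 10000,
              paradigms = c("bock_cutting", "wagers"), seed = 1)
```

which writes per-paradigm trial, effect and coefficient tables, the
probing reports, and a JSON run manifest.

## Notes on scope

The toy grammar is a controlled stand-in for natural training corpora:
it reproduces the *structural* conditions for agreement attraction
(number marking, modifier attachment, disjunction) but not lexical
semantics, so paradigms that hinge on notional number are expected to
show null effects. See the methods vignette
(`vignettes/agreement-attraction.Rmd`) for the model, the linking
functions, the statistical conventions, and known limitations.
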