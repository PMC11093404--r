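---
title: "Modeling agreement attraction with recurrent language models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling agreement attraction with recurrent language models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
`agreesim`: the model, the linking hypotheses, what the synthetic corpus
does and does not emulate, the statistical conventions, and the
package's known limitations. It is the place to look when a default
needs to be questioned.

## The modeling paradigm

A word-level autoregressive language model assigns a distribution
$P(w_i \mid w_0 \dots w_{i-1})$ over the next word. The package treats
such a model, together with an explicit *linking function*, as a
processing model of agreement:

* **Comprehension (self-paced reading).** The per-word *surprisal*
  $s(w_i) = -\log_2 P(w_i \mid w_0 \dots w_{i-1})$ is the linking
  quantity for reading times, under the standard assumption that the
  surprisal–reading-time relation is approximately linear. The measure
  analyzed is the surprisal at the critical word; the full series is
  retained so spillover regions can be reported, but spillover pooling
  is an option, not part of the statistic.
* **Production (sentence completion).** Given a preamble, the
  probabilities of a singular/plural candidate pair (by default the
  present-tense forms of *be*, which are frequent and plausible after
  nearly any preamble) are renormalized to sum to one. Under the
  *one-sample* rule the renormalized singular probability is the
  probability that a single production sample is singular; *n-sample*
  takes the majority of $n$ independent draws (the upper binomial tail
  at $\lceil n/2 \rceil$; even $n$ is rejected because the majority is
  undefined), and *max-prob* is the $n \to \infty$ limit, a
  deterministic argmax. One-sample is the package default because it
  preserves sensitivity to graded probability differences; max-prob
  collapses them.

A trial's **error rate** is defined as the linked probability of the
verb form incongruent with the subject's grammatical number — a
continuous quantity, not a sampled binary outcome, because that is what
the beta regression consumes. For disjunct and collective subjects there
is no canonical agreement pattern, so the reported measure is the plural
rate itself.

Exact ties under max-prob are recorded as a distinct flagged outcome
(with a warning) and excluded from error-rate summaries: the rule does
not define a winner and we do not invent one. Candidate forms must be in
the vocabulary after sanitization; linking rejects out-of-vocabulary
candidates rather than silently using the unknown token.

## The encoders

Two encoders are provided. The SRN updates its state as
$h_i = \tanh(W_h h_{i-1} + W_w w_i)$. The LSTM uses the standard gating
equations — input, forget and output gates with logistic nonlinearities
and a tanh candidate cell — which the package states explicitly (and
tests against an independent R implementation) because "an LSTM" is
otherwise underdetermined. Both are trained with a softmax word decoder
over the vocabulary; the multi-task variant adds a second linear decoder
that predicts the supertag of the *most recent* input word from the same
hidden state. The two objectives are combined as the unweighted sum of
the two mean per-token cross-entropies ("equal weighting"); setting a
weight to zero provably leaves the corresponding decoder untouched.

Training is plain SGD over sentence minibatches with full
backpropagation through time. Sentences in this grammar are short and
bounded, so BPTT truncation would never bind and is not implemented; a
reserved `<s>` symbol conditions the first prediction and `</s>` is
predicted at sentence end. Numerical choices: uniform initialization on
$[-0.1, 0.1]$; LSTM forget-gate biases initialized at 1 so early
training does not discard state; global gradient-norm clipping at 5; the
learning rate is multiplied by `lr_decay` each epoch and halved whenever
the epoch's training loss fails to improve. A non-finite loss aborts
training with a diagnostic rather than returning a corrupt model.
Determinism is contracted: a fixed seed fixes initialization and batch
shuffling, and repeated runs produce identical parameters.

The ablation and amnesic analyses share one code path: both are a linear
map applied to the final-layer hidden state before *both* decoders —
ablating unit $j$ is exactly multiplication by a diagonal 0/1 mask, and
the amnesic step is multiplication by a projector, so the two analyses
are composable and mutually checkable.

## What the synthetic corpus emulates

The generator is a probabilistic grammar over an artificial lexicon in
which number is marked on surface forms (plural nouns end in `-s`,
singular verbs end in `-s`, the copula is `is`/`are`), so number is
learnable from form alone, as in English. Each sentence has grammatical
agreement between the subject and the main verb (and between a
relative-clause verb and its own subject): agreement errors in the
simulations must come from learning, not from corpus noise, mirroring
edited text.

Per-sentence construction rates are configurable; the defaults (PP
subject modifiers 0.15, RC modifiers 0.02, nested PPs 0.02, disjunct
subjects 0.005) follow the per-sentence rates of these constructions
observed in large parsed corpora of edited English text. Nouns are
plural with probability 0.35 — plural subjects are the rarer, marked
option, as in natural corpora. Verb phrases are copular predicates
(probability 0.5, keeping *is*/*are* frequent), intransitives (0.3) or
transitives (0.2); relative clauses are subject relatives with an object
(0.4), subject relatives with an oblique PP (0.3) or object relatives
(0.3). These interior proportions are fixed implementation constants;
the construction rates that matter for attraction are config-exposed.
When the subject is a disjunction the generator makes the verb agree
with the linearly closer (second) disjunct, the dominant prescriptive
pattern; this convention, not a discovery, defines `subject_number` for
disjuncts.

Supertags come from a closed inventory of eleven slash categories
derived from the grammar (determiner `NP/N`, noun `N`, copula
`(S\NP)/ADJ`, and so on). Assignment is a deterministic local rule: an
adjective is predicative after the copula and attributive otherwise; a
preposition is verb-modifying after a non-copular verb; a verb is
transitive exactly when a determiner follows. The last rule depends on
material to the verb's *right*, so a left-to-right supertagger faces
genuine ambiguity at verbs — as with natural supertag inventories —
while adjective and preposition tags are resolvable from the left
context. This is deliberate: it separates a context-using supertagger
from the per-word most-frequent-tag baseline, which no model could beat
if every word had a unique tag.

What the toy corpus does **not** emulate: lexical semantics (so
"collective-biased" versus "distributive-biased" prepositions are an
arbitrary designation of two preposition subsets, and null effects in
the notional-number paradigm are the expected outcome), morphological
irregularity, frequency skew within categories, and discourse structure.
Passing tests therefore license conclusions about the *pipeline* and
about structurally driven effects, not about what models learn from
natural text.

## Experimental items

Item generators produce full factorial minimal-pair sets over the toy
lexicon: each item appears in every condition cell and cells differ only
in the manipulated tokens. Completion items end at the preamble boundary
(the verb is never included); reading items carry an explicit critical
index. Noun-phrase membership flags are emitted per token so no parser
is needed downstream.

The out-of-vocabulary policy follows the logic that number-bearing or
design-manipulated words must not be replaced by an uninformative
unknown token: an OOV token inside a noun phrase or varying across cells
requires a curated, in-vocabulary substitute (a hard error otherwise),
while any other OOV token is replaced by `<unk>`. The policy is
idempotent and returns a positional change log. Substitution tables are
user data: the package ships none.

## Statistical conventions

* **Coding.** All two-level factors are sum-to-zero coded as numeric
  ±0.5 contrasts, with a fixed "marked" level at +0.5 (mismatch,
  singular subject, PP modifier, ungrammatical, oblique, distributive,
  plural closer-disjunct). With balanced designs the intercept is the
  grand mean on the link scale and a main effect reads as the full
  difference between level means. Coefficient magnitudes depend on this
  coding, which is why it is fixed package-wide.
* **Probability responses** are fit by maximum-likelihood beta
  regression in the mean/precision parameterization (logit link for the
  mean, log link for the precision), with random intercepts integrated
  by the Laplace approximation (via `glmmTMB`); Wald z tests per
  coefficient. Responses exactly at 0 or 1 are squeezed by
  $y' = (y(N-1) + 0.5)/N$; interior responses — the normal case for
  one-sample measures — are left untouched. An all-constant response is
  rejected as degenerate rather than fit.
* **Surprisal responses** are fit by REML linear mixed-effects
  regression (via `lme4`), with t statistics and p-values from a normal
  approximation (the degrees-of-freedom convention is unsettled; the
  output flags this).
* **Random-effect pruning** starts from the declared maximal model and
  removes terms in a fixed order until convergence: highest-order
  (interaction) slopes first, instance slopes before item slopes at
  equal order, then the instance intercept, then the item intercept. A
  singular fit counts as non-converged. The path is recorded; the
  standard endpoint — random intercepts only, for items and instances —
  is reachable by construction. Grouping factors with a single level are
  dropped up front with a flag.
* **Comparing two fixed effects** uses a likelihood-ratio test: both
  models are refit by maximum likelihood, the constrained model sums the
  two design columns into one predictor, and
  $2(\ell_{full} - \ell_{constrained})$ is referred to $\chi^2_1$. An
  LRT (rather than a Wald contrast) is the natural reading of
  "comparing the fit" of the two models; a Wald check is available
  indirectly through the reported covariances.

The mock predictor used to validate the harness injects known log-odds
contributions for named condition combinations, plus optional item and
instance intercepts and beta trial noise; its contributions are defined
on the log-odds of the *error* response, so a positive contribution
raises error rates for both subject numbers and the recovered
coefficients have closed-form expectations (the projection of the true
cell log-odds onto the sum-coded design).

## Probing

The supertag probe is a linear classifier $C(x) = Wx + b$. Its nullspace
projector is $T = I - W^{+}W$, computed from the SVD with a relative
singular-value cutoff of $10^{-10}$; $T$ is symmetric, idempotent, and
annihilates the row space of $W$. The statement "the classifier can no
longer distinguish projected representations" is implemented as removal
of the input-dependent logit component ($WTx = 0$ for all $x$): the bias
survives, so post-projection predictions are a constant class and
post-projection accuracy equals that class's empirical rate. Projection
is applied at evaluation time only — a single nullspace-projection step,
with no retraining and no iteration. If $W$ has full column rank the
projector is zero (every direction is predictive) and the function warns
rather than errors.

For LM-only models the probe is trained on frozen hidden states by
full-batch gradient descent on the multinomial cross-entropy; the
encoder checksum is unchanged by construction and verified in tests.
The four-condition report (LM+CCG / LM-Only × baseline / amnesic)
contrasts the drop in word-prediction loss attributable to supertag
information learned from the auxiliary objective with the drop
attributable to supertag-usable information present from word prediction
alone.

## Problem sizes

The package's study-scale defaults, used by its own validation runs, are
deliberately modest: 50,000 generated training sentences, 2-layer
64-unit LSTMs (embedding 64), two epochs, five independently initialized
instances per variant, 3,000 held-out sentences, and 16–60 items per
paradigm. These sizes are where the toy grammar's learning curve has
visibly converged while a full pipeline run stays in the minutes range
on a single CPU; the 650-unit, 12-epoch configuration of full-scale
simulations remains available through `encoder_config()` and
`train_config()`.

## Known limitations

* Perplexities and supertag accuracies on the toy grammar are not
  comparable to values obtained on natural corpora; only *relative*
  statements (against the unigram and most-frequent-tag baselines) are
  meaningful.
* The number asymmetry and other directional effects in the toy setting
  depend on the generator's construction statistics (e.g. the 0.35
  plural rate); the package makes the dependence explorable rather than
  claiming a fixed direction.
* The grammar licenses a small closed lexicon; item generators error
  when asked for more distinct frames than the lexicon supports.
* `n_sample` saturates at double precision for large $n$; its
  convergence to max-prob is monotone but numerically flat beyond the
  point where the binomial tail underflows.
* Only two-level factors are supported in the regression layer; the six
  designs need nothing more.
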