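---
title: "SELIMI: model, design choices and validation strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SELIMI: model, design choices and validation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selimi)
```

## The model

SELIMI scores a child's spoken narrative with the probability that its
author has developmental language disorder (DLD), using only the
*semantic content* of the words produced. The chain has three stages.

**Distributional word semantics.** Word meaning is represented by latent
semantic analysis: a target × context co-occurrence matrix is counted
over a corpus with a symmetric window of `window_half_width` tokens
(windows never cross document boundaries, and a token is never its own
context), damped by $x \mapsto \ln(x+1)$ to moderate high-frequency
words, and compressed by a truncated SVD. Word $w$'s vector is row $w$
of $U_k \Sigma_k$, renormalized to unit length. The underlying
assumption is purely associative: words acquire meaning from the company
they keep, and no syntax, morphology or word order is used. All words —
including function words and pronouns — stay in the space; no stop-word
removal or stemming is applied, and the identical tokenizer (lowercase,
split on every non-letter) is used for corpus and narratives so that
narrative tokens can be looked up at all.

**Narrative summarization.** A narrative is the unit-normalized sum of
its tokens' word vectors, each *occurrence* contributing once. Because
addition commutes, the representation is strictly bag-of-words; this is
a modelling commitment, not an implementation accident. Occurrence
weighting (rather than one contribution per word *type*) is the default
because a summed representation naturally weights what the child
actually said; a `types_only` switch exists for sensitivity analyses.
Narratives with no in-space token raise an error rather than yielding a
zero vector — a silent zero would be indistinguishable from data and
would poison the classifier.

**Classification.** With ~100 predictors and only 36–72 narratives per
cohort, plain logistic regression is ill-posed; ridge-penalized maximum
likelihood
$$\max_{\beta_0,\beta}\;\sum_i \big[y_i\log p_i+(1-y_i)\log(1-p_i)\big]-\tfrac{\lambda}{2}\lVert\beta\rVert^2,\qquad p_i=\operatorname{logit}^{-1}(\beta_0+\beta^\top x_i),$$
with the intercept unpenalized, restores a unique optimum. Performance
is estimated by leave-one-out cross-validation *within cohort*: the two
cohorts differ in age and severity profile and are never pooled. A
score strictly above the cut-off (default .5) is a DLD call; a score
exactly at the cut-off is called control, so tie behaviour is defined
even though ties have probability zero.

## Tunable parameters

| parameter | default | rationale |
|---|---|---|
| `n_target_words` / `n_context_words` | 2,000 / 500 | desk-scale analogue of the classical 100,000 / 10,000 configuration; both overridable |
| `window_half_width` | 15 tokens | the classical context width for newspaper-scale corpora |
| `k` | 50 (space default), 100 at full scale | LSA quality typically peaks at a few hundred dimensions; small corpora support fewer |
| `lambda` | 1 | an explicit, reproducible choice on unit-norm inputs; `select_lambda = TRUE` replaces it with a per-fold inner 5-fold CV over $10^{-3..3}$ (deviance criterion, deterministic round-robin folds) |
| `cutoff` | .5 | the probability interpretation of the score: call DLD when it is the more probable class |
| `standardize` | off | inputs are unit-norm already; within-fold standardization is available for sensitivity analyses |
| `balance_folds` | on | see below |

## Why training folds are class-balance weighted

Both cohorts are balanced by design (36 + 36 and 18 + 18). Leaving one
child out therefore *always* unbalances the training fold by exactly
one member of the held-out child's class (e.g. 35 DLD vs 36 controls).
The unpenalized intercept tracks that tilt: when shrinkage drives
$\beta$ toward zero, every fitted probability collapses to the fold
prevalence, which is below .5 exactly when the held-out child has DLD
and above .5 exactly when they are a control. The held-out call is then
*always wrong* — leave-one-out accuracy near 0%, not 50%, on data with
no signal at all, and an inverted ROC whenever the true signal is weak
relative to the penalty. This below-chance cross-validation artifact is
well documented for balanced designs. The package therefore reweights
each training fold so both classes carry equal total weight (restoring
the cohort's design prevalence of 50%); with signal present the weights
are within 3% of one and the fit is essentially unchanged, while on
null data accuracy returns to chance. The weighting can be disabled
(`balance_folds = FALSE`) to reproduce the artifact.

## Numerical choices

- **Optimizer.** Damped Newton/IRLS from $\beta = 0$ (no randomness),
  convergence at penalized-gradient max-norm $< 10^{-8}$. Near-separable
  folds at small $\lambda$ flatten the Hessian; the step is first
  halved, then the Hessian is stiffened Levenberg-style, and a stalled
  ascent is accepted only if the gradient norm is below $10^{-4}$,
  otherwise the fit errors out.
- **SVD determinism.** Each singular vector's sign is flipped so its
  largest-magnitude component (first index on ties) is positive, making
  space builds bit-reproducible across runs.
- **Vocabulary ties.** Frequency ties are broken lexicographically, for
  the same reason.
- **Degenerate words.** Target words whose weighted row is all zero (or
  whose truncated projection has norm $< 10^{-12}$) are excluded and
  flagged rather than renormalized into noise.
- **Synonym-test ties.** Equal cosines rank lexicographically.
- **Binomial test.** Exact, two-sided by the point-mass convention (sum
  of all outcome probabilities not exceeding the observed outcome's),
  which is also base R's `binom.test` convention; this reproduces the
  reference p-values (e.g. 49/72 at chance gives p = 0.003). One-sided
  alternatives are available by flag.
- **Printed figures.** Internally everything is kept at full precision.
  The presentation layer rounds percentages to whole percent but
  *truncates* likelihood ratios (one decimal for LR+, two for LR−):
  the published figures for the reference tables (4.6 from 4.667, 0.26
  from 0.267) are truncations, not roundings, and `format_report()`
  follows that convention so printed output matches them digit for
  digit.
- **ROC ties.** All equal scores flip together, producing diagonal
  segments; the trapezoid area then equals the Mann–Whitney rank
  statistic exactly, which the tests verify against exhaustive pair
  counting.

## The synthetic study

The generator emulates the statistical structure the analysis assumes,
not real language. A vocabulary of `vocab_size` letter-only types is
partitioned among `n_topics` topics; topic $t$ places $1 -$
`topic_background` of its mass on its own block with Zipf-decaying
probabilities plus a uniform background. Corpus documents draw topic
mixtures from a symmetric Dirichlet (concentration 0.3: topically
focused articles) and emit tokens i.i.d. from the implied word
distribution. Children draw personal mixtures from a Dirichlet centred
on their group's mean mixture (concentration 30: moderate between-child
variation); the control and DLD means sit at $\pm \delta/2$ along the
immature-vs-mature topic direction, so `group_shift` $= \delta$ is the
Euclidean distance between them, with $\delta = 0$ making the groups
identically distributed. The DLD difference is thus a *distributional*
shift in topic use, not a truncated vocabulary, matching the premise
that weak or immature semantic representations — not merely missing
words — drive the group difference. Narrative lengths are log-normal
with median 90 tokens (sd-log 0.6), calibrated so that roughly half of
all narratives fall under 100 words, as in the reference samples;
cohort sizes default to 36 + 36 (A) and 18 + 18 (B). A single seed
drives everything; the corpus stream uses `seed` and the narrative
stream `seed + 1`, so the pipeline is byte-reproducible end to end.

What the generator does **not** emulate: Zipfian mixing across topics
beyond the background term, grammatical structure and disfluencies,
transcription noise, age effects within cohort, and the vocabulary
mismatch between newspaper text and children's storytelling. Passing
the simulation study therefore shows that the machinery recovers a
*distributional semantic* group difference when one exists and stays at
chance when none does — it does not certify performance on real
clinical transcripts.

The packaged simulation study (also run by `scripts/acceptance.R` and
the acceptance tests) uses a corpus of 250 documents (~60 tokens each)
over 400 types with 6 topics, a 400 × 300 space with window 15 and
$k = 30$, and the default cohort sizes — sizes chosen to make a full
pipeline run take about a second while keeping $n < k$, the regime the
ridge penalty exists for. Under these conditions, 20-seed null runs
($\delta = 0$) give pooled LOOCV accuracy binomially consistent with
chance in ≥ 90% of runs, $\delta = 0.4$ (nearly disjoint immature vs
mature topic mass for 6 topics) gives mean AUC above 0.99, and mean AUC
is non-decreasing along the grid $\delta \in \{0, .15, .25, .4\}$.

## Known limitations

- The two printed reference AUCs and raw SELIMI scores of the original
  child samples cannot be recomputed here: the narratives are not
  deposited. The package validates the machinery by oracle equivalence
  and simulation instead, and reproduces every metric derivable from
  the published confusion matrices.
- The exact penalty used by the original glmnet-based analysis is not
  recoverable; both an explicit $\lambda$ and an inner-CV selector are
  provided, and results always carry the $\lambda$ used.
- Whether the original space scaled rows by $\Sigma_k$ before
  normalization is unknowable; `scale_by_singular_values` exposes both
  conventions, defaulting to the classical $U_k\Sigma_k$.
- LOOCV scores within a cohort are strongly correlated (folds share all
  but one child), so the run-level accuracy distribution is wider than
  binomial; significance claims should treat the binomial test as
  approximate at the run level.
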