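---
title: "Models and methods in knowjudge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in knowjudge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knowjudge)
```

# The scientific problem

How well can people judge *how much someone knows* purely from the language
that person uses?  The study design this package analyses has two
populations of participants.  **Informants** answer general-knowledge
questions in several categories (their accuracy per category, written
$\theta$, is the ground-truth measure of knowledgeability) and write short
descriptions of category images.  Trained raters count, for every
description, the *specific statements* it contains — details that go beyond
what is visible in the image — and label each statement true or false.
**Evaluators** then see pairs of informants' descriptions and judge which
informant is more knowledgeable; evaluators also complete the knowledge
questions, so their own $\theta$ is known.

The package implements the complete quantitative pipeline for this design:
rater aggregation and reliability, knowledgeability scoring, a
discrimination performance ceiling, two Bayesian logistic choice models with
custom MCMC and Savage–Dickey model comparison, default-prior Bayes-factor
tests, and a calibrated synthetic-data generator so every stage runs and is
testable without any human data.

# Rater aggregation and reliability

Each description is scored by `n_raters = 7` raters, each reporting counts
of specific statements (`n_specific`), true statements (`n_true`) and false
statements (`n_false`), with `n_true + n_false == n_specific` per rater.
Counts are aggregated across raters by the **mode**, computed independently
per field (`mode_aggregate()`, `aggregate_annotations()`).  Two choices were
genuinely open:

* **Tie-breaking.** Modal ties return the *smallest* tied count — a
  deterministic rule, conservative toward claiming fewer statements.
* **Inconsistent modes.** Because the three modes are computed
  independently, `n_true_mode + n_false_mode` can differ from
  `n_specific_mode`.  We keep all three and set `consistent_flag = FALSE`
  rather than reconciling, because the downstream models only use the
  specific and false counts.

Inter-rater reliability is the intraclass correlation computed from two-way
ANOVA mean squares.  The reliability literature distinguishes several ICC
forms and the analysis convention here is not recorded anywhere; we default
to **ICC(2,1)** — two-way random effects, absolute agreement, single rater —
because raters are interchangeable draws from a rater population and the
analysis consumes single-rater-equivalent counts.  `icc_agreement(form =
"ICC3_1")` gives the consistency form for sensitivity analyses.

# Knowledgeability and the split-half ceiling

`score_knowledge()` scores $\theta$ as the proportion of a category's 30
questions answered correctly; timed-out questions count as incorrect (the
response window locks, and scoring unanswered items as wrong is the
conservative convention).  `selection_contrast()` compares self-selected
against assigned categories with a default-prior paired *t*-test Bayes
factor.

Because ground truth is measured by only 30 questions, even a perfect
evaluator could not discriminate informants perfectly.  The
`split_half_ceiling()` estimates this limit: for each informant pair, an
idealised observer sees each informant's correctness on a random half of
the questions and predicts who scores higher on the unseen half.  Ties on
the seen or unseen half receive 0.5 credit (the natural scoring for a
forced choice with no information).  Halves are drawn uniformly without
replacement, independently per pair and split, with `n_splits = 10000` by
default; the estimate averages over splits and then over distinct pairs
(each pair once, regardless of how many trials used it — `weight_by =
"trial"` switches to trial weighting).

# The two choice models

Let $n_A - n_B$ be the difference in total specific statements over exactly
the descriptions shown in a trial, and $m_A - m_B$ the difference in total
false statements.  The **informant discriminability model** asks how
diagnostic these cues are of true knowledgeability:

$$p(A \text{ more knowledgeable}) = f\!\left(w_0 + w_1 (n_A - n_B) + w_2 (m_A - m_B)\right),$$

with $f$ the logistic function.  The **evaluator choice model** asks how
evaluators actually use the cues, letting the veracity cue interact with
the evaluator's own knowledgeability $\theta$:

$$p(\text{choose } A) = f\!\left(w_0 + w_1 (n_A - n_B) + w_2\, \theta\, (m_A - m_B)\right).$$

$\theta$ enters as raw accuracy in $[0,1]$, not centred (predictions are
reported at accuracy values 0.5/0.75/0.9; a `center_theta` option exists
but is off by default).  With $w_1 > 0$ and $w_2 < 0$, one extra false
statement changes the linear predictor by $w_1 + w_2\theta$ — positive for
low-knowledge evaluators (a false detail reads as expertise) and negative
above the crossover $\theta^\* = w_1 / (-w_2)$ (`false_statement_crossover()`;
0.889 at the canonical weights $w_1 = 0.32$, $w_2 = -0.36$).

## Priors, sampling and model comparison

The regression priors behind the original analysis are unrecorded; we use
independent zero-mean normal priors with scale 1 on all weights — proper,
as the Savage–Dickey method requires — and expose the scale, with
robustness curves over scales $\{0.5, 1, 2\}$ by default.

Posteriors are sampled by coordinate-wise **stepping-out/shrinkage slice
sampling**, with the study's sampler configuration as default: 8 chains,
1000 burn-in scans, then 100 retained draws per chain taken every 20th scan
(800 pooled draws).  Convergence is checked with split-$\widehat R$ at a
1.05 threshold ("standard methods" admits many choices; split-$\widehat R$
is the current default diagnostic).  Intervals are equal-tailed 95%
percentile intervals with linear interpolation between order statistics.

`fit_model()` uses a compiled implementation of the identical algorithm
that (a) collapses duplicate design rows into weighted rows — an exact
likelihood rewrite — and (b) sizes the per-coordinate stepping-out bracket
from a preliminary iteratively-reweighted-least-squares fit, capped at the
configured `step_width` (slice sampling is valid for any fixed bracket
width; this only reduces the number of density evaluations).  The generic
`slice_sample()` takes any log density; the two engines are cross-checked
in the test suite.

Term-wise model comparison uses the **Savage–Dickey density ratio**: for a
nested point null $w_j = 0$, $BF_{10} = p(0)/p(0 \mid \text{data})$, with
the posterior ordinate estimated by a Gaussian kernel density with
Silverman bandwidth.  A normal-approximation cross-check is logged whenever
the two ordinate estimates disagree by more than 25% — with very strong
effects the null sits far in the posterior tail, the ordinate underflows,
and the Bayes factor is then reported as censored (`">100"`), matching the
reporting rule that all Bayes factors above 100 are displayed as
`BF > 100`.  Evidence labels follow the conventional bands (3 and 10,
with their reciprocals; boundary values fall in the inconclusive band).

## Default-prior Bayes factors

Correlation and *t*-test Bayes factors use the defaults of the standard
Bayesian-statistics software: a Cauchy prior with scale $\sqrt 2/2$ on the
standardised effect for *t* tests (JZS), and a stretched beta of width 1 —
uniform on $(-1,1)$ — on the population correlation.  Both are computed by
adaptive quadrature of exact marginal likelihoods: the noncentral-*t*
likelihood integrated over the Cauchy prior, and the exact sampling density
of $r$ (via a series evaluation of the Gauss hypergeometric function)
integrated over the stretched beta.  The test suite checks both against
independent quadrature routes (the classical $g$-integral; Euler-integral
hypergeometric with trapezoid quadrature) to four significant figures.
A symmetry property test ($BF_{10}(r) = BF_{10}(-r)$) caught a real error
in the null ordinate during development, which is why it remains in the
suite.

# The synthetic-study generator

`generate_study()` draws a complete study under one master seed: 100
informants and 160 evaluators, 30 categories with 30 questions, four
categories per participant (two self-selected, two assigned), 12
descriptions per informant-category with 7 raters in three groups, and 32
trials per evaluator balanced over 1/3/6/12 shown descriptions.  The
generative assumptions, and what they are calibrated to:

* **Knowledgeability**: $\theta \sim \mathrm{Beta}$ with condition means
  0.730 (self-selected) and 0.573 (assigned) and a common concentration.
  The concentration default (80) was chosen once so the mean worst-to-best
  realized-accuracy spread per category is near the observed 0.51 (a scan
  over 10–120 gave spreads 0.70–0.49); the implied interquartile range
  ($\approx 0.17$) is also close to the observed 0.19.  Answers are
  Bernoulli($\theta$) — no item effects (no item-response modelling).
* **Statement production**: per-description counts are Poisson with a
  log-linear rate in latent $\theta$.  The two coefficients are solved
  (by numerical integration over the $\theta$ mixture and the binomial
  realized accuracy) so that the *conditional mean counts* among
  informant-categories scoring above 90% and below 50% equal 1.68 and
  0.55 — the published group summaries are conditional means, so the
  generator is calibrated to exactly that estimand.  Each statement is
  false independently with probability 0.14, independent of $\theta$
  (the data show no overall knowledgeability–falsehood correlation).
* **Rater noise**: each rater misses a statement with probability
  $\rho$, adds a spurious statement with $\rho/2$, and flips a veracity
  label with $\rho/4$.  The mechanism is an invented measurement model
  whose single rate is calibrated so the nine group-by-type ICCs fall in
  the observed 0.59–0.85 band ($\rho = 0.14$ gives 0.63–0.84).  The flip
  rate is half the add rate because extracting statements is harder to
  agree on than classifying their truth, which reproduces the observed
  ordering of reliabilities (total/true counts above false counts).
* **Evaluators** are exact choice-model responders at weights
  $(0, 0.32, -0.36)$, with $\theta$ their own realized accuracy in the
  trial's category and the covariates summed over the latent (true)
  description counts.

What the generator does *not* emulate: category and image heterogeneity in
statement rates, informant-level verbosity differences, rater bias, item
difficulty, and any evaluator heuristic other than the fitted model form
(alternative responders can be simulated by changing
`evaluator_weights`, e.g. a veracity-blind evaluator with $w_2 = 0$).
Passing recovery tests therefore demonstrates the pipeline's correctness
under its own assumptions, not that real raters or evaluators behave this
way.

A consequence of the realistic measurement structure is visible in
parameter recovery at the study's scale: choices are generated from latent
counts but fitted on mode-aggregated rater counts, so the veracity weight
is slightly attenuated and the specificity weight inherits a small upward
bias ($\approx +0.015$) through the correlation between the two covariates.
Credible-interval coverage of the generating weights remains at the
expected level (8–10 of 10 replicates in the frozen test), and the bias
disappears when `rater_noise = 0`.

# Numerical choices and problem sizes

Quadratures use `integrate()` at tight relative tolerances; the
hypergeometric series is summed to machine precision (it converges fast in
the relevant regime $0 \le z < 1$ with a large third parameter).  The
slice sampler caps interval expansion at 100 steps per side and reports a
diagnostic error beyond it; zero-width shrinkage collapses return the
current point.  Per-chain seeds are derived deterministically from the
master seed, and every table writer is byte-deterministic, so full
pipeline reports regenerate identically.

The test suite exercises the full study scale (160 × 32 trials) where the
claim depends on it — parameter-recovery coverage uses ten full-scale
replicates — and reduced scales (40 informants, 16 evaluators; shorter
chains) where only correctness of the plumbing is at stake.  The
generator-versus-model agreement check pools ten studies (51,200 choices);
the split-half ceiling oracle uses exhaustive enumeration on a 4-question
toy pair against 10,000 Monte-Carlo splits.

# Known limitations

* The ICC form, regression prior, convergence diagnostic, and the exact
  sample sizes entering the published correlation tests are all
  unrecorded in the source analysis; our defaults are declared above and
  exposed as options, but posterior summaries could shift slightly under
  other choices.  (Reassuringly, the implemented correlation test
  reproduces four independently printed Bayes factors when the implied
  sample units are used.)
* The Savage–Dickey estimator is a tail-density estimate; for very strong
  effects it is only reliable up to the censoring rule, which is why
  results are reported as `">100"` beyond that point.
* The pipeline fits pooled trial-level models; there is no per-evaluator
  random-effect extension.
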