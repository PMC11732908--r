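---
title: "Adaptive testing for lexical decision: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive testing for lexical decision: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptlex)
```

## The measurement model

A lexical decision task asks the respondent whether a letter string is a real
word or a pronounceable pseudoword. Because it is a two-alternative forced
choice, a guesser succeeds half the time, so the response model is a
one-parameter logistic (Rasch-type) item response function with the lower
asymptote fixed at 0.5:

$$P(X_i = 1 \mid \theta) \;=\; 0.5 + 0.5\,
  \frac{e^{\theta - b_i}}{1 + e^{\theta - b_i}},$$

where $\theta$ is reading ability and $b_i$ item difficulty, both in logits.
Discrimination is fixed at 1. Difficulty is the ability at which success
probability is 0.75 — midway between the guessing floor and certainty.

The Fisher information of an item is

$$I(\theta) = \frac{Q}{P}\left(\frac{P - 0.5}{1 - 0.5}\right)^2
  = 4\,\frac{Q}{P}\,(P - 0.5)^2, \qquad Q = 1 - P,$$

equivalently $s^2(1-s)/(1+s)$ with $s = \mathrm{logistic}(\theta - b)$. Two
consequences of the guessing floor shape everything downstream: information
at $\theta = b$ is only $1/12$, and the information maximum sits *above* the
item's difficulty, at $\theta - b = \log\!\big((1+\sqrt5)/2\big) \approx
0.481$ where $I \approx 0.090$. Test information is the sum over
administered items and the standard error of measurement is
$SEM(\theta) = 1/\sqrt{I(\theta)}$, uncapped: after a single ill-matched
first item the SEM can exceed 10 logits, and the package reports that value
as is.

## Ability estimation

`estimate_mle()` maximises the Bernoulli log-likelihood over a bounded theta
range ((-4, 4) by default; (-6, 6) is the widened operational alternative
for differentiating very low-ability readers). All-correct and all-incorrect
patterns have monotone likelihoods and return the bound exactly, with the
SEM evaluated there — the "theta limit" convention. Interior solutions are
found by a 0.05-step grid scan (the likelihood is unimodal but can be very
flat), golden-section refinement of the bracketing cell, and a final Newton
polish on the score function. The polish matters for reproducibility: two
optimisations of the same likelihood that approach the flat maximum along
different paths agree only to ~1e-8 without it, and to ~1e-12 with it, which
is what lets a replayed session's final estimate match a from-scratch
full-bank fit to well below the 1e-6 contract used in the tests. The grid
step was chosen after verifying that refinement from a 0.05 bracket reaches
the same optimum as a much finer scan; the session loop refits the MLE
roughly 1.2 million times in the Monte Carlo harness, so per-call cost
matters.

`estimate_eap()` is the posterior mean under a normal prior (standard normal
by default) computed by rectangular quadrature on the bounded range. The
default of 241 equally spaced nodes keeps the quadrature error of the
posterior mean below 1e-3 everywhere on the default range; half that many
nodes leaves errors up to ~2e-3 in the tails. An empty response set returns
the prior mean with `sem = prior_sd`; otherwise the SEM is `1/sqrt(I)` at
the returned theta, the same convention as the MLE.

## The adaptive session

A session (`run_session()`, or stepwise `cat_begin()`/`cat_next()`/
`cat_update()`) proceeds:

1. **Category coin.** With content balancing on (the default), a fair coin
   drawn from the session RNG decides real vs pseudoword before *every*
   selection, including the first. If the chosen category's pool is
   exhausted, the other pool is used silently (counted in `n_fallback`).
2. **First item.** The median-difficulty item of the chosen pool; for even
   pool sizes the lower of the two middle items, so starts are
   deterministic.
3. **Selection.** `"mfi"` picks the unadministered item with maximum Fisher
   information at the current estimate; `"closest_difficulty"` minimises
   $|\hat\theta - b|$; `"random"` draws uniformly (this is the comparison
   arm, sharing all other scaffolding). Ties are broken uniformly at random
   so bank file order never biases selection.
4. **Update.** Theta is refit by MLE over all scored responses after every
   scored trial.

Uncalibrated validation items can be interleaved on a fixed schedule
(`validation_layout()`): one new item after each block of *every* scored
trials, e.g. 84 scored with a new item after each five gives a 100-trial
session with unscored slots at positions 6, 12, ..., 96. Unscored trials
draw uniformly from the uncalibrated pool and never touch the ability
estimate. Presentation blocks (e.g. 33/33/34 with breaks) are metadata only
and never alter selection or estimation.

The per-trial refit uses an incrementally updated log-likelihood grid: each
scored response adds its log-contribution to a cached grid, so locating the
new maximum costs O(grid) instead of O(grid × items). The inner loop is
compiled (Rcpp) because the simulation harness runs thousands of full-length
sessions; it consumes R's own RNG stream, so `set.seed()` gives bit-identical
trajectories, and the pure-R stepwise administration draws the same stream
and reproduces the compiled loop exactly (this equivalence is itself a test).

## Calibration

`fit_1pl()` estimates item difficulties by marginal maximum likelihood EM
with a standard-normal ability prior on 61 equally spaced quadrature nodes
spanning [-6, 6]. The prior mean of 0 identifies the scale — "mean ability
of the calibration sample is 0" — so a lower-ability sample assigns higher
difficulties to the same items, and only the *ordering* of difficulties is
expected to transfer across samples. The M-step solves each item's marginal
score equation by safeguarded bisection (the item likelihood is unimodal in
$b$); EM stops when no difficulty moves more than 1e-4, or at 500 cycles.
Difficulties are clamped to [-6, 6]; items driven to a bound are flagged
divergent. That includes items everyone answered correctly and — a quirk of
the guessing floor — items with at-or-below-chance observed accuracy, whose
likelihood increases without bound in $b$. Item standard errors use the
quadrature-expected information at convergence (the expected trial count at
each node times the item information there), the standard MML approximation;
exact observed-information errors would need two additional E-steps per item
and no downstream analysis consumes them.

Parameter recovery at the sizes used in the acceptance suite (500 persons,
50 items with difficulties uniform on [-3, 3], 10 seeds) gives mean
$r(\hat b, b) > 0.97$ and mean RMSE ≈ 0.32. Translating all generating
abilities by a constant moves the estimated origin by the same constant and
leaves relative difficulties in place; the suite verifies this with common
random numbers at 30,000 persons, where sampling noise in per-item contrasts
falls below the 0.05 bound being asserted.

## Parameter invariance and its noise ceiling

Even under perfect invariance, two samples' difficulty estimates correlate
below 1 because each estimate is noisy, and more so for small samples.
`permutation_invariance()` estimates this noise ceiling: each iteration
reassigns every person to a pseudo-group multinomially with probabilities
proportional to the supplied size ratio (so group sizes vary across
iterations, as they would under random recruitment), calibrates each
pseudo-group, and correlates difficulties against the reference
pseudo-group. The mean, SD and percentile 95% interval over 50 iterations
summarise the ceiling. An observed between-group correlation *inside* the
interval is indistinguishable from sampling noise; one *below* it indicates
real non-invariance. The percentile form of the interval was chosen because
the iteration distribution is visibly skewed near $r = 1$; a normal-theory
interval can exceed 1. Iterations that leave any pseudo-group under 10
persons are redrawn (calibrating a 3-person group is meaningless); ten
consecutive failures abort with an error naming the ratio.

The acceptance suite exercises this at the reference design — four groups in
ratio 306:1230:315:109, 50 iterations — on a synthetic cohort of 1,960
persons and a 120-item (60/60) bank. These sizes are the package's choice:
the person total matches the reference design's cohort; the halved bank
keeps the double run (null cohort plus a sensitivity cohort in which one
group answers 20% of items as if they were 2 logits harder) comfortably fast
while leaving per-item noise small relative to the effects probed. On the
null cohort the observed correlation falls inside the permuted interval; on
the shifted cohort it falls below it.

## Simulation harnesses

`run_monte_carlo()` implements the efficiency comparison: full-bank response
patterns are generated from each simulated person's theta under the model,
persons are randomly split into an adaptive and a random-ordering arm
(reassigned each iteration — the alternative of fixing assignment once is
defensible but re-assignment averages over composition as well), each
person's pattern is replayed under their arm's policy, and per-test-length
metric curves are computed against the *generating* thetas. Results average
over 5 iterations. `posthoc_replay()` is the same machinery fed observed
response rows, with ground truth defined as the full-bank estimate instead;
both truth definitions are recorded and labelled. Because the full-data
likelihood is order-invariant, a replayed person's final estimate is
identical across policies — the suite checks agreement to 1e-9.

Sub-seeds for iterations and persons derive from the master seed by a fixed
integer hash (`derive_seed()`), kept below $2^{31}$, so any slice of a
simulation can be reproduced in isolation.

The packaged scenario (`gen_study2_scenario()`) encodes the validation-study
conditions: a 246-item bank split 123/123, 472 simulated persons, bounds
(-4, 4), MFI with counterbalancing, full-length administration, 5
iterations. The cohort's ability distribution is normal with mean -0.9 and
SD 1.55 — a weighted blend of the two reported arm-level moments
(-0.73/1.48 and -1.07/1.61), since the raw sample is not available. The
bank's difficulty distribution is normal(-1, 1.5²) truncated to [-6, 6],
chosen so the pool consists primarily of easier items relative to a
mean-zero cohort — the regime of a screener aimed at struggling readers —
while covering the screening range. Under these conditions the adaptive arm
reaches empirical reliability 0.9 in roughly 50–65 items versus roughly
95–110 for random ordering, and its mean-SEM curve lies below the random
arm's (by ~0.1 logits through the middle of the test) at essentially every
length from 10 items on. The exception is the terminal plateau: once the
bank is nearly exhausted both arms have administered almost identical item
sets, the ordering policy no longer does anything, and person-composition
noise between the randomised arms (a few thousandths of a logit) can flip
the sign of the gap in the last handful of trials — at full-bank length the
comparison is vacuous. The suite asserts dominance away from that plateau
and near-equality on it; the acceptance script reports the dominance
fraction over lengths 10–245.

## Evaluation metrics

For a cohort of $N$ estimates at a given test length:

* empirical reliability $R_{emp} = \mathrm{Var}(\hat\theta)\,/\,
  (\mathrm{Var}(\hat\theta) + \overline{SEM^2})$, with the population (1/N)
  variance and the mean of per-person squared SEMs — the scalar
  $SEM(\theta)^2$ in the defining formula is read as that mean, the standard
  empirical-reliability convention and the dimensionally consistent one;
* $MSE = \overline{(\hat\theta - \theta)^2}$ and
  $bias = \overline{\hat\theta - \theta}$, so $MSE \ge bias^2$ always.

`curves_by_length()` evaluates these after every scored trial.
`quintile_bins()` partitions a cohort at the 20/40/60/80th percentiles of
ground-truth theta, ties going to the lower bin (deterministic, and matching
half-open interval reporting). `flag_rapid_guessers()` implements the
data-quality rule: per presentation block, a person whose median log RT
falls more than 3 SDs below that block's cohort mean is flagged; the
strictly-below rule means a degenerate cohort (SD 0) flags nobody. The
mean/SD are computed per block rather than pooled across blocks — the
pooled reading of "sample mean" is possible but conflates block-level
speed differences with non-compliance. `rt_item_means()` trims trials
outside 200–5000 ms before averaging log RTs (natural log; the base is an
argument, since only the correlation structure matters downstream).

`robust_correlation()` is the percentage-bend correlation (bend constant
0.2) with a seeded 2,000-resample percentile-bootstrap 95% CI. The robust
family was specified only by citation; percentage-bend was chosen as the
member most commonly used for convergent-validity reporting, and Pearson or
Spearman can be substituted trivially where sensitivity analysis is wanted.
External instrument scores are treated as numeric inputs supplied by the
user; no ordinal coding scheme is imposed.

## What the synthetic generators do and do not emulate

`gen_bank()` / `gen_cohort()` / `gen_study2_scenario()` reproduce the
*statistical* structure the algorithms care about: difficulty spreads,
multi-group ability distributions, Bernoulli responses under the model,
lognormal RTs with an optional rapid-guessing subpopulation (log-mean 6.7
vs 5.0, i.e. ~800 ms vs ~150 ms medians). Stimuli are placeholder
consonant–vowel strings; no lexical properties (frequency, neighbourhood,
length effects) are modelled, responses are conditionally independent given
theta, and there are no position, practice or engagement effects. Passing
tests therefore demonstrate that the algorithms behave as designed *under
the model*; they cannot certify behaviour under real response processes
that violate it — the gap that made the original empirical validation
worthwhile.

## Known limitations

* Scoring assumes the fixed-guessing 1PL; 2PL/3PL/4PL variants and
  multidimensional models are out of scope.
* No item-exposure control, early-stopping rules or multistage designs.
* The EM calibration treats persons as exchangeable; no age or group
  covariates.
* Reliability comparisons between arms of a randomised design inherit
  person-composition noise; with 5 iterations this is visible at the third
  decimal of the metric curves.
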