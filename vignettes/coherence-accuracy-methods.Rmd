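---
title: "Methods: simulating and testing the coherence–accuracy link"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and testing the coherence-accuracy link}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohacc)
```

## The scientific question

Coherence (conformity to probability theory) and accuracy (closeness to the
true probabilities) are formally linked: perfectly accurate judgments are
necessarily coherent, and for any incoherent set of estimates there is a
coherent set that dominates it in accuracy. Yet several studies of experts
found no empirical correlation between the two. `cohacc` implements a
paradigm in which the truth is exactly computable — the three-card poker
flop and a formally identical urn — together with a response model and a
power analysis that jointly explain both the positive link in this paradigm
and the earlier null results.

## Exact stimulus structure

The deck is 13 ranks × 4 suits; a flop is an unordered 3-subset, so there
are choose(52, 3) = 22,100 flops, all enumerated explicitly. Each task
(Card, Ball) asks nine questions in three subtasks, each a mutually
exclusive and exhaustive triple, and every probability is an exact count
over the enumeration:

```{r truth}
truth <- true_probabilities(build_stimulus_set())
truth[truth$task == "card", c("event_id", "role", "count", "probability")]
```

Two conventions needed fixing where the task description leaves room:

* **Run adjacency.** The Ace is adjacent to both the 2 and the King (the
  urn's "magic ball" sits at either end of the ranking), so A-2-3 and Q-K-A
  are 3-in-a-row, but K-A-2 is not: straights do not wrap. "Exactly 2 in a
  row" means at least one adjacent rank pair without a 3-term run.
* **Roles.** Within each subtask the three events are labelled
  `low`/`middle`/`high` by their position in the stimulus layout
  (3-of-a-feature, exactly-2, none/other). For the run and kind subtasks
  this coincides with ordering by true probability; for the suit subtask it
  does not (exactly-2-same-suit is the *most* probable event). The layout
  convention is the one that matters analytically: the four nested pairs
  per task used for extension errors never involve a `middle` event, which
  is what lets middle-item inaccuracy serve as an unconfounded accuracy
  partner for extension errors.

The nested pairs themselves are not taken on trust: the constructor
verifies by enumeration that every triple partitions the 22,100 flops and
that every claimed inclusion holds flop-by-flop, and it fails loudly
otherwise. The four pairs per task are: 3-of-a-kind ⊂ 3-different-suits,
3-of-a-kind ⊂ no-2-in-a-row, 3-in-a-row ⊂ no-pair, and all-same-suit ⊂
no-pair.

Suit-isomorphism classes ("strategically different" flops) are counted by
canonicalizing each flop under all 24 suit permutations and counting
distinct minimal representatives; a brute-force orbit enumeration on toy
decks is the independent oracle in the tests.

## The response model

A judgment of an event with true probability $p$ is
$\hat{p} = (M + \beta)/(N + 2\beta)$ with $M \sim \mathrm{Binomial}(N, p)$:
the posterior mean after $N$ mental samples under a symmetric
$\mathrm{Beta}(\beta, \beta)$ prior. Parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| $\beta$ | 1 | prior pseudo-count; 1 = uniform prior. Larger values moderate harder toward 0.5 |
| $N$ | 1 or 10 | latent number of mental samples, one value per participant, shared across all 18 questions |
| mixture | 0.7 / 0.7 / 0.1 | P(N = 1) for novices / amateurs / experts |

Sharing one $N$ across a participant's questions is the mechanism that
produces a *cross-subtask* correlation between incoherence and inaccuracy:
both scores are decreasing in $N$, so between-participant variation in $N$
correlates them. The expected sum of an exhaustive triple is
$(N + 3\beta)/(N + 2\beta) > 1$, i.e. the model predicts subadditivity that
vanishes as $N \to \infty$.

Simulated estimates are kept as real numbers by default; an
`integer_frequencies` mode rounds to integer counts out of 1000 to mimic
the elicitation format. The continuous default reflects the model
simulations rather than the response interface.

## Scoring

All scores are computed on the probability scale (frequencies divided by
1000); multiplying by 1000 recovers the frequency scale. Incoherence of a
triple is $|1 - \sum \hat{p}_i|$, which equals the guaranteed loss per unit
stake of the Dutch book that buys all three claims when the sum is below 1
and sells all three when above; `sure_loss()` returns the book alongside
the loss, and the tests verify the guarantee by settling the book under
each of the three outcomes. Inaccuracy is $\sum_i |\hat p_i - p_i|$.
Extension errors use strict inequality (a tie is not an error, since the
error is *judging higher*). Matching-question inconsistency aggregates the
nine |card − ball| differences by their mean, keeping the scale
interpretable; a sum option exists.

## Inference

* **Unconfounded pairs.** Coherence from subtask $i$, accuracy from subtask
  $j \ne i$: 30 ordered pairs over the six subtasks. Correlations on the
  *same* judgments are excluded by design because noise alone links them.
* **Correlation.** Pearson throughout (it is also what the
  partial-correlation machinery assumes). The bootstrap resamples
  participants with replacement, recomputes all 30 correlations per
  replicate, and takes 2.5/97.5 percentiles of the replicate mean. The mean
  is the arithmetic mean of the 30 coefficients; a Fisher-z average is
  available as an option. Replicates where a correlation is undefined
  (zero variance) drop that pair; fully degenerate replicates are skipped
  and counted.
* **Partial correlations.** First-order, by residualizing both scores on
  the covariate; the bootstrap of full-minus-partial mean correlation uses
  the equivalent closed-form identity on the joint correlation matrix for
  speed, with the residualization route kept as the tested oracle.
* **Group tests.** Welch's unequal-variance t with Welch–Satterthwaite
  degrees of freedom, two-sided, α = 0.05 everywhere.

## The synthetic cohort

`generate_cohort()` stands in for the human data with the structure the
analysis assumes: group sizes 45 novices / 37 amateurs / 186 experts, one
latent $N$ per participant from the group mixture, 18 independent sampler
responses at the exact truths, and two covariates generated *independently
of* $N$ — recent poker experience (RPE, ordinal 0–4, distribution shifted
upward with expertise) and a gambling-fallacies score (GFM,
Binomial(10, 0.6) for novices/amateurs and Binomial(10, 0.8) for experts,
matching medians of 6 and 8). Covariate independence is deliberate: it
reproduces by construction the finding that RPE/GFM explain none of the
coherence–accuracy link, and a dependence knob exists for power
exploration. The latent $N$ is written to a sidecar, never into the
response table, so the analysis path cannot see it;
`recover_sample_size_structure()` classifies participants from responses
alone and reports a confusion matrix against the sidecar.

What the generator does **not** emulate: response rounding habits, the
60-second time limit, drop-out and exclusion, task-order effects, and any
systematic deviation of human estimates from the sampler model (e.g.
anchoring on round numbers). Passing tests therefore show that the
*pipeline* recovers the model's structure, not that the model is true of
people.

## The four-question reconciliation

The earlier null result came from 125 economists judging four prostate-
cancer probabilities. Truths for the two lifetime questions are published
(0.177, 0.028); the two conditionals are constrained only by
P(C|+)/P(+|C) = 0.5. Defaults assume P(+|C) = 0.8 and hence P(C|+) = 0.4 —
clinically plausible magnitudes — and `medrisk_sensitivity()` sweeps the
assumed sensitivity with the ratio fixed, showing the simulated link stays
positive across the grid. Inaccuracy is the mean absolute log percentage
deviation, $100\,|\ln(\hat p / p)|$, over the two lifetime questions
(mean rather than sum: the choice rescales, but does not re-rank,
participants, so correlations are unchanged); incoherence is the same
deviation of the estimated ratio from 0.5. Estimates are floored at
$10^{-6}$ before logging because uniform responses can approach zero.
Expert sampler parameters (10% N = 1, 90% N = 10, β = 1) are used, as the
respondents were professionals.

With these conditions the simulated population correlation is ≈ 0.09 and
the design's power at α = 0.05 is ≈ 0.21–0.27, while uniform random
responding gives a correlation indistinguishable from 0 and power at the
type-I rate — the quantitative reconciliation of the earlier null. The
incoherence score depends only on questions 3–4 and the inaccuracy score
only on questions 1–2, so under random responding the two are functions of
disjoint independent inputs and the population correlation is exactly zero.

## Numerical and scale choices

* Problem sizes: the test suite uses 10^4-participant Monte-Carlo nulls,
  10^4 simulated four-question experiments, and bootstrap B between 10^3
  and 4×10^3; the full analysis sets B = 10^5 via `run_config()`. These
  sizes put Monte-Carlo error well inside each assertion's tolerance.
* All randomness flows from a single integer seed per run; outputs carry
  the seed, and equal seeds give byte-identical output files.
* Degenerate inputs (zero-variance scores, truthful cohorts) are flagged
  and excluded from averages rather than silently propagating NaN.
* Tie-breaks: extension errors use strict inequality; sample-size recovery
  prefers the larger N on an exact likelihood tie (ties have measure zero
  in continuous mode).

## Known limitations

* The exact wording of the original nine questions is reconstructed from
  the task structure; the reconstruction is validated against all stated
  structural constraints (exhaustive triples, the four nested pairs, the
  printed example pair) but not against the original appendix.
* The sure-loss normalization is per unit stake on each of the three
  claims; other stake conventions rescale the score without reordering
  participants.
* The snooker-forecasting rows of the reconciliation table require
  external Elo-derived win probabilities and are not implemented, though
  `medrisk_design()` accepts arbitrary event probabilities, so a user with
  those inputs could run the same machinery.
* Empirical human correlations (≈ 0.2–0.4 in the study this models) are
  properties of the human data; the synthetic cohort reproduces the
  qualitative pattern, not those numbers.
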