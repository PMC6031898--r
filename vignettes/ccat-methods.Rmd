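---
title: "Models and methods behind the ccat battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the ccat battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccat)
```

## What the package models

`ccat` is a headless engine for a computerized cognitive addiction therapy
(CCAT) battery developed for methamphetamine use disorder: four adaptive
training tasks aimed at attention bias and working memory, four scored
assessments of impulsive and risky decision making, simulated respondents
that exercise all of them with known ground truth, and the statistics of a
two-arm pre/post trial. There is no UI and no stimulus rendering: drug and
neutral words/pictures are opaque category-tagged tokens from a lexicon
file, and every run is a pure function of (configuration, agent
parameters, seed).

Each (task, session) pair draws from its own random stream, derived from
the master seed by a stable string hash (`stream_seed()`), so adding or
reordering tasks never perturbs another task's schedule.

## Training tasks and their staircases

**Attention bias modification (ABM).** A left word names one of four
colors (red, yellow, blue, green); a right item — drug-related or neutral
word — is printed in some ink with a drug-picture distractor. The correct
judgment is `consistent` iff the left word's *meaning* equals the right
item's *ink*; the left word's own ink and the distractor are irrelevant,
which is precisely what makes ignoring them trainable. Sessions start
with 20 practice trials free of drug cues.

**Attention control training (ACT).** One picture: report its border
color. Two pictures (always one drug-related, one neutral): report the
neutral picture's border color. 240 trials per session.

**Adaptive N-back.** Colored shapes (3 shapes x 4 colors) on the right,
drug pictures on the left as distraction. A response is `yes` iff shape
*and* color match the stimulus N back. The level starts at 1-back and is
upgraded — never downgraded — after two consecutive blocks at >= 90%
accuracy, capped at 3-back. The accuracy window is not defined by the
protocol text; we score non-overlapping blocks of 20 trials, small enough
that a good responder can progress within a session. Each block is
preceded by N unscored warm-up trials.

**Memory matrix.** A pattern of `span` cells lights up for 3 s on a 5x5
grid and must be recalled within 3 s (no response counts as incorrect).
Three consecutive successes raise the span, three consecutive failures
lower it, with a floor of 2 and a starting span of 3. The protocol's
"three times were set as the response threshold" is read as this streak
length, consistent with the sentence that follows it. Grid size is not
stated; 5x5 growing to 6x6 above span 8 keeps patterns feasible.

The time-budgeted tasks (ABM about 8 minutes; N-back and matrix 10) run
under deterministic trial-count surrogates — 120 main ABM trials, 4
N-back blocks of 20 scored trials, 40 matrix trials — so logs are exactly
reproducible; all counts are configurable.

Unstated stimulus mixes default to balanced and are exact by
construction, not in expectation: 1:1 consistent:inconsistent (ABM), 1:1
one-picture:two-picture (ACT), 30% N-back targets, drug distractors on
100% of main ABM trials.

## Assessments and scores

**Delay discounting.** Delayed reward A = 1000 yuan against an immediate
offer starting at 500, at delays of 2, 7, 30, 90, 180 and 360 days. The
decreasing-adjustment titration lowers the offer after an immediate
choice and raises it after a delayed choice, with steps 250, 125, ...
halving each trial; after 6 adjustments the adjusted offer is the
indifference point V(D). This bisection-style rule brackets any
deterministic threshold within `A / 2^(n+1)` = 7.8125 yuan. All offers
are halvings of the initial amount — dyadic rationals that binary doubles
represent exactly, so the arithmetic is exact without a decimal type.
The discount rate is the hyperbolic-decay parameter: `hyperbolic_k()`
inverts one point via k = (A − V)/(V·D) and `fit_global_k()` least-squares
fits one k across delays (one-dimensional bounded optimization, tolerance
1e-10, k >= 0; ln k is reported alongside since group change is usually
summarized on the log scale).

**Iowa Gambling Task.** 150 picks over four decks. We use the canonical
payoff magnitudes: A/B win 100 per pick, C/D win 50; per 10-pick block the
losses net each deck to −250 (A/B) or +250 (C/D), with deck A (and C)
spreading five losses across the block and deck B (and D) concentrating
one. The outcome is the net score (#C + #D) − (#A + #B).

**Balloon Analogue Risk Task.** 100 balloons; each balloon's burst point
is drawn once, uniformly on 1..128, before the run (the classic
specification — the protocol states only that each inflation risks a
burst). The headline score divides *all* pumps by the number of
unexploded balloons, implementing the stated formula literally; because
"total inflations" is often read as pumps on unexploded balloons only,
that adjusted variant is always computed too. The literal score is never
smaller, with equality exactly when nothing exploded.

**Drug-word Stroop.** 8 drug and 8 neutral words, each presented 8 times
balanced 2 per ink color — 128 trials, the reading consistent with a
typical session length ("8 per color", 512 trials, is available via
`presentations_per_word = 32`). The sequence is a seeded shuffle repaired
deterministically so no more than 3 consecutive trials share a category.
Attention bias = mean correct-trial latency on drug words minus neutral
words; per-category error rates are reported with it.

## Simulated respondents

Agents are test fixtures with recoverable ground truth, not cognitive
claims:

* the discounting chooser applies V = A/(1 + kD) with a known `k_true`
  (optionally a logistic choice on the value difference);
* the gambling learner is a single-parameter delta rule with softmax
  choice — enough to make net scores rise with experience;
* the balloon pumper cashes at a fixed threshold T, so the exploded
  fraction is T/128 in expectation;
* the generic responder answers correctly with probability `p_correct`
  (per-level for the N-back) and draws latencies from a lognormal floored
  at 150 ms, positively skewed like real reaction times, with an additive
  latency shift on drug-related stimuli whose recovery is exactly the
  Stroop bias.

## Trial statistics

Baseline tables compare groups from summary statistics alone: the F is
the square of the pooled-variance two-sample t with df (1, n1+n2−2), and
categorical rows use Pearson's chi-square without continuity correction.
On the shipped example baseline table (a 20-per-arm two-arm study), age,
education and onset-age rows recompute to 1.199, 0.522 and 0.084; the
abstinence row (printed 0.224) recomputes to 0.290 and the use-frequency
chi-square (printed 2.4) to 2.0 under any standard convention, so those
two rows are treated as not reproducible from the printed summaries and
are not used as checks.

Pre/post outcomes use an exactly specified 2x2 mixed ANOVA (between:
group; within: time) in place of SPSS-style generalized estimating
equations; for a balanced two-occasion design the interaction test is
identical to the two-sample t on change scores, which is what a
GEE with exchangeable working correlation tests in that case. Sums of
squares are computed explicitly and must partition exactly; the tests
cross-check against `stats::aov` and the analytic power of the
change-score t (`power.t.test`). Post hoc pre/post contrasts within each
group are paired t tests Bonferroni-corrected by the family size of 2.
Degenerate zero-variance strata yield an explicit infinite-F flag rather
than NaN. Subjects missing a time point are dropped (complete-case) and
counted.

`simulate_trial()` draws panels from value = mu(group, time) + subject
intercept + residual with Gaussian components. Under the null it
reproduces the nominal 5% rejection rate of the interaction test; it does
not emulate dropout, floor/ceiling effects, non-normal outcomes or
practice effects, so calibration here says nothing about those
complications in real data.

## The study replica

`run_study_replica()` wires everything together: per subject a
pre-assessment battery, then (treatment arm only) the full training plan
— 20 sessions, five per week, each of the four programs twice per session
— then a post-assessment battery, ending in per-subject score rows and
the per-outcome group-by-time analysis. The "training effect" is nothing
but the configured shift in agent parameters between the pre and post
sets; defaults make the treated arm improve on every outcome while
controls stay at baseline, so the demo reproduces the qualitative pattern
of a positive trial without claiming anything about real efficacy.
Interrupted replicas resume by reusing existing session logs.

## Problem sizes and numerical choices

The shipped tests run the full protocol constants where they are cheap
(240-trial sessions, 150 picks, 100 balloons), and scale simulations to
sizes that keep the suite fast while retaining power: 100-200 seeded
replicates for behavioural means, 400 replicates against the analytic
power oracle, 1000 replicates for null calibration of the interaction
test, and a 2-subject / 2-session replica for the end-to-end path. Ties
in the discounting chooser go to the delayed reward; `optimize()`
boundary results are snapped to k = 0 only when the boundary is at least
as good; latencies are floored, never truncated above, except that
Stroop responses slower than the 3000 ms exposure become timeouts.

## Known limitations

Stimulus content is symbolic; nothing here validates that real drug
imagery produces the modeled latency shifts. The proprietary cognitive
screening battery used alongside these tasks in clinical work is out of
scope — only its score columns could be analyzed. Inter-trial intervals
and response deadlines that the protocol leaves unstated default to "no
deadline" (matrix and Stroop excepted) and carry no behavioural
consequence for simulated agents beyond the timeout rules described
above. The mixed ANOVA assumes two occasions; more time points would
need a different error structure.
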