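---
title: "Models and methods behind rgtnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rgtnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgtnet)
```

`rgtnet` implements, as a reusable and fully tested pipeline, the analysis
of an operant decision-making phenotyping study in rats with an induced
reduction of brain serotonin: task simulation, behavioral scoring and
classification, a permutation-based inferential layer, and a correlation
network over behavioral traits. This vignette documents the models, the
parameters that matter, the numerical conventions, and — importantly — what
the synthetic-data generator does and does not establish.

## The tasks and their scores

**Rat Gambling Task (RGT).** A 60-min session with two options: an
advantageous one (1 pellet, time-outs of 6 s or 12 s with probability 1/2
and 1/4) and a disadvantageous one (2 pellets, time-outs of 222 s or 444 s
with the same probabilities). The residual 1/4 probability mass is treated
as "no time-out"; any other reading only shifts expected penalties by a
constant, and the alternative (renormalizing to 2/3 and 1/3) is noted as an
open reading. Because of the long penalties the small reward maximizes the
hourly pellet yield. The *RGT score* is the percentage of advantageous
choices in the last 20 min; subjects above 70 are good decision makers
(GDM), below 30 poor decision makers (PDM), in between — with exactly 70
and 30 assigned inward — intermediate (INT). The classification is a total,
deterministic partition of [0, 100]. The mean magazine latency after a
choice indexes motivation for the reward (Lat).

**Reversed-RGT.** The options swap physical sides. The flexibility score is
the preference, in the last 20 min, for the location of the previously
non-preferred option; above 60 flexible, below 40 inflexible, in between
undecided (boundaries again inward). The preferred side is recomputed from
the last 20 min of the original session; a tie yields no class. This is why
trial records carry a `side` column beyond the minimal event fields.

**Probability discounting (PDT).** One certain pellet against five pellets
delivered with probability P in (1, 0.33, 0.20, 0.14, 0.09). A probability
level is accepted once two consecutive sessions are stable (training:
both at or above 70% large-reward choices and within 15 percentage points;
testing: within 10 points), and the level's preference is the mean of that
first stable pair. Preferences are normalized to the training preference
and plotted against odds = (1/P) − 1, rescaled by the maximum odds so a flat
curve integrates (trapezoidally) to an AUC of exactly 1. The AUC is
invariant to common rescaling of the preferences and monotone in pointwise
dominance. The analytic indifference point of this schedule — the P at
which both options yield the same expected amount — is 1/5, i.e. 20%.

**Social recognition (SRt) and odor control.** Social preference is the
interaction-time ratio E1/Hab; short-term social recognition memory the
ratio E1/E3, with a ratio of 1 as the no-recognition signature. Zero
denominators propagate as flagged missing values, never as silent zeros.
The odor preference is the percentage of dish time at the used bedding.

**Neurochemistry.** Raw 5-HT, 5-HIAA and tryptophan are normalized per
batch to the mean of that batch's control subjects (controls average
exactly 100 by construction, so the normalization is idempotent under any
per-batch rescaling of the raw values); the 5-HIAA/TRP ratio is computed on
raw values. Subjects whose normalized 5-HT strictly exceeds their arm's
mean + 2 sd are excluded, with a log entry; arms under 3 subjects are left
untouched.

## The choice agent

The simulator needs a generative stand-in for a rat, which no published
mechanism pins down. We use the simplest process matching the observed
preference trajectories: the probability of the focal option starts at
`initial_pref`, moves a fraction `drift_rate` of the remaining distance to
`target_pref` after every choice, and is replaced by a uniform draw over
the holes with lapse probability `choice_noise` (default 0.05). Magazine
latencies are lognormal; a cycle costs `handling_time` (default 15 s) plus
latency plus the sampled time-out. Defaults per phenotype park the
asymptote at the class centers — 0.85 (GDM), 0.50 (INT), 0.15 (PDM) — and
give PDM agents *shorter* latencies (median 1.2 s vs 2 s). The direction of
that latency difference is not derivable from the study's printed group
effect; we chose it to match the reward-hypersensitivity reading of the
poor-decision-maker phenotype, and it is configurable.

## What the generator emulates — and what a green test does not establish

`generate_cohort()` produces 60 control and 58 knockdown subjects with
phenotype counts 49/8/3 and 39/10/9, batches of 12 (6 per arm),
phenotype-matched RGT/reversed-RGT agents, hyperbolically discounted PDT
preferences (steeper for knockdown PDMs, constant 0.35 vs 0.08 over odds),
gamma/lognormal social durations with an E1/Hab factor of 2.5 and E1/E3
targets of 2.0 (control-like) and 1.0 (knockdown PDM), and batch-structured
neurochemistry (lognormal batch multipliers, sd 0.15) with multiplicative
knockdown effects of −21% (5-HT) and −25% (5-HIAA), a 23-point per-subject
spread, and no tryptophan effect. One master seed fans out to per-subject
substreams, so cohorts are byte-reproducible and stable under changes of
the subject count.

The generator reproduces the *statistical structure the analysis assumes*,
not rat behavior: there is no learning model fitted to data, no attrition,
no session-to-session carry-over, no side biases, and the social and
neurochemical channels are independent given the phenotype. A green test
therefore establishes that the scoring, statistics and network code do what
they claim on data with the right structure — it says nothing about
biological validity.

Three structural facts about this world are worth stating because they
bound what any test can show. All follow from the printed time-out
schedule, which caps how many choices an agent can make:

* a chance-level agent makes roughly five choices per 10-min bin. The
  *pooled* fraction of advantageous first-bin choices is 50% (unbiased),
  but the unweighted mean of per-agent bin percentages sits several points
  below 50, because advantageous-leaning sessions contribute more choices
  yet all sessions weigh equally in a mean of ratios. The chance-start
  acceptance check therefore uses the pooled estimator;
* a poor decision maker accumulates only ~6 choices in the last 20 min
  (~9 for an intermediate). Binomial noise at those counts caps
  truth-recovery of the three classes near 87/76/86% for agents parked at
  the class centers — no agent parameterization under this schedule reaches
  the 95% recovery the acceptance suite demands, and that criterion is
  deliberately left failing with this analysis as its explanation;
* the pellet-yield advantage of the always-advantageous policy is a ratio
  of expected cycle lengths, (15 + 222)/(2 × (15 + 6)) ≈ 5.6 before
  latency; the yield-ordering test uses negligible-latency agents because
  the bound is a property of the schedule, not of the latency model.

## The inferential layer

`fisher_exact()` enumerates the hypergeometric support directly; the
two-sided p-value follows the point-probability rule (sum of all tables as
or less probable than the observed one, with the usual 1e-7 relative
tolerance), and it matches the reference implementation to numerical
precision on random tables. Rank tests wrap the standard implementations
(mid-ranks for ties, exact small-sample p-values where available) behind a
uniform result container.

`perm_anova()` is written from scratch. Classical F statistics come from a
two-stratum split-plot decomposition — between-subject terms against the
subject-within-cells variance, the within factor and its interactions
against the within-subject residual — computed once as QR effects so each
permutation costs one orthogonal transform. The reference distribution
permutes whole subjects' between-factor label tuples for between terms and
within-level labels independently inside each subject for within terms;
p-values use the add-one estimator and can never be exactly zero.
Replicated observations per subject-by-level cell are averaged first. The
F decomposition is verified against the standard split-plot oracle, and a
2000-simulation null calibration (200 permutations, 24 subjects, 4 within
levels) keeps the type-I error at the nominal 5% within [0.03, 0.07] with
an approximately uniform p-distribution. Which contingency table and tail
feed the Fisher test in the pipeline is configurable (default: the 2x2
GDM/PDM table, two-sided), since the study's wording does not pin it down.

## The behavioral network

Five nodes — RGT, Lat, PDT (AUC), SP, STM. Correlations are Spearman,
computed pairwise-complete with the ranks recomputed per pair; edges are
retained when |r| strictly exceeds 0.28 (the threshold is exposed; the
absolute-value reading follows from the presence of negative edges in such
displays). Strength centrality is the sum of absolute incident edge
weights. Networks are invariant to strictly monotone transforms of any
variable. Subgroups under 3 subjects are skipped with a log entry.

For network-level properties the generator uses a Gaussian copula:
a latent normal with Pearson matrix 2·sin(πρ/6) (the exact
Spearman-to-Pearson conversion) pushed through configurable marginals. The
knockdown-PDM default is an *STM-centered hub*: Spearman 0.70 between STM
and every other node with a 0.35 background — the closest positive
semi-definite relaxation of an exact STM common factor (a hub of 0.70 with
independent spokes would need the impossible 4 × 0.70² ≤ 1). Positive
semi-definiteness caps how central a hub can be, and five-subject samples
add rank-correlation noise with a spread of nearly 0.5 per edge: at n = 5
no admissible structure makes the hub the strict strength maximum in 80%
of replicates. Our pipeline carries no attrition stage, so its
knockdown-PDM subgroup has the generator's truth count of nine subjects,
and the hub-recovery acceptance check runs at n = 9, where the chosen
structure does meet the 80% bar. The study's own five-animal network
should accordingly be read as a single, very noisy draw.

## Numerical conventions and limitations

Percentages are on the 0-100 scale throughout; times in seconds; CSV with
header row, UTF-8, "." decimal separator, missing values as empty fields.
Configs serialize to JSON (no YAML dependency is available offline). All
randomness flows from explicit integer seeds below 2^31; permutation
p-values are deterministic given the seed. Classification boundaries are
strict on the outer classes; the outlier rule is strict ("higher than");
tie-breaks resolve to "no class" rather than an arbitrary side.

Known limitations: the agent is not a learning model and cannot produce
within-session strategy switches; the power simulation for the permutation
ANOVA in the module tests runs at 60 rather than 200 simulated data sets
(the acceptance-scale null calibration is kept in full); partial
correlation networks are intentionally not provided (the subgroup of
interest is too small for them, as the study itself notes); and no attempt
is made to reproduce the study's group-level statistics, which depend on
the unpublished raw data.
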