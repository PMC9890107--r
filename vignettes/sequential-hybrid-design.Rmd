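---
title: "The sequential hybrid design: models, calibration and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sequential hybrid design: models, calibration and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

seqpsi implements the analysis machinery of a preregistered, multi-laboratory
forced-choice precognition experiment: participants guess which of two
curtains hides a reward image, the target side is drawn by the computer
*after* the guess, and the scientific question is whether the success rate on
erotic-image trials exceeds the 50% chance level. This vignette explains the
statistical design the package encodes, the choices that were genuinely open
when writing it, and what the simulation-based checks do and do not
establish.

## The two models and the four simultaneous tests

Two models are contrasted. Under M0 every guess succeeds with probability
exactly 0.5. Under M1 the population success probability p on erotic trials
exceeds 0.5. Four tests are evaluated *simultaneously* at each pre-specified
analysis point, and the study only stops early (or concludes anything) when
all four support the same model — a conjunction rule that trades power for
robustness across statistical frameworks.

**Test 1 — mixed-effects logistic regression.** An intercept-only logistic
regression with a participant-level random intercept,
$\mathrm{logit}\,P(\text{success}_{ij}=1) = \beta_0 + u_i$, $u_i \sim N(0,
\tau^2)$, accounts for the dependence of trials within a participant. The
Wald interval for $\beta_0$ is mapped through the inverse logit to a
probability-scale interval. The verdict rule is equivalence-style and
ordered: if the upper CI bound is below the smallest effect size of interest
(SESOI, 0.51) the test supports M0; failing that, if the lower bound exceeds
0.50 it supports M1; otherwise it is inconclusive. Because two one-sided
checks are made at each of (up to) five looks, the interval level is widened
per look by Bonferroni, $1 - 0.005/(2L)$: 99.75%, 99.875%, 99.91667%,
99.9375%, and 99.95% at look five (the schedule's formula extrapolates the
four registered levels; the fifth is implied, not separately registered).

**Tests 2–4 — Bayes factors on the pooled counts.** Pooling all erotic
trials into a single (k, n) pair deliberately ignores participant structure:
a pooled proportion cannot be gamed by premature stopping of individual
sessions, which is the complementary robustness property to the mixed
model's. BF01 compares the point null p = 0.5 with M1 priors on (0.5, 1):

$$\mathrm{BF}_{01} = \frac{0.5^{\,n}\,B(a,b)\,\bigl(1 - I_{0.5}(a,b)\bigr)}
{B(k+a,\,n-k+b)\,\bigl(1 - I_{0.5}(k+a,\,n-k+b)\bigr)}$$

with three beta priors truncated and renormalized on (0.5, 1): uniform
Beta(1, 1); the knowledge-based Bem–Utts–Johnson prior Beta(7, 7), whose
truncated 90th percentile sits at the probability equivalent of Cohen's
d = 0.5 under the logistic conversion $p = \mathrm{logit}^{-1}(d\pi/\sqrt3)$;
and the replication prior Beta(829, 733) built from the original
experiment's 828 successes in 1560 trials. BF01 above 25 supports M0, below
1/25 supports M1.

One detail worth stating precisely: Beta(7, 7) truncated at 0.5 puts 90% of
its mass below 0.71295, while the d = 0.5 conversion gives 0.71237. The two
anchors agree only to about three decimals; the package treats the
d-conversion as exact and the "90% below 0.712" description as the
approximation it is, and its tests assert accordingly.

## Stopping, pooling and the decision sequence

Analysis points are cumulative erotic-trial counts: 37 836, 62 388, 86 958,
111 528 and 136 080 — at 18 erotic trials per participant, cohorts of 2102,
3466, 4831, 6196 and 7560. `run_study()` walks them in order; the first
look at which all four verdicts agree stops the study with that conclusion;
reaching the last look without agreement is an inconclusive study, also a
registered outcome. Between looks only the closed-form Bayes factors are
recomputed (`bf_trajectory()`), since that is what a live born-open report
can afford to redraw per trial; the mixed model is fitted at looks only.

Inclusion rules are part of the design: only erotic trials enter; completed
erotic trials of terminated sessions are retained (dropping them would
reopen the premature-stopping loophole); the stream is cut strictly after
the analysis-point-th erotic trial in deposit order, so sessions in
progress contribute partial data.

## Robustness and exploratory layers

Two registered robustness views of the same pooled counts: a pair of
one-sided binomial tests at alpha 0.005 (reject "p ≥ 0.51" → M0; else
reject "p ≤ 0.50" → M1), and a conjugate posterior Beta(829 + k, 733 +
n − k) summarized by its mode, 90% highest-density interval and a
region-of-practical-equivalence decision on [0, 0.506] at 95% mass. Note
the asymmetry kept deliberately: the BF priors are truncated at 0.5, the
robustness posterior is not — the registered update formula uses the plain
beta, and the package preserves both behaviours rather than "fixing" one.
The proportion tests default to exact binomial tails rather than the normal
approximation: the registered analysis named only "proportion tests", and
exact tails are reproducible without a continuity-correction convention;
the normal variant is available behind `method = "normal"`.

Exploratory analyses probe person-level structure that the pooled tests
integrate out: the distribution of per-participant success rates (complete
18-trial participants only) against a simulated chance-level reference,
quantified by the earth mover's distance on raw rates — binning a
lattice-valued sample before computing a transport distance adds an
arbitrary choice without adding information — and the odd-even split-half
correlation of individual performance, with within-participant erotic-trial
order defining the halves (the natural 1-based indexing; no other indexing
is registered anywhere).

## The synthetic stream and the truth models

`generate_study()` emulates the born-open data stream end to end: 36-trial
sessions with 18 erotic trials placed by a without-replacement draw,
guesses with a 49.08% left bias, 4.17% pre-trial dropout, 1.18% mid-session
termination at a uniform random trial, deposition in 200-row batches, and
opaque tokens where the live pipeline published hashed timestamps. Success
is drawn first from the participant's chance p_i and the target side
derived from (guess, success); because the real protocol draws the target
after the guess, the two formulations are equivalent for any p_i, and this
one makes the truth model explicit. Non-erotic successes are drawn at 0.5;
no hypothesis touches them.

Truth models for calibration: `fixed` (homogeneous p); `beta_sampled` (one
population p per simulated experiment from Beta(829, 733) — between-study,
not between-participant, variation); `heterogeneous` (per-participant
chance clip(p + N(0, sd)), default sd 0.15, putting ~10.3% of participants
above a 70% chance — the clipping to [0, 1] affects ~5 × 10⁻⁴ of the mass
and is applied deterministically); and `sheep_goat`, which the source
design never parameterized and is defined here as symmetric contamination —
a fraction f at p + δ, an equal fraction at p − δ, the rest at p — so the
population mean stays at p and any detection signal is purely
distributional.

What the generator does *not* emulate: real lab/experimenter imbalance
(rosters are round-robin), session interleaving across labs (deposit order
is session order), stimulus content, and any dependence between guesses and
covariates. Tests passing on this stream therefore validate the analysis
machinery, not the behavioural realism of the data.

## Numerical choices

**Mixed-model fitting.** The marginal likelihood is computed on collapsed
(successes, trials) patterns — for an intercept-only model the per-pattern
pattern counts are sufficient, which turns 37 836 rows into ~19 patterns —
with the random intercept integrated out by adaptive Gauss–Hermite
quadrature: 21 nodes, each pattern standardized at its conditional mode and
curvature (mode found by Newton iterations, vectorized over patterns). The
optimizer is Nelder–Mead on (β₀, log τ); the τ = 0 boundary is resolved by
comparing against the profiled fixed-effects fit, where the interval
collapses to the single-proportion Wald logit CI. The intercept's standard
error is the (β₀, β₀) entry of the inverse observed information (invariant
to the τ parameterization). On heterogeneous test data the fit matches
`lme4::glmer` at nAGQ = 25 to ~1e-4 in all three quantities; the in-package
implementation exists because design calibration needs tens of thousands of
fits at milliseconds each, and glmer remains the independent cross-check in
the test suite. Increasing nodes from 21 to 51 moves the log-likelihood by
less than 1e-8 at the optimum.

**Bayes factors** are evaluated entirely in log space through `lbeta()` and
the log upper tail of `pbeta()`; this is stable for n up to at least 10⁵
and shapes to 10³ (checked against interval quadrature to better than 1e-6
relative error). `bf01(..., log = TRUE)` exists because the BF itself
leaves double range once |log BF| exceeds ~709. BF01 at (k = n = 0) is 1
by convention.

**HDI** of a Beta(a, b) with interior mode: the width is minimized over the
lower endpoint with the upper endpoint tied through the fixed-mass
constraint (`optimize`, tolerance 1e-12); agreement with a grid-search
shortest interval is ~1e-4, and the endpoint densities match as the
shortest-interval condition requires. Shapes ≤ 1 are refused rather than
special-cased.

**Simulation seeding.** Operating-characteristics replicates use seeds
derived from (base seed, scenario, replicate) by integer hashing below
2³¹, so any scenario row reproduces in isolation and scenario tables are
order-independent. A true counter-based RNG would give the same property
natively but base R does not ship one.

## Problem sizes used by the checks

The calibration checks simulate complete sequential studies at desk scale,
chosen as the smallest sizes whose Monte-Carlo error still separates the
claims being checked: 200 replicates for the p = 0.51 power claim (a ≥0.95
bound, observed essentially at 1), 300 for the p = 0.507 and
heterogeneous scenarios (3 Monte-Carlo SEs ≈ 0.056 around 0.88 and 0.052
around 0.90), and 20 000 null replicates for the false-support bound, all
with the full five-look design. The registered design was calibrated off
the same machinery at 5000–10 000 replicates per scenario on a grid of 23
fixed effect sizes; nothing in the package prevents rerunning at that
scale, and `operating_characteristics()` reports Monte-Carlo standard
errors so any scale is self-describing.

## Known limitations

* The mixed model is intercept-only by design; no covariates, no crossed
  lab/experimenter effects. The experimenter-belief regressions that a full
  analysis of such a study might add are ordinary `lme4` fits outside this
  package's scope.
* The Wald CI relies on the asymptotic normality of β̂₀; at the registered
  cohort sizes this is excellent, but the same function applied to
  toy-sized streams (as some tests do deliberately) inherits Wald's known
  boundary optimism.
* `beta_hdi()` assumes unimodality and refuses boundary-modal shapes.
* The generator's dropout and termination processes are independent
  Bernoulli thinnings; real attrition is likely clustered by lab and time,
  which would not change any pooled count but could matter for analyses
  this package does not perform.
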