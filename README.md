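# seqpsi

Sequential hybrid analysis for two-alternative forced-choice guessing
experiments — the kind of multi-laboratory precognition ("psi") study in
which a participant guesses which of two curtains hides a reward image,
the computer draws the target side *after* the guess, and the question is
whether the success rate on erotic trials exceeds the 50% chance level.

The package is written for methodologists and replication teams who want
to run, audit or recalibrate such a design: it implements the full
preregistered decision machine, the robustness and exploratory analyses
around it, the operating-characteristics simulations used to calibrate it,
and a synthetic generator for the born-open trial stream, so the entire
pipeline is exercisable without any external data.

## The design in brief

Two models are compared — M0: success probability exactly 0.5; M1:
probability above 0.5 — by **four simultaneous tests** evaluated at
pre-specified cumulative erotic-trial counts (37 836, 62 388, 86 958,
111 528, 136 080):

1. an intercept-only random-effects logistic regression
   (logit P = β₀ + uᵢ, uᵢ ~ N(0, τ²)); its Wald CI on the probability
   scale, Bonferroni-widened per look to 1 − 0.005/(2L), supports M0 when
   the upper bound is below the SESOI of 0.51, else M1 when the lower
   bound exceeds 0.50;
2. –4. Bayes factors BF01 on the pooled counts against beta priors
   truncated to (0.5, 1) — uniform Beta(1,1), knowledge-based Beta(7,7),
   and replication Beta(829,733):

   BF01 = [0.5ⁿ · B(a,b) · (1 − I₀.₅(a,b))] / [B(k+a, n−k+b) · (1 − I₀.₅(k+a, n−k+b))],

   with BF01 > 25 supporting M0 and BF01 < 1/25 supporting M1.

The study stops at the first look where **all four** verdicts agree;
disagreement through the final look is itself a registered (inconclusive)
outcome. Robustness layers: one-sided exact binomial tests at α = 0.005,
and the conjugate posterior Beta(829 + k, 733 + n − k) with 90% HDI and a
ROPE decision on [0, 0.506]. Exploratory layers: earth mover's distance
between observed and chance-level success-rate distributions, and the
odd-even split-half correlation.

## Worked example

```r
library(seqpsi)
cfg <- design_config()          # the registered design, all defaults

make_prior("buj")
#> Beta(7, 7) truncated to (0.5, 1)  [buj]
truncated_quantile(make_prior("buj"), 0.9)
#> [1] 0.712951                  # ~ the d = 0.5 probability, 0.712

bf01(19003, 37836, make_prior("uniform"))
#> [1] 65.48                     # > 25: this test supports M0

set.seed(55)
out <- simulate_study(truth_model("fixed", p = 0.60), cfg)
out
#> Sequential study outcome: support_M1 (stopped at look 1, 37836 trials used)
out$looks[[1]]$ci
#> $level 0.9975   $lo 0.5925   $hi 0.6083   $estimate 0.6005
```

A true 60% success chance is detected at the first analysis point: the
99.75% CI (0.593, 0.608) lies wholly above 0.50, and all three Bayes
factors underflow toward zero (overwhelming evidence against M0), so the
conjunction stops the study for M1 after 37 836 trials.

The `analysis/` directory holds the numbered workflow drivers —
`01_simulate_stream.R` (synthetic born-open stream in 200-row batches),
`02_confirmatory_analysis.R` (four-test look evaluation + BF trajectory),
`03_robustness.R`, `04_operating_characteristics.R`, `05_exploratory.R` —
each a thin narrative script over the package functions, writing its
tables under `results/` and bulky regenerable data under `scratch/`.

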