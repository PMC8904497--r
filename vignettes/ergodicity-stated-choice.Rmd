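---
title: "Methods: ergodicity-aware stated-choice experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ergodicity-aware stated-choice experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergochoice)
library(dplyr)
```

## The scientific question

A repeated 50/50 gamble can be judged by two different averages. The
*ensemble average* (expected value) describes what happens to infinitely
many individuals each playing once; the *time average* describes what
happens to one individual playing forever. For additive wealth dynamics —
outcomes added to capital — the two coincide and the process is ergodic.
For multiplicative dynamics — outcomes are growth factors — they diverge:
a bet multiplying capital by 1.5 or 0.6 with equal probability has expected
growth factor 1.05 per round but time-average growth `log(0.9)/2 ≈ −5.3%`
per round, so the ensemble mean grows exponentially while almost every
individual trajectory decays. Ergodicity economics predicts that intuitive
decision makers track the time average; classical expected-utility accounts
predict dynamic-independent risk attitudes.

The experimental design this package implements probes that prediction with
stated choices between *bet couples*: pairs of two-outcome 50/50 bets with
equal expected value but unequal variance. Picking the lower-variance
(safer) bet is coded risk-averse (1), the higher-variance bet risk-taking
(0). The design is diagnostic because in the additive setting both bets of
a couple also share the same time-average growth — a time-average optimiser
is indifferent — whereas in the multiplicative setting the safer bet always
has the strictly higher time-average growth (AM–GM at equal means). A shift
toward safer bets *only* in the multiplicative setting is therefore the
signature of time-average optimisation, not of a generic variance aversion.

The curvature argument needs no fitted utility function: for a couple with
outcomes `a < b < c < d` and equal means, Jensen's inequality makes every
monotone utility with constant curvature sign prefer `{b, c}` if concave
and `{a, d}` if convex, with exact indifference when linear.
`safer_preferred()` evaluates this, and the test suite sweeps random
concave/convex piecewise-linear utilities to confirm the classification is
exhaustive.

## Bet-couple generation

`generate_bet_table()` draws the riskier bet of each couple uniformly from
a bounded feasible region and then places the safer bet on the
equal-expected-value locus with a strictly smaller spread:

* additive: outcomes within ±300, expected value within ±100;
* multiplicative: outcomes (growth factors) within [0.7, 1.4] and the
  riskier bet's per-round average growth factor `sqrt(lo·hi)` within
  [0.945, 1.05].

Two details of the region are genuinely open and were fixed once as design
choices. First, the feasible region excludes a band around the
zero-variance diagonal (minimum spread 20 currency units additive, 0.10
multiplicative) so that every seed bet leaves room for a strictly safer
partner; the safer partner itself is constrained by the outcome bounds
only, since the equal-mean locus legitimately passes through the
low-variance region. Second, sampling is uniform over the region and
uniform over admissible safer spreads — the natural minimal-assumption
choice.

Outcomes are quantized (integers additive, two decimals multiplicative) by
working in integer grid units, and expected-value equality is *restored
exactly on the grid*: the safer bet's second outcome is set to
`sum(riskier) − safer_lo` in units, so the audit can assert equality with
`==`, not a tolerance. Couples whose quantized spreads coincide are
rejected and resampled, keeping the safer/riskier distinction strict.

"No-brainer" attention checks are couples in which one bet state-wise
dominates the other (each outcome at least as good, one strictly). With
the default layout — 35 scored + 5 no-brainer couples per setting — the
no-brainers occupy indices 36–40 and 76–80.

## Synthetic respondents

`simulate_responses()` replaces the human cohort with softmax agents. Each
agent scores the two bets of a couple with a decision value — expected
value, time-average growth, or expected isoelastic utility at a fixed
reference wealth of 1000 (respondents receive no capital updates, so there
is no within-experiment wealth to track) — and chooses the safer bet with
probability `plogis((v_safer − v_riskier)/temperature)`.

The default scenario *encodes* the behavioural hypothesis rather than
discovering it, which is the honest thing a synthetic stand-in can do:
timed-group respondents are time-average optimisers (time pressure elicits
intuition), control respondents are expected-value-indifferent. Because
both decision models tie on additive couples, additive choices are fair
coin flips in both groups; in the multiplicative setting only the timed
group leans safer. The default temperature of 0.05 (log-growth units) was
chosen from the closed-form choice probabilities: typical generated couples
have time-average gaps of 0.01–0.05, giving safer-choice probabilities of
roughly 0.55–0.70 — a marked but far from deterministic preference, in the
range of plausible group-level estimates. `choice_prob()` exposes the
closed form so simulated frequencies can be checked against it exactly.

No-brainers are answered correctly with probability 0.78 (error rate
0.22), matching the observed overall fraction of correct no-brainer
answers the design anchors on. Under a homogeneous Bernoulli error model
this implies an expected QC retention of
`P(Binom(5, 0.78) ≥ 3)² ≈ 0.857` — about 86 of 100 respondents, somewhat
above the 81/100 a heterogeneous cohort (a few inattentive respondents
with much higher error rates) would produce. We kept the homogeneous model
for transparency; it reproduces the per-answer accuracy and the filter
logic, not the exact retention count of any particular human cohort.

Cumulative response times are log-normal per group — positive,
right-skewed — parameterised by the target medians (defaults 579 s timed,
694 s control) and per-group shape (0.25 vs 0.45, making the control group
more dispersed). Each respondent's total is split across the 80 couples by
normalised Gamma(2) weights; the per-couple times are a modelling
convenience (only cumulative times are analysed), and group sample medians
converge to the configured targets by construction.

## Quality control

`apply_filter()` retains a respondent iff they answered at least 3 of the
5 no-brainers correctly in *each* setting (inclusive threshold, per-setting
conjunction). The filter is idempotent and monotone in correctness, and the
report gives the overall correct fraction among all and among retained
respondents (the two natural denominators). The survey design forces
completion, so missing no-brainer answers are an error by default
(`strict = FALSE` downgrades this to exclusion). No response-time outlier
removal is applied.

## Inference

Choices within a couple are Bernoulli with safer-choice probability `p_i`,
so counts are binomial `C(n,k) p_i^k (1−p_i)^{n−k}`. `fit_couple()`
estimates `p_i` by naive Bayesian updating in two stages: a random 80% of
the observations update the Jeffreys prior Beta(½, ½) in one conjugate
step, and the remaining 20% are added one observation at a time. Conjugacy
makes the final posterior Beta(½+k, ½+n−k) regardless of the split or
ordering — the procedure is kept because it is the estimation protocol
being modelled, the which-observations-form-the-prior question is moot by
construction, and the test suite asserts the invariance exactly over the
full grid `0 ≤ k ≤ n ≤ 200`. Posteriors are represented analytically by
their beta parameters; `check_normality()` samples from them for
Shapiro–Wilk and Jarque–Bera screening. (The Jarque–Bera statistic
`n/6·(S² + (K−3)²/4)` with a χ²₂ reference is computed directly from the
sample moments.) At a few hundred draws the Shapiro–Wilk test has enough
power to detect the mild skew of even a moderate-count beta posterior, so
the screening should be read as a gross-shape check — it cleanly separates
near-normal posteriors from the U-shaped prior — rather than a certificate
of exact normality.

Setting-level aggregation averages the per-couple posterior means,
`p_s = mean(p_i)`, and propagates uncertainty assuming independence across
couples: `sd_s = sqrt(Σ sd_i²)/m`. Independence is an approximation (the
same respondents answer all couples); it is isolated in
`aggregate_settings()` so an alternative propagation can be swapped in.
Groups are then compared per setting with a one-sided z-test,
`z = (p_timed − p_control)/sqrt(sd²_timed + sd²_control)`, alternative
fixed to "timed more risk-averse" (configurable), using the normal limit
with no small-sample correction. Simulation places the empirical size of
this test near the nominal 5% under the null.

Response times are compared with a two-sided Mann–Whitney test on
per-respondent cumulative seconds (exact for small tie-free samples,
normal approximation with tie correction otherwise), and
`standardized_ranking()` replays all stated choices against one shared set
of coin flips in a standardized couple order (additive block added first,
then the multiplicative block multiplied), so final-capital differences
reflect choices alone.

## Numerical and degenerate-input choices

* Quantized outcomes are materialised as `units / 100` rather than
  `units × 0.01`, which keeps grid values at their shortest binary
  representation and makes CSV round trips byte-identical.
* Additive capital is plain floating point with no clamp at zero; losses
  can legitimately drive it negative. Multiplicative capital in very long
  single trajectories can underflow double precision (a 10⁶-round
  trajectory of the canonical bet decays ~e⁻⁵²⁷⁰⁰), so long-horizon
  diagnostics split the same number of log increments across an ensemble
  of shorter trajectories.
* `fit_couple(k = 0, n = 0)` returns the bare Jeffreys prior with a
  warning; a zero pooled posterior sd makes the group comparison error
  rather than return ±Inf.
* Equal-variance couples are rejected at generation, so
  `classify_choice()` never faces a tie; no-brainer couples route to the
  QC flag instead and raise an error if classified.
* Random draws in trajectory simulation are consumed round-major, making
  the matrix reproducible from the seed alone; the pipeline fans a single
  top-level seed out to fixed per-stage seeds so stages can be rerun in
  isolation.

## Problem sizes used in validation

The shipped validation suite uses: 10,000 generated couples per setting
for the constraint audit; the full `0 ≤ k ≤ n ≤ 200` grid for the
conjugacy sweep; 1,000 random monotone piecewise-linear utilities over 100
generated couples for the Jensen sweep; a 200 × 500 trajectory ensemble
(with exhaustive 2⁸-path enumeration for the exact small-horizon mean);
100-respondent cohorts for end-to-end runs; and 1,000 replicate null
experiments at 50 respondents per group for the z-test size check. These
sizes give Monte-Carlo standard errors comfortably below the effect sizes
being checked.

## What the synthetic cohort does and does not show

The generator reproduces the *statistical structure* of a stated-choice
cohort: block design, randomised orders, binomial choice counts with known
per-couple probabilities, log-normal cumulative times with the configured
medians, and an attention-check failure process. Passing tests therefore
demonstrate that the pipeline recovers known probabilities, holds its
error rates, and detects the encoded timed-vs-control contrast. They do
not — and cannot — demonstrate that human respondents behave like
time-average optimisers; the default scenario assumes exactly that
hypothesis. Analysing a real cohort requires only the response CSV schema
and the same pipeline stages.

## Known limitations

* Only 50/50 two-outcome bets; varying outcome probabilities at fixed
  expected value is out of scope.
* The independence assumption in uncertainty propagation ignores
  within-respondent correlation across couples.
* Choices are modelled without learning, wealth updating or
  dynamic-programming lookahead — deliberate, since respondents receive no
  feedback, but a limitation for designs that provide any.
* Isoelastic agents evaluate utility at a fixed reference wealth; η is a
  simulation input, never estimated from data.
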