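---
title: "Measuring collaboration in simulation games: density, diversity, and a seeded game simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring collaboration in simulation games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gamenet)
```

## The problem

A Web-based policy simulation game enrolls players into stakeholder roles
and asks them to communicate and negotiate. The platform's backend records
every exchange as a `sender -> receiver` event. Whether the game fostered
collaboration is then a question about the recorded interaction network:
how much of its connective potential was realized, and how evenly the
communication volume was spread. gamenet computes both quantities, and
ships a seeded simulator so the whole evaluation pipeline can be exercised,
tested and calibrated without human subjects.

## The two measures

Let `N` be the number of enrolled players. Excluding self-to-self ties, the
number of possible ties is `PT = N(N-1)/2` for nondirectional analysis and
`PT = N(N-1)` for directional analysis (`possible_ties()`).

**Density.** `network_density()` counts the pairs whose cumulative exchange
count is at least 1 and divides by `PT`. The presence threshold is exactly
one exchange: the measure is deliberately binary about ties, so repeated
exchanges between an already-connected pair leave it unchanged. DEN is 1
exactly when every countable pair communicated and 0 exactly on a silent
network.

**Diversity.** `network_diversity()` treats the pair-level exchange counts
as a probability distribution `p` over all `PT` possible pairs (zero-weight
pairs stay in the support) and reports

\[ \mathrm{DIV} = \frac{H(p)}{\log PT}, \qquad
   H(p) = -\sum_i p_i \log p_i , \]

the Shannon evenness of the exchange distribution. The construction is the
standard Pielou-style normalized entropy: it is 1 if and only if all pairs
carry equal weight, 0 if and only if one pair carries everything, invariant
to relabeling actors, to scaling all counts by a common factor, and to the
base of the logarithm (the base cancels in the ratio; we compute in nats).
Both `H` and `log PT` are reported alongside the ratio, so the
unnormalized entropy is available to readers who prefer it.

Two conventions about the support deserve emphasis:

* the support is *all possible pairs of enrolled players*, not just the
  active ones — diversity is relative to the whole roster, which is what
  makes "everyone else remained silent" lower the score;
* the default analysis is nondirectional with the two directions summed
  (direction carries no content in the evenness question); directional mode
  normalizes by `log(N(N-1))` instead.

**Focal comparison.** `focal_vs_all()` contrasts the ties that involve the
focal organization with all possible ties. Two conventions are provided
because the conventional tabulation of this comparison is internally
inconsistent at small `N`: it reports `focal = N` together with
`all = N(N-1)/2` (10 vs 45 at `N = 10`), yet an actor in an `N`-actor
network has only `N - 1` dyads, and the `N = 1, 2` rows of that tabulation
(1 vs 1, 2 vs 3) match neither reading. `convention = "printed"`
reproduces the tabulated values; `convention = "self_consistent"` reports
`focal = N - 1`. The choice is recorded in the result object rather than
hidden, and `evaluate_game()` defaults to the self-consistent form. The
often-quoted "exponential" growth of the whole network's advantage is,
literally, quadratic-versus-linear: `all/focal = (N-1)/2` exactly, which is
what the test suite asserts.

## Degenerate inputs and numerical choices

* **Silent networks.** DEN of an all-zero matrix is 0 (defined). DIV of a
  silent network is an *error* — the evenness of nothing is undefined — and
  the longitudinal pipeline records it as missing (`NA`) rather than
  inventing a value.
* **`PT = 1`.** With two actors and nondirectional ties the normalization
  `log(1) = 0` is undefined, so diversity requires at least three actors
  (undirected) and errors otherwise.
* **Self-exchanges** in logs are dropped with a warning count (game chatter
  to oneself is meaningless under the no-self-ties convention), not errors.
* **Probability checks.** `shannon_entropy()` requires its input to sum to
  1 within `1e-8` and uses the convention `0 log 0 = 0`. Entropy equality
  with a brute-force oracle is asserted to `1e-12` in the tests.
* **Time windows** are half-open `[start, end)`, so consecutive snapshot
  windows partition the log with no double counting; windows are laid over
  the observed round span, the last window possibly short. Cumulative mode
  (`[span_start, end)`) makes density nondecreasing, the natural view for
  "how connected has the game become"; per-window mode shows die-down.
* **Determinism.** Actor order is roster order everywhere, JSON reports fix
  key order and render numbers at 12 significant digits, so identical
  inputs give byte-identical reports.

## What the simulator models

`simulate_game()` realizes a six-role health-policy game
(`aca_game_config()`: federal and state government, hospital, insurance
company, physician, patient; multiple players per role; scenario
segmentation) as the minimum stochastic structure under which every
quantity above is exercised and recoverable:

1. **Who talks to whom** — per scenario, a propensity vector over all
   unordered player pairs is drawn from a symmetric Dirichlet with
   concentration `alpha`, multiplied by the role-pair affinity matrix and
   renormalized (`sample_pair_propensities()`). `alpha` is the evenness
   dial: small values concentrate communication on a few pairs, large
   values spread it. Affinity encodes scenario-dependent role chemistry
   (e.g. insurers and the state government while building the
   marketplace).
2. **How much** — per round, the total exchange count is Poisson(`lambda`),
   allocated to pairs multinomially by the propensity vector; each exchange
   takes a uniformly random direction. Volume (`lambda`) and evenness
   (`alpha`) are thus independently controllable, mirroring the separation
   between "how many interactions" and "how evenly distributed".
3. **Environment and scores** — each round every role draws one categorical
   environmental event (market share up or down, patient status improved or
   worsened, ...) with a fixed utility; a player's task score sums their
   role's event utilities, the engagement score counts the exchanges they
   participated in, and `total = task + 0.1 * engagement`. The scoring rule
   is a documented toy: the games this emulates compute *some* score, and
   the pipeline only needs scores that are reproducible and coupled to the
   log.

The RNG stream advances in a fixed, documented order (scenario
propensities, then per round: volume, allocation, directions, events), so a
config with its seed reproduces the run bit-for-bit; the caller's RNG state
is saved and restored.

### Default study conditions

The reference configuration is 6 roles x 2 players (12 actors, 66 possible
pairs), two scenarios of 10 rounds, `lambda = 30` expected exchanges per
round, `alpha = 1`, uniform affinity. Role count, multiple players per
role, scenario segmentation and the evenness contrast `alpha in
{0.05, 50}` define the game family; `lambda = 30` (about 2.5 exchanges per
player-round) and the 0.1 engagement weight are this package's own choices
of a realistic, moderately active game, fixed once and used by all tests.

### What passing tests do and do not show

The simulator emulates the *structure* the measures consume: seeded
stochastic volume, an evenness dial, role-pair chemistry, scenario
segmentation, per-role random environments. It does not model human
behavior — no reminders, no adaptive play (scores do not feed back into
propensities), no content of messages, no attrition, and no claim that its
event probabilities match any real policy environment. Tests passing on
simulated logs therefore validate the measurement and pipeline code, and
the recoverability of the simulator's own parameters, not any empirical
claim about real games.

### Calibration behavior of the evenness dial

The test suite checks that mean diversity is monotone in `alpha` (rank
correlation across `alpha in {0.05, 0.5, 5, 50}`, 50 seeds each) and that a
5-fold insurance/state-government affinity boost makes that role pair the
modal role-pair cell. The affinity check runs at the even-concentration
endpoint `alpha = 50`: there the Dirichlet draw is nearly uniform and the
propensity vector essentially proportional to affinity, so the check
isolates the affinity mechanism. At small `alpha` the pair-level Dirichlet
noise is of the same order as any affinity signal — by design, since
`alpha` *is* the concentration dial — and the two dials would be
confounded. For the same reason diversity at `alpha = 0.05` is *low but
dispersed*: the expected normalized entropy of a symmetric Dirichlet draw
over `K = 66` pairs is `(psi(K a + 1) - psi(a + 1)) / log K`, about 0.44 at
`a = 0.05`, with wide across-seed spread; the suite asserts its median
below 0.5 and its 90th percentile below the 10th percentile of the
`alpha = 50` distribution, rather than a tail bound the construction does
not support.

## Problem sizes in the test suite

Property-style tests run on 1000 randomized distributions/matrices for the
entropy oracle, evenness-transfer and boundedness checks, 100 seeds for the
affinity-recovery rate, 50 seeds per `alpha` level for the monotonicity
check, and rosters of 3-12 actors for the density properties — sizes at
which every check is exact or statistically decisive while the full suite
runs in well under a minute.

## Known limitations

* DEN and DIV are descriptive; the package deliberately provides no
  statistical tests for differences between scenarios or time windows.
* Diversity over role *pairs* aggregated matrices (rather than actor pairs)
  is not defined here; `role_pair_counts()` reports raw totals only.
* Per-scenario diversity normalizes by the roster-wide `PT` (all enrolled
  players), not by the scenario-active subset; enrolled-but-silent players
  lower a scenario's diversity, which matches the whole-roster reading of
  evenness. The scenario-active alternative can be had by subsetting the
  roster before calling `network_diversity()`.
* No other network measures (centrality, clustering, communities) and no
  alternative evenness indices (Simpson, Gini) are provided.

## A compact session

```{r example, eval = FALSE}
cfg <- aca_game_config(concentration = 0.3, marketplace_boost = 5, seed = 1)
run <- simulate_game(cfg)
ev  <- evaluate_game(run$log, run$roster, window_length = 5)
ev
plot(ev$snapshots)
ev$per_scenario$marketplace$role_pairs
```
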