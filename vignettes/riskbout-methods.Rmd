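---
title: "Modelling risk-sensitive novel-object exploration with riskbout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling risk-sensitive novel-object exploration with riskbout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskbout)
```

## The behavioural problem

When a mouse meets a novel object in a familiar arena it faces a
risk-coloured exploration dilemma: the object might hide untapped reward, or
an unseen danger. Mice resolve it with intermittent approach — short visits
("bouts") separated by returns to safety — and they differ enormously in how
they do so. Some ("brave") start with short, cautious, tail-behind visits
and soon switch to longer, confident, tail-exposed engagement at a high rate
that later relaxes; some ("intermediate") switch but never relax; others
("timid") never approach confidently at all, settling into sparse cautious
checking.

`riskbout` implements a generative account of these individual differences:
a Bayes-adaptive Markov decision process (BAMDP) agent whose behaviour is
shaped by (i) a Bayesian prior over a hazard of being detected by a
hypothetical predator, (ii) a depletable, regenerating exploration-bonus
pool that supplies the urge to approach, and (iii) a nested conditional
value at risk (nCVaR) objective expressing trait risk sensitivity. Nine
fitted parameters — six for the hazard prior, the risk level, the initial
pool, and the forgetting rate — span the whole brave-to-timid spectrum, and
an ABC-SMC loop fits them to summary statistics of minute-resolution bout
records.

## The decision problem

Time is discretised into turns; two turns correspond to one minute, so the
standard 200-turn simulation models a 100-minute session. The agent occupies
one of three real states — nest, cautious object, confident object — and
plans over three additional imagined states (cautious detect, confident
detect, dead) that no real trajectory ever enters, because no predator
exists. From the nest it may stay or approach in either posture; the
approach turn is the first turn of a bout (`tau = 1`) and is hazard-free,
which is how "actually approaching" is encoded in the hazard support. At the
object it must stay at least to `tau = 2` (one-turn bouts do not exist), may
stay or retreat at `tau` 2–3, and is forced out after `tau = 4`. Retreating
is a one-turn transition back to the nest that carries the travel cost.
Treating retreat as a separate occupied state would stretch a complete
nest–object–nest cycle to six planning stages, one more than the five-stage
horizon that is meant to cover it; the truncation then hides the value of
everything after the retreat, and the planner falls into a degenerate
equilibrium in which approaching is always postponed. With the one-turn
transition the five-stage horizon covers the longest bout cycle exactly.

### Hazard belief

The probability of having been detected after `tau` turns at the object is a
noisy-or over independent per-turn Bernoulli causes
`Z_j ~ Bernoulli(theta_j)`:

$$h(\tau) = 1 - \prod_{j \le \tau} (1 - \theta_j), \qquad \theta_1 = 0,$$

with independent Beta priors on `theta_2..theta_4` parameterised by mean and
variance (the variance must satisfy `v < mu - mu^2`; the package validates
this everywhere, including inside the ABC priors). The construction makes
`h` monotone in `tau` — the agent's inductive bias that a watching predator
accumulates evidence. Because the environment is benign, every completed
bout of length `tau` is a negative observation and the conjugate posterior
update just increments the failure pseudocounts for `j <= tau`
(`observe_safe_bout()`); positive observations, whose noisy-or posterior is
intractable, never occur. Learning generalises: safe short stays lower the
predictive hazard for longer stays too.

When the planner evaluates staying into turn `tau + 1`, the detect
probability of that chance stage is the cumulative hazard `h(tau + 1)` under
the branch's current posterior. This level-based reading — the detect risk
of a stage is the hazard function evaluated at the new stay length — is what
lets hazard generalisation move behaviour: as the posterior on `theta_2`
collapses, `h(3)` falls and length-3 stays unlock, then length-3 experience
pulls down `h(4)`, and so on. The survival-conditional increment
`[h(tau+1) - h(tau)] / [1 - h(tau)]` may look like the more orthodox hazard
semantics, but for the noisy-or it collapses to the posterior mean of
`theta_{tau+1}` alone, so nothing the agent learns from short stays could
ever change a stay/retreat margin and bout durations could never grow; we
therefore use the level-based form. Both forms coincide on the first stay
decision, where `h(1) = 0`.

### Exploration pool

The urge to approach is a heuristic exploration bonus: a pool `G(t)` that
starts at `G0`, is harvested at the object at rate `omega` per turn
(confident: `omega = R / G0` with `R = 1.1`; cautious: `K = 0.89` times
that), and regenerates linearly by the forgetting rate `f` in every state,
clamped at `G0`. The per-turn imagined reward at the object is
`omega * G + n1 / (n1 + n0)`, where the Beta-style reward pseudocounts
`n1 = n0 = 1` never change here (no real reward is ever delivered) and
contribute a constant 0.5. We apply the update in the literal order
deplete–regenerate–clamp; for very small `G0` the ratio `R / G0` would
exceed one, so depletion rates are capped at 0.999 to stay meaningful for
extreme parameter draws during fitting. Confident approach harvests more per
turn but also exhausts the pool faster, which is what eventually slows the
bout rate: the peak-to-steady transition happens when the agent starts
waiting multiple turns at the nest for the pool to regenerate.

### Risk-sensitive planning

Action values are computed by receding-horizon tree search (default depth 5)
over hyperstates (physical state, branch-local hazard posterior, pool
level, risk level). At every chance stage the outcome distribution is
reweighted by the CVaR envelope
`{xi : 0 <= xi <= 1/alpha, sum(xi * p) = 1}` minimising the expected
backup — nested CVaR, applied per stage, hence time-consistent. The inner
minimisation is solved in closed form by sorting outcomes and loading
`1/alpha` onto the worst until unit mass is allocated; a linear-program
solution over the envelope is kept in the test suite as an independent
oracle, and the whole tree search is checked against an exhaustive
enumeration oracle at depth ≤ 3. At `alpha = 1` the backup provably reduces
to risk-neutral Bayes-adaptive expectimax, which the tests also verify. Leaf
values are zero: with the retreat-as-transition structure, depth 5 covers a
complete cycle, so no heuristic leaf evaluation is needed. Ties between
actions are broken by the fixed order stay_nest, approach_cautious,
approach_confident, stay_object, retreat, making every simulation
deterministic; the real environment delivers only the no-detection branch.
Within a bout the branch belief absorbs one failure increment per survived
turn, so a branch that completes a length-`tau` bout has received exactly
the safe-bout update; the persistent belief is updated once per completed
real bout, and the bout clock (hence the hazard) resets on any return to
the nest.

### Fixed environment constants

The movement costs, escape-failure probabilities and discount are free
constants of this package, chosen once so that the fitted parameter ranges
can express all three phenotypes, and overridable everywhere
(`env_constants()`, pipeline config):

| constant | default | role |
|---|---|---|
| `travel_cost` | −0.2 | per nest↔object traversal; makes bout extension preferable to needless re-entry |
| `dying_cost` | −4 | imagined death; scales the hazard's bite |
| `p1` | 0.6 | failed escape from confident detect |
| `p2` | 0.3 | failed escape from cautious detect (`p2 < p1` is what makes caution worth its lower harvest) |
| `gamma` | 0.95 | per-turn discount; also the counterweight against postponing approach |

Two calibration facts are worth recording. With a very large dying cost
(order −50) no admissible prior ever approaches the object, so no phenotype
exists; the default −4 keeps a cautious length-2 bout marginally worthwhile
under priors around `mu_2 ≈ 0.3` while leaving confident approach
suppressed until the posterior relaxes. And with a near-unit discount plus a
nearly free travel cost, waiting at the nest is almost costless, which makes
the truncated-horizon planner procrastinate; `gamma = 0.95` and a
non-trivial travel cost remove that degeneracy.

## Reference phenotypes

`phenotype_params()` provides one fixture per group, used as worked
examples, as recovery targets, and as the package's own study conditions:

* **brave** — low-tail, flexible prior (`mu = 0.30, 0.15, 0.10`, variances
  at half their admissible maximum), `alpha = 0.95`, `G0 = 5`, `f = 0.3`.
  Produces cautious length-2 bouts, a persistent switch to confident
  approach, non-decreasing bout lengths, and a later peak-to-steady
  slowdown.
* **intermediate** — moderate prior with a high `tau = 4` mean,
  `alpha = 0.85`, `G0 = 20`, `f = 1.5`. Switches to confident approach but
  the large, fast-regenerating pool never forces a slowdown.
* **timid** — high, inflexible prior (variances two orders of magnitude
  below their admissible maximum), `alpha = 0.6`, `G0 = 5`, `f = 0.25`.
  Only cautious length-2 bouts, with an early transition to sparse,
  steady-state checking.

A known expressive limit under the default constants: realised bout lengths
are 2 and 3. The `tau = 4` stay is always dominated by retreat-and-re-enter,
because re-entry restarts the hazard clock and meets a regenerated pool
while the fourth turn would harvest a depleted one. Length-4 stays still
matter in planning (their hazard shapes the `tau = 3` decision), but the
canonical duration progression realises as 2 → 3.

## From trajectories and records to statistics

Minute records carry four channels: % time in cautious and in confident
approach, mean bout duration (s), and bouts per minute. Phase structure is
recovered by boxcar (two-level step) fits minimising squared error over an
exhaustive change-point search — exact and fast at 100 minutes; per-phase
levels are segment means (the abstraction averages statistics over phases;
we use means, not medians). The cautious→confident transition `t1` is read
from the collapse of the cautious curve; the peak→steady transition `t2`
from the level drop of the confident curve after `t1` (brave) or of the
cautious curve (timid). Groups are classified by the rule: no confident time
at all → timid; otherwise the ratio of confident time in the first ten
minutes of the confident phase to the last ten minutes of the record
separates brave (> 1) from intermediate, with the boundary assigned to
intermediate. The optional permutation refinement of borderline animals is
not implemented; the plain threshold is the classification.

Group-specific statistic vectors hold five entries for brave (two
transition times, cautious and peak-confident durations, peak/steady
frequency ratio) and four for intermediate and timid; the intermediate
frequency ratio is clamped at 1 because the generative model can only
decrease bout frequency. Model trajectories are mapped into the same space
with turns/2 minutes for transition times, the linear duration map
`d_animal = 0.75 + 1.5 (d_agent − 2)` seconds, and per-phase frequencies as
the inverse mean bout-start period. Degenerate cases are defined, not
errors: a transition that never happens is placed at the end of the
session, an empty phase contributes zero duration and a unit frequency
ratio, a phase with a single bout uses the phase length as its period, and
a trajectory with no bouts yields a maximally timid summary flagged as
degenerate.

## Fitting by ABC-SMC

`run_abcsmc()` follows the standard sequential importance-resampling
scheme: 30 generations of 100 particles by default, uniform priors
(`mu ~ U(0.01, 0.99)` per turn, `v | mu ~ U(0, mu − mu^2)` sampled
conditionally, `alpha ~ U(0.05, 1)`, `G0 ~ U(2, 40)`, `f ~ U(0, 2)`), a
diagonal Gaussian perturbation kernel with per-dimension Silverman
bandwidths, acceptance thresholds set to the lowest 30-percentile of the
previous generation's distances (non-increasing by construction), and
importance weights `pi(theta) / sum_j w_j K(theta | theta_j)`. The distance
is a normalised L1: durations are scaled by a constant 4 s, transition
times by `min(30, 10 + 0.8 max(x − 5, 0))`, frequency ratios by
`min(20, 2 + (18/19) max(x − 1, 0))`, each normaliser evaluated at the
simulated value — the asymmetry is intentional and prevents extreme
simulated values from dominating. Unstated details we fixed: the kernel
covariance is diagonal; a generation has a retry budget of 30·B proposals
and returns the populations fitted so far (with a warning) if it exhausts
them; fitting stops early if the acceptance rate falls below 1%; and each
of the three hazard priors is sampled independently per `tau`. One global
seed drives a fit; runs are serial and reproducible.

The package's recovery checks run at a reduced scale — 16 particles over 5
generations against targets simulated from the reference phenotypes at 200
turns — and assert qualitative facts: thresholds shrink, the final
population sits closer to a brave target than the prior generation did, and
for a timid target the posterior shows the positive `alpha`–`mu_2` rank
correlation characteristic of the model's risk/prior non-identifiability
(lower risk tolerance can be traded against a more optimistic prior).

## The synthetic-data generator

`generate_minute_record()` emulates the abstraction the pipeline assumes —
boxcar-shaped channels with phase transitions at `t1`/`t2` and additive
Gaussian noise truncated to valid ranges. Noise is added to a percentage
channel only where its level is positive: the presence or absence of an
approach type is treated as observed without error, so a timid archetype's
confident channel is exactly zero and classification stays well defined at
any noise level. Default levels are dyadic-friendly fixtures (noiseless
records round-trip to their generating statistics exactly); they are
plausible shapes for the three groups, not estimates of any animal. What
passing the round-trip tests shows is that the statistics pipeline is the
inverse of this idealised generator; real records have drifting levels,
non-instantaneous transitions and channel-correlated noise that the
generator deliberately omits, so those tests say nothing about boxcar
adequacy on real data.

## Known limitations

* Bout durations can only increase across a session, and frequencies only
  decrease; animals whose confident bouts shorten at steady state are
  outside the model family. Duration monotonicity is asserted for the
  reference phenotypes; extreme pool configurations (large `G0`, slow
  forgetting) can dip from 3 to 2 around the approach switch.
* Under the default constants the expressed duration range is 2–3 turns
  (0.75–2.25 s of the 0.75–3.75 s the mapping allows).
* The detect-probability semantics are level-based by design (see above);
  with them the per-stage probabilities are not a coherent single survival
  process across a bout, which is the price of making generalisation
  behaviourally effective.
* Planning is a depth-5 truncation, not value iteration over hyperstates;
  horizon artefacts beyond one bout cycle (e.g. multi-bout trade-offs) are
  invisible to the agent.
* Real-data ingestion expects records already abstracted to the four
  channels; video processing and bout classification are out of scope.
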