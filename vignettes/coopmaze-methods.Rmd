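---
title: "Scoring rules and simulator design in coopmaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring rules and simulator design in coopmaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopmaze)
```

coopmaze scores two-subject maze trajectories by the cooperation rules of
an automated behavioral assay and simulates coupled agent pairs so the
whole pipeline — rules, metrics, learning curves — can be exercised without
hardware or animals. This vignette is the package's account of how the
rules are formalised, which parameters matter, and where the design was
genuinely open.

## The trial state machine

The maze is a 120 cm corridor (two parallel lanes) split into three
virtual zones by two boundaries, by default at equal thirds (40 and
80 cm). Zone assignment depends only on the longitudinal coordinate and is
half-open, lower inclusive: a sample exactly on a boundary belongs to the
farther zone, and zone C is closed at the far wall. This makes "arrival" at
a zone unambiguous on a discrete grid. The boundary positions are
configuration, not fact: the assay fixes only that three zones span the
maze, so `maze_geometry()` exposes them.

Scoring replays a resampled track pair sample by sample through five
phases: *pre-armed* (before the first simultaneous occupancy of A),
*armed* (both in A), *active* (any subject has left A), *broken* (between
an outcome and re-arming) and *done*. While a trial is active:

- occupying different zones accumulates a continuous mismatch timer that
  resets to zero whenever the pair reunites; strictly exceeding 10 s
  breaks the trial. "More than 10 seconds" is read strictly: a lag of
  exactly 10 s still rewards, 10 s + one sample does not. A float guard of
  10⁻⁹ s makes the comparison robust to accumulated `dt` rounding, so the
  strict reading survives any sane sampling rate.
- being more than one zone apart (A and C) breaks the trial at that very
  sample — no grace period.
- the trial is rewarded when both subjects stand in C simultaneously, each
  having visited B since arming.

After either outcome the coordination rules are suspended until both
subjects are back in A: the animals must drink at C and walk back, and the
assay imposes its conditions only on the A-to-C run. Ties within one
sample resolve in a fixed order: session caps first, then the two-apart
break, then the mismatch timeout, then reward.

Two points in the published rule description are genuinely open and were
decided as follows:

- **"20 successive trials"** is interpreted as 20 *rewarded* trials. In
  free-running behavior, failed coordination is a continuous condition, not
  a discrete countable attempt, so a cap on successes is the only
  well-defined reading; it is configurable (`max_rewarded_trials`).
- **Progression order.** Reward requires each subject's A-then-B-then-C
  order within the trial, implemented as progression flags: a B visit since
  arming is remembered and never reset by backtracking (the assay restarts
  trials only when both rats return to A). Consequently a subject that
  somehow registers in C without a B visit (possible for synthetic zone
  timelines, not for continuous motion) can recover by visiting B and
  returning to C within the same trial. The flag semantics, not a
  first-C-entry test, define the rule here, because they are what a
  real-time tracker algorithm can evaluate sample by sample.

Degenerate inputs behave conservatively: subjects that never appear
simultaneously in A never arm a trial; a session shorter than the caps
ends at the last sample (`end_cause = "track_end"`); a trial still open at
any session end is recorded as interrupted, separate from coordination
breaks.

### The independent oracle

`score_session_oracle()` recomputes rewards and breaks with no incremental
state: for each trial it searches the whole zone sequences for the arming
instant, the first A/C co-occupancy, the first run of more-than-10-s
mismatch (via run-length encoding), and the first eligible simultaneous C
occupancy, then takes the earliest. The engine is a compiled per-sample
state machine; the oracle is a vectorised whole-sequence scan. The tests
require exact agreement on counts and reward instants over 1,200+
randomized sessions, which is what gives the engine its warrant.

## Metrics

- **Activity** is operationalised as total path length (cm) — the sum of
  Euclidean steps of the resampled track — summed over the pair. The assay
  reports "activity" without units; distance moved is the standard tracker
  measure. Per-subject components are retained.
- **Efficacy** is rewards · activity⁻¹ (rewards per cm), 0 by convention
  for a motionless session.
- **Latency** is the first simultaneous pair occupancy of C (first own C
  entry for solitary runs), whether or not it earned a reward — the
  published definition speaks of the A-to-C transition, not the first
  reward. A flag (`latency = "first_reward"`) switches to the
  reward-based variant. Sessions that never reach C are censored (`NA`),
  never imputed at the cap; day aggregation excludes them with `n`
  adjusted.
- Metrics are computed on the track truncated at the scored duration: the
  session is over once a cap fires, so movement beyond it does not exist in
  the physical protocol. This also keeps activity comparable between arms
  that reach the trial cap at different times.
- Percent change versus a baseline day (the latency-reduction reporting
  convention) propagates SEM to first order treating the day and baseline
  cells as independent; the baseline row is exactly 0 ± 0.

## The simulator

Each agent is a one-dimensional shuttling process on the maze axis:

x' = s · [g(d) · u + c_eff · tanh(Δ / 25 cm)] + η,

where `s` is the agent's speed, `u = ±1` points at the current goal wall
(C while seeking, A while returning, switching on arrival within 3 cm,
with an 8 s drinking pause at C and a 2 s re-arm pause at A), `Δ` is the
partner's lead, and `η` is Ornstein–Uhlenbeck velocity noise (sd 5 cm/s,
relaxation 0.5 s). Velocity noise — rather than white positional noise —
keeps path length finite and sampling-rate invariant, so activity is
meaningful at any frame rate. The `tanh` saturation bounds the partner's
influence at large separations, so a lost partner cannot fling the agent.
Positions are clipped to the maze; the lateral coordinate is carried
through the I/O schema but held at the lane centre (it is never scored,
and decorative jitter would silently inflate path length).

Learning is exponential saturation per individual: the goal drive grows
from 0.12 to 0.95 of full speed and the partner coupling from 0.15 to 0.90,
at 0.15/day. The effective coupling of a session is

c_eff = c(day) × familiarity × divider multiplier × (1 − context penalty).

- **Familiarity** is the pair-specific part of coupling: it saturates from
  a floor of 0.35 toward 1 at 0.25/day of shared training and restarts at
  the floor when the partner changes. Individual skills persisting across
  the swap while familiarity resets is what produces the latent-learning
  signature — a day-19 dip that stays far above day 1 and recovers in a few
  days — without any hard-coded day effect. Some pair-specific component is
  necessary: with purely individual parameters, day 19 would be
  indistinguishable from day 18.
- **Divider multipliers** (transparent-perforated 1.0, transparent 0.7,
  sealed 0.4, perforated 0.35) encode only the published ordering of the
  four divider conditions — the full-modality divider best, transparent
  next, sealed and perforated indistinguishable — not measured effect
  sizes. They are configuration values.
- **Contextual cues** are modelled as a coupling penalty of 0.35
  (attention diverted from the partner), not a speed penalty, which is how
  the simulator reproduces "fewer rewards, unchanged activity".
- The **sex** arm is a stylised speed multiplier (female 1.25): faster
  pairs earn more rewards and cover more ground with roughly unchanged
  efficacy.
- **Solitary** runs drop the coupling term and the partner-dependent rules;
  with no coordination to maintain, solitary agents out-earn pairs at
  matched parameters.

Baseline speed is 6.5 cm/s with a cohort log-normal jitter of sd 0.15, so
that an asymptotic pair completes a circuit in roughly 50–60 s and the
15-minute budget — not the 20-trial cap — limits performance. That regime
matters: it is what the published learning curves imply (performance still
rising on day 18), and it is what makes coupling load-bearing, since a
coordination break costs a circuit's worth of session time. The speed
heterogeneity is likewise what gives coupling its job: identical agents
stay synchronized for free.

All randomness flows from one master seed through deterministic per-pair,
per-day substreams, so any single session can be reproduced in isolation
and whole experiments are bit-reproducible.

### What the simulator does and does not emulate

It emulates: zone-level coordination and its failure modes, per-individual
acquisition, pair familiarity, the divider/context/sex/solitary contrasts
as directional effects, and tracker output in the package's track schema
at 25 Hz. It does not emulate: biophysically realistic rodent locomotion,
posture or lane-internal behavior, reinforcement-learning from the reward
signal (learning is a fitted-form schedule, not closed-loop), tracker
artifacts (identity swaps, dropouts), or the magnitudes of the published
group differences. Tests passing on simulated data therefore validate the
scoring rules and the directional phenomenology, not quantitative claims
about real animals.

## Test problem sizes

The property suite replays ~1,200 randomized zone-timeline sessions
(dwells 0.5–30 s at 10 Hz) through both engine and oracle; the
learning-curve checks run the published scale of 11 pairs × 24 days at
25 Hz; the condition contrasts use 5 pairs per arm × 18 days; coupling
monotonicity uses 50 seeds at each of five coupling levels. These sizes
were chosen as the smallest that exercise every rule path and the full
published protocol; the complete suite runs in about a minute on one core.

## Known limitations

- Zone assignment ignores the lateral coordinate entirely; a subject
  straddling the divider is scored by its longitudinal position alone.
- The optional boundary hysteresis (default off) trades a small assignment
  lag for jitter robustness; with it off, tracker noise exactly on a
  boundary can flicker zones, though the 10 s window makes the scoring
  insensitive to single-sample flicker.
- The resampler interpolates across arbitrarily long gaps (with a
  warning); there is no missing-data concept downstream.
- Simulated activity on early days is dominated by the noise process, so
  absolute day-1 activity values are not calibrated to animal data — only
  the within-experiment contrasts are meaningful.
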