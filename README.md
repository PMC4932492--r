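# coopmaze

Automated scoring and simulation of a two-lane social-cooperation maze for
rats.

## The assay

In the automated cooperation maze, two rats run in parallel lanes of a
120 cm × 40 cm box that is divided into three virtual longitudinal zones —
A (start), B (middle), C (reward end). A trial is armed when both rats are
in zone A and is **rewarded** when they shuttle coordinately A → B → C and
arrive at zone C together, upon which both pumps deliver 70 µl of 20%
sucrose for 1.5 s. The trial **breaks** if the rats occupy different zones
for more than 10 continuous seconds, or are ever more than one zone apart
(A and C). Re-gaining reward requires both rats to return to zone A. A
daily session ends after 20 rewarded trials or 15 minutes, whichever comes
first.

Performance is summarised per session by

- **rewards** — the number of mutual rewards,
- **activity** — total distance moved (cm), summed over the pair,
- **efficacy index** — rewards · activity⁻¹, the utility of cooperation,
- **latency** — time of the initial A-to-C pair transition,

aggregated across pairs into day-by-day learning curves (mean ± SEM).

`coopmaze` implements the scoring algorithm as a replayable state machine
over tracker coordinates (`run_session()`), the metrics
(`session_metrics()`, `aggregate_days()`, `percent_change()`), and a
coupled stochastic two-agent simulator with per-individual learning
(`simulate_session()`, `simulate_experiment()`) that emulates tracker
output for the assay's experimental arms: the 18-day learning protocol with
a partner swap on day 19, the four lane-divider conditions (sealed,
perforated, transparent, transparent-perforated), contextual wall cues, sex
differences, and solitary controls. An independent brute-force scorer
(`score_session_oracle()`) cross-checks the engine in the tests.

## Worked example

Score a deterministic fixture in which both rats run three perfectly
synchronized 25 s circuits A → B → C → A:

```r
library(coopmaze)

circuit <- list(list("A", 6), list("B", 6), list("C", 7),
                list("B", 3), list("A", 3))
tl <- do.call(c, rep(list(circuit), 3))
tracks <- fixture_from_zone_timeline(list(tl, tl), dt_s = 0.1)

result <- run_session(tracks, engine_params(), maze_geometry())
summary(result)
#> 3 reward(s), 0 break(s), scored 74.9 s (track_end)
#> reward times (s): 12.0, 37.0, 62.0

head(result$events, 4)
#>   t_s       event zone_1 zone_2 detail reward_volume_ul pump_duration_s
#> 1   0 trial_armed      A      A                      NA              NA
#> 2  12      reward      C      C                      70             1.5
#> 3  22 trial_armed      A      A                      NA              NA
#> 4  37      reward      C      C                      70             1.5

session_metrics(result, tracks)[, c("rewards", "activity_cm",
                                    "efficacy", "latency_s")]
#>   rewards activity_cm efficacy latency_s
#> 1       3         960 0.003125        12
```

Each circuit earns one mutual reward the moment both subjects stand in
zone C with a completed A–B–C progression (t = 12, 37, 62 s); the pair
covers 2 × 480 cm of track, giving an efficacy of 3/960 rewards per cm, and
the first pair arrival at C fixes the latency at 12 s.

To simulate a whole cohort (the default plan is 11 pairs, 18 learning days
plus 6 latent-learning days with a partner swap on day 19):

```r
rows  <- simulate_experiment(experiment_plan(seed = 1))
curve <- aggregate_days(rows)
plot(curve, metric = "rewards")
```

A command-line wrapper over the same functions lives at
`inst/cli/coopmaze.R` with `score`, `simulate`, and `aggregate`
subcommands.

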