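# smartrand

Automated double (two-stage) randomization for Sequential Multiple
Assignment Randomized Trials (SMARTs).

## The problem

A SMART randomizes each participant twice: once at entry, and again after
an intermediate *tailoring variable* is observed. Most electronic data
capture (EDC) systems support only one randomization model per project, so
SMART teams run the second (or both) randomizations through an external
engine that queries the trial database every morning, consumes a
pre-generated allocation table, and writes assignments back.

`smartrand` implements that engine end-to-end, file-based and fully
deterministic:

- **Eligibility rules** — each stage's daily report is a conjunction of
  `equals` / `is_blank` / `is_not_blank` clauses over the participant
  record (stage 1: approved ∧ consented ∧ not yet randomized; stage 2:
  first-randomized ∧ not yet re-randomized ∧ tailoring variable assessed).
- **Stage-1 rotation** — each eligible subject gets the treatment at the
  top of the allocation table; the row then moves to the bottom.
  Equivalently, the *i*-th subject (0-based) receives row *i mod n*.
- **Stage-2 stratified scan** — rows carry criteria (first-stage arm ×
  tester status); the table is read top-down to the first matching row,
  whose treatment is assigned and which alone rotates to the bottom.
- **Permuted-block table generation** — seeded, balanced within every
  block, so arm totals stay within one block of 1:1 at any stopping point.
- **Daily batch scheduler** — two strictly ordered passes per day,
  all-or-nothing persistence, a weekday entry gate (default Mon–Thu) that
  keeps assignments off weekends, and an append-only JSON-lines audit log
  whose replay reproduces the final records and tables exactly.
- **Cohort simulator** — synthetic SMART cohorts with the realistic
  anomaly taxonomy (dropouts before re-randomization, tailoring data never
  entered, manual delivery overrides).
- **Flow accounting** — CONSORT-style participant-flow counts, failure
  categories and percentages, plus a text flow diagram and a power helper
  for two-sample proportions.

The arm vocabulary mirrors the motivating COVID-19 testing uptake trial:
first stage `NAVIGATION` vs `BROCHURE`; second stage continue vs switch
(testers to `BRIEF_COUNSELING`, non-testers to `CRITICAL_DIALOGUE`).

## Worked example

```r
library(smartrand)

# Over-provisioned allocation tables (seeded permuted blocks)
s1 <- generate_first_stage_table(n_rows = 1400, block_size = 2, seed = 11)
s2 <- generate_second_stage_table(n_rows_per_stratum = 350,
                                  block_size = 2, seed = 12)

# A full simulated trial at the default study conditions:
# 675 participants, 7-day assessment lag, Mon-Thu entry gate,
# P(tester | assessed) = 0.225, 3 dropouts, 2 manual overrides.
sim <- run_simulated_trial(simulation_params(seed = 42))
print(sim$flow)
```

```
First randomization: n = 675
+-- NAVIGATION: 337 (49.9%)
|   +-- tested: 72
|   |   +-- BRIEF_COUNSELING: 36
|   |   +-- NAVIGATION: 36
|   +-- not tested: 262
|   |   +-- CRITICAL_DIALOGUE: 131
|   |   +-- NAVIGATION: 131
+-- BROCHURE: 338 (50.1%)
|   +-- tested: 76
|   |   +-- BRIEF_COUNSELING: 38
|   |   +-- BROCHURE: 38
|   +-- not tested: 258
|   |   +-- BROCHURE: 129
|   |   +-- CRITICAL_DIALOGUE: 129
Second randomization: n = 668
Failures: 9 (1.3%)
+-- dropout_before_r2: 3
+-- missing_tailoring: 4
+-- manual_override: 2
```

Reading it: all 675 simulated participants were first-randomized, split
337/338 by the blocked 1:1 table. A week later each assessed participant
was re-randomized within their stratum — e.g. of the 72 navigation-arm
testers, 36 continued navigation and 36 switched to brief counseling. The
9 failures (1.3% of 675) are the participants with no engine second
assignment or with a hand-delivered intervention differing from the
assigned one.

The power helper, at 291 per arm and a 15-point difference from a 50%
baseline:

```r
power_two_proportions(0.5, 0.65, n_per_arm = 291)
#> [1] 0.9562066
```

A command-line interface wraps the same functions
(`inst/scripts/smartrand`): subcommands `gen-table`, `eligible`,
`randomize`, `simulate`, `report`, with logging to stderr and an exit-code
contract (0 ok, 2 usage, 3 data, 4 allocation configuration).

## Documentation

The methods vignette
(`vignettes/smart-double-randomization.Rmd`) describes the model and its
assumptions, the fixed conventions (report ordering, time visibility,
rounding), the simulator's scope, and the numerical design choices.
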