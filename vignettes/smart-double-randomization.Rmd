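---
title: "Automating double randomization for SMARTs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automating double randomization for SMARTs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smartrand)
```

## The problem

A Sequential Multiple Assignment Randomized Trial (SMART) randomizes each
participant more than once: a first-stage assignment at entry, and a
second-stage assignment conditioned on an intermediate *tailoring variable*
observed some days later. Mainstream electronic data capture (EDC) systems
typically support a single randomization model per project, so running a
SMART requires an external engine that (a) queries the trial database daily
for participants who have become eligible for each stage, (b) consumes a
pre-generated allocation table, and (c) writes the assignments back.

`smartrand` is a self-contained implementation of that engine. Its shape
follows the motivating use case — a COVID-19 testing uptake trial in which
participants were first randomized to peer **navigation** or an
informational **brochure**, then, after staff assessed at one week whether
the participant had taken a COVID-19 test, re-randomized either to continue
the first-stage intervention or to switch (testers to **brief counseling**,
non-testers to a **critical dialogue** group). Everything is file-based and
deterministic, so a full trial can be replayed and audited; nothing depends
on a live EDC connection. A documented seam for wiring in a real system is
the pair `load_records()` / `write_records()` — replace them with an
export-report / import-records API client and the rest of the engine is
unchanged.

## Eligibility as declarative rules

Each stage's eligibility query is a conjunction of clauses over the
participant record, mirroring how report-based EDC queries are written:

* **Stage 1:** `approve_b == "yes"` AND `consent_2 == "yes"` AND
  `randomization1` is blank.
* **Stage 2:** `randomization1` is not blank AND `randomization2` is blank
  AND `covid_test` (the tailoring variable) is not blank AND its instrument
  is marked complete.

The rule language (`rule_clause()`) is deliberately minimal: conjunctions of
`equals` / `is_blank` / `is_not_blank` only, with case-insensitive equality
because EDC exports vary in casing. Blankness is the semantic state — a
missing cell, empty string, or whitespace-only value are all "blank". Other
trials can supply their own clause lists; the two study rule sets ship as
`stage_rules(1)` and `stage_rules(2)`.

Two conventions had to be fixed where practice is silent:

* **Report ordering.** Eligible participants are processed in ascending
  `record_id` order. Any fixed order would do; it must be *fixed* because it
  feeds straight into allocation-table consumption and therefore into which
  participant gets which row.
* **Time visibility.** The engine models the overnight batch: a run dated
  *d* sees only variables entered strictly before *d* (entry of
  approval/consent via `entry_date`, the tailoring variable via its
  assessment date). Engine-written fields are always current, which makes a
  same-day rerun a no-op. Stage 2 additionally requires the first-stage
  assignment to predate the run, so no participant ever jumps both stages in
  one morning — in the real trial this is guaranteed by the one-week
  assessment lag; here it is enforced structurally.

## Allocation tables and their consumption

Both stages consume a pre-generated, ordered allocation table, CSV on disk,
rewritten in full (atomically: temp file + rename) after every batch:

* **Stage 1 — rotation.** The eligible list is stepped through; each subject
  receives the treatment at the *top* of the table, and that row moves to
  the *bottom*. Consequently the i-th subject (0-based) of a batch stream
  receives row *i mod n* of the current order — the cyclic-slicing identity
  that the test suite uses as an independent oracle. Rotation makes
  exhaustion impossible, but a wrap-around raises a warning since tables
  should be heavily over-provisioned.
* **Stage 2 — stratified sequential scan.** Rows carry concrete criteria
  (first-stage arm × tester status). For each eligible participant the table
  is read top-down until the first row matching the participant's stratum;
  that row's treatment is assigned and exactly that row rotates to the
  bottom, preserving the relative order of all others. Wildcard criteria in
  stage-2 rows are rejected outright to prevent silent stratum bleed. A
  stratum with no matching row aborts the whole batch before anything is
  persisted — it signals a misconfigured or under-provisioned table.

Table *construction* uses permuted blocks (default block size 2), so arm
totals stay within one block of 1:1 at any stopping point even though
consumption is deterministic rotation. For stage 2 the blocks are built per
stratum and the strata interleaved by a seeded shuffle that preserves each
stratum's internal order — the scan then walks each stratum's blocked
sequence exactly in sequence. Simple randomization is available by setting
the block size equal to the table length. Within-stratum allocation is 1:1
by default.

## The daily batch and the audit log

`run_daily_batch()` performs the two passes in strict order (the study ran
them at 3:00 and 3:05 a.m.; only the ordering is semantically meaningful,
so the engine models ordering, not clock time). All assignments of a batch
are computed before anything is written; any error leaves records and
tables untouched. Every assignment appends one event (date, stage, record,
treatment, source row, stratum) to an append-only audit log, serialized as
JSON-lines. `replay_audit()` re-applies the log to the initial state and
must reproduce the final records and both tables exactly — the suite checks
this bit-for-bit across seeded simulated trials, making the audit log a
complete, machine-checkable account of engine behaviour.

The weekday **entry gate** (`gate_policy()`, default Monday–Thursday)
defers the *entry* of approval/consent so that assignments generated by the
next morning's batch never land on a weekend when staff cannot deliver the
intervention within 24 hours. It never touches assessment dates. The gate
models prevention of weekend assignments, not retrospective re-dating.

## The cohort simulator

`simulate_cohort()` generates synthetic trials with the study's flow
structure so the engine is testable end-to-end without any external data.
Defaults are the study conditions: 675 participants, all approved and
consented (the cohort is defined as those meeting all inclusion criteria),
tailoring variable assessed at enrollment + 7 days, probability 0.225 of
being a tester conditional on assessment, 4/675 chance the tailoring
variable is never entered, and exactly 3 dropouts and 2 manual delivery
overrides injected per run. Enrollment dates are uniform over a 60-day
window — an assumption; no accrual curve is published. The tester
probability is treated as conditional on assessment because the printed
percentages use the assessed count as denominator.

Anomalies follow the observed taxonomy:

* **Dropouts before the second randomization** are modeled as staff never
  completing the tailoring instrument (the record's `covid_test` stays
  blank), with a dropout date between the first assignment and the missed
  assessment. The stage-2 report therefore never captures them.
* **Missing tailoring data** arises stochastically (`p_missing_test`):
  first-randomized participants whose test information was never entered
  and who therefore never receive a second assignment.
* **Manual overrides** are applied *after* the engine runs and touch only
  `delivered_intervention`; the engine's outputs are never mutated. An
  override is detected as delivered ≠ assigned.

What the simulator does **not** emulate: intervention efficacy (testing
uptake is independent of arm — no arm-specific rates are published to
calibrate to), survey content, consent workflows, staggered staffing, or
entry errors other than the three categories above. Passing tests therefore
demonstrate the engine's allocation, gating, accounting and replay logic
under realistic flow, not behaviour under adversarial data entry.

## Flow accounting

`flow_summary()` computes the SMART flow diagram purely from record fields:
per-arm first-stage counts, the eight second-stage cells, and failures by
category. Conventions, fixed and used consistently:

* Percentages use the first-randomized total as denominator and round
  **half-up** to one decimal (matching the convention of published flow
  summaries; base R's `round()` would round half-to-even).
* `dropout_before_r2` takes precedence over `missing_tailoring`, so the
  categories partition the records lacking a second assignment.
* A record whose assessment is merely scheduled after the accounting date
  counts as *awaiting assessment*, not as missing tailoring data.
* `records_from_flow()` inverts the accounting: it builds a synthetic
  record set realizing given flow counts, which is how the suite verifies
  the accounting against a published-style flow (675 first-randomized,
  666 second-randomized, nine failures = 1.3%). In that fixture the two
  manually-overridden participants carry a hand-delivered intervention and
  no engine second assignment — the only reading under which the published
  cell sums, the stage totals and the failure taxonomy are simultaneously
  consistent.

## The power helper

`power_two_proportions()` gives two-sided power for the equal-allocation
two-sample proportion z-test (pooled variance under the null). The default
method enumerates the joint binomial distribution of the two arm counts and
sums the actual rejection region — deterministic, exact for the test as
run. The textbook first-order formula (unpooled variance under the
alternative) is available as `method = "normal"`; it was not made the
default because enumeration shows it misstates absolute power by up to
about 0.015 at a few hundred per arm, which is larger than the accuracy the
test suite demands of this helper (agreement within 0.01 with an
independent Monte-Carlo oracle). Above 2000 per arm the two methods agree
to well under 0.001 and the enumeration hands over to the formula.

The helper is generic, not a reconstruction of any particular protocol's
power statement: published power claims rarely state their baseline rate,
sidedness or attrition assumptions, and at 291 per arm a 15-point
difference near a 50% baseline yields power well above 0.85 under any of
the usual conventions.

## Numerical and engineering choices

* All randomness is confined to table generation and cohort simulation, and
  every such function takes an explicit seed, evaluated under a temporarily
  swapped RNG state so library calls never perturb the caller's RNG.
  Assignment itself is fully deterministic.
* Dates are ISO-8601 calendar dates without times; within-day ordering is
  the two-pass structure of the batch.
* File writes are atomic (temp + rename). CSV is RFC-4180 with a header;
  JSON-lines carries one object per line with blank fields omitted.
* Problem sizes in the test suite: the rotation oracle runs 1,000 random
  table/list pairs; replay and idempotency run 20 seeded trials of 30
  participants; calibration runs 50 seeded trials at the full 675; stratum
  fairness feeds 10,000 entries of one stratum through a balanced table and
  checks the 50/50 split by chi-square goodness of fit at α = 0.01; the
  power helper is checked against 100,000-replicate Monte-Carlo on a 3×3
  (p1, p2) grid at 100 and 291 per arm.

## Known limitations

* Single-site: no site stratification, though the stratum-key design would
  admit it by widening the criteria columns.
* The rule language is purely conjunctive — no OR/NOT/nesting.
* No covariate-adaptive methods (minimization, biased coin); the mechanism
  is list-based by design.
* The engine trusts its inputs' schema: it validates values and dates but
  does not reconcile against an external data dictionary.
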