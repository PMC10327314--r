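# Daily batch orchestration: gating, two-pass ordering, idempotency,
# audit replay, JSON-lines audit round-trip.

fresh_state <- function(records, seed = 1, start = "2022-01-03") {
  trial_state(records,
              generate_first_stage_table(n_rows = 40, block_size = 2,
                                         seed = seed),
              generate_second_stage_table(n_rows_per_stratum = 10,
                                          block_size = 2, seed = seed + 1),
              as.Date(start) - 1)
}

test_that("weekday gate defers entries to the next allowed day", {
  pol <- gate_policy()  # Mon-Thu
  expect_identical(apply_gate(as.Date("2022-01-04"), pol),
                   as.Date("2022-01-04"))  # Tuesday passes
  expect_identical(apply_gate(as.Date("2022-01-07"), pol),
                   as.Date("2022-01-10"))  # Friday -> Monday
  expect_identical(apply_gate(as.Date("2022-01-08"), pol),
                   as.Date("2022-01-10"))  # Saturday -> Monday
  off <- gate_policy(enabled = FALSE)
  expect_identical(apply_gate(as.Date("2022-01-07"), off),
                   as.Date("2022-01-07"))
  expect_error(gate_policy(character(), enabled = TRUE), "at least one")
  expect_error(gate_policy("Funday"), "unknown weekday")
})

test_that("a batch with nobody eligible only advances the date", {
  st <- fresh_state(make_record("R1"))  # no approval/consent
  out <- run_daily_batch(st, "2022-01-04")
  expect_identical(out$records, st$records)
  expect_identical(out$stage1_table$rows, st$stage1_table$rows)
  expect_identical(nrow(out$audit), 0L)
  expect_identical(out$current_date, as.Date("2022-01-04"))
})

test_that("stage-1 then stage-2 run in order and the audit counts match", {
  recs <- bind_records(
    make_record("A1", approve_b = "yes", consent_2 = "yes"),
    make_record("A2", approve_b = "yes", consent_2 = "yes"),
    make_record("B1", approve_b = "yes", consent_2 = "yes",
                randomization1 = "NAVIGATION",
                randomization1_date = "2022-01-03",
                covid_test = "yes", covid_test_complete = "complete",
                covid_test_assessed_date = "2022-01-03"))
  st <- fresh_state(recs)
  out <- run_daily_batch(st, "2022-01-04")
  expect_identical(nrow(out$audit), 3L)
  expect_identical(out$audit$stage, c(1L, 1L, 2L))
  got <- out$records
  expect_true(all(nzchar(got$randomization1[got$record_id %in%
                                              c("A1", "A2")])))
  expect_true(nzchar(got$randomization2[got$record_id == "B1"]))
})

test_that("running the same date twice changes nothing the second time", {
  recs <- bind_records(
    make_record("A1", approve_b = "yes", consent_2 = "yes"),
    make_record("A2", approve_b = "yes", consent_2 = "yes"))
  once <- run_daily_batch(fresh_state(recs), "2022-01-04")
  twice <- run_daily_batch(once, "2022-01-04")
  expect_identical(as.data.frame(twice$records), as.data.frame(once$records))
  expect_identical(twice$stage1_table$rows, once$stage1_table$rows)
  expect_identical(twice$audit, once$audit)
})

test_that("a subject is never second-randomized on its stage-1 day", {
  # approved, consented and already assessed: still two separate mornings
  recs <- make_record("X1", approve_b = "yes", consent_2 = "yes",
                      enrollment_date = "2022-01-03",
                      covid_test = "no", covid_test_complete = "complete",
                      covid_test_assessed_date = "2022-01-03")
  st <- run_span(fresh_state(recs, start = "2022-01-04"),
                 "2022-01-04", "2022-01-06")
  got <- st$records
  expect_identical(got$randomization1_date, as.Date("2022-01-04"))
  expect_identical(got$randomization2_date, as.Date("2022-01-05"))
  expect_identical(nrow(st$audit), 2L)
})

test_that("run_span equals the fold of daily runs", {
  recs <- simulate_cohort(simulation_params(n_participants = 25,
                                            enrollment_days = 8, seed = 4))
  span <- run_span(fresh_state(recs), "2022-01-03", "2022-01-20")
  fold <- fresh_state(recs)
  for (d in as.character(seq(as.Date("2022-01-03"), as.Date("2022-01-20"),
                             by = "day"))) {
    fold <- run_daily_batch(fold, d)
  }
  expect_identical(as.data.frame(span$records), as.data.frame(fold$records))
  expect_identical(span$audit, fold$audit)
})

test_that("gated entries never produce weekend stage-1 assignments", {
  p <- simulation_params(n_participants = 60, enrollment_days = 21,
                         seed = 12)
  sim <- run_simulated_trial(p)
  days <- weekdays(sim$state$audit$run_date[sim$state$audit$stage == 1L])
  expect_false(any(days %in% c("Saturday", "Sunday")))
  # and no record jumps both stages on one day
  recs <- sim$state$records
  both <- !is.na(recs$randomization1_date) &
    !is.na(recs$randomization2_date)
  expect_false(any(recs$randomization1_date[both] ==
                     recs$randomization2_date[both]))
})

test_that("replaying the audit reproduces records and tables exactly", {
  recs <- simulate_cohort(simulation_params(n_participants = 30,
                                            enrollment_days = 10, seed = 9))
  init <- fresh_state(recs, seed = 21)
  fin <- run_span(init, "2022-01-03", "2022-01-25")
  re <- replay_audit(init, fin$audit)
  expect_identical(as.data.frame(re$records), as.data.frame(fin$records))
  expect_identical(re$stage1_table$rows, fin$stage1_table$rows)
  expect_identical(re$stage2_table$rows, fin$stage2_table$rows)
})

test_that("audit events partition by run date with one event per stage", {
  recs <- simulate_cohort(simulation_params(n_participants = 40,
                                            enrollment_days = 15, seed = 2))
  fin <- run_span(fresh_state(recs, seed = 31), "2022-01-03", "2022-02-05")
  audit <- fin$audit
  expect_false(any(duplicated(audit[, c("record_id", "stage")])))
  expect_true(all(diff(order(audit$run_date)) > 0) ||
                !is.unsorted(audit$run_date))
})

test_that("audit log round-trips through JSON-lines", {
  recs <- bind_records(
    make_record("A1", approve_b = "yes", consent_2 = "yes",
                covid_test = "no", covid_test_complete = "complete",
                covid_test_assessed_date = "2022-01-03"))
  fin <- run_span(fresh_state(recs), "2022-01-04", "2022-01-06")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_audit(fin$audit, path)
  expect_identical(read_audit(path), fin$audit)
  write_audit(smartrand:::empty_audit(), path)
  expect_identical(nrow(read_audit(path)), 0L)
})

test_that("a missing stage-2 stratum aborts the batch without changes", {
  recs <- make_record("B1", approve_b = "yes", consent_2 = "yes",
                      randomization1 = "BROCHURE",
                      randomization1_date = "2022-01-03",
                      covid_test = "yes", covid_test_complete = "complete",
                      covid_test_assessed_date = "2022-01-03")
  bad_s2 <- smartrand:::new_allocation_table(2L, data.frame(
    sequence_id = 1L, first_arm = "NAVIGATION", test_status = "yes",
    treatment = "NAVIGATION", stringsAsFactors = FALSE))
  st <- trial_state(recs,
                    generate_first_stage_table(n_rows = 4, seed = 1),
                    bad_s2, as.Date("2022-01-03"))
  expect_error(run_daily_batch(st, "2022-01-04"),
               "no allocation row matches stratum \\(BROCHURE, yes\\)")
})
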