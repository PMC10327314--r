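# Daily two-pass batch: stage-1 eligibility report -> rotation assignment,
# then stage-2 report -> stratified assignment, with an append-only audit
# log. The study's two 3:00/3:05 a.m. jobs become two strictly ordered
# passes of one run; only the order is semantically meaningful.

AUDIT_FIELDS <- c("run_date", "stage", "record_id", "treatment",
                  "sequence_id", "stratum_first_arm", "stratum_test_status")

empty_audit <- function() {
  data.frame(run_date = as.Date(character()), stage = integer(),
             record_id = character(), treatment = character(),
             sequence_id = integer(), stratum_first_arm = character(),
             stratum_test_status = character(), stringsAsFactors = FALSE)
}

#' Weekday entry gate
#'
#' Entry of the approval/consent variables is restricted to a set of
#' weekdays (default Monday through Thursday) so that assignments generated
#' by the next morning's batch never land on a weekend, when staff cannot
#' deliver the intervention within the 24-hour window.
#'
#' @param allowed_entry_weekdays Character subset of
#'   `c("Mon","Tue","Wed","Thu","Fri","Sat","Sun")`.
#' @param enabled Logical; a disabled gate passes dates through unchanged.
#' @return A `gate_policy` list.
#' @export
gate_policy <- function(allowed_entry_weekdays = c("Mon", "Tue", "Wed",
                                                   "Thu"),
                        enabled = TRUE) {
  days <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  bad <- setdiff(allowed_entry_weekdays, days)
  if (length(bad)) {
    stop(sprintf("unknown weekday(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (enabled && length(allowed_entry_weekdays) == 0) {
    stop("an enabled gate needs at least one allowed weekday", call. = FALSE)
  }
  structure(list(allowed_entry_weekdays = allowed_entry_weekdays,
                 enabled = enabled), class = "gate_policy")
}

#' Apply the weekday entry gate to a date
#'
#' Returns `entry_date` itself when its weekday is allowed (or the gate is
#' disabled); otherwise the next allowed weekday. The gate applies only to
#' the entry of the approval/consent variables, never to assessment dates.
#'
#' @param entry_date Date (or coercible) on which staff would enter the
#'   variables.
#' @param policy A [gate_policy()].
#' @return The effective entry date.
#' @export
apply_gate <- function(entry_date, policy = gate_policy()) {
  entry_date <- as.Date(entry_date)
  if (!policy$enabled) return(entry_date)
  out <- entry_date
  for (i in seq_along(out)) {
    k <- 0L
    while (!(weekday_abbrev(out[i]) %in% policy$allowed_entry_weekdays)) {
      out[i] <- out[i] + 1L
      k <- k + 1L
      if (k > 7L) stop("gate never opens", call. = FALSE)  # unreachable
    }
  }
  out
}

#' Construct a trial state
#'
#' Bundles the participant records, the two allocation tables, the audit log
#' and the current date into the unit the daily batch advances.
#'
#' @param records A `participant_records` data frame.
#' @param stage1_table,stage2_table `allocation_table` objects of the
#'   matching stage.
#' @param current_date Date of the last completed run (start date minus one
#'   day for a fresh trial).
#' @param audit Optional existing audit log (defaults to empty).
#' @return A `trial_state`.
#' @export
trial_state <- function(records, stage1_table, stage2_table, current_date,
                        audit = empty_audit()) {
  stopifnot(inherits(stage1_table, "allocation_table"),
            inherits(stage2_table, "allocation_table"))
  if (stage1_table$stage != 1L || stage2_table$stage != 2L) {
    stop("tables passed in the wrong stage order", call. = FALSE)
  }
  structure(list(records = records, stage1_table = stage1_table,
                 stage2_table = stage2_table,
                 audit = audit, current_date = as.Date(current_date)),
            class = "trial_state")
}

#' @export
print.trial_state <- function(x, ...) {
  cat(sprintf(paste0(
    "Trial state as of %s: %d record(s), %d stage-1 and %d stage-2 ",
    "assignment(s)\n"),
    format(x$current_date), nrow(x$records),
    sum(x$audit$stage == 1L), sum(x$audit$stage == 2L)))
  invisible(x)
}

#' Run one daily randomization batch
#'
#' Executes the two passes in strict order: the stage-1 eligibility report is
#' assigned from the top of the rotating first-stage table, then the stage-2
#' report is assigned by stratified sequential scan. Assigned treatments and
#' dates are written back to the records and one audit event is appended per
#' assignment. If both reports are empty, nothing changes except the current
#' date. The batch is all-or-nothing: a stage-2 stratum with no matching
#' table row aborts the whole run, leaving the state untouched.
#'
#' @param state A [trial_state()].
#' @param date Run date; must not precede `state$current_date`.
#' @return The updated `trial_state`.
#' @export
run_daily_batch <- function(state, date) {
  stopifnot(inherits(state, "trial_state"))
  date <- as.Date(date)
  if (date < state$current_date) {
    stop("batch date precedes the trial state's current date", call. = FALSE)
  }
  records <- state$records
  audit <- state$audit

  # pass 1 (3:00): first randomization
  rep1 <- first_stage_report(records, date)
  s1_table <- state$stage1_table
  if (nrow(rep1$entries)) {
    res1 <- assign_from_table(rep1$entries$record_id, s1_table)
    s1_table <- res1$table
    idx <- match(res1$assignments$record_id, records$record_id)
    records$randomization1[idx] <- res1$assignments$treatment
    records$randomization1_date[idx] <- date
    audit <- rbind(audit, data.frame(
      run_date = date, stage = 1L,
      record_id = res1$assignments$record_id,
      treatment = res1$assignments$treatment,
      sequence_id = res1$assignments$sequence_id,
      stratum_first_arm = "", stratum_test_status = "",
      stringsAsFactors = FALSE))
  }

  # pass 2 (3:05): second randomization, stratified
  rep2 <- second_stage_report(records, date)
  s2_table <- state$stage2_table
  if (nrow(rep2$entries)) {
    eligible <- data.frame(record_id = rep2$entries$record_id,
                           first_arm = rep2$entries$randomization1,
                           test_status = rep2$entries$covid_test,
                           stringsAsFactors = FALSE)
    res2 <- assign_stratified(eligible, s2_table)
    s2_table <- res2$table
    idx <- match(res2$assignments$record_id, records$record_id)
    records$randomization2[idx] <- res2$assignments$treatment
    records$randomization2_date[idx] <- date
    audit <- rbind(audit, data.frame(
      run_date = date, stage = 2L,
      record_id = res2$assignments$record_id,
      treatment = res2$assignments$treatment,
      sequence_id = res2$assignments$sequence_id,
      stratum_first_arm = res2$assignments$first_arm,
      stratum_test_status = res2$assignments$test_status,
      stringsAsFactors = FALSE))
  }

  trial_state(records, s1_table, s2_table, date, audit)
}

#' Run a span of daily batches
#'
#' Folds [run_daily_batch()] over every date from `start_date` to `end_date`
#' inclusive (the daily cadence; run it over a thinned date sequence to model
#' a less frequent schedule).
#'
#' @param state A [trial_state()].
#' @param start_date,end_date Inclusive date range, `start_date <= end_date`.
#' @return The updated `trial_state`.
#' @export
run_span <- function(state, start_date, end_date) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (start_date > end_date) {
    stop("start_date is after end_date", call. = FALSE)
  }
  for (d in seq(start_date, end_date, by = "day")) {
    state <- run_daily_batch(state, as.Date(d, origin = "1970-01-01"))
  }
  state
}

#' Replay an audit log over an initial state
#'
#' Re-applies every assignment event in order: writes the treatment and date
#' to the record and rotates the originating table row (located by
#' `sequence_id`) to the bottom. Replaying the audit of a finished trial
#' over its initial state reproduces the final records and both tables
#' exactly - the audit log is a complete account of everything the engine
#' did.
#'
#' @param state The initial [trial_state()] (before any batch ran).
#' @param audit An audit data frame as produced by the scheduler.
#' @return A `trial_state` with records and tables as after the logged runs.
#' @export
replay_audit <- function(state, audit) {
  stopifnot(inherits(state, "trial_state"))
  records <- state$records
  s1 <- state$stage1_table$rows
  s2 <- state$stage2_table$rows
  rotate <- function(rows, sequence_id) {
    j <- which(rows$sequence_id == sequence_id)
    if (length(j) != 1) {
      stop(sprintf("audit references unknown sequence_id %d", sequence_id),
           call. = FALSE)
    }
    rbind(rows[-j, , drop = FALSE], rows[j, , drop = FALSE])
  }
  for (i in seq_len(nrow(audit))) {
    ev <- audit[i, ]
    idx <- match(ev$record_id, records$record_id)
    if (is.na(idx)) {
      stop(sprintf("audit references unknown record %s", ev$record_id),
           call. = FALSE)
    }
    if (ev$stage == 1L) {
      records$randomization1[idx] <- ev$treatment
      records$randomization1_date[idx] <- as.Date(ev$run_date)
      s1 <- rotate(s1, ev$sequence_id)
    } else {
      records$randomization2[idx] <- ev$treatment
      records$randomization2_date[idx] <- as.Date(ev$run_date)
      s2 <- rotate(s2, ev$sequence_id)
    }
  }
  rownames(s1) <- NULL
  rownames(s2) <- NULL
  end_date <- if (nrow(audit)) max(as.Date(audit$run_date)) else
    state$current_date
  trial_state(records,
              structure(list(stage = 1L, rows = s1),
                        class = "allocation_table"),
              structure(list(stage = 2L, rows = s2),
                        class = "allocation_table"),
              end_date, audit)
}

#' Read / write the audit log as JSON-lines
#'
#' One object per assignment event, append-only. The stratum fields are
#' omitted for stage-1 events.
#'
#' @param audit Audit data frame.
#' @param path File path.
#' @return `read_audit` returns the audit data frame.
#' @export
write_audit <- function(audit, path) {
  write_atomic(function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(audit))) {
      ev <- list(run_date = format_iso_date(audit$run_date[i]),
                 stage = audit$stage[i],
                 record_id = audit$record_id[i],
                 treatment = audit$treatment[i],
                 sequence_id = audit$sequence_id[i])
      if (audit$stage[i] == 2L) {
        ev$stratum_first_arm <- audit$stratum_first_arm[i]
        ev$stratum_test_status <- audit$stratum_test_status[i]
      }
      writeLines(jsonlite::toJSON(ev, auto_unbox = TRUE), con)
    }
  }, path)
  invisible(NULL)
}

#' @rdname write_audit
#' @export
read_audit <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_audit())
  rows <- lapply(lines, function(l) {
    o <- jsonlite::fromJSON(l)
    data.frame(run_date = as.Date(o$run_date), stage = as.integer(o$stage),
               record_id = as.character(o$record_id),
               treatment = as.character(o$treatment),
               sequence_id = as.integer(o$sequence_id),
               stratum_first_arm = if (is.null(o$stratum_first_arm)) "" else
                 o$stratum_first_arm,
               stratum_test_status = if (is.null(o$stratum_test_status)) ""
                 else o$stratum_test_status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
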