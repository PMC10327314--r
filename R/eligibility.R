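# Declarative eligibility rules: conjunctions of (field, operator, value)
# clauses over participant records, mirroring report-based EDC queries.

#' Build a rule clause
#'
#' @param field A participant record field name.
#' @param operator One of `"equals"`, `"is_blank"`, `"is_not_blank"`.
#' @param value Comparison literal; required for `"equals"` only. Equality is
#'   case-insensitive (EDC exports vary in casing).
#' @return A `rule_clause` list.
#' @export
rule_clause <- function(field, operator = c("equals", "is_blank",
                                            "is_not_blank"), value = NULL) {
  operator <- match.arg(operator)
  if (operator == "equals" && is.null(value)) {
    stop("'equals' clauses need a value", call. = FALSE)
  }
  structure(list(field = field, operator = operator, value = value),
            class = "rule_clause")
}

#' Default stage-specific rule sets
#'
#' Stage 1 pulls all records where approval and consent are both "yes" and no
#' first-stage assignment exists. Stage 2 pulls all records with a
#' first-stage assignment, no second-stage assignment, a non-blank tailoring
#' variable (COVID-19 test taken yes/no) and its instrument marked complete.
#'
#' @param stage 1 or 2.
#' @return List of [rule_clause()] objects (a conjunction).
#' @export
stage_rules <- function(stage) {
  if (stage == 1) {
    list(rule_clause("approve_b", "equals", "yes"),
         rule_clause("consent_2", "equals", "yes"),
         rule_clause("randomization1", "is_blank"))
  } else if (stage == 2) {
    list(rule_clause("randomization1", "is_not_blank"),
         rule_clause("randomization2", "is_blank"),
         rule_clause("covid_test", "is_not_blank"),
         rule_clause("covid_test_complete", "equals", "complete"))
  } else {
    stop("stage must be 1 or 2", call. = FALSE)
  }
}

#' Evaluate a clause conjunction over records
#'
#' @param records A `participant_records` data frame.
#' @param clauses Non-empty list of [rule_clause()] objects, AND-joined.
#' @return Logical vector, one element per record.
#' @export
evaluate_rule <- function(records, clauses) {
  if (length(clauses) == 0) stop("empty clause list", call. = FALSE)
  hit <- rep(TRUE, nrow(records))
  for (cl in clauses) {
    if (!cl$field %in% names(records)) {
      stop(sprintf("rule references unknown field '%s'", cl$field),
           call. = FALSE)
    }
    x <- records[[cl$field]]
    hit <- hit & switch(cl$operator,
      equals = !is_blank(x) &
        tolower(as.character(x)) == tolower(as.character(cl$value)),
      is_blank = is_blank(x),
      is_not_blank = !is_blank(x))
  }
  hit
}

# Mask a record set down to what the 3 a.m. batch on `date` can see:
# variables entered on or after the run date are still invisible.
# approve_b/consent_2 become visible the day after entry_date; the tailoring
# variable the day after its assessment date. Engine-written fields
# (randomization1/2) are always current - within-day idempotency relies on
# them.
records_as_of <- function(records, date) {
  hide_entry <- is.na(records$entry_date) | records$entry_date >= date
  records$approve_b[hide_entry] <- ""
  records$consent_2[hide_entry] <- ""
  hide_test <- is.na(records$covid_test_assessed_date) |
    records$covid_test_assessed_date >= date
  records$covid_test[hide_test] <- ""
  records$covid_test_complete[hide_test] <- "incomplete"
  records
}

new_eligibility_report <- function(stage, as_of_date, entries) {
  structure(list(stage = stage, as_of_date = as.Date(as_of_date),
                 entries = entries),
            class = "eligibility_report")
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat(sprintf("Stage-%d eligibility report, as of %s: %d record(s)\n",
              x$stage, format(x$as_of_date), nrow(x$entries)))
  if (nrow(x$entries)) print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Daily first-stage eligibility report
#'
#' Records approved and consented (entered before `as_of_date`) that have no
#' first-stage assignment yet, ordered by `record_id` ascending. The report
#' carries only the record IDs and the evaluated criteria fields.
#'
#' @param records A `participant_records` data frame.
#' @param as_of_date Run date of the batch.
#' @return An `eligibility_report` (stage 1).
#' @export
first_stage_report <- function(records, as_of_date) {
  as_of_date <- as.Date(as_of_date)
  visible <- records_as_of(records, as_of_date)
  hit <- evaluate_rule(visible, stage_rules(1))
  entries <- visible[hit, c("record_id", "approve_b", "consent_2",
                            "randomization1")]
  entries <- entries[order(entries$record_id), , drop = FALSE]
  rownames(entries) <- NULL
  new_eligibility_report(1L, as_of_date, as.data.frame(entries))
}

#' Daily second-stage eligibility report
#'
#' Records with a first-stage assignment made before `as_of_date`, no
#' second-stage assignment, and a tailoring variable assessed (instrument
#' complete) before `as_of_date`. The criteria snapshot includes
#' `randomization1` and `covid_test`, which downstream stratified assignment
#' matches on. The strict "before the run date" requirement on
#' `randomization1_date` means a participant first-randomized today is never
#' second-randomized the same day.
#'
#' @inheritParams first_stage_report
#' @return An `eligibility_report` (stage 2).
#' @export
second_stage_report <- function(records, as_of_date) {
  as_of_date <- as.Date(as_of_date)
  visible <- records_as_of(records, as_of_date)
  hit <- evaluate_rule(visible, stage_rules(2))
  hit <- hit & !is.na(visible$randomization1_date) &
    visible$randomization1_date < as_of_date
  entries <- visible[hit, c("record_id", "randomization1", "covid_test",
                            "covid_test_complete", "randomization2")]
  entries <- entries[order(entries$record_id), , drop = FALSE]
  rownames(entries) <- NULL
  new_eligibility_report(2L, as_of_date, as.data.frame(entries))
}
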