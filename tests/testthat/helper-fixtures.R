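# Shared fixture builders. Everything is generated in code; no stored data.

# One participant record with sensible defaults, overridable per field.
make_record <- function(record_id = "R001", ...) {
  defaults <- list(record_id = record_id,
                   enrollment_date = "2022-01-03",
                   approve_b = "", consent_2 = "",
                   randomization1 = "", randomization1_date = "",
                   covid_test = "", covid_test_complete = "",
                   covid_test_assessed_date = "",
                   randomization2 = "", randomization2_date = "",
                   delivered_intervention = "", dropout_date = "")
  args <- utils::modifyList(defaults, list(...))
  participant_records(as.data.frame(args, stringsAsFactors = FALSE))
}

bind_records <- function(...) {
  parts <- lapply(list(...), as.data.frame)
  participant_records(do.call(rbind, parts))
}

# The eight second-stage cells of the motivating study's flow diagram.
results_cells <- function() {
  data.frame(
    first_arm = rep(c("NAVIGATION", "BROCHURE"), each = 4),
    test_status = rep(c("yes", "yes", "no", "no"), 2),
    second_arm = c("NAVIGATION", "BRIEF_COUNSELING",
                   "NAVIGATION", "CRITICAL_DIALOGUE",
                   "BROCHURE", "BRIEF_COUNSELING",
                   "BROCHURE", "CRITICAL_DIALOGUE"),
    n = c(41, 35, 124, 130, 36, 32, 131, 137),
    stringsAsFactors = FALSE)
}

results_records <- function() {
  records_from_flow(c(NAVIGATION = 333, BROCHURE = 342), results_cells(),
                    n_dropout = 3, n_missing = 4, n_override = 2)
}

# A small stage-1 table with a fixed treatment sequence (no randomness).
fixed_stage1_table <- function(treatments) {
  smartrand:::new_allocation_table(1L, data.frame(
    sequence_id = seq_along(treatments),
    first_arm = character(length(treatments)),
    test_status = character(length(treatments)),
    treatment = treatments, stringsAsFactors = FALSE))
}

fixed_stage2_table <- function(first_arm, test_status, treatment) {
  smartrand:::new_allocation_table(2L, data.frame(
    sequence_id = seq_along(treatment), first_arm = first_arm,
    test_status = test_status, treatment = treatment,
    stringsAsFactors = FALSE))
}

# Random record set for property-style report tests.
random_records <- function(n, seed) {
  set.seed(seed)
  yn <- function() sample(c("yes", "no", ""), n, replace = TRUE)
  r1 <- sample(c(arm_labels(1), ""), n, replace = TRUE)
  has_r1 <- nzchar(r1)
  r2 <- ifelse(has_r1 & runif(n) < 0.3,
               sample(arm_labels(2), n, replace = TRUE), "")
  covid <- yn()
  enroll <- as.Date("2022-01-03") + sample(0:20, n, replace = TRUE)
  participant_records(data.frame(
    record_id = sprintf("Q%03d", sample(n)),
    enrollment_date = enroll,
    entry_date = enroll,
    approve_b = yn(), consent_2 = yn(),
    randomization1 = r1,
    randomization1_date = as.Date(ifelse(has_r1, format(enroll + 1),
                                         NA)),
    covid_test = covid,
    covid_test_complete = ifelse(nzchar(covid), "complete", "incomplete"),
    covid_test_assessed_date = as.Date(ifelse(nzchar(covid),
                                              format(enroll + 7), NA)),
    randomization2 = r2,
    randomization2_date = as.Date(ifelse(nzchar(r2), format(enroll + 8),
                                         NA)),
    stringsAsFactors = FALSE))
}
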