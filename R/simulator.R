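# Synthetic SMART cohort simulator. Emulates the motivating trial's flow:
# enrollment over a window, approval + consent entered under the weekday
# gate, first randomization the next morning, tailoring variable (COVID-19
# test taken yes/no) assessed by staff 7 days after enrollment, second
# randomization the morning after assessment, plus the observed anomaly
# taxonomy (dropouts before the second randomization, tailoring data never
# entered, manual delivery overrides).

#' Simulation parameters
#'
#' Defaults reproduce the study conditions of the motivating COVID-19
#' testing SMART: 675 participants enrolled over roughly nine working weeks,
#' everyone approved and consented (the cohort is defined as those who met
#' all inclusion criteria), a 22.5% tester rate conditional on assessment,
#' 4/675 records whose tailoring variable is never entered, 3 dropouts
#' before the second randomization, 2 manual delivery overrides, a 7-day
#' assessment lag and a Monday-Thursday entry gate.
#'
#' @param n_participants Cohort size.
#' @param enrollment_start First enrollment date.
#' @param enrollment_days Length of the enrollment window in days.
#' @param p_approve,p_consent Probability that `approve_b` / `consent_2` is
#'   entered as "yes".
#' @param p_test Probability the tailoring variable is "yes" (took the
#'   test), conditional on being assessed.
#' @param p_missing_test Probability the tailoring variable is never
#'   entered (instrument stays incomplete).
#' @param n_dropout_before_r2 Exact number of dropouts injected between
#'   first randomization and assessment.
#' @param n_manual_override Exact number of post-hoc delivery overrides.
#' @param assessment_lag_days Days from enrollment to staff assessment of
#'   the tailoring variable (>= 1).
#' @param gate A [gate_policy()] applied to the entry of approval/consent.
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(n_participants = 675,
                              enrollment_start = as.Date("2022-01-03"),
                              enrollment_days = 60,
                              p_approve = 1, p_consent = 1,
                              p_test = 0.225,
                              p_missing_test = 4 / 675,
                              n_dropout_before_r2 = 3,
                              n_manual_override = 2,
                              assessment_lag_days = 7,
                              gate = gate_policy(),
                              seed = 1) {
  p <- list(n_participants = as.integer(n_participants),
            enrollment_start = as.Date(enrollment_start),
            enrollment_days = as.integer(enrollment_days),
            p_approve = p_approve, p_consent = p_consent,
            p_test = p_test, p_missing_test = p_missing_test,
            n_dropout_before_r2 = as.integer(n_dropout_before_r2),
            n_manual_override = as.integer(n_manual_override),
            assessment_lag_days = as.integer(assessment_lag_days),
            gate = gate, seed = as.integer(seed))
  probs <- c(p$p_approve, p$p_consent, p$p_test, p$p_missing_test)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p$n_participants < 0 || p$enrollment_days < 1 ||
      p$assessment_lag_days < 1) {
    stop("invalid cohort size, window or assessment lag", call. = FALSE)
  }
  if (p$n_dropout_before_r2 > p$n_participants ||
      p$n_manual_override > p$n_participants) {
    stop("anomaly counts exceed the cohort size", call. = FALSE)
  }
  structure(p, class = "simulation_params")
}

#' Simulate a SMART cohort (pre-randomization)
#'
#' Enrollment dates are uniform over the window; the approval/consent entry
#' date is the enrollment date pushed through the weekday gate. For
#' approved + consented participants the tailoring variable is assessed at
#' enrollment + lag: with probability `p_missing_test` it is never entered
#' (instrument stays incomplete), otherwise it is "yes" with probability
#' `p_test`. All randomization fields are left blank - the engine fills
#' them.
#'
#' @param params A [simulation_params()].
#' @return A `participant_records` data frame.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  n <- params$n_participants
  withr_seed(params$seed, {
    enroll <- params$enrollment_start +
      sample.int(params$enrollment_days, n, replace = TRUE) - 1L
    enroll <- sort(enroll)
    entry <- apply_gate(enroll, params$gate)
    approve <- ifelse(stats::runif(n) < params$p_approve, "yes", "no")
    consent <- ifelse(stats::runif(n) < params$p_consent, "yes", "no")
    assessed_pool <- approve == "yes" & consent == "yes"
    missing_test <- assessed_pool & stats::runif(n) < params$p_missing_test
    assessed <- assessed_pool & !missing_test
    covid <- character(n)
    covid[assessed] <- ifelse(stats::runif(sum(assessed)) < params$p_test,
                              "yes", "no")
    complete <- ifelse(assessed, "complete", "incomplete")
    assess_date <- rep(as.Date(NA), n)
    assess_date[assessed] <- enroll[assessed] + params$assessment_lag_days
    participant_records(data.frame(
      record_id = sprintf("P%04d", seq_len(n)),
      enrollment_date = enroll, entry_date = entry,
      approve_b = approve, consent_2 = consent,
      covid_test = covid, covid_test_complete = complete,
      covid_test_assessed_date = assess_date,
      stringsAsFactors = FALSE))
  })
}

#' Inject protocol anomalies into a cohort
#'
#' Two phases, selected by when the engine runs relative to the injection:
#' \describe{
#'   \item{`"pre"`}{(before the engine) picks exactly
#'     `n_dropout_before_r2` assessed-to-be participants and turns them into
#'     dropouts: the tailoring instrument is never completed (so the stage-2
#'     report never captures them) and `dropout_date` falls between the
#'     first randomization and the scheduled assessment.}
#'   \item{`"post"`}{(after the engine) picks exactly `n_manual_override`
#'     second-randomized participants and records a delivered intervention
#'     different from the assigned one. Engine outputs are never mutated;
#'     every other second-randomized record gets
#'     `delivered_intervention == randomization2`.}
#' }
#' Selection is seeded and reproducible.
#'
#' @param records A `participant_records` data frame.
#' @param params A [simulation_params()].
#' @param phase `"pre"` or `"post"`.
#' @return The modified record set.
#' @export
inject_anomalies <- function(records, params, phase = c("pre", "post")) {
  phase <- match.arg(phase)
  stopifnot(inherits(params, "simulation_params"))
  if (phase == "pre") {
    k <- params$n_dropout_before_r2
    if (k == 0) return(records)
    hosts <- which(records$approve_b == "yes" & records$consent_2 == "yes" &
                     nzchar(records$covid_test))
    if (length(hosts) < k) {
      stop(sprintf("need %d dropout hosts, only %d assessed records", k,
                   length(hosts)), call. = FALSE)
    }
    pick <- withr_seed(params$seed + 1L, sample(hosts, k))
    # first randomization lands the morning after entry; dropout falls
    # strictly between it and the scheduled assessment
    r1_expected <- records$entry_date[pick] + 1L
    assess <- records$enrollment_date[pick] + params$assessment_lag_days
    records$dropout_date[pick] <- pmin(r1_expected + 1L, assess - 1L)
    records$covid_test[pick] <- ""
    records$covid_test_complete[pick] <- "incomplete"
    records$covid_test_assessed_date[pick] <- as.Date(NA)
  } else {
    k <- params$n_manual_override
    assigned <- which(nzchar(records$randomization2))
    records$delivered_intervention[assigned] <-
      records$randomization2[assigned]
    if (k == 0) return(records)
    if (length(assigned) < k) {
      stop(sprintf("need %d override hosts, only %d second-randomized", k,
                   length(assigned)), call. = FALSE)
    }
    pick <- withr_seed(params$seed + 2L, sample(assigned, k))
    for (i in pick) {
      others <- setdiff(arm_labels(2), records$randomization2[i])
      swap <- withr_seed(params$seed + 2L + i, sample(others, 1))
      records$delivered_intervention[i] <- swap
    }
  }
  records
}

#' Run a fully simulated SMART end-to-end
#'
#' Builds the cohort, injects the pre-engine anomalies, generates both
#' allocation tables (permuted blocks, over-provisioned to at least twice
#' the cohort size), runs the daily batch over the enrollment window plus
#' the assessment lag (plus slack so every assessed participant is
#' captured), applies the post-hoc overrides, and returns the final state
#' with its flow accounting. Fully deterministic given `params$seed`.
#'
#' @param params A [simulation_params()].
#' @return `list(state, flow)`: the final [trial_state()] and a
#'   [flow_counts()] summary.
#' @export
run_simulated_trial <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  cohort <- simulate_cohort(params)
  cohort <- inject_anomalies(cohort, params, "pre")
  n <- max(params$n_participants, 1L)
  n1 <- 2L * as.integer(ceiling(n / 2)) * 2L        # >= 2n, multiple of 2
  nps <- 2L * as.integer(ceiling(n / 4))            # 4 strata, >= 2n total
  s1 <- generate_first_stage_table(n_rows = n1, block_size = 2,
                                   seed = params$seed + 101L)
  s2 <- generate_second_stage_table(n_rows_per_stratum = nps, block_size = 2,
                                    seed = params$seed + 102L)
  start <- params$enrollment_start
  end <- start + params$enrollment_days + params$assessment_lag_days + 7L
  state <- trial_state(cohort, s1, s2, start - 1L)
  state <- run_span(state, start, end)
  state$records <- inject_anomalies(state$records, params, "post")
  flow <- flow_summary(state$records, as_of_date = end)
  list(state = state, flow = flow)
}
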